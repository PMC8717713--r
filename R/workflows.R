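# End-to-end orchestration and the command-line surface.

default_config <- function() {
  list(mode = "experiment", dims = "2d", tracer = "fdg", n = 32,
       N_S = 10, N_B = 10, seed = 1L, dose_mult = 1,
       with_projection = FALSE, with_recycle = FALSE,
       N_B_star = 10, N_tilde = 200, out_dir = "petboot_out",
       target_noise = 0.15, L_bins = 64L, reconstruction = "fbp")
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$dims %in% c("1d", "2d"),
            cfg$tracer %in% c("fdg", "flt"),
            cfg$reconstruction %in% c("fbp", "ml"),
            cfg$n >= 8, cfg$N_S >= 2, cfg$N_B >= 2,
            cfg$dose_mult > 0, cfg$target_noise > 0)
  cfg
}

#' Run a full simulate-scan-fit-bootstrap-evaluate experiment
#'
#' Phantom -> scan -> reconstruct -> GLM fit -> bootstraps -> kinetic maps
#' and SD maps -> calibration tables, writing every artifact with a
#' manifest (config, seed, file list) to the output directory.
#'
#' @param config named list overriding the defaults (see
#'   `petboot:::default_config()`): `dims` ("2d"/"1d"), `tracer`, `n`,
#'   `N_S`, `N_B`, `seed`, `out_dir`, ...
#' @return the manifest (invisibly also written as JSON).
#' @export
run_full_experiment <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  res <- if (cfg$dims == "2d") {
    stage("experiment_2d",
          experiment_2d(n = cfg$n, N_S = cfg$N_S, N_B = cfg$N_B,
                        tracer_style = cfg$tracer, seed = cfg$seed,
                        target_noise = cfg$target_noise,
                        dose_mult = cfg$dose_mult,
                        with_projection = cfg$with_projection,
                        with_recycle = cfg$with_recycle,
                        N_B_star = cfg$N_B_star, N_tilde = cfg$N_tilde,
                        L_bins = cfg$L_bins))
  } else {
    stage("experiment_1d",
          experiment_1d(n = cfg$n, N_S = cfg$N_S, N_B = cfg$N_B,
                        tracer_style = cfg$tracer,
                        reconstruction = cfg$reconstruction,
                        seed = cfg$seed, target_noise = cfg$target_noise,
                        dose_mult = cfg$dose_mult, L_bins = cfg$L_bins))
  }
  files <- character(0)
  wr <- function(obj, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
    files <<- c(files, path)
  }
  stage("outputs", {
    wr(res$true_sd, "true_sd.csv")
    wr(res$true_mean, "true_mean.csv")
    wr(res$boot_sd, "bootstrap_sd.csv")
    if (!is.null(res$proj_sd)) wr(res$proj_sd, "projection_sd.csv")
    if (!is.null(res$recycle_sd)) wr(res$recycle_sd, "recycle_sd.csv")
    fit_path <- file.path(cfg$out_dir, "glm_fit.rds")
    save_fit(res$fit, fit_path)
    files <<- c(files, fit_path)
    cal <- lapply(KINETIC_PARAMS, function(p) {
      cc <- calibrate(res$true_sd[, p], res$boot_sd[, p])
      data.frame(parameter = p, slope = cc$slope,
                 r_squared = cc$r_squared, n = cc$n)
    })
    wr(do.call(rbind, cal), "calibration.csv")
  })
  manifest <- list(config = cfg, seed = cfg$seed, files = files,
                   tau = res$tau, bandwidth = res$bandwidth)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `fit`, `bootstrap`, `simulate`, `experiment`.  Invoke via
#' `Rscript -e 'petboot::petboot_cli()' <subcommand> --key value ...`, or
#' through the wrapper script in `inst/cli/petboot`.
#'
#' @param args character vector (default: the command line).
#' @return exit code: 0 success, 2 validation error, 3 numerical failure.
#' @export
petboot_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: petboot <experiment|fit|bootstrap|simulate> [--key value ...]",
    "  experiment --dims 2d|1d --tracer fdg|flt --n 32 --n-s 10 --n-b 10",
    "             --seed 1 --out-dir DIR [--config FILE.json]",
    "  fit        --image FILE.nii --schedule FILE.csv --basis FILE.csv",
    "             --out FILE.rds",
    "  bootstrap  --fit FILE.rds --kind image --n-reps 25 --seed 1",
    "             --out-dir DIR",
    "  simulate   --mode 2d|1d --tracer fdg|flt --n 32 --seed 1 --out-dir DIR",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opts <- list()
  kv <- args[-1]
  i <- 1L
  while (i <= length(kv)) {
    if (!startsWith(kv[i], "--")) {
      message("unexpected argument: ", kv[i]); return(invisible(2L))
    }
    key <- gsub("-", "_", sub("^--", "", kv[i]))
    opts[[key]] <- kv[i + 1L]
    i <- i + 2L
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  code <- tryCatch({
    switch(cmd,
      experiment = {
        cfg <- list()
        if (!is.null(opts$config)) cfg <- jsonlite::read_json(opts$config)
        override <- list(dims = opts$dims, tracer = opts$tracer,
                         n = num(opts$n), N_S = num(opts$n_s),
                         N_B = num(opts$n_b), seed = num(opts$seed),
                         out_dir = opts$out_dir,
                         dose_mult = num(opts$dose_mult))
        cfg <- utils::modifyList(cfg, Filter(Negate(is.null), override))
        run_full_experiment(cfg)
        0L
      },
      fit = {
        study <- load_dynamic_study(opts$image, opts$schedule)
        X <- as.matrix(utils::read.csv(opts$basis))
        fit <- fit_glm(study, temporal_basis(X))
        save_fit(fit, opts$out %||% "glm_fit.rds")
        0L
      },
      bootstrap = {
        fit <- load_fit(opts$fit)
        n_reps <- as.integer(num(opts$n_reps) %||% 25)
        seed <- as.integer(num(opts$seed) %||% 1)
        bs <- switch(opts$kind %||% "image",
          image = image_bootstrap(fit, n_reps, seed),
          stop("CLI bootstrap supports --kind image; use the R API for ",
               "projection/recycle"))
        dir.create(opts$out_dir %||% ".", showWarnings = FALSE,
                   recursive = TRUE)
        saveRDS(bs, file.path(opts$out_dir %||% ".", "bootstrap.rds"))
        0L
      },
      simulate = {
        ph <- make_phantom(opts$mode %||% "2d", opts$tracer %||% "fdg",
                           n = as.integer(num(opts$n) %||% 32),
                           seed = as.integer(num(opts$seed) %||% 1))
        dir.create(opts$out_dir %||% ".", showWarnings = FALSE,
                   recursive = TRUE)
        saveRDS(ph, file.path(opts$out_dir %||% ".", "phantom.rds"))
        0L
      },
      { message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("validation|must be|needs|unsupported", conditionMessage(e)))
      2L else 3L
  })
  invisible(code)
}
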