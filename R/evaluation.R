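# Replication truth, bootstrap calibration regressions, RMSE summaries,
# ROI analysis, the relative-error model, and the end-to-end 2-D and 1-D
# validation experiments.

#' No-intercept calibration regression
#'
#' Least-squares slope through the origin of `true_sd` on `est_sd`
#' (`sigma_true ~ slope * sigma_est`) with the uncentered coefficient of
#' determination.  A slope above 1 means the bootstrap under-estimates the
#' true standard deviation; below 1, over-estimation.
#'
#' @param true_sd,est_sd positive vectors of equal length (non-finite pairs
#'   dropped).
#' @return list with `slope`, `r_squared`, `n`.
#' @export
calibrate <- function(true_sd, est_sd) {
  ok <- is.finite(true_sd) & is.finite(est_sd)
  x <- est_sd[ok]; y <- true_sd[ok]
  if (!length(x) || all(x == 0)) stop("degenerate all-zero predictor")
  slope <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  list(slope = slope, r_squared = r2, n = length(x))
}

#' RMSE of bootstrap standard-deviation estimates
#'
#' `RMSE = sqrt(mean over voxels and replicates of (sigma_hat - sigma)^2)`,
#' also expressed as a percentage of a scale (typically the maximum of the
#' replicate-averaged parameter map).
#'
#' @param est_sd N x S matrix (bootstrap SD per voxel per replicate) or a
#'   vector (S = 1).
#' @param true_sd length-N true SDs.
#' @param scale positive scalar for the percentage form.
#' @return list with `rmse` and `rmse_pct`.
#' @export
rmse_table <- function(est_sd, true_sd, scale = NA_real_) {
  est_sd <- as.matrix(est_sd)
  stopifnot(nrow(est_sd) == length(true_sd))
  d2 <- (est_sd - true_sd)^2
  rmse <- sqrt(mean(d2[is.finite(d2)]))
  list(rmse = rmse, rmse_pct = 100 * rmse / scale)
}

#' Relative-error versus reconstruction-error regression
#'
#' Fits `log(sigma_p / mu_p) = gamma0 + gamma1 log(sigma_R / mu_p) + err`
#' across voxels by ordinary least squares.
#'
#' @param sigma_p true (or bootstrap) parameter SDs per voxel.
#' @param mu_p parameter means per voxel.
#' @param sigma_R per-voxel reconstruction error.
#' @return list with `gamma0`, `gamma1`, `r_squared`, `n`.
#' @export
relative_error_model <- function(sigma_p, mu_p, sigma_R) {
  ok <- is.finite(sigma_p) & is.finite(mu_p) & is.finite(sigma_R) &
    sigma_p > 0 & mu_p > 0 & sigma_R > 0
  if (sum(ok) < 10L) stop("fewer than 10 valid voxels")
  y <- log(sigma_p[ok] / mu_p[ok])
  x <- log(sigma_R[ok] / mu_p[ok])
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(gamma0 = unname(coef(fit)[1]), gamma1 = unname(coef(fit)[2]),
       r_squared = r2, n = sum(ok))
}

#' Nested rectangular ROI grids
#'
#' Partitions an n x n image into square blocks at several block sizes;
#' blocks overlapping the support mask (majority inside) become ROIs.
#'
#' @param n image side.
#' @param block_sizes block sides in pixels.
#' @param support optional logical mask; an ROI is kept when at least half
#'   its pixels are inside.
#' @return object of class `roi_set`: list `rois` of voxel-index vectors,
#'   `sizes` (block size per ROI).
#' @export
roi_grid <- function(n, block_sizes = c(4L, 8L, 16L), support = NULL) {
  rois <- list(); sizes <- integer(0)
  for (bs in block_sizes) {
    nb <- n %/% bs
    for (by in seq_len(nb)) for (bx in seq_len(nb)) {
      xs <- ((bx - 1L) * bs + 1L):(bx * bs)
      ys <- ((by - 1L) * bs + 1L):(by * bs)
      idx <- as.integer(outer(xs, (ys - 1L) * n, "+"))
      if (!is.null(support) && mean(support[idx]) < 0.5) next
      rois[[length(rois) + 1L]] <- idx
      sizes <- c(sizes, bs)
    }
  }
  if (!length(rois)) stop("no ROIs intersect the support")
  structure(list(rois = rois, sizes = sizes), class = "roi_set")
}

roi_means <- function(map_vec, roi) {
  vapply(roi$rois, function(idx) mean(map_vec[idx], na.rm = TRUE), 0)
}

#' ROI-level calibration of bootstrap standard errors
#'
#' Replaces the voxel index by an ROI index: parameter maps are averaged
#' over each ROI per replicate, true and bootstrap SDs of the ROI means are
#' formed across replicates, and the no-intercept calibration and RMSE are
#' evaluated, overall and stratified by ROI size.
#'
#' @param true_maps list of per-replicate parameter vectors (one parameter).
#' @param boot_maps list of per-replicate parameter vectors from a
#'   bootstrap set.
#' @param roi a [roi_grid()] result.
#' @return list with `slope`, `r_squared`, `rmse`, `by_size` (data frame),
#'   `true_sd`, `boot_sd`.
#' @export
roi_analysis <- function(true_maps, boot_maps, roi) {
  nr <- length(roi$rois)
  tm <- matrix(vapply(true_maps, roi_means, numeric(nr), roi = roi), nr)
  bm <- matrix(vapply(boot_maps, roi_means, numeric(nr), roi = roi), nr)
  true_sd <- apply(tm, 1, stats::sd)
  boot_sd <- apply(bm, 1, stats::sd)
  cal <- calibrate(true_sd, boot_sd)
  by_size <- do.call(rbind, lapply(unique(roi$sizes), function(bs) {
    sel <- roi$sizes == bs
    c2 <- calibrate(true_sd[sel], boot_sd[sel])
    data.frame(size = bs, slope = c2$slope, r_squared = c2$r_squared,
               n = c2$n)
  }))
  list(slope = cal$slope, r_squared = cal$r_squared,
       rmse = rmse_table(boot_sd, true_sd)$rmse,
       by_size = by_size, true_sd = true_sd, boot_sd = boot_sd)
}

#' Replication truth for a simulated scanner
#'
#' Simulates, scans and reconstructs `N_S` independent replicates of a
#' phantom through a caller-supplied pipeline, maps kinetics on each, and
#' returns the across-replicate standard deviation (the target the
#' bootstraps are judged against), the mean maps, and the per-voxel
#' weighted reconstruction error
#' `sigma_R = sqrt(sum_j w0_j (z_ij - lambda_ij)^2 / T)`.
#'
#' @param phantom a [make_phantom()] result.
#' @param simulate_recon function(seed) returning one reconstructed N x T
#'   replicate.
#' @param N_S number of replicates (>= 2).
#' @param w0 per-frame weights for the kinetic fits.
#' @param seed master seed.
#' @param T_B vascular bound for the kinetic summaries.
#' @return list with `sd`, `mean` (N x 6), `recon_err` (length N), `maps`.
#' @export
replication_truth <- function(phantom, simulate_recon, N_S, w0,
                              seed = 1L, T_B = phantom$T_B) {
  stopifnot(N_S >= 2)
  summaries <- basis_kinetic_summaries(phantom$basis, T_B = T_B)
  rep_seeds <- replicate_seeds(seed, N_S)
  maps <- vector("list", N_S)
  recon_err <- matrix(0, nrow(phantom$truth), N_S)
  for (s in seq_len(N_S)) {
    z <- simulate_recon(rep_seeds[s])
    maps[[s]] <- kinetic_params(nnls_map(z, phantom$basis, w0), summaries)
    recon_err[, s] <- sqrt(rowSums(sweep((z - phantom$truth)^2, 2, w0,
                                         "*")) / ncol(z))
  }
  arr <- simplify2array(maps)
  sd_ <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  mean_ <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  colnames(sd_) <- colnames(mean_) <- KINETIC_PARAMS
  list(sd = sd_, mean = mean_, recon_err = rowMeans(recon_err),
       maps = maps)
}

# ---- 2-D experiment ---------------------------------------------------------

#' Replication-truth and bootstrap experiment on the 2-D scanner
#'
#' Full pipeline: phantom, attenuated Radon projection, dose calibration,
#' MSE-optimal common FBP bandwidth, `N_S` independent replicate
#' simulations mapped to kinetic parameters (replication truth), a GLM fit
#' to one replicate driving an image-domain bootstrap (and optionally a
#' projection-domain bootstrap and coefficient recycling), and the
#' calibration summaries.
#'
#' @param n grid side.
#' @param N_S replication count (>= 2; >= 20 for stable truth).
#' @param N_B bootstrap replicates.
#' @param tracer_style `"fdg"` or `"flt"`.
#' @param seed master seed.
#' @param target_noise relative single-frame reconstruction noise fixing
#'   the reference dose.
#' @param dose_mult multiplier on the calibrated reference dose.
#' @param with_projection also run the projection-domain bootstrap.
#' @param with_recycle also run recycling (`N_B_star` retained fits,
#'   `N_tilde` recycled replicates).
#' @param N_B_star,N_tilde recycling sizes.
#' @param L_bins kappa bins for the GLM fit.
#' @return list with the phantom, per-parameter true SD / mean matrices,
#'   bootstrap SD matrices (`boot_sd`, optionally `proj_sd`, `recycle_sd`),
#'   per-replicate maps, reconstruction errors, the fitted GLM, dose and
#'   bandwidth.
#' @export
experiment_2d <- function(n = 64, N_S = 60, N_B = 25,
                          tracer_style = "fdg", seed = 1L,
                          target_noise = 0.15, dose_mult = 1,
                          with_projection = FALSE, with_recycle = FALSE,
                          N_B_star = 10, N_tilde = 200, L_bins = 64L) {
  ph <- make_phantom("2d", tracer_style, n = n)
  geom <- sinogram_geometry(n)
  att <- attenuation_factors(ph$mu_map, geom)
  proj <- as.matrix(geom$P %*% ph$truth) * geom$scale * att
  dur <- ph$schedule$durations
  rates <- sweep(proj, 2, dur, "*")      # expected counts per unit dose
  seeds <- replicate_seeds(seed, 6L)

  # reference dose from a pilot single-frame reconstruction at bandwidth 1
  pilot_frame <- which.max(colMeans(ph$truth))
  sim_one <- function(tau, sd_) {
    cnt <- simulate_counts(rates[, pilot_frame], tau, seed = sd_)
    fbp_reconstruct_2d(cnt, geom, att, tau, bandwidth = 1,
                       frame_durations = dur[pilot_frame])[, 1]
  }
  tau_R <- calibrate_dose(sim_one, ph$truth[, pilot_frame], ph$support,
                          target = target_noise, tau0 = 2e5,
                          seed = seeds[1])
  tau <- tau_R * dose_mult

  recon <- function(cnt, h) {
    fbp_reconstruct_2d(cnt, geom, att, tau, bandwidth = h,
                       frame_durations = dur)
  }
  cnt0 <- simulate_counts(rates, tau, seed = seeds[2])
  bandwidth <- select_bandwidth(recon, cnt0, ph$truth,
                                bandwidths = c(0.1, 0.25, 0.5, 0.75, 1,
                                               1.5, 2, 3),
                                frame_durations = dur)

  w0 <- initial_weights(ph$schedule, colMeans(ph$truth))$w0
  summaries <- basis_kinetic_summaries(ph$basis, T_B = ph$T_B)
  P <- length(KINETIC_PARAMS)
  map_one <- function(z) {
    kinetic_params(nnls_map(z, ph$basis, w0), summaries)
  }

  # replication truth
  rep_seeds <- replicate_seeds(seeds[3], N_S)
  true_maps <- vector("list", N_S)
  recon_err <- matrix(0, ph$grid$n, N_S)
  for (s in seq_len(N_S)) {
    cnt <- simulate_counts(rates, tau, seed = rep_seeds[s])
    z <- recon(cnt, bandwidth)
    true_maps[[s]] <- map_one(z)
    recon_err[, s] <- sqrt(rowSums(sweep((z - ph$truth)^2, 2, w0, "*")) /
                             ncol(z))
  }
  arr <- simplify2array(true_maps)
  true_sd <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  true_mean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  colnames(true_sd) <- colnames(true_mean) <- KINETIC_PARAMS

  # the "observed" study: one more independent replicate
  cnt_obs <- simulate_counts(rates, tau, seed = seeds[4])
  z_obs <- recon(cnt_obs, bandwidth)
  study <- dynamic_image(z_obs, ph$grid, ph$schedule)
  fit <- fit_glm(study, ph$basis, L_bins = L_bins)
  bs <- image_bootstrap(fit, N_B, seed = seeds[5])
  boot <- map_bootstrap_kinetics(bs, ph$basis, w0, T_B = ph$T_B)

  out <- list(phantom = ph, geom = geom, tau = tau, bandwidth = bandwidth,
              w0 = w0, true_sd = true_sd, true_mean = true_mean,
              true_maps = true_maps, recon_err = rowMeans(recon_err),
              fit = fit, boot_sd = boot$sd, boot_maps = boot$maps,
              study = study)

  if (with_projection) {
    pb <- projection_bootstrap(cnt_obs, N_B, seed = seeds[6])
    pmaps <- lapply(pb$replicates, function(cb) map_one(recon(cb, bandwidth)))
    parr <- simplify2array(pmaps)
    out$proj_sd <- apply(parr, c(1, 2), stats::sd, na.rm = TRUE)
    colnames(out$proj_sd) <- KINETIC_PARAMS
    out$proj_maps <- pmaps
  }
  if (with_recycle) {
    keep <- lapply(bs$replicates[seq_len(min(N_B_star, bs$count))],
                   function(zb) wls_alpha(zb, ph$basis, w0)$alpha)
    rec <- recycle_bootstrap(keep, fit, N_tilde, seed = seeds[6] + 1L)
    rmaps <- map_bootstrap_kinetics(rec, ph$basis, w0, T_B = ph$T_B)
    out$recycle_sd <- rmaps$sd
    out$recycle_maps <- rmaps$maps
  }
  out
}

# ---- 1-D experiment ---------------------------------------------------------

#' Replication-truth and bootstrap experiment on the 1-D scanner
#'
#' @param n profile length (even).
#' @param N_S replication count.
#' @param N_B bootstrap replicates (projection- and image-domain).
#' @param tracer_style `"fdg"` or `"flt"`.
#' @param reconstruction `"fbp"` (least squares) or `"ml"` (EM).
#' @param beta operator exponent.
#' @param seed master seed.
#' @param target_noise,dose_mult dose control, as in [experiment_2d()].
#' @param n_em EM iterations for `"ml"`.
#' @param L_bins kappa bins.
#' @return list mirroring [experiment_2d()], additionally with `proj_sd`
#'   (the projection-domain bootstrap is always run in 1-D).
#' @export
experiment_1d <- function(n = 128, N_S = 100, N_B = 25,
                          tracer_style = "fdg",
                          reconstruction = c("fbp", "ml"),
                          beta = 1.35, seed = 1L, target_noise = 0.15,
                          dose_mult = 1, n_em = 50L, L_bins = 64L) {
  reconstruction <- match.arg(reconstruction)
  ph <- make_phantom("1d", tracer_style, n = n)
  op <- operator_1d(n, beta)
  a <- ph$attenuation
  dur <- ph$schedule$durations
  # expected counts per unit dose: a_x * (K_beta lambda_.t)(x) * dt
  proj <- apply_kbeta(op, ph$truth) * a
  rates <- sweep(pmax(proj, 0), 2, dur, "*")
  seeds <- replicate_seeds(seed, 6L)

  recon <- function(cnt, h) {
    scaled <- sweep(as.matrix(cnt), 2, dur, "/")
    if (reconstruction == "fbp")
      ls_reconstruct_1d(scaled, op, a, tau, bandwidth = h)
    else em_ml_1d(scaled, op, a, tau, n_iter = n_em, bandwidth = h)
  }

  pilot_frame <- which.max(colMeans(ph$truth))
  support <- rowSums(ph$alpha) > 0.05 * max(rowSums(ph$alpha))
  tau <- 1   # placeholder so recon() can be used during calibration
  sim_one <- function(tau_try, sd_) {
    cnt <- simulate_counts(rates[, pilot_frame], tau_try, seed = sd_)
    if (reconstruction == "fbp")
      ls_reconstruct_1d(cnt / dur[pilot_frame], op, a, tau_try, 1)
    else em_ml_1d(cnt / dur[pilot_frame], op, a, tau_try, n_em, 1)
  }
  tau_R <- calibrate_dose(sim_one, ph$truth[, pilot_frame], support,
                          target = target_noise, tau0 = 2e4,
                          seed = seeds[1])
  tau <- tau_R * dose_mult

  cnt0 <- simulate_counts(rates, tau, seed = seeds[2])
  bandwidth <- select_bandwidth(recon, cnt0, ph$truth,
                                bandwidths = c(0.5, 1, 1.5, 2, 3, 4, 6, 8),
                                frame_durations = dur)

  w0 <- initial_weights(ph$schedule, colMeans(ph$truth))$w0
  summaries <- basis_kinetic_summaries(ph$basis, T_B = ph$T_B)
  map_one <- function(z) kinetic_params(nnls_map(z, ph$basis, w0), summaries)

  rep_seeds <- replicate_seeds(seeds[3], N_S)
  true_maps <- vector("list", N_S)
  recon_err <- matrix(0, n, N_S)
  for (s in seq_len(N_S)) {
    cnt <- simulate_counts(rates, tau, seed = rep_seeds[s])
    z <- recon(cnt, bandwidth)
    true_maps[[s]] <- map_one(z)
    recon_err[, s] <- sqrt(rowSums(sweep((z - ph$truth)^2, 2, w0, "*")) /
                             ncol(z))
  }
  arr <- simplify2array(true_maps)
  true_sd <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  true_mean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  colnames(true_sd) <- colnames(true_mean) <- KINETIC_PARAMS

  cnt_obs <- simulate_counts(rates, tau, seed = seeds[4])
  z_obs <- recon(cnt_obs, bandwidth)
  study <- dynamic_image(z_obs, ph$grid, ph$schedule)
  fit <- fit_glm(study, ph$basis, L_bins = L_bins)
  bs <- image_bootstrap(fit, N_B, seed = seeds[5])
  boot <- map_bootstrap_kinetics(bs, ph$basis, w0, T_B = ph$T_B)

  pb <- projection_bootstrap(cnt_obs, N_B, seed = seeds[6])
  pmaps <- lapply(pb$replicates, function(cb) map_one(recon(cb, bandwidth)))
  parr <- simplify2array(pmaps)
  proj_sd <- apply(parr, c(1, 2), stats::sd, na.rm = TRUE)
  colnames(proj_sd) <- KINETIC_PARAMS

  list(phantom = ph, op = op, tau = tau, bandwidth = bandwidth, w0 = w0,
       true_sd = true_sd, true_mean = true_mean, true_maps = true_maps,
       recon_err = rowMeans(recon_err), fit = fit,
       boot_sd = boot$sd, boot_maps = boot$maps,
       proj_sd = proj_sd, proj_maps = pmaps, study = study)
}

#' Pooled cross-method calibration (projection vs image domain)
#'
#' Regresses projection-domain bootstrap voxel SDs on image-domain
#' bootstrap voxel SDs through the origin, pooling parameters after
#' scaling each parameter by its own maximum mean (so no single parameter
#' dominates).
#'
#' @param proj_sd,boot_sd N x P SD matrices.
#' @param true_mean N x P mean parameter maps (scaling).
#' @return list with `slope`, `r_squared`, `n`.
#' @export
cross_method_calibration <- function(proj_sd, boot_sd, true_mean) {
  xs <- c(); ys <- c()
  for (p in seq_len(ncol(proj_sd))) {
    sc <- max(true_mean[, p], na.rm = TRUE)
    if (!is.finite(sc) || sc <= 0) next
    xs <- c(xs, boot_sd[, p] / sc)
    ys <- c(ys, proj_sd[, p] / sc)
  }
  calibrate(ys, xs)
}
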