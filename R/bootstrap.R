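# The three bootstrap engines: model-based image-domain simulation,
# fully non-parametric projection-domain multinomial resampling, and the
# approximate coefficient-recycling scheme.

new_bootstrap_set <- function(kind, replicates, seed) {
  structure(list(kind = kind, replicates = replicates, seed = seed,
                 count = length(replicates)),
            class = "bootstrap_set")
}

#' @export
print.bootstrap_set <- function(x, ...) {
  cat(sprintf("bootstrap_set: %d %s-domain replicates (seed %s)\n",
              x$count, x$kind, format(x$seed)))
  invisible(x)
}

#' Image-domain bootstrap from a fitted model
#'
#' For each replicate and frame, a white standard-Gaussian field is
#' spectrally filtered to the fitted power spectrum (giving the
#' sub-ordinate field eta*), passed through the conditional quantile
#' transform at the voxel's kappa bin, scaled by `sigma_i phi_j`, and added
#' to the fitted means.  Frames are independent; each replicate has its own
#' sub-seed derived from `seed` so replicates are reproducible regardless
#' of how many are requested.
#'
#' @param fit a `glm_fit`.
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @return a `bootstrap_set` of kind `"image"`; replicates are N x T value
#'   matrices.
#' @export
image_bootstrap <- function(fit, n_reps, seed = 1L) {
  stopifnot(inherits(fit, "glm_fit"), n_reps >= 1)
  seeds <- replicate_seeds(seed, n_reps)
  grid <- fit$grid
  T_ <- ncol(fit$zhat)
  sig_phi <- outer(fit$sigma, fit$phi)
  lam <- fit$spectrum$lambda
  qt <- fit$qtransform
  bins <- fit$bin_index
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    reps[[b]] <- with_seed(seeds[b], {
      err <- matrix(0, grid$n, T_)
      for (j in seq_len(T_)) {
        eta <- as.numeric(filter_white(stats::rnorm(grid$n), lam, grid))
        err[, j] <- q_apply(qt, eta, bins[, j])
      }
      fit$zhat + sig_phi * err
    })
  }
  new_bootstrap_set("image", reps, seed)
}

#' Projection-domain multinomial bootstrap of binned counts
#'
#' Each replicate is one multinomial draw with `N_e = sum(counts)` trials
#' and bin probabilities proportional to the observed counts, so every
#' replicate conserves the total detected events exactly (list-mode
#' resampling with replacement of binned events).
#'
#' @param counts non-negative integer array of any shape.
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @return a `bootstrap_set` of kind `"projection"`; replicates keep the
#'   shape of `counts`.
#' @export
projection_bootstrap <- function(counts, n_reps, seed = 1L) {
  cnt <- as.numeric(counts)
  if (any(cnt < 0) || any(abs(cnt - round(cnt)) > 1e-8))
    stop("counts must be non-negative integers")
  Ne <- sum(cnt)
  if (Ne <= 0) stop("all-zero count array cannot be resampled")
  seeds <- replicate_seeds(seed, n_reps)
  dims <- dim(counts)
  reps <- lapply(seq_len(n_reps), function(b) {
    with_seed(seeds[b], {
      out <- as.numeric(stats::rmultinom(1L, size = Ne, prob = cnt))
      if (!is.null(dims)) dim(out) <- dims
      out
    })
  })
  new_bootstrap_set("projection", reps, seed)
}

#' Approximate image-domain bootstrap by coefficient recycling
#'
#' A small retained set of coefficient arrays from image-domain bootstrap
#' fits is converted to standardized deviations
#' `D_i^b = (alpha_i^b - alpha_hat_i) / sigma_hat_i`.  Each output
#' replicate resamples a deviation row per voxel (from the voxel's own
#' deviation set, or from the pooled set over all voxels), restores spatial
#' correlation by filtering each coefficient column with the spectral
#' square-root filter (variance-preserving since the spectrum has mean 1),
#' and returns `alpha_hat + sigma_hat * D`.
#'
#' @param alpha_samples a `bootstrap_set` (or list) of N x K coefficient
#'   arrays from image-domain bootstrap fits, length >= 2.
#' @param fit the `glm_fit` the samples were derived from.
#' @param n_out number of recycled replicates.
#' @param seed master seed.
#' @param mode `"rowwise"` (per-voxel empirical deviation set) or
#'   `"pooled"`.
#' @return a `bootstrap_set` of kind `"recycled"`; replicates are N x K
#'   coefficient arrays.
#' @export
recycle_bootstrap <- function(alpha_samples, fit, n_out, seed = 1L,
                              mode = c("rowwise", "pooled")) {
  mode <- match.arg(mode)
  samples <- if (inherits(alpha_samples, "bootstrap_set"))
    alpha_samples$replicates else alpha_samples
  NBs <- length(samples)
  if (NBs < 2L) stop("need at least 2 retained coefficient arrays")
  stopifnot(inherits(fit, "glm_fit"))
  N <- nrow(fit$alpha); K <- ncol(fit$alpha)
  grid <- fit$grid
  sig <- fit$sigma
  live <- sig > 0
  D <- array(0, c(N, K, NBs))
  for (b in seq_len(NBs)) {
    d <- (samples[[b]] - fit$alpha)
    d[live, ] <- d[live, , drop = FALSE] / sig[live]
    d[!live, ] <- 0
    D[, , b] <- d
  }
  lam <- fit$spectrum$lambda
  seeds <- replicate_seeds(seed, n_out)
  reps <- lapply(seq_len(n_out), function(b) {
    with_seed(seeds[b], {
      if (mode == "rowwise") {
        pick <- sample.int(NBs, N, replace = TRUE)
        Dt <- vapply(seq_len(N), function(i) D[i, , pick[i]], numeric(K))
        Dt <- if (K == 1L) matrix(Dt, ncol = 1L) else t(Dt)
      } else {
        pick_i <- sample.int(N, N, replace = TRUE)
        pick_b <- sample.int(NBs, N, replace = TRUE)
        Dt <- vapply(seq_len(N), function(m) D[pick_i[m], , pick_b[m]],
                     numeric(K))
        Dt <- if (K == 1L) matrix(Dt, ncol = 1L) else t(Dt)
      }
      filt <- vapply(seq_len(K), function(k) {
        as.numeric(filter_white(Dt[, k], lam, grid))
      }, numeric(N))
      out <- fit$alpha + sig * filt
      out
    })
  })
  new_bootstrap_set("recycled", reps, seed)
}
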