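# Synthetic dynamic phantoms for the validation simulators.
#
# Sources have the separable form lambda(x, t) = sum_k alpha_k(x) mu_k(t)
# with two-compartment sub-TACs driven by a synthetic arterial input
# function.  The "fdg" style uses slow brain-like kinetics, the "flt"
# style faster early kinetics (higher k2, negligible k4, larger blood
# signal), mirroring the tracers the method targets.

#' Synthetic arterial input function
#'
#' A gamma-variate bolus with a slowly decaying recirculation tail, sampled
#' densely (1 s) over the study.
#'
#' @param T_end last time needed (minutes).
#' @param style `"fdg"` (60-90 min studies) or `"flt"` (faster bolus).
#' @return an [input_function()].
#' @export
synthetic_aif <- function(T_end = 90, style = c("fdg", "flt")) {
  style <- match.arg(style)
  tt <- seq(0, T_end + 1, by = 1 / 60)
  bolus <- if (style == "fdg") 30 * tt * exp(-tt / 0.35) else
    45 * tt * exp(-tt / 0.25)
  tail_amp <- if (style == "fdg") 0.9 else 0.7
  tail <- tail_amp * (1 - exp(-2.5 * tt)) * exp(-0.012 * tt)
  input_function(tt, bolus + tail)
}

two_compartment_library <- function(style, T_B, T_E) {
  # kinetically distinct tissue classes: trapping (gray/white/tumor at
  # different flux-to-flow ratios), a pure-washout rim (Kety-Schmidt) and a
  # slow low-exchange deep class, so sub-TAC shapes are well separated
  pars <- if (style == "fdg") list(
    gray   = c(k1 = 0.105, k2 = 0.160, k3 = 0.070, k4 = 0.0060, fb = 0.04),
    white  = c(k1 = 0.040, k2 = 0.100, k3 = 0.028, k4 = 0.0050, fb = 0.02),
    tumor  = c(k1 = 0.170, k2 = 0.380, k3 = 0.180, k4 = 0.0010, fb = 0.07),
    rim    = c(k1 = 0.090, k2 = 0.550, k3 = 0.000, k4 = 0.0000, fb = 0.03),
    deep   = c(k1 = 0.018, k2 = 0.045, k3 = 0.010, k4 = 0.0040, fb = 0.01)
  ) else list(
    gray   = c(k1 = 0.110, k2 = 0.700, k3 = 0.055, k4 = 0.0000, fb = 0.08),
    white  = c(k1 = 0.050, k2 = 0.180, k3 = 0.020, k4 = 0.0000, fb = 0.04),
    tumor  = c(k1 = 0.210, k2 = 1.300, k3 = 0.180, k4 = 0.0000, fb = 0.12),
    rim    = c(k1 = 0.095, k2 = 1.500, k3 = 0.000, k4 = 0.0000, fb = 0.06),
    deep   = c(k1 = 0.020, k2 = 0.060, k3 = 0.008, k4 = 0.0000, fb = 0.02)
  )
  lapply(pars, function(p) {
    two_compartment_residue(p["k1"], p["k2"], p["k3"], p["k4"],
                            f_b = p["fb"], T_B = T_B, T_E = T_E)
  })
}

#' Default dynamic acquisition schedule for phantoms
#'
#' T = 20 frames over 60 minutes: 4 x 15 s, 4 x 30 s, 4 x 1.5 min,
#' 4 x 3.5 min, 4 x 9.25 min (dense early sampling, long late frames).
#'
#' @return a [frame_schedule()].
#' @export
phantom_schedule <- function() {
  dur <- c(rep(0.25, 4), rep(0.5, 4), rep(1.5, 4), rep(3.5, 4),
           rep(9.25, 4))
  ends <- cumsum(dur)
  frame_schedule(ends - dur / 2, dur, decay_constant = 0)
}

ellipse_mask <- function(centers, cx, cy, a, b) {
  ((centers$x - cx) / a)^2 + ((centers$y - cy) / b)^2 <= 1
}

#' Synthetic dynamic phantom
#'
#' 2-D mode: an elliptical "head" with gray/white-like shells, a rim region,
#' a focal tumor insert and a vascular (AIF) pool; attenuation is a uniform
#' coefficient over the support.  1-D mode: six smooth spatial bumps with
#' six two-compartment temporal components and a smooth attenuation
#' profile.  The truth is `lambda = sum_k alpha_k(x) mu_k(t)`.
#'
#' @param mode `"2d"` or `"1d"`.
#' @param tracer_style `"fdg"` or `"flt"` (kinetic ranges).
#' @param n grid side (2-D) or even profile length (1-D).
#' @param schedule a [frame_schedule()] (default [phantom_schedule()]).
#' @param seed reserved for randomized variants; the default phantom is
#'   deterministic.
#' @param T_B vascular bound used for the generating residues.
#' @return object of class `phantom`: `truth` (N x T), `alpha` (N x K),
#'   `basis` (a `temporal_basis` with the generating residues), `grid`,
#'   `schedule`, `aif`, and either `mu_map` + support (2-D) or
#'   `attenuation` profile (1-D).
#' @export
make_phantom <- function(mode = c("2d", "1d"), tracer_style = c("fdg", "flt"),
                         n = 64, schedule = phantom_schedule(), seed = 1L,
                         T_B = 1 / 12) {
  mode <- match.arg(mode)
  tracer_style <- match.arg(tracer_style)
  T_end <- max(schedule$mid_times + schedule$durations / 2)
  aif <- synthetic_aif(T_end, tracer_style)
  lib <- two_compartment_library(tracer_style, T_B, T_end)
  R_blood <- spike_residue(duration = 5 / 60, T_E = T_end)
  residues <- c(list(blood = R_blood), lib)
  K <- length(residues)
  X <- vapply(residues, residue_subtac, numeric(length(schedule$mid_times)),
              aif = aif, schedule = schedule)
  basis <- temporal_basis(X, names = names(residues), residues = residues,
                          delays = rep(0, K), aif_col = 1L,
                          patlak_col = NA_integer_)

  if (mode == "2d") {
    grid <- voxel_grid(c(n, n, 1), spacing = c(2.25, 2.25, 1))
    px <- 2 / n
    cc <- seq(-1 + px / 2, 1 - px / 2, length.out = n)
    centers <- expand.grid(x = cc, y = cc)
    head_m <- ellipse_mask(centers, 0, 0, 0.85, 0.70)
    inner <- ellipse_mask(centers, 0, 0, 0.62, 0.48)
    deep_m <- ellipse_mask(centers, -0.18, 0, 0.28, 0.22)
    tumor <- ellipse_mask(centers, 0.32, 0.18, 0.16, 0.13)
    rim <- head_m & !ellipse_mask(centers, 0, 0, 0.76, 0.61)
    vessel <- ellipse_mask(centers, -0.05, -0.45, 0.07, 0.06)
    alpha <- cbind(
      blood = 0.03 * head_m + 0.85 * vessel,
      gray  = pmax(inner & !deep_m & !tumor, 0) * 0.9,
      white = pmax(head_m & !inner & !rim, 0) * 0.85,
      tumor = tumor * 1.0,
      rim   = rim * 0.7,
      deep  = (deep_m & !tumor) * 0.95)
    # mild partial-volume blur so region edges are not binary
    alpha <- apply(alpha, 2, function(v) {
      as.numeric(gaussian_smooth_2d(v, n, 0.6))
    })
    alpha <- pmax(alpha, 0)
    alpha[!head_m, ] <- 0
    mu_map <- 0.8 * as.numeric(head_m)
    truth <- alpha %*% t(basis$X)
    structure(list(mode = mode, tracer_style = tracer_style,
                   truth = truth, alpha = alpha, basis = basis,
                   grid = grid, schedule = schedule, aif = aif,
                   mu_map = mu_map, support = head_m, T_B = T_B),
              class = "phantom")
  } else {
    n <- as.integer(n)
    if (n %% 2L != 0L) stop("1-D profile length must be even")
    grid <- voxel_grid(c(n, 1, 1), spacing = c(2.25, 1, 1))
    x <- seq_len(n)
    ctr <- n * c(0.14, 0.30, 0.46, 0.60, 0.74, 0.88)
    wid <- n * c(0.05, 0.07, 0.05, 0.08, 0.05, 0.04)
    amp <- c(0.55, 0.90, 0.75, 1.00, 0.80, 0.60)
    alpha <- vapply(seq_len(6), function(k) {
      amp[k] * exp(-(x - ctr[k])^2 / (2 * wid[k]^2))
    }, numeric(n))
    colnames(alpha) <- names(residues)
    attenuation <- 0.35 + 0.60 * exp(-((x - n / 2) / (n / 2.6))^2)
    truth <- alpha %*% t(basis$X)
    structure(list(mode = mode, tracer_style = tracer_style,
                   truth = truth, alpha = alpha, basis = basis,
                   grid = grid, schedule = schedule, aif = aif,
                   attenuation = attenuation, T_B = T_B),
              class = "phantom")
  }
}

#' Calibrate the reference dose of a simulated scanner
#'
#' Chooses the dose scale `tau_R` so that the relative voxel-level noise of
#' a single-frame reconstruction (SD of the reconstruction error over the
#' support, divided by the mean true activity there) matches a target,
#' emulating matching simulated noise to the apparent noise of real data.
#' Uses the `1 / sqrt(tau)` Poisson scaling from a pilot simulation.
#'
#' @param simulate_fn function(tau, seed) returning a reconstruction of the
#'   pilot frame (vector over voxels).
#' @param truth_frame true activity for the pilot frame.
#' @param support logical mask of voxels entering the noise summary.
#' @param target relative noise target (default 0.15).
#' @param tau0 pilot dose.
#' @param n_pilot pilot replicates.
#' @param seed seed.
#' @return the calibrated `tau_R`.
#' @export
calibrate_dose <- function(simulate_fn, truth_frame, support, target = 0.15,
                           tau0 = 1e5, n_pilot = 4L, seed = 1L) {
  seeds <- replicate_seeds(seed, n_pilot)
  errs <- vapply(seq_len(n_pilot), function(i) {
    rec <- simulate_fn(tau0, seeds[i])
    stats::sd(rec[support] - truth_frame[support])
  }, 0)
  rel <- mean(errs) / mean(truth_frame[support])
  tau0 * (rel / target)^2
}
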