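# Tissue residue functions and their kinetic decomposition.
#
# The residue R(t) is the impulse response of tissue to arterial delivery:
# a non-negative, non-increasing "life table" of tracer travel times.  The
# measured tissue curve is the convolution of R with the (possibly delayed)
# arterial input function C_p.  Kinetic summaries follow from splitting R
# into a vascular component on [0, T_B], an in-distribution component, and
# the flat extraction tail R(T_E) = K_i.

#' Residue model
#'
#' @param times evaluation grid in minutes, increasing from 0.
#' @param values residue values (dimensionless fraction per unit flow),
#'   non-negative and non-increasing.
#' @param delay arterial delay in minutes.
#' @return an object of class `residue_model`.
#' @export
residue_model <- function(times, values, delay = 0) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 2L)
    stop("times and values must be equal-length vectors (>= 2)")
  if (times[1] < 0 || any(diff(times) <= 0))
    stop("residue grid must be increasing and start at >= 0")
  if (any(values < -1e-10)) stop("residue must be non-negative")
  if (any(diff(values) > 1e-8 * max(abs(values), 1)))
    stop("residue must be non-increasing")
  structure(list(times = times, values = pmax(values, 0),
                 delay = as.numeric(delay)),
            class = "residue_model")
}

eval_residue <- function(R, t) {
  out <- fast_interp(R$times, R$values, t)
  out[t < 0] <- R$values[1]
  out
}

# default residue evaluation grid: dense (sub-second) early where vascular
# kinetics live, coarsening towards T_E
residue_grid <- function(T_E, T_B = 1 / 12) {
  g <- c(seq(0, min(T_B * 2, T_E), length.out = 41L),
         exp(seq(log(max(T_B / 10, 1e-4)), log(T_E), length.out = 600L)))
  sort(unique(pmin(c(g, T_E), T_E)))
}

#' Two-compartment residue function (analytic oracle)
#'
#' Builds the residue of the standard irreversible/reversible
#' two-compartment tissue model with rate constants `k1..k4` (1/min) and
#' fractional blood volume `f_b`.  The tissue impulse response is the
#' two-exponential mixture
#' \deqn{I_C(t) = k_1 (1-\pi) e^{-t\lambda_1} + k_1 \pi e^{-t\lambda_2}}
#' and the blood contribution is represented by a triangular residue on
#' `[0, T_B]` integrating to `f_b`, so the total residue is
#' `R_C = R_o + (1 - f_b) I_C`.
#'
#' @param k1,k2,k3,k4 rate constants (1/min), all non-negative.
#' @param f_b fractional blood volume in `[0, 1)`.
#' @param T_B vascular transit bound (minutes), default 5 s.
#' @param T_E end of the evaluation grid (minutes).
#' @param times optional explicit grid.
#' @return a [residue_model()].
#' @export
two_compartment_residue <- function(k1, k2, k3, k4 = 0, f_b = 0,
                                    T_B = 1 / 12, T_E = 90,
                                    times = NULL) {
  stopifnot(k1 >= 0, k2 >= 0, k3 >= 0, k4 >= 0, f_b >= 0, f_b < 1,
            T_B > 0, T_E > T_B)
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  lam1 <- (s + disc) / 2
  lam2 <- (s - disc) / 2
  pi_ <- if (lam1 > lam2) (k3 + k4 - lam2) / (lam1 - lam2) else 1
  if (is.null(times)) times <- sort(unique(c(residue_grid(T_E, T_B), T_B)))
  IC <- k1 * (1 - pi_) * exp(-times * lam1) + k1 * pi_ * exp(-times * lam2)
  Ro <- ifelse(times <= T_B, 2 * f_b / T_B * (1 - times / T_B), 0)
  residue_model(times, Ro + (1 - f_b) * IC, delay = 0)
}

#' Spiked residue representing the arterial input itself
#'
#' A triangular residue of very short duration (default 5 s) and unit
#' integral; its convolution with the input function is (approximately) the
#' input function, making it the blood/AIF basis element.
#'
#' @param duration spike duration in minutes (must be <= 5 s).
#' @param T_E grid end (minutes).
#' @return a [residue_model()].
#' @export
spike_residue <- function(duration = 1 / 12, T_E = 90) {
  stopifnot(duration <= 5 / 60 + 1e-12)
  times <- sort(unique(c(seq(0, duration, length.out = 21L),
                         residue_grid(T_E, duration))))
  vals <- ifelse(times <= duration, 2 / duration * (1 - times / duration), 0)
  residue_model(times, vals, delay = 0)
}

#' Constant residue (Patlak element)
#'
#' @param level constant residue level (flux per unit coefficient).
#' @param T_E grid end (minutes).
#' @return a [residue_model()] that is constant; its sub-TAC is the running
#'   integral of the input function.
#' @export
constant_residue <- function(level = 1, T_E = 90) {
  residue_model(c(0, T_E), c(level, level), delay = 0)
}

#' Decompose a residue into vascular, distribution and extraction parts
#'
#' `R = R_B + R_D + R_E` with `R_E = R(T_E)` (the flux `K_i`),
#' `R_B(t) = R(t) - R(T_B)` on `[0, T_B]` and zero after, and
#' `R_D` the remainder.
#'
#' @param R a [residue_model()].
#' @param T_B vascular bound (minutes), `0 < T_B < T_E`.
#' @param T_E evaluation horizon (minutes); defaults to the end of the grid.
#' @return list with components `times`, `R_B`, `R_D`, `R_E`, `T_B`, `T_E`.
#' @export
decompose_residue <- function(R, T_B = 1 / 12, T_E = max(R$times)) {
  stopifnot(inherits(R, "residue_model"))
  if (T_B >= T_E) stop("T_B must be smaller than T_E")
  times <- sort(unique(c(R$times[R$times <= T_E], T_B, T_E)))
  r <- eval_residue(R, times)
  KI <- eval_residue(R, T_E)
  RTB <- eval_residue(R, T_B)
  RB <- ifelse(times <= T_B, r - RTB, 0)
  RE <- rep(KI, length(times))
  RD <- r - RB - RE
  list(times = times, R_B = RB, R_D = pmax(RD, 0), R_E = RE,
       T_B = T_B, T_E = T_E)
}

#' Kinetic summaries of a single residue
#'
#' @param R a [residue_model()].
#' @inheritParams decompose_residue
#' @return list with `V_B` (blood volume), `K_D` (flow), `V_D`
#'   (distribution volume), `K_i` (flux) and the delay.
#' @export
residue_summaries <- function(R, T_B = 1 / 12, T_E = max(R$times)) {
  d <- decompose_residue(R, T_B, T_E)
  sel <- d$times <= d$T_B
  V_B <- trapz(d$times[sel], d$R_B[sel])
  K_D <- d$R_D[1]
  V_D <- trapz(d$times, d$R_D)
  list(V_B = V_B, K_D = K_D, V_D = V_D, K_i = d$R_E[1], delay = R$delay)
}

# ---- sub-TAC construction -------------------------------------------------

# cumulative integral of the input function on a fine grid, for fast
# evaluation of int_0^t Cp(s - delay) ds at arbitrary t
aif_cum <- function(aif, T_E, step = 1 / 120) {
  tt <- seq(0, T_E, by = step)
  cp <- eval_input_function(aif, tt)
  cum <- c(0, cumsum((cp[-1] + cp[-length(cp)]) / 2) * step)
  list(times = tt, cum = cum)
}

aif_cum_eval <- function(ac, t) {
  out <- fast_interp(ac$times, ac$cum, t)
  out[t <= 0] <- 0
  out
}

# Frame-averaged sub-TAC of a piecewise constant residue given as right-open
# step heights: R(t) = sum_m theta_m * 1{t < tau_m}.  Each step's
# convolution with Cp(. - delay) is Cpint(t - delay) - Cpint(t - tau_m -
# delay), where Cpint is the running integral of Cp.
step_subtac_matrix <- function(knots, delay, schedule, ac, n_sub = 8L) {
  T_ <- length(schedule$mid_times)
  lo <- schedule$mid_times - schedule$durations / 2
  M <- matrix(0, T_, length(knots))
  for (j in seq_len(T_)) {
    ts <- lo[j] + schedule$durations[j] * (seq_len(n_sub) - 0.5) / n_sub
    base <- aif_cum_eval(ac, ts - delay)
    for (m in seq_along(knots)) {
      M[j, m] <- mean(base - aif_cum_eval(ac, ts - knots[m] - delay))
    }
  }
  M
}

#' Frame-averaged tissue curve of a residue model
#'
#' Convolves the residue with the (delayed) input function and averages the
#' result over each frame of the schedule.
#'
#' @param R a [residue_model()].
#' @param aif an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param n_sub sub-samples per frame for the frame average.
#' @return numeric vector of length T.
#' @export
residue_subtac <- function(R, aif, schedule, n_sub = 8L) {
  T_end <- max(schedule$mid_times + schedule$durations / 2)
  if (max(aif$times) < max(schedule$mid_times) - 1e-9)
    stop("input function does not cover the study duration")
  ac <- aif_cum(aif, T_end + R$delay + 1e-9)
  # represent R by steps at its own grid nodes
  times <- R$times; vals <- R$values
  inc <- -diff(c(vals, 0))            # step heights dropping at each node
  keep <- inc > 1e-14
  knots <- c(times[-1], max(times))[keep]
  theta <- inc[keep]
  if (!length(knots)) return(rep(0, length(schedule$mid_times)))
  M <- step_subtac_matrix(knots, R$delay, schedule, ac, n_sub)
  as.numeric(M %*% theta)
}

#' Fit a monotone non-parametric residue model to a time-activity curve
#'
#' The residue is parameterized as a non-negative sum of decreasing step
#' functions on a geometric knot grid (dense early), which enforces
#' monotone non-increasing shape by construction.  For each candidate delay
#' the step weights are found by weighted non-negative least squares
#' against the frame-averaged convolution model; the delay minimizing the
#' weighted residual sum of squares is selected.
#'
#' @param tac time-activity values at the frame mid-times (length T).
#' @param aif an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param weights per-frame weights (default: the simple scheme of
#'   [initial_weights()] computed from `tac` itself is *not* used; uniform
#'   weights are the default).
#' @param delay_grid candidate delays in minutes (default 0-30 s by 2.5 s).
#' @param n_knots number of residue knots.
#' @param knots explicit knot times (minutes), overriding the default
#'   geometric grid.  With more knots than frames the fitted tissue curve
#'   is reproduced but the residue itself is not pointwise identifiable.
#' @return a [residue_model()] with attribute `wrss` (criterion value).
#' @export
fit_residue_model <- function(tac, aif, schedule, weights = NULL,
                              delay_grid = seq(0, 0.5, by = 2.5 / 60),
                              n_knots = 24L, knots = NULL) {
  T_ <- length(schedule$mid_times)
  stopifnot(length(tac) == T_)
  if (max(aif$times) < max(schedule$mid_times) - 1e-9)
    stop("input function does not cover the study duration")
  if (is.null(weights)) weights <- rep(1, T_)
  T_end <- max(schedule$mid_times + schedule$durations / 2)
  if (all(abs(tac) < 1e-300)) {
    return(structure(residue_model(c(0, T_end), c(0, 0)), wrss = 0))
  }
  ac <- aif_cum(aif, T_end + max(delay_grid) + 1e-9)
  if (is.null(knots))
    knots <- unique(c(exp(seq(log(1 / 60), log(T_end),
                              length.out = n_knots - 1L)), T_end))
  knots <- sort(unique(knots))
  sw <- sqrt(weights)
  best <- NULL
  for (delta in delay_grid) {
    M <- step_subtac_matrix(knots, delta, schedule, ac)
    theta <- drop(.nnls_multi(M * sw, cbind(tac * sw)))
    wrss <- sum((sw * (tac - M %*% theta))^2)
    if (is.null(best) || wrss < best$wrss - 1e-12)
      best <- list(delta = delta, theta = theta, wrss = wrss)
  }
  # assemble the step residue with sharp drops at the knots (nodes placed
  # just before each knot keep the piecewise-linear representation
  # step-like); the final knot (T_end) represents tracer never released
  # within the study, so its level persists: it is the flux K_i
  kn_eff <- knots
  kn_eff[which.max(kn_eff)] <- Inf
  grid <- sort(unique(c(0, knots, pmax(knots - 1e-9, 0))))
  vals <- vapply(grid, function(t) sum(best$theta[kn_eff > t + 1e-12]), 0)
  # evaluate just left of each knot so the step shape is retained
  out <- residue_model(grid, vals, delay = best$delta)
  attr(out, "wrss") <- best$wrss
  out
}
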