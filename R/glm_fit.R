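# Estimation of the image-domain generalized linear model
#
#   z_ij = x_j' alpha_i + sigma_i phi_j Q(eta_ij | kappa_ij),
#   eta ~ N(0,1) with independent frames and a stationary spatial
#   correlation diagonalized by the FFT (power spectrum lambda).
#
# Identifiability conventions: sum_j phi_j^2 = T, sum_l h_l^2 = L (h_l is
# the per-bin standard deviation of Q), mean(lambda) = 1 so that the
# sub-ordinate field has unit marginal variance.

#' Simple fixed temporal weighting scheme
#'
#' The initial frame weights are
#' `w_j = exp(-t_j * zeta) * dt_j / max(mu_j, m)` with `m` one tenth of the
#' largest frame mean, and the associated scale factors
#' `phi_j ~ w_j^(-1/2)` normalized so that `sum(phi^2) = T`.
#'
#' @param schedule a [frame_schedule()].
#' @param frame_means per-frame mean of the reconstructed values.
#' @return list with `w0` and `phi0`, both length T.
#' @export
initial_weights <- function(schedule, frame_means) {
  t_ <- schedule$mid_times; dt <- schedule$durations
  zeta <- schedule$decay_constant
  stopifnot(length(frame_means) == length(t_))
  if (any(!is.finite(frame_means))) stop("non-finite frame means")
  if (max(frame_means) <= 0) stop("no signal: all frame means are <= 0")
  m <- 0.1 * max(frame_means)
  mu_star <- pmax(frame_means, m)
  w0 <- exp(-t_ * zeta) * dt / mu_star
  phi0 <- 1 / sqrt(w0)
  phi0 <- phi0 * sqrt(length(t_) / sum(phi0^2))
  list(w0 = w0, phi0 = phi0)
}

#' Unconstrained weighted least squares coefficients
#'
#' Solves `alpha_i = argmin sum_j w_j (z_ij - x_j' a)^2` for every voxel
#' through one shared K x K normal-equations factorization.
#'
#' @param z N x T data matrix (or a [dynamic_image()]).
#' @param X T x K basis matrix (or a `temporal_basis`).
#' @param w per-frame weights, length T.
#' @return list with `alpha` (N x K) and `residuals` (N x T).
#' @export
wls_alpha <- function(z, X, w) {
  if (inherits(z, "dynamic_image")) z <- z$values
  X <- basis_matrix(X)
  T_ <- ncol(z); K <- ncol(X)
  stopifnot(nrow(X) == T_, length(w) == T_, all(w > 0))
  XtW <- t(X * w)                       # K x T
  G <- XtW %*% X
  qrG <- qr(G, tol = 1e-12)
  if (qrG$rank < K) {
    dep <- setdiff(seq_len(K), qrG$pivot[seq_len(qrG$rank)])
    stop("singular weighted design; dependent basis columns: ",
         paste(dep, collapse = ", "))
  }
  alpha <- t(solve(qrG, XtW %*% t(z)))  # N x K
  r <- z - alpha %*% t(X)
  list(alpha = alpha, residuals = r)
}

#' Coefficient covariance of the weighted least squares fit
#'
#' `Sigma_K = [X' W X]^{-1}` with `W = diag(phi_j^{-2})`; the covariance of
#' the standardized coefficient deviations `(alpha_hat - alpha) / sigma_i`.
#'
#' @param X T x K basis matrix (or `temporal_basis`).
#' @param phi per-frame scale factors.
#' @return K x K covariance matrix.
#' @export
coef_covariance <- function(X, phi) {
  X <- basis_matrix(X)
  W <- 1 / phi^2
  solve(t(X * W) %*% X)
}

#' Iterative estimation of spatial/temporal scales and the variance function
#'
#' Stage 1 alternates `phi_j^2 = mean_i(r_ij^2 / sigma_i^2)` and
#' `sigma_i^2 = mean_j(r_ij^2 / phi_j^2)` (renormalizing `sum(phi^2) = T`)
#' with the variance function held at 1, giving the basic-model scales used
#' to define the skewness surrogate `kappa = zhat / (sigma phi)`.  Stage 2
#' bins `kappa` into `L_bins` equal-count percentile bins and iterates the
#' scale updates jointly with the per-bin variance
#' `h_l^2 = mean(r^2 / (sigma^2 phi^2))` over the bin, normalized so
#' `sum(h^2) = L_bins`.  Finally `sigma` is inflated by `sqrt(T / (T - K))`
#' to correct the residual-variance bias from fitting K coefficients.
#'
#' @param r N x T residual matrix.
#' @param zhat N x T fitted means (defines `kappa`).
#' @param K number of fitted basis columns.
#' @param L_bins number of kappa bins (reduced if bins would hold < 50
#'   residuals).
#' @param tol,max_iter convergence control.
#' @return list with `sigma`, `phi`, `h`, `kappa`, `bin_index` (N x T
#'   integer, NA for degenerate voxels), `edges`, the stage-1 scales
#'   `sigma_tilde`, `phi_tilde`, and `converged`.
#' @export
iterate_scales <- function(r, zhat, K, L_bins = 64L, tol = 1e-6,
                           max_iter = 200L) {
  N <- nrow(r); T_ <- ncol(r)
  stopifnot(all(dim(zhat) == dim(r)))
  r2 <- r^2

  # stage 1: product scales under h == 1
  sigma2 <- rep(1, N)
  phi2 <- rep(1, T_)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    live <- sigma2 > 0
    if (!any(live)) { phi2 <- rep(1, T_); break }
    phi2_new <- colMeans(r2[live, , drop = FALSE] / sigma2[live])
    if (all(phi2_new == 0)) phi2_new <- rep(1, T_)
    phi2_new <- phi2_new * T_ / sum(phi2_new)
    sigma2_new <- rowMeans(sweep(r2, 2, phi2_new, "/"))
    d <- max(abs(phi2_new - phi2)) / max(phi2, 1e-300)
    phi2 <- phi2_new; sigma2 <- sigma2_new
    if (d < tol) { converged <- TRUE; break }
  }
  sigma_tilde <- sqrt(sigma2); phi_tilde <- sqrt(phi2)

  # degeneracy is judged against the scale of the fitted means, so that
  # numerically-zero residuals from a noiseless study register as such
  scale_ref <- max(abs(zhat), max(abs(r)), 1e-300)
  degenerate <- sigma_tilde <= 1e-10 * scale_ref
  if (all(degenerate)) {
    # noiseless data: zero scales, unit frame factors and variance function
    bin_index <- matrix(NA_integer_, N, T_)
    return(list(sigma = numeric(N), phi = rep(1, T_), h = 1,
                kappa = matrix(0, N, T_), bin_index = bin_index,
                edges = c(-Inf, Inf), sigma_tilde = numeric(N),
                phi_tilde = rep(1, T_), converged = TRUE))
  }

  kappa <- matrix(0, N, T_)
  kappa[!degenerate, ] <- zhat[!degenerate, , drop = FALSE] /
    (sigma_tilde[!degenerate] * rep(phi_tilde, each = sum(!degenerate)))

  # equal-count kappa bins from the basic-model fit (fixed hereafter)
  n_live <- sum(!degenerate) * T_
  L_bins <- max(1L, min(as.integer(L_bins), n_live %/% 50L))
  bin_index <- matrix(NA_integer_, N, T_)
  kl <- kappa[!degenerate, , drop = FALSE]
  rk <- rank(kl, ties.method = "first")
  bin_index[!degenerate, ] <- as.integer(ceiling(rk * L_bins / n_live))
  edges <- c(-Inf, stats::quantile(kl, probs = seq_len(L_bins) / L_bins,
                                   names = FALSE, type = 7))
  edges[length(edges)] <- Inf

  # stage 2: joint iteration of sigma, phi and h
  h2 <- rep(1, L_bins)
  live_idx <- which(!is.na(bin_index))
  bin_flat <- bin_index[live_idx]
  h2mat <- matrix(1, N, T_)
  converged2 <- FALSE
  for (it in seq_len(max_iter)) {
    h2mat[live_idx] <- h2[bin_flat]
    rw <- r2 / h2mat
    live <- sigma2 > 0
    phi2_new <- colMeans(rw[live, , drop = FALSE] / sigma2[live])
    phi2_new <- phi2_new * T_ / sum(phi2_new)
    sigma2_new <- rowMeans(sweep(rw, 2, phi2_new, "/"))
    eps2 <- sweep(r2, 2, phi2_new, "/") / pmax(sigma2_new, 1e-300)
    h2_new <- vapply(seq_len(L_bins), function(l) {
      v <- eps2[live_idx[bin_flat == l]]
      if (length(v)) mean(v) else 1
    }, 0)
    h2_new <- h2_new * L_bins / sum(h2_new)
    d <- max(max(abs(phi2_new - phi2)) / max(phi2),
             max(abs(h2_new - h2)) / max(h2))
    phi2 <- phi2_new; sigma2 <- sigma2_new; h2 <- h2_new
    if (d < tol) { converged2 <- TRUE; break }
  }
  # alternating updates approach the joint fix point at a ~1/iteration
  # rate; after max_iter the remaining drift is far below statistical
  # accuracy, so the last iterate is returned with converged = FALSE

  sigma <- sqrt(sigma2) * sqrt(T_ / (T_ - K))
  list(sigma = sigma, phi = sqrt(phi2), h = sqrt(h2), kappa = kappa,
       bin_index = bin_index, edges = edges,
       sigma_tilde = sigma_tilde, phi_tilde = phi_tilde,
       converged = converged && converged2)
}

#' Empirical conditional quantile transform
#'
#' Within each kappa bin, the sorted scaled residuals
#' `eps = r / (sigma phi)` are paired with standard-normal quantiles
#' `qnorm((k - 0.5) / n)`.  `Q(. | l)` interpolates the eta -> eps table
#' linearly, clamped at the extreme order statistics; the inverse map gives
#' every residual its normal score.
#'
#' @param r N x T residuals.
#' @param sigma,phi converged scale estimates.
#' @param bin_index N x T bin assignment from [iterate_scales()].
#' @param h per-bin variance-function values.
#' @param edges kappa bin edges (length `L + 1`, from [iterate_scales()]).
#' @param max_nodes cap on stored table nodes per bin (quantile-thinned).
#' @return an object of class `q_transform` with fields `edges`, `tables`
#'   (per bin: `eta`, `eps`), `h`, `L`.
#' @export
estimate_qtransform <- function(r, sigma, phi, bin_index, h, edges,
                                max_nodes = 2000L) {
  L <- max(bin_index, na.rm = TRUE)
  live <- sigma > 0
  eps <- matrix(0, nrow(r), ncol(r))
  eps[live, ] <- r[live, , drop = FALSE] /
    (sigma[live] * rep(phi, each = sum(live)))
  tables <- vector("list", L)
  for (l in seq_len(L)) {
    v <- eps[which(bin_index == l)]
    if (!length(v)) {           # empty bin: borrow the nearest populated one
      warning("empty kappa bin ", l, "; merged with neighbour")
      next
    }
    e <- sort(v)
    n <- length(e)
    eta <- stats::qnorm((seq_len(n) - 0.5) / n)
    if (n > max_nodes) {
      idx <- unique(round(seq(1, n, length.out = max_nodes)))
      e <- e[idx]; eta <- eta[idx]
    }
    tables[[l]] <- list(eta = eta, eps = e)
  }
  for (l in seq_len(L)) {       # resolve any empty bins
    if (is.null(tables[[l]])) {
      nb <- c(seq(l - 1, 1), seq(l + 1, L))
      nb <- nb[nb >= 1 & nb <= L]
      src <- nb[which(!vapply(tables[nb], is.null, TRUE))[1]]
      tables[[l]] <- tables[[src]]
    }
  }
  structure(list(edges = edges, tables = tables, h = h, L = L),
            class = "q_transform")
}

#' Apply the Q transform (eta -> eps) for given bins
#'
#' @param qt a `q_transform`.
#' @param eta numeric values of the sub-ordinate Gaussian.
#' @param bins integer bin index per value (NA entries map to 0).
#' @return numeric vector of the same length.
#' @export
q_apply <- function(qt, eta, bins) {
  out <- numeric(length(eta))
  for (l in seq_len(qt$L)) {
    idx <- which(bins == l)
    if (!length(idx)) next
    tab <- qt$tables[[l]]
    out[idx] <- fast_interp(tab$eta, tab$eps, eta[idx])
  }
  out
}

#' @rdname q_apply
#' @param eps scaled residual values to map back to normal scores.
#' @export
q_inverse <- function(qt, eps, bins) {
  out <- numeric(length(eps))
  for (l in seq_len(qt$L)) {
    idx <- which(bins == l)
    if (!length(idx)) next
    tab <- qt$tables[[l]]
    out[idx] <- fast_interp(tab$eps, tab$eta, eps[idx])
  }
  out
}

# ---- spatial spectrum ------------------------------------------------------

grid_fft <- function(x, grid, inverse = FALSE) {
  a <- array(x, dim = grid$dim)
  out <- stats::fft(a, inverse = inverse)
  if (inverse) out <- out / grid$n
  out
}

#' Estimate the stationary spatial power spectrum of the normalized residuals
#'
#' Per frame the 3-D periodogram `|FFT(eta_.j)|^2 / N` is computed on the
#' voxel grid; periodograms are averaged over frames with weights
#' proportional to `phi_j^{-2}` (normalized to sum 1), and the result is
#' scaled to mean 1 so that fields simulated from it have unit marginal
#' variance.  The autocorrelation is the (real) inverse FFT, normalized to
#' `rho(0) = 1`.
#'
#' @param eta N x T matrix of normal scores.
#' @param phi per-frame scale factors (weights `phi^-2`).
#' @param grid a [voxel_grid()].
#' @return object of class `spectral_model` with `lambda` (array, mean 1),
#'   `rho` (array, `rho[1] == 1`) and the grid.
#' @export
estimate_spectrum <- function(eta, phi, grid) {
  stopifnot(nrow(eta) == grid$n, length(phi) == ncol(eta))
  w <- 1 / phi^2
  w <- w / sum(w)
  lambda <- array(0, dim = grid$dim)
  for (j in seq_len(ncol(eta))) {
    lambda <- lambda + w[j] * Mod(grid_fft(eta[, j], grid))^2 / grid$n
  }
  m <- mean(lambda)
  if (m <= 0) lambda[] <- 1 else lambda <- lambda / m
  rho <- Re(grid_fft(lambda, grid, inverse = TRUE)) * grid$n
  rho <- rho / rho[1]
  structure(list(lambda = lambda, rho = rho, grid = grid),
            class = "spectral_model")
}

# filter a white-noise field to the spectrum lambda (unit marginal variance
# when mean(lambda) == 1): eta = F^-1 (lambda^(1/2) F xi)
filter_white <- function(xi, lambda, grid) {
  Re(stats::fft(sqrt(lambda) * stats::fft(array(xi, dim = grid$dim)),
                inverse = TRUE)) / grid$n
}

# ---- orchestration ---------------------------------------------------------

#' Fit the image-domain generalized linear model
#'
#' Runs [initial_weights()], [wls_alpha()], [iterate_scales()],
#' [estimate_qtransform()] and [estimate_spectrum()] and collects every
#' estimated unknown into a `glm_fit` container.
#'
#' @param study a [dynamic_image()].
#' @param basis a `temporal_basis` or plain T x K matrix.
#' @param L_bins number of kappa bins.
#' @param tol,max_iter scale-iteration control.
#' @return an object of class `glm_fit`.
#' @export
fit_glm <- function(study, basis, L_bins = 64L, tol = 1e-6,
                    max_iter = 200L) {
  stopifnot(inherits(study, "dynamic_image"))
  z <- study$values
  X <- basis_matrix(basis)
  iw <- initial_weights(study$schedule, colMeans(z))
  ls <- wls_alpha(z, X, iw$w0)
  zhat <- z - ls$residuals
  # Per-frame studentization: fitting K coefficients per voxel suppresses
  # a leverage-dependent share of the error variance at each frame.  Under
  # the product variance model, E r_ij^2 = sigma_i^2 sum_k (I-H)_jk^2
  # phi_k^2 with H = X (X'WX)^-1 X'W, so residuals are rescaled by the
  # frame-wise factor c_j = sum_k (I-H)_jk^2 phi_k^2 / phi_j^2 (two passes:
  # phi from a first leverage-corrected fit feeds the exact correction).
  # With few frames and very uneven weights this matters far more than the
  # average-case sqrt(T/(T-K)) inflation.
  XtWX <- t(X * iw$w0) %*% X
  Hmat <- X %*% solve(XtWX, t(X * iw$w0))
  A2 <- (diag(ncol(z)) - Hmat)^2            # (I - H)_jk^2
  H <- diag(Hmat)
  lev <- 1 / sqrt(pmax(1 - H, 0.05))
  r_adj <- sweep(ls$residuals, 2, lev, "*")
  sc <- iterate_scales(r_adj, zhat, K = 0L, L_bins = L_bins,
                       tol = tol, max_iter = max_iter)
  for (pass in 1:2) {
    if (all(sc$sigma == 0)) break
    # entry-wise suppression under the current variance model:
    # E r_ij^2 = sum_k (I-H)_jk^2 v_ik with v = sigma^2 phi^2 h(kappa)^2
    vhat <- (pmax(sc$sigma, 1e-12 * max(sc$sigma)) %o% sc$phi)^2
    ok <- !is.na(sc$bin_index)
    hm <- matrix(1, nrow(z), ncol(z))
    hm[ok] <- sc$h[sc$bin_index[ok]]^2
    vhat <- vhat * hm
    s_ij <- (vhat %*% t(A2)) / vhat
    r_adj <- ls$residuals / sqrt(pmax(s_ij, 0.05))
    sc <- iterate_scales(r_adj, zhat, K = 0L, L_bins = L_bins,
                         tol = tol, max_iter = max_iter)
  }
  if (all(sc$sigma == 0)) {
    # degenerate (noiseless) study: identity transform, flat spectrum
    qt <- structure(list(edges = c(-Inf, Inf),
                         tables = list(list(eta = c(-1, 1), eps = c(-1, 1))),
                         h = 1, L = 1L), class = "q_transform")
    spec <- structure(list(lambda = array(1, study$grid$dim),
                           rho = {
                             r0 <- array(0, study$grid$dim); r0[1] <- 1; r0
                           },
                           grid = study$grid), class = "spectral_model")
    eta <- matrix(0, nrow(z), ncol(z))
  } else {
    qt <- estimate_qtransform(r_adj, sc$sigma, sc$phi, sc$bin_index,
                              sc$h, sc$edges)
    live <- sc$sigma > 0
    eps <- matrix(0, nrow(z), ncol(z))
    eps[live, ] <- r_adj[live, , drop = FALSE] /
      (sc$sigma[live] * rep(sc$phi, each = sum(live)))
    eta <- matrix(0, nrow(z), ncol(z))
    ok <- !is.na(sc$bin_index)
    eta[ok] <- q_inverse(qt, eps[ok], sc$bin_index[ok])
    spec <- estimate_spectrum(eta, sc$phi, study$grid)
  }
  structure(list(basis = basis, alpha = ls$alpha,
                 sigma = sc$sigma, phi = sc$phi,
                 w0 = iw$w0, phi0 = iw$phi0,
                 kappa = sc$kappa, bin_index = sc$bin_index,
                 h = sc$h, qtransform = qt, spectrum = spec,
                 zhat = zhat, residuals = ls$residuals,
                 residuals_adj = r_adj, leverage = H, eta = eta,
                 grid = study$grid, schedule = study$schedule,
                 sigma_tilde = sc$sigma_tilde, phi_tilde = sc$phi_tilde,
                 converged = sc$converged),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit: N = %d voxels, T = %d frames, K = %d basis columns\n",
              nrow(x$alpha), length(x$phi), ncol(x$alpha)))
  cat(sprintf("  sum(phi^2) = %.6f (T = %d); %d kappa bins\n",
              sum(x$phi^2), length(x$phi), x$qtransform$L))
  invisible(x)
}

#' Residual diagnostics of a fitted model
#'
#' @param fit a `glm_fit`.
#' @param lags autocorrelation lags (voxels) per axis.
#' @return list of numeric tables: `frame_quartiles` (per-frame quartiles of
#'   fully standardized residuals r / (sigma phi h)), `bin_table` (per-bin
#'   quartiles and `h_l`), `qq` (overall normal-quantile table), and
#'   `axis_autocorrelation` (lags in mm per grid axis).
#' @export
residual_diagnostics <- function(fit, lags = 0:5) {
  stopifnot(inherits(fit, "glm_fit"))
  live <- fit$sigma > 0
  std <- matrix(NA_real_, nrow(fit$residuals), ncol(fit$residuals))
  h_mat <- matrix(1, nrow(fit$residuals), ncol(fit$residuals))
  ok <- !is.na(fit$bin_index)
  h_mat[ok] <- fit$h[fit$bin_index[ok]]
  std[live, ] <- fit$residuals[live, , drop = FALSE] /
    (fit$sigma[live] * rep(fit$phi, each = sum(live))) /
    h_mat[live, , drop = FALSE]
  frame_q <- t(apply(std, 2, stats::quantile,
                     probs = c(0.25, 0.5, 0.75), na.rm = TRUE))
  colnames(frame_q) <- c("q25", "q50", "q75")
  L <- fit$qtransform$L
  bin_tab <- t(vapply(seq_len(L), function(l) {
    v <- std[which(fit$bin_index == l)]
    c(stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE), h = fit$h[l])
  }, numeric(4)))
  colnames(bin_tab) <- c("q25", "q50", "q75", "h")
  v <- sort(std[is.finite(std)])
  pr <- (seq_along(v) - 0.5) / length(v)
  qq <- cbind(normal = stats::qnorm(pr), residual = v)
  if (nrow(qq) > 512) qq <- qq[round(seq(1, nrow(qq), length.out = 512)), ]
  rho <- fit$spectrum$rho
  d <- fit$grid$dim
  ax <- lapply(1:3, function(a) {
    lag_ok <- lags[lags < d[a]]
    idx <- rep(1L, 3)
    val <- vapply(lag_ok, function(l) {
      ii <- idx; ii[a] <- l + 1L
      rho[ii[1], ii[2], ii[3]]
    }, 0)
    cbind(lag_mm = lag_ok * fit$grid$spacing[a], rho = val)
  })
  names(ax) <- c("x", "y", "z")
  list(frame_quartiles = frame_q, bin_table = bin_tab, qq = qq,
       axis_autocorrelation = ax)
}
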