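# shared fixtures, built in code

# small schedule: T frames, geometric-ish durations over ~20 min
tiny_schedule <- function(T_ = 10L) {
  dur <- rep(20 / T_, T_)
  ends <- cumsum(dur)
  frame_schedule(ends - dur / 2, dur)
}

# simple input function for tests
tiny_aif <- function(T_end = 25) {
  tt <- seq(0, T_end, by = 1 / 60)
  input_function(tt, 10 * tt * exp(-tt / 0.4) + 0.5 * (1 - exp(-3 * tt)))
}

# simulate from the generalized linear model with Q = identity:
# z = alpha X' + (sigma o phi) * eta, eta spatially filtered white noise
simulate_glm_study <- function(n = 16, T_ = 10, K = 2, sigma = NULL,
                               phi = NULL, lambda = NULL, seed = 1) {
  set.seed(seed)
  grid <- voxel_grid(c(n, n, 1))
  N <- grid$n
  sch <- tiny_schedule(T_)
  X <- cbind(seq_len(T_) / T_, exp(-sch$mid_times / 4))[, seq_len(K),
                                                        drop = FALSE]
  alpha <- matrix(runif(N * K, 0.5, 3), N, K)
  if (is.null(sigma)) sigma <- runif(N, 0.1, 0.3)
  if (is.null(phi)) {
    phi <- sqrt(T_ * seq_len(T_) / sum(seq_len(T_)))
  }
  if (is.null(lambda)) lambda <- array(1, grid$dim)
  eta <- vapply(seq_len(T_), function(j) {
    as.numeric(petboot:::filter_white(rnorm(N), lambda, grid))
  }, numeric(N))
  z <- alpha %*% t(X) + (sigma %o% phi) * eta
  list(study = dynamic_image(z, grid, sch), X = X, alpha = alpha,
       sigma = sigma, phi = phi, lambda = lambda, eta = eta, grid = grid,
       schedule = sch)
}

# minimal hand-built glm_fit with identity Q and flat spectrum, for tests
# that need full control of the generator
manual_glm_fit <- function(zhat, sigma, phi, grid, schedule,
                           lambda = NULL) {
  N <- nrow(zhat); T_ <- ncol(zhat)
  if (is.null(lambda)) lambda <- array(1, grid$dim)
  qt <- structure(list(
    edges = c(-Inf, Inf),
    tables = list(list(eta = c(-8, 8), eps = c(-8, 8))),
    h = 1, L = 1L), class = "q_transform")
  rho <- array(0, grid$dim); rho[1] <- 1
  spec <- structure(list(lambda = lambda, rho = rho, grid = grid),
                    class = "spectral_model")
  structure(list(basis = NULL, alpha = matrix(0, N, 1), sigma = sigma,
                 phi = phi, w0 = rep(1, T_), phi0 = rep(1, T_),
                 kappa = matrix(0, N, T_),
                 bin_index = matrix(1L, N, T_), h = 1,
                 qtransform = qt, spectrum = spec, zhat = zhat,
                 residuals = matrix(0, N, T_),
                 residuals_adj = matrix(0, N, T_),
                 leverage = rep(0, T_),
                 eta = matrix(0, N, T_), grid = grid,
                 schedule = schedule, sigma_tilde = sigma,
                 phi_tilde = phi, converged = TRUE),
            class = "glm_fit")
}
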