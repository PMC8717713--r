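test_that("initial weights reproduce the hand-computed scheme", {
  # zeta = 0, t = [1,2,4], dt = [1,1,2], frame means [2,10,5]:
  # m = 1, w0 = dt / max(mu, m) = [0.5, 0.1, 0.4], phi0 ~ w0^(-1/2)
  sch <- frame_schedule(c(1, 2, 4), c(1, 1, 2), 0)
  iw <- initial_weights(sch, c(2, 10, 5))
  expect_equal(iw$w0, c(0.5, 0.1, 0.4))
  oracle <- (1 / sqrt(iw$w0)) * sqrt(3 / sum(1 / iw$w0))
  expect_equal(iw$phi0, oracle, tolerance = 1e-12)
  expect_equal(sum(iw$phi0^2), 3, tolerance = 1e-12)
  expect_equal(iw$phi0, c(0.643, 1.438, 0.719), tolerance = 1e-3)

  # constant dt and means -> phi0 all one
  sch2 <- tiny_schedule(6)
  expect_equal(initial_weights(sch2, rep(4, 6))$phi0, rep(1, 6))

  # zero frame mean floored at m, weight finite
  iw3 <- initial_weights(sch, c(0, 10, 5))
  expect_true(all(is.finite(iw3$w0)))
  expect_equal(iw3$w0[1], 1 / 1)       # floored denominator = 0.1 * 10

  expect_error(initial_weights(sch, c(0, 0, 0)), "signal")
})

test_that("weighted least squares matches the closed form", {
  set.seed(21)
  T_ <- 20; K <- 5
  X <- matrix(rnorm(T_ * K), T_, K)
  w <- runif(T_, 0.5, 2)
  z <- matrix(rnorm(T_), 1, T_)
  res <- wls_alpha(z, X, w)
  brute <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% t(z))
  expect_equal(as.numeric(res$alpha), as.numeric(brute), tolerance = 1e-10)

  # noiseless interpolation recovers alpha, residuals vanish
  alpha <- matrix(runif(30 * K), 30, K)
  zz <- alpha %*% t(X)
  r2 <- wls_alpha(zz, X, w)
  expect_equal(r2$alpha, alpha, tolerance = 1e-9)
  expect_lt(max(abs(r2$residuals)), 1e-9)

  # K = 1 constant basis with uniform weights = frame mean
  r3 <- wls_alpha(zz, matrix(1, T_, 1), rep(1, T_))
  expect_equal(as.numeric(r3$alpha), rowMeans(zz), tolerance = 1e-12)

  # duplicated column -> informative singularity error
  expect_error(wls_alpha(zz, cbind(X, X[, 1]), w), "singular")
})

test_that("scale iteration recovers product-form scales and normalizations", {
  set.seed(22)
  N <- 500; T_ <- 20
  sigma <- runif(N, 0.5, 2)
  phi <- sqrt(T_ * seq_len(T_) / sum(seq_len(T_)))
  r <- (sigma %o% phi) * matrix(rnorm(N * T_), N)
  sc <- iterate_scales(r, zhat = matrix(1, N, T_), K = 0, L_bins = 8)
  expect_lt(sqrt(mean((sc$phi - phi)^2)) / mean(phi), 0.05)
  # sigma recovered up to the global scale convention
  rat <- sc$sigma / sigma
  expect_lt(sd(rat) / mean(rat), 0.25)
  # exact normalizations
  expect_equal(sum(sc$phi^2), T_, tolerance = 1e-8)
  expect_equal(sum(sc$h^2), length(sc$h), tolerance = 1e-8)
})

test_that("homogeneous residuals give flat scales and variance function", {
  r <- matrix(2, 40, 8)           # identical rows and columns
  sc <- iterate_scales(r, zhat = matrix(5, 40, 8), K = 0, L_bins = 4)
  expect_equal(sc$phi, rep(1, 8), tolerance = 1e-8)
  expect_lt(diff(range(sc$sigma)), 1e-8)
  expect_equal(sc$h, rep(1, length(sc$h)), tolerance = 1e-8)
})

test_that("empirical Q transform matches its generating quantiles", {
  # bin data that are exact standard-normal quantiles -> identity, h = 1
  N <- 100; T_ <- 10
  n <- N * T_
  qs <- qnorm((seq_len(n) - 0.5) / n)
  r <- matrix(sample(qs), N, T_)
  sigma <- rep(1, N); phi <- rep(1, T_)
  bins <- matrix(1L, N, T_)
  qt <- estimate_qtransform(r, sigma, phi, bins, h = 1,
                            edges = c(-Inf, Inf))
  tab <- qt$tables[[1]]
  expect_equal(tab$eps, tab$eta, tolerance = 1e-10)
  # table nodes are the identity, so Q(eta) = eta on the node range
  expect_equal(q_apply(qt, c(-1, 0, 2), rep(1L, 3)), c(-1, 0, 2),
               tolerance = 1e-6)

  # lognormal bin: Q convex increasing, positive skew of Q(eta)
  e <- exp(qs); e <- (e - mean(e)) / sd(e)
  r2 <- matrix(sample(e), N, T_)
  qt2 <- estimate_qtransform(r2, sigma, phi, bins, h = 1,
                             edges = c(-Inf, Inf))
  tb <- qt2$tables[[1]]
  expect_true(all(diff(tb$eps) >= 0))          # monotone by construction
  grid_eta <- qnorm(seq(0.005, 0.995, length.out = 401))
  qv <- q_apply(qt2, grid_eta, rep(1L, length(grid_eta)))
  sk <- mean((qv - mean(qv))^3) / sd(qv)^3
  expect_gt(sk, 0.5)                           # generating lognormal skew
  # convex increasing overall: right slope exceeds left slope
  q3 <- q_apply(qt2, c(-2, 0, 2), rep(1L, 3))
  expect_gt(q3[3] - q3[2], q3[2] - q3[1])

  # inverse map returns the normal scores of the table entries
  eta_back <- q_inverse(qt2, tb$eps, rep(1L, length(tb$eps)))
  expect_equal(eta_back, tb$eta, tolerance = 1e-8)
})

test_that("periodogram averaging recovers flat and structured spectra", {
  set.seed(23)
  n <- 32; T_ <- 24
  grid <- voxel_grid(c(n, n, 1))
  # white noise -> flat spectrum within periodogram sampling error
  eta <- matrix(rnorm(grid$n * T_), grid$n, T_)
  sp <- estimate_spectrum(eta, phi = rep(1, T_), grid)
  expect_equal(mean(sp$lambda), 1, tolerance = 1e-12)
  expect_equal(sp$rho[1], 1, tolerance = 1e-12)
  # bin-averaged lambda: chi2_2-based SE of a mean of T_ periodograms per
  # frequency, further averaged over rings of >= 50 bins
  lam <- as.numeric(sp$lambda)
  ring <- cut(seq_along(lam), 8)
  ring_mean <- tapply(lam, ring, mean)
  ring_n <- tapply(lam, ring, length)
  se <- 1 / sqrt(T_ * ring_n)
  expect_true(all(abs(ring_mean - 1) < 4 * se))

  # known low-pass spectrum recovered within sampling error
  fx <- c(0:(n / 2), -(n / 2 - 1):-1) / n
  lam_true <- outer(fx, fx, function(a, b) 1 / (1 + 30 * (a^2 + b^2)))
  lam_true <- array(lam_true / mean(lam_true), grid$dim)
  eta2 <- vapply(seq_len(T_), function(j) {
    as.numeric(petboot:::filter_white(rnorm(grid$n), lam_true, grid))
  }, numeric(grid$n))
  sp2 <- estimate_spectrum(eta2, rep(1, T_), grid)
  rel <- as.numeric(sp2$lambda) / as.numeric(lam_true)
  ring_mean2 <- tapply(rel, ring, mean)
  expect_true(all(abs(ring_mean2 - 1) < 4 / sqrt(T_ * ring_n)))
})

test_that("full GLM fit recovers the generating model components", {
  sim <- simulate_glm_study(n = 32, T_ = 20, K = 2, seed = 24)
  fit <- fit_glm(sim$study, temporal_basis(sim$X), L_bins = 16)
  T_ <- 20
  # normalization identities hold on any input
  expect_equal(sum(fit$phi^2), T_, tolerance = 1e-8)
  expect_equal(sum(fit$h^2), length(fit$h), tolerance = 1e-8)
  expect_equal(mean(fit$spectrum$lambda), 1, tolerance = 1e-12)
  expect_equal(fit$spectrum$rho[1], 1, tolerance = 1e-12)
  # phi recovered within stage-level tolerance (white spatial noise)
  expect_lt(sqrt(mean((fit$phi - sim$phi)^2)) / mean(sim$phi), 0.05)
  # sigma field recovered up to per-voxel estimation noise
  rat <- fit$sigma / sim$sigma
  expect_lt(abs(mean(rat) - 1), 0.1)
  # coefficients recovered within a few WLS standard errors
  expect_lt(max(abs(fit$alpha - sim$alpha)) /
              max(abs(sim$alpha)), 0.5)
  # flat generating spectrum -> flat estimate
  expect_lt(abs(mean(as.numeric(fit$spectrum$lambda) > 1) - 0.5), 0.15)
})

test_that("refitting noiseless fitted means hits the degenerate-scale guard", {
  sim <- simulate_glm_study(n = 8, T_ = 6, seed = 25)
  clean <- sim$alpha %*% t(sim$X)
  st <- dynamic_image(clean, sim$grid, sim$schedule)
  fit <- fit_glm(st, temporal_basis(sim$X))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_true(all(fit$sigma == 0))
  # bootstrap of a noiseless fit returns the fitted means exactly
  bs <- image_bootstrap(fit, 3, seed = 1)
  expect_equal(bs$replicates[[1]], fit$zhat, tolerance = 1e-12)
})

test_that("residual diagnostics return consistent tables", {
  sim <- simulate_glm_study(n = 32, T_ = 12, seed = 26)
  fit <- fit_glm(sim$study, temporal_basis(sim$X), L_bins = 8)
  d <- residual_diagnostics(fit)
  # Gaussian-simulated data: per-frame medians near 0 (3 SE at N = 1024)
  expect_true(all(abs(d$frame_quartiles[, "q50"]) < 0.12))
  # per-bin h column equals the fitted variance function
  expect_equal(unname(d$bin_table[, "h"]), fit$h)
  # white sub-ordinate field: off-origin axis autocorrelation near 0
  ax <- d$axis_autocorrelation$x
  expect_true(all(abs(ax[-1, "rho"]) < 0.1))
})
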