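test_that("1-D operator has unit DC gain and exact LS inversion", {
  op <- operator_1d(64, beta = 1.35)
  expect_equal(apply_kbeta(op, rep(3, 64)), rep(3, 64), tolerance = 1e-10)
  # noiseless counts invert exactly with no smoothing
  set.seed(61)
  lam <- pmax(0.2 + sin(seq(0, 2 * pi, length.out = 64))^2, 0)
  a <- 0.4 + 0.5 * exp(-((1:64 - 32) / 20)^2)
  y <- 500 * a * apply_kbeta(op, lam)
  z <- ls_reconstruct_1d(y, op, a, tau = 500, bandwidth = 0)
  expect_equal(z, lam, tolerance = 1e-8)
})

test_that("LS reconstruction is unbiased for the source", {
  set.seed(62)
  n <- 64
  op <- operator_1d(n, 1.35)
  lam <- pmax(0.3 + cos(seq(0, 3 * pi, length.out = n))^2, 0)
  a <- rep(0.8, n)
  tau <- 2000
  rate <- pmax(a * apply_kbeta(op, lam), 0)
  B <- 1000
  acc <- matrix(0, n, B)
  for (b in 1:B) {
    y <- rpois(n, tau * rate)
    acc[, b] <- ls_reconstruct_1d(y, op, a, tau, bandwidth = 0)
  }
  m <- rowMeans(acc)
  se <- apply(acc, 1, sd) / sqrt(B)
  expect_gt(mean(abs(m - lam) < 3 * se), 0.98)
})

test_that("EM reconstruction has its fixed point and monotone likelihood", {
  n <- 32
  # beta = 0 gives the identity operator: kernel is a delta
  op0 <- operator_1d(n, beta = 0)
  expect_equal(op0$kernel, c(1, rep(0, n - 1)), tolerance = 1e-12)
  y <- rpois(n, 20)
  z1 <- em_ml_1d(y, op0, attenuation = rep(1, n), tau = 1, n_iter = 1)
  expect_equal(z1, as.numeric(y), tolerance = 1e-8)

  # log-likelihood non-decreasing along iterations
  set.seed(63)
  op <- operator_1d(n, 1.35)
  a <- 0.5 + 0.4 * exp(-((1:n - 16) / 8)^2)
  lam <- pmax(0.5 + sin((1:n) / 4), 0)
  y <- rpois(n, 300 * a * pmax(apply_kbeta(op, lam), 0))
  lls <- vapply(c(1, 2, 5, 10, 20, 40), function(k) {
    loglik_1d(y, em_ml_1d(y, op, a, 300, n_iter = k), op, a, 300)
  }, 0)
  expect_true(all(diff(lls) > -1e-6 * abs(lls[1])))

  # high-count limit: ML and LS agree within 2% relative L2 when both use
  # the same (non-negative) forward kernel; EM convergence on this
  # ill-conditioned deconvolution is slow, hence the long iteration run
  n2 <- 128
  op2 <- operator_1d(n2, 1.35)
  op2k <- op2
  op2k$multiplier <- pmax(Re(fft(op2$kernel)), 1e-6)
  a2 <- 0.5 + 0.4 * exp(-((1:n2 - 64) / 30)^2)
  lam2 <- pmax(0.5 + sin((1:n2) / 12), 0)
  tau <- 1e6
  y2 <- simulate_counts(pmax(a2 * apply_kbeta(op2, lam2, kernel = TRUE), 0),
                        tau, seed = 5)
  zls <- ls_reconstruct_1d(y2, op2k, a2, tau, bandwidth = 2)
  zml <- em_ml_1d(y2, op2, a2, tau, n_iter = 2000, bandwidth = 2)
  expect_lt(sqrt(sum((zml - zls)^2) / sum(zls^2)), 0.02)
})

test_that("Poisson count simulation has the stated moments", {
  # tau = 0: all zero
  expect_true(all(simulate_counts(matrix(2, 3, 4), 0, seed = 1) == 0))
  # mean and variance match tau * rate within CI
  rate <- c(0.5, 2, 7)
  tau <- 40
  draws <- vapply(1:3000, function(i) {
    simulate_counts(rate, tau, seed = 10000 + i)
  }, numeric(3))
  m <- rowMeans(draws); v <- apply(draws, 1, var)
  expect_true(all(abs(m - tau * rate) < 4 * sqrt(tau * rate / 3000)))
  expect_true(all(abs(v / (tau * rate) - 1) < 0.15))
  # reproducible under seed
  expect_identical(simulate_counts(rate, tau, seed = 7),
                   simulate_counts(rate, tau, seed = 7))
  expect_error(simulate_counts(c(-1, 2), 1), "non-negative")
})

test_that("2-D projector matches analytic geometry and its adjoint", {
  n <- 32
  geom <- sinogram_geometry(n)
  set.seed(64)
  x <- rnorm(n * n); y <- rnorm(geom$n_dist * geom$n_angle)
  lhs <- sum(radon_project(x, geom) * y)
  rhs <- sum(x * radon_backproject(y, geom))
  expect_lt(abs(lhs - rhs), 1e-10 * abs(lhs))

  # point source at the centre: near-constant ridge at distance 0
  img <- numeric(n * n)
  ctr <- (n / 2 - 1) * n + n / 2   # pixel nearest the origin
  img[ctr] <- 1
  sino <- matrix(radon_project(img, geom), geom$n_dist, geom$n_angle)
  ridge <- apply(sino, 2, which.max)
  mid <- which.min(abs(geom$dists))
  expect_true(all(abs(ridge - mid) <= 1))

  # uniform disk: chord-length profile 2 sqrt(r^2 - s^2)
  px <- 2 / n
  cc <- seq(-1 + px / 2, 1 - px / 2, length.out = n)
  xy <- expand.grid(x = cc, y = cc)
  r0 <- 0.6
  disk <- as.numeric(xy$x^2 + xy$y^2 <= r0^2)
  sino2 <- matrix(radon_project(disk, geom), geom$n_dist, geom$n_angle)
  chord <- ifelse(abs(geom$dists) < r0,
                  2 * sqrt(pmax(r0^2 - geom$dists^2, 0)), 0)
  err <- vapply(seq_len(geom$n_angle), function(a) {
    sqrt(mean((sino2[, a] - chord)^2))
  }, 0)
  expect_lt(max(err) / max(chord), 0.05)

  # attenuation factors in (0, 1]
  att <- attenuation_factors(0.5 * disk, geom)
  expect_true(all(att > 0 & att <= 1))
  expect_lt(min(att), 0.6)
})

test_that("FBP reconstruction is accurate, linear, and degrades gracefully", {
  n <- 48
  geom <- sinogram_geometry(n)
  px <- 2 / n
  cc <- seq(-1 + px / 2, 1 - px / 2, length.out = n)
  xy <- expand.grid(x = cc, y = cc)
  # smooth truth: sum of Gaussian blobs inside an ellipse
  truth <- 2 * exp(-((xy$x / 0.5)^2 + (xy$y / 0.4)^2)) +
    1.5 * exp(-(((xy$x - 0.25) / 0.15)^2 + ((xy$y - 0.1) / 0.15)^2))
  proj <- radon_project(truth, geom)
  rec <- fbp_reconstruct_2d(proj, geom, att_factors = 1, tau = 1,
                            bandwidth = 0.5)
  supp <- truth > 0.05 * max(truth)
  rel <- sqrt(sum((rec[supp, 1] - truth[supp])^2) / sum(truth[supp]^2))
  expect_lt(rel, 0.05)

  # linearity
  proj_b <- radon_project(0.5 * truth, geom)
  rec_ab <- fbp_reconstruct_2d(proj + proj_b, geom, 1, 1, 0.5)
  rec_b <- fbp_reconstruct_2d(proj_b, geom, 1, 1, 0.5)
  expect_equal(rec_ab, rec + rec_b, tolerance = 1e-10)

  # zero counts -> zero image
  expect_true(all(fbp_reconstruct_2d(0 * proj, geom, 1, 1, 1) == 0))
})

test_that("bandwidth selection is MSE-driven and scale equivariant", {
  n <- 32
  geom <- sinogram_geometry(n)
  set.seed(65)
  px <- 2 / n
  cc <- seq(-1 + px / 2, 1 - px / 2, length.out = n)
  xy <- expand.grid(x = cc, y = cc)
  truth_img <- 3 * exp(-((xy$x / 0.5)^2 + (xy$y / 0.4)^2))
  truth <- cbind(truth_img, 0.8 * truth_img, 0.5 * truth_img)
  proj <- radon_project(truth, geom)
  recon <- function(cnt, h) fbp_reconstruct_2d(cnt, geom, 1, tau, h)
  grid_h <- c(0.25, 0.5, 1, 2, 4)

  # noiseless data select the smallest bandwidth where inversion is exact
  # (the 1-D LS model); an edge warning flags the too-narrow grid
  op1 <- operator_1d(32, 1.35)
  lam1 <- pmax(0.4 + cos((1:32) / 5), 0)
  y1 <- 100 * apply_kbeta(op1, lam1)
  rec1 <- function(cnt, h) ls_reconstruct_1d(cnt, op1, rep(1, 32), 100, h)
  expect_warning(h0 <- select_bandwidth(rec1, cbind(y1), cbind(lam1),
                                        grid_h), "edge")
  expect_equal(h0, min(grid_h))
  tau <- 1

  # joint rescaling of truth and counts leaves the choice unchanged
  tau <- 300
  cnt <- simulate_counts(proj, tau, seed = 2)
  h1 <- suppressWarnings(select_bandwidth(recon, cnt, truth, grid_h))
  h2 <- suppressWarnings(select_bandwidth(
    function(cn, h) 4 * recon(cn, h), cnt, 4 * truth, grid_h))
  expect_equal(h1, h2)

  # smoothing decreases with dose: selection at low dose >= at 25x dose
  pick <- function(tau_val, sd_) {
    tau <<- tau_val
    cnt <- simulate_counts(proj, tau_val, seed = sd_)
    suppressWarnings(select_bandwidth(recon, cnt, truth, grid_h))
  }
  lo <- vapply(1:5, function(i) pick(60, i), 0)
  hi <- vapply(1:5, function(i) pick(1500, 100 + i), 0)
  expect_gte(median(lo), median(hi))
})

test_that("phantoms satisfy their structural contracts", {
  ph2 <- make_phantom("2d", "fdg", n = 24)
  expect_true(all(ph2$truth >= 0))
  expect_true(all(ph2$mu_map >= 0))
  expect_equal(dim(ph2$truth), c(24 * 24, 20))
  # reproducible bit-exactly
  ph2b <- make_phantom("2d", "fdg", n = 24)
  expect_identical(ph2$truth, ph2b$truth)

  ph1 <- make_phantom("1d", "flt", n = 64)
  expect_true(all(ph1$truth >= 0))
  expect_equal(ncol(ph1$alpha), 6L)           # six temporal components
  expect_equal(ncol(ph1$basis$X), 6L)
  expect_true(all(ph1$attenuation > 0 & ph1$attenuation <= 1))

  # count conservation in expectation: sum of expected counts equals
  # tau x sum of attenuated projected activity
  op <- operator_1d(64, 1.35)
  rate <- ph1$attenuation * apply_kbeta(op, ph1$truth[, 5])
  tau <- 100
  draws <- vapply(1:400, function(i) {
    sum(simulate_counts(pmax(rate, 0), tau, seed = i))
  }, 0)
  expect_lt(abs(mean(draws) - tau * sum(pmax(rate, 0))) /
              (tau * sum(pmax(rate, 0))), 0.01)
})
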