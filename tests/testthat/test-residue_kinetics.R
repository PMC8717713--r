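test_that("two-compartment residue reproduces its closed forms", {
  # Kety-Schmidt reduction: k3 = k4 = 0, f_b = 0 -> R(t) = k1 exp(-k2 t)
  R <- two_compartment_residue(0.1, 0.2, 0, 0, f_b = 0, T_B = 1e-3,
                               T_E = 90)
  tt <- c(0.5, 1, 5, 20, 60)
  expect_equal(petboot:::eval_residue(R, tt), 0.1 * exp(-0.2 * tt),
               tolerance = 1e-4)

  # triangular blood component integrates to f_b for any T_B (pure blood:
  # k1 = 0 removes the tissue impulse response)
  for (TB in c(1e-3, 1 / 12, 0.5)) {
    R2 <- two_compartment_residue(0, 0.2, 0.05, 0.004, f_b = 0.07,
                                  T_B = TB, T_E = 60)
    s <- residue_summaries(R2, T_B = TB, T_E = 60)
    expect_equal(s$V_B, 0.07, tolerance = 1e-3)
  }
  # with tissue present the overlap term vanishes linearly in T_B
  R2b <- two_compartment_residue(0.1, 0.2, 0.05, 0.004, f_b = 0.07,
                                 T_B = 1e-3, T_E = 60)
  expect_equal(residue_summaries(R2b, T_B = 1e-3, T_E = 60)$V_B, 0.07,
               tolerance = 1e-3)

  # k4 = 0 limits (small T_B, large T_E): the irreversible closed forms
  k1 <- 0.14; k2 <- 0.3; k3 <- 0.08; fb <- 0.04
  K1 <- (1 - fb) * k1
  R3 <- two_compartment_residue(k1, k2, k3, 0, f_b = fb, T_B = 1e-3,
                                T_E = 400)
  s3 <- residue_summaries(R3, T_B = 1e-3, T_E = 400)
  expect_equal(s3$K_i, K1 * k3 / (k2 + k3), tolerance = 1e-3)
  expect_equal(s3$K_D, K1 * k2 / (k2 + k3), tolerance = 1e-2)
  expect_equal(s3$V_D, K1 * k2 / (k2 + k3)^2, tolerance = 1e-2)
  expect_equal(s3$V_B, fb, tolerance = 1e-3)

  # error terms decrease linearly in T_B
  errs <- vapply(c(0.2, 0.1, 0.05), function(TB) {
    s <- residue_summaries(
      two_compartment_residue(k1, k2, k3, 0, f_b = fb, T_B = TB, T_E = 400),
      T_B = TB, T_E = 400)
    abs(s$K_D - K1 * k2 / (k2 + k3))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / errs[1], 0.5)

  # degenerate rate constants handled
  R4 <- two_compartment_residue(0.1, 0, 0, 0, f_b = 0, T_E = 10)
  expect_equal(petboot:::eval_residue(R4, 5), 0.1, tolerance = 1e-12)
})

test_that("residue decomposition follows its definition", {
  # constant residue: pure flux
  Rc <- constant_residue(0.3, T_E = 60)
  d <- decompose_residue(Rc, T_B = 0.1, T_E = 60)
  expect_equal(unique(d$R_E), 0.3)
  expect_equal(max(abs(d$R_B)), 0)
  expect_equal(max(abs(d$R_D)), 0)

  # R(t) = exp(-t): symbolic oracle
  tt <- seq(0, 5, by = 0.001)
  Re_ <- residue_model(tt, exp(-tt))
  TB <- 0.25; TE <- 5
  d2 <- decompose_residue(Re_, T_B = TB, T_E = TE)
  expect_equal(d2$R_E[1], exp(-TE), tolerance = 1e-6)
  expect_equal(d2$R_B[1], 1 - exp(-TB), tolerance = 1e-6)
  expect_equal(d2$R_D[1], exp(-TB) - exp(-TE), tolerance = 1e-6)
  # sum identity at every grid node
  expect_equal(d2$R_B + d2$R_D + d2$R_E,
               petboot:::eval_residue(Re_, d2$times), tolerance = 1e-9)

  expect_error(decompose_residue(Rc, T_B = 2, T_E = 1), "smaller")
})

test_that("monotone residue fitting recovers identifiable residues", {
  sch <- tiny_schedule(14)
  aif <- tiny_aif()
  T_end <- max(sch$mid_times + sch$durations / 2)

  # well-posed: fit on the generating knots -> near-exact recovery
  kn <- c(0.5, 3, T_end)
  th <- c(0.05, 0.03, 0.02)
  kn_eff <- c(0.5, 3, Inf)
  grid <- sort(unique(c(0, kn, seq(0, T_end, by = 0.02))))
  vals <- vapply(grid, function(t) sum(th[kn_eff > t + 1e-9]), 0)
  Rtrue <- residue_model(grid, vals)
  tac <- residue_subtac(Rtrue, aif, sch)
  Rfit <- fit_residue_model(tac, aif, sch, delay_grid = 0, knots = kn)
  tev <- seq(0, T_end, by = 0.05)
  rel <- sqrt(mean((petboot:::eval_residue(Rfit, tev) -
                    petboot:::eval_residue(Rtrue, tev))^2)) /
    sqrt(mean(petboot:::eval_residue(Rtrue, tev)^2))
  expect_lt(rel, 1e-3)

  # Patlak case: tac = c * running integral of Cp -> constant residue c
  # (identifiable over the sampled time range; the split between the last
  # two knots is not, so evaluation stops before them)
  pat <- residue_subtac(constant_residue(1, T_E = T_end), aif, sch)
  Rp <- fit_residue_model(0.015 * pat, aif, sch, delay_grid = 0)
  mid <- petboot:::eval_residue(Rp, c(1, 5, 10))
  expect_equal(mid, rep(0.015, 3), tolerance = 5e-3)

  # zero tac -> zero residue
  R0 <- fit_residue_model(rep(0, 14), aif, sch)
  expect_true(all(R0$values == 0))

  # AIF not covering the study -> error
  short_aif <- input_function(c(0, 1), c(0, 1))
  expect_error(fit_residue_model(tac, short_aif, sch), "cover")

  # default (over-parameterized) knots still reproduce the tissue curve
  Rfree <- fit_residue_model(tac, aif, sch, delay_grid = 0)
  tac_fit <- residue_subtac(Rfree, aif, sch)
  expect_lt(sqrt(mean((tac_fit - tac)^2)) / sqrt(mean(tac^2)), 1e-3)
})

test_that("non-negative mapping solves the constrained problem", {
  set.seed(41)
  T_ <- 12; K <- 3
  X <- matrix(runif(T_ * K, 0.2, 1), T_, K)
  w <- runif(T_, 0.5, 1.5)
  # exact recovery with non-negative generating coefficients
  alpha <- matrix(runif(40 * K, 0, 2), 40, K)
  z <- alpha %*% t(X)
  a_hat <- nnls_map(z, X, w)
  expect_equal(a_hat, alpha, tolerance = 1e-8)

  # active-set oracle at K = 2: enumerate all sign patterns
  X2 <- X[, 1:2]
  z1 <- matrix(X2[, 1] - 0.6 * X2[, 2], 1)    # unconstrained soln negative
  a2 <- as.numeric(nnls_map(z1, X2, w))
  obj <- function(a) sum(w * (as.numeric(z1) - as.numeric(X2 %*% a))^2)
  # oracle: best of {unconstrained clamped, each axis, zero}
  ls1 <- max(sum(w * X2[, 1] * z1) / sum(w * X2[, 1]^2), 0)
  ls2 <- max(sum(w * X2[, 2] * z1) / sum(w * X2[, 2]^2), 0)
  cands <- list(c(ls1, 0), c(0, ls2), c(0, 0))
  oracle_obj <- min(vapply(cands, obj, 0))
  expect_equal(a2[2], 0)
  expect_lte(obj(a2), oracle_obj + 1e-10)

  # optimality certificate against random non-negative candidates
  z3 <- matrix(rnorm(T_), 1)
  a3 <- as.numeric(nnls_map(z3, X, w))
  o3 <- sum(w * (as.numeric(z3) - as.numeric(X %*% a3))^2)
  for (i in 1:100) {
    cand <- runif(K, 0, 2)
    expect_gte(sum(w * (as.numeric(z3) - as.numeric(X %*% cand))^2),
               o3 - 1e-10)
  }
})

test_that("kinetic parameter maps follow the flow-weighted formulas", {
  summ <- data.frame(V_B = c(0.1, 0), K_D = c(0.2, 0.05),
                     V_D = c(0.5, 0.4), K_i = c(0, 0.02),
                     delay = c(0.1, 0.3))
  # single element, zero delay: MTT = V_D / K_D (central volume theorem)
  one <- data.frame(V_B = 0.05, K_D = 0.25, V_D = 0.75, K_i = 0.01,
                    delay = 0)
  m1 <- kinetic_params(matrix(2, 1, 1), one)
  expect_equal(unname(m1[1, "MTT"]), 0.75 / 0.25)
  expect_equal(unname(m1[1, "Vb"]), 0.1)
  expect_equal(unname(m1[1, "KiK1"]), 0.02 / (0.02 + 0.5))

  # two elements, alpha = (1,1): hand-computed flow-weighted average
  a <- matrix(c(1, 1), 1, 2)
  m2 <- kinetic_params(a, summ)
  w_flow <- c(1 * 0.2, 1 * 0.05); w_flow <- w_flow / sum(w_flow)
  delta_w <- sum(w_flow * c(0.1, 0.3))
  expect_equal(unname(m2[1, "MTT"]), delta_w + (0.5 + 0.4) / (0.2 + 0.05))
  expect_equal(unname(m2[1, "Ki"]), 0.02)
  expect_equal(unname(m2[1, "Kd"]), 0.25)

  # equal delays -> delay contribution constant across voxels
  summ_eq <- summ; summ_eq$delay <- 0.2
  A <- matrix(runif(20, 0.1, 2), 10, 2)
  m3 <- kinetic_params(A, summ_eq)
  vd <- as.numeric(A %*% summ_eq$V_D); kd <- as.numeric(A %*% summ_eq$K_D)
  expect_equal(unname(m3[, "MTT"] - vd / kd), rep(0.2, 10),
               tolerance = 1e-12)

  # all-zero coefficient row: maps 0 and undefined markers
  m4 <- kinetic_params(matrix(0, 1, 2), summ)
  expect_equal(unname(m4[1, c("Vb", "Vd", "Kd", "Ki")]), rep(0, 4))
  expect_true(is.na(m4[1, "MTT"]))
  expect_true(is.na(m4[1, "KiK1"]))
})

test_that("non-negative combinations of basis residues stay monotone", {
  sch <- tiny_schedule(12)
  T_end <- max(sch$mid_times + sch$durations / 2)
  gens <- list(spike_residue(5 / 60, T_E = T_end),
               constant_residue(1, T_E = T_end),
               two_compartment_residue(0.1, 0.3, 0.05, 0, f_b = 0.02,
                                       T_E = T_end))
  tev <- seq(0, T_end, by = 0.01)
  vals <- vapply(gens, petboot:::eval_residue, numeric(length(tev)), t = tev)
  set.seed(42)
  for (i in 1:50) {
    a <- runif(3, 0, 2)
    r <- as.numeric(vals %*% a)
    expect_true(all(diff(r) <= 1e-9 * max(r)))
  }
})

test_that("bootstrap kinetic mapping yields SD maps with the right structure", {
  set.seed(43)
  sch <- tiny_schedule(12)
  aif <- tiny_aif()
  T_end <- max(sch$mid_times + sch$durations / 2)
  gens <- list(blood = spike_residue(5 / 60, T_E = T_end),
               patlak = constant_residue(1, T_E = T_end))
  X <- vapply(gens, residue_subtac, numeric(12), aif = aif, schedule = sch)
  basis <- temporal_basis(X, names = names(gens), residues = gens,
                          delays = c(0, 0), aif_col = 1L, patlak_col = 2L)
  w <- rep(1, 12)

  # identical replicates -> zero SD maps
  z <- matrix(runif(30 * 12, 0, 2), 30, 12)
  same <- list(z, z, z)
  mb <- map_bootstrap_kinetics(same, basis, w)
  expect_true(all(mb$sd[is.finite(mb$sd)] == 0))
  expect_true(all(mb$sd[is.finite(mb$sd)] >= 0))

  # single-voxel linear case: bootstrap SD of V_d matches the closed-form
  # WLS standard error propagated through the linear map (constraints
  # inactive at this noise level)
  gens2 <- list(blood = gens$blood,
                tissue = two_compartment_residue(0.1, 0.3, 0, 0, f_b = 0,
                                                 T_E = T_end))
  X2 <- vapply(gens2, residue_subtac, numeric(12), aif = aif,
               schedule = sch)
  basis2 <- temporal_basis(X2, names = names(gens2), residues = gens2,
                           delays = c(0, 0), aif_col = 1L)
  sigma <- 0.02
  alpha_true <- c(0.4, 0.8)
  mu <- as.numeric(X2 %*% alpha_true)
  set.seed(99)
  reps <- lapply(1:2000, function(b) matrix(mu + rnorm(12, sd = sigma), 1))
  mbs <- map_bootstrap_kinetics(reps, basis2, w)
  Sig <- solve(t(X2) %*% X2)
  vD <- basis_kinetic_summaries(basis2)$V_D
  se_vd <- sigma * sqrt(as.numeric(t(vD) %*% Sig %*% vD))
  expect_lt(abs(mbs$sd[1, "Vd"] - se_vd) / se_vd, 0.1)
})

test_that("VOI percentile distributions behave like order statistics", {
  set.seed(44)
  N <- 400
  mask <- voi_mask(c(rep(TRUE, 100), rep(FALSE, 300)))
  # constant map: every percentile equals the constant
  cmap <- matrix(2.5, N, 6, dimnames = list(NULL, petboot:::KINETIC_PARAMS))
  expect_equal(voi_percentile_distribution(list(cmap, cmap), mask, 95, "Ki"),
               c(2.5, 2.5))
  # q = 100 -> maximum within the mask
  m2 <- cmap; m2[7, "Ki"] <- 9
  expect_equal(voi_percentile_distribution(list(m2), mask, 100, "Ki"), 9)
  # Gaussian map noise: replicate spread of the 95th percentile matches
  # order-statistic simulation
  maps <- lapply(1:400, function(b) {
    m <- cmap; m[, "Ki"] <- rnorm(N); m
  })
  got <- voi_percentile_distribution(maps, mask, 95, "Ki")
  oracle <- replicate(4000, quantile(rnorm(100), 0.95, names = FALSE))
  expect_lt(abs(mean(got) - mean(oracle)), 4 * sd(oracle) / sqrt(400) +
              4 * sd(oracle) / sqrt(4000))
  expect_lt(abs(sd(got) / sd(oracle) - 1), 0.25)
  expect_error(voi_percentile_distribution(maps,
    structure(list(indicator = rep(FALSE, N), label = "x"),
              class = "voi_mask"), 95, "Ki"), "empty")
})
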