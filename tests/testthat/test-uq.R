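test_that("parameter sampling recovers means, spreads and joint correlation", {
  d <- list(param_dist("alpha0", 2.7, 0.16 * 2.7),
            param_dist("kappa", 0.545, 0.0545, group = "thermal"),
            param_dist("vhc", 3.361e6, 3.361e5, group = "thermal"))
  X <- sample_parameters(d, 1e4, seed = 5,
                         group_correlation = list(thermal = 0.9))
  expect_equal(mean(X[, "alpha0"]), 2.7, tolerance = 0.03)
  expect_equal(sd(X[, "alpha0"]), 0.16 * 2.7, tolerance = 0.03)
  expect_equal(cor(X[, "kappa"], X[, "vhc"]), 0.9, tolerance = 0.035)
  expect_true(all(X > 0))
  # zero spread collapses to the means
  d0 <- lapply(d, function(p) { p$sd <- 0; p })
  X0 <- sample_parameters(d0, 5, seed = 5)
  expect_true(all(X0[, 1] == 2.7) && all(X0[, 3] == 3.361e6))
  # invalid joint correlation
  expect_error(sample_parameters(d, 10, 1,
                                 group_correlation = list(thermal = 1.5)),
               "positive definite")
})

test_that("scenario distributions carry the characterization uncertainties", {
  d <- scenario_distributions(30, 7.9)
  nm <- vapply(d, `[[`, character(1), "name")
  expect_setequal(nm, c("alpha0", "sos", "power", "rho", "kappa", "vhc"))
  a <- d[[which(nm == "alpha0")]]
  expect_equal(a$mean, 2.7)
  expect_equal(a$sd / a$mean, 0.16)
  p <- d[[which(nm == "power")]]
  expect_equal(p$sd / p$mean, 0.0105)
  expect_equal(d[[which(nm == "kappa")]]$group, "thermal")
})

test_that("expected experimental variability is 100 / SNR", {
  expect_equal(epsilon_from_snr(20), 5)
  expect_equal(epsilon_from_snr(100), 1)
  expect_equal(epsilon_from_snr(33.3), 3.0, tolerance = 0.01)
  expect_error(epsilon_from_snr(0), "positive")
})

test_that("the 95%-confidence iteration rule reproduces its worked cases", {
  expect_equal(required_iterations(0.129, 1, 3), 71L)
  expect_equal(required_iterations(0, 1, 3), 1L)
  expect_equal(required_iterations(0.03, 1, 3), 4L)
  expect_error(required_iterations(0.1, 0, 3), "zero")
})

test_that("SRC analysis standardizes regression coefficients", {
  set.seed(11)
  X <- cbind(x1 = rnorm(200, 10, 2), x2 = rnorm(200, 5, 1))
  # exactly linear: SRC of the only driver is 1 and R^2 = 1
  r1 <- src_analysis(X, X[, "x1"])
  expect_equal(unname(r1$src[["x1"]]), 1, tolerance = 1e-10)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  # independent-input linear model: sum SRC^2 = R^2 identity (columns made
  # empirically orthogonal so the finite-sample identity is exact)
  Xo <- X
  Xo[, 2] <- stats::residuals(stats::lm(X[, 2] ~ X[, 1])) + mean(X[, 2])
  Y <- 3 * Xo[, 1] - Xo[, 2]
  r2 <- src_analysis(Xo, Y)
  expect_equal(sum(r2$src^2), r2$r_squared, tolerance = 1e-10)
  # noisy known-coefficient recovery at the pooled sample size
  set.seed(12)
  Xn <- cbind(x1 = rnorm(568, 10, 2), x2 = rnorm(568, 5, 1))
  Yn <- 3 * Xn[, 1] - Xn[, 2] + rnorm(568, 0, 0.5)
  rn <- src_analysis(Xn, Yn)
  sd_y <- sd(Yn)
  expect_equal(unname(rn$src[["x1"]]), 3 * sd(Xn[, 1]) / sd_y,
               tolerance = 0.05)
  expect_equal(unname(rn$src[["x2"]]), -1 * sd(Xn[, 2]) / sd_y,
               tolerance = 0.05)
  # degenerate design matrices are refused
  expect_error(src_analysis(cbind(a = rep(1, 10), b = rep(2, 10)),
                            rnorm(10)), "rank deficient")
  expect_error(src_analysis(X[1:2, ], Y[1:2]), "more samples")
})

test_that("Monte Carlo summaries report U = 100 sd / mean per metric", {
  mc <- run_mc(linear_model(), linear_dists(), n = 400, seed = 21)
  Y <- mc$Y[, "y"]
  expect_equal(mc$summary$U, 100 * sd(Y) / mean(Y))
  # all-zero spreads give identical iterations and U = 0
  d0 <- lapply(linear_dists(), function(p) { p$sd <- 0; p })
  mc0 <- run_mc(linear_model(), d0, n = 5, seed = 21)
  expect_equal(mc0$summary$U, 0)
  # deterministic per seed
  mc2 <- run_mc(linear_model(), linear_dists(), n = 400, seed = 21)
  expect_identical(mc$Y, mc2$Y)
})

test_that("pooled split-seed runs are statistically equivalent to one run", {
  a <- run_mc(linear_model(), linear_dists(), n = 120, seed = 31)
  b <- run_mc(linear_model(), linear_dists(), n = 120, seed = 32)
  one <- run_mc(linear_model(), linear_dists(), n = 240, seed = 33)
  ks <- suppressWarnings(stats::ks.test(c(a$Y[, 1], b$Y[, 1]), one$Y[, 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("one-at-a-time uncertainties isolate each parameter exactly", {
  d <- linear_dists()
  oat <- one_at_a_time(linear_model(c(2, 1, 0)), d, n = 300, seed = 41)
  # matches a full MC with only that parameter varied, same seed, exactly
  d1 <- lapply(seq_along(d), function(i) {
    p <- d[[i]]; if (i != 1) p$sd <- 0; p
  })
  mc1 <- run_mc(linear_model(c(2, 1, 0)), d1, n = 300, seed = 41)
  expect_equal(oat$U_j[oat$parameter == "x1"], mc1$summary$U)
  # closed form on the sampled moments: Y = 2 x1 + x2, x2, x3 at their means
  X <- sample_parameters(d1, 300, seed = 41)
  Yexp <- 2 * X[, "x1"] + 5
  expect_equal(oat$U_j[oat$parameter == "x1"], 100 * sd(Yexp) / mean(Yexp),
               tolerance = 1e-12)
  # a parameter that never enters the model contributes zero uncertainty
  expect_equal(oat$U_j[oat$parameter == "x3"], 0, tolerance = 1e-12)
  expect_equal(oat$sigma_X_pct[oat$parameter == "x2"], 20)
})
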