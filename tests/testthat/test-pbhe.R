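phantom50 <- function() phantom_properties(50)

test_that("no deposition means no temperature rise", {
  m <- uniform_model(c(9, 9, 9), 1, phantom50())
  qf <- q_field(m$grid, array(0, dim = m$grid$shape))
  tf <- solve_pbhe(qf, m, thermal_sim_config(dt = 0.1, heat_duration = 1,
                                             total_duration = 2))
  expect_true(all(tf$data == 0))
})

test_that("zero conductivity gives the exact adiabatic ramp Q t / VHC", {
  props <- medium_properties(alpha0 = 4.2, sos = 1560, rho = 1040,
                             kappa = 0, vhc = 3.371e6)
  m <- uniform_model(c(7, 7, 7), 1, props)
  q <- array(0, dim = m$grid$shape)
  q[4, 4, 4] <- 1e7
  qf <- q_field(m$grid, q)
  for (scheme in c("adi", "explicit")) {
    cfg <- thermal_sim_config(dt = 0.08, heat_duration = 1.6,
                              total_duration = 2.4, scheme = scheme)
    tf <- solve_pbhe(qf, m, cfg)
    # during heating: linear ramp; frame values are window midpoints
    steps <- seq_len(dim(tf$data)[4])
    expected <- pmin(steps, 20) * 0.08 * 1e7 / 3.371e6
    expect_equal(tf$data[4, 4, 4, ], expected, tolerance = 1e-12)
    expect_true(all(tf$data[-4, , , ] == 0))
  }
})

test_that("a localized deposition relaxes along the analytic heat kernel", {
  props <- phantom50()
  D <- props$kappa / props$vhc * 1e6   # mm^2/s
  m <- uniform_model(c(41, 41, 41), 1, props,
                     origin = c(-20.5, -20.5, -20.5))
  grid <- m$grid
  x <- grid_coords(grid, 1); y <- grid_coords(grid, 2); z <- grid_coords(grid, 3)
  sig0 <- 2.5 # mm; initial Gaussian deposition width (resolved at 1-mm voxels)
  g <- exp(-outer(outer(x^2, y^2, "+"), z^2, "+") / (2 * sig0^2))
  dt <- 0.08
  q <- 1e8 * g                         # W/m^3 for one step
  qf <- q_field(grid, q)
  t_end <- 24
  cfg <- thermal_sim_config(dt = dt, heat_duration = dt,
                            total_duration = t_end, scheme = "adi")
  tf <- solve_pbhe(qf, m, cfg, frame_duration = t_end)
  Tend <- attr(tf, "final")
  # analytic: Gaussian stays Gaussian, variance grows by 2 D t per axis
  E_vox <- 1e8 * dt / props$vhc        # peak deposition in deg C
  sig2 <- sig0^2 + 2 * D * t_end
  amp <- E_vox * (sig0^2 / sig2)^(3 / 2)
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  analytic <- amp * exp(-r2 / (2 * sig2))
  core <- r2 <= (3 * sqrt(sig2))^2
  expect_lt(max(abs(Tend[core] - analytic[core])) / amp, 0.02)
})

test_that("frame averaging of a linear ramp returns window midpoints", {
  props <- medium_properties(alpha0 = 0, sos = 1500, rho = 1000, kappa = 0,
                             vhc = 2e6)
  m <- uniform_model(c(5, 5, 5), 1, props)
  q <- array(2e6, dim = m$grid$shape)  # dT/dt = 1 C/s everywhere (interior)
  qf <- q_field(m$grid, q)
  cfg <- thermal_sim_config(dt = 0.1, heat_duration = 4, total_duration = 4)
  tf <- solve_pbhe(qf, m, cfg, frame_duration = 1)
  # ramp a*t: frame over [t0, t0+1] averages to a*(t0 + 0.55) on the step grid
  mids <- vapply(1:4, function(f) mean(seq((f - 1) * 10 + 1, f * 10) * 0.1),
                 numeric(1))
  expect_equal(tf$data[3, 3, 3, ], mids, tolerance = 1e-12)
  # constant-in-time field: frame averaging is the identity
  cfg2 <- thermal_sim_config(dt = 0.1, heat_duration = 0, total_duration = 4)
  tf2 <- solve_pbhe(qf, m, cfg2, frame_duration = 1)
  expect_true(all(tf2$data == 0))
})

test_that("match_mrti reproduces affine fields exactly under resampling", {
  grid <- voxel_grid(c(8, 8, 8), 0.25, origin = c(0, 0, 0))
  x <- grid_coords(grid, 1)
  a <- array(0, dim = c(8, 8, 8, 4))
  for (f in 1:4) a[, , , f] <- outer(outer(2 * x, 0 * x, "+"), 0 * x, "+") + f
  tf <- temperature_field(grid, a, times = (1:4) * 0.5 - 0.25,
                          frame_duration = 0.5)
  out <- match_mrti(tf, frame_duration = 1, target_spacing = 0.5)
  expect_equal(dim(out$data), c(4L, 4L, 4L, 2L))
  # linear-in-x field: interior resampled values equal 2 * new x
  xn <- grid_coords(out$grid, 1)
  expect_equal(out$data[2:3, 2, 2, 1], 2 * xn[2:3] + 1.5, tolerance = 1e-12)
  expect_error(match_mrti(tf, frame_duration = 0.1), "at least")
})

test_that("the maximum principle holds after heat-off", {
  m <- uniform_model(c(15, 15, 15), 1, phantom50())
  q <- array(0, dim = m$grid$shape)
  q[8, 8, 8] <- 5e7
  qf <- q_field(m$grid, q)
  cfg <- thermal_sim_config(dt = 0.08, heat_duration = 0.8,
                            total_duration = 4)
  tf <- solve_pbhe(qf, m, cfg)
  peaks <- apply(tf$data, 4, max)
  after <- peaks[11:length(peaks)]
  expect_true(all(diff(after) <= 1e-12))
})

test_that("insulated-boundary heating balances energy step by step", {
  props <- phantom50()
  m <- uniform_model(c(13, 13, 13), 1, props)
  q <- array(0, dim = m$grid$shape)
  q[5:9, 5:9, 5:9] <- 2e7
  qf <- q_field(m$grid, q)
  cfg <- thermal_sim_config(dt = 0.08, heat_duration = 2, total_duration = 2,
                            boundary = "insulated")
  tf <- solve_pbhe(qf, m, cfg)
  dV <- (1e-3)^3
  Etot <- apply(tf$data, 4, function(a) sum(props$vhc * a) * dV)
  dE <- diff(c(0, Etot))
  expect_equal(dE, rep(sum(q) * dV * 0.08, length(dE)), tolerance = 0.005)
})

test_that("implicit stepping agrees with a fine-step explicit solution", {
  props <- phantom50()
  m <- uniform_model(c(17, 17, 17), 1, props)
  q <- array(0, dim = m$grid$shape)
  q[9, 9, 9] <- 5e7
  q[8:10, 8:10, 8:10] <- q[8:10, 8:10, 8:10] + 2e7
  qf <- q_field(m$grid, q)
  adi <- solve_pbhe(qf, m, thermal_sim_config(dt = 0.08, heat_duration = 4,
                                              total_duration = 4))
  expl <- solve_pbhe(qf, m, thermal_sim_config(dt = 0.008, heat_duration = 4,
                                               total_duration = 4,
                                               scheme = "explicit"))
  expect_equal(attr(adi, "final")[9, 9, 9], attr(expl, "final")[9, 9, 9],
               tolerance = 0.005)
})

test_that("an unstable explicit step size is refused with the stability bound", {
  m <- uniform_model(c(9, 9, 9), 0.25, phantom50())
  qf <- q_field(m$grid, array(0, dim = m$grid$shape))
  cfg <- thermal_sim_config(dt = 0.08, heat_duration = 1, total_duration = 1,
                            scheme = "explicit")
  expect_error(solve_pbhe(qf, m, cfg), "stability bound")
})
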