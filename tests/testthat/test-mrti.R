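# small noiseless truth series on an isotropic grid
make_truth <- function(shape = c(6, 6, 4), spacing = 1, dt = 0.42, nt = 16,
                       fill = NULL) {
  grid <- voxel_grid(shape, spacing, origin = c(0, 0, 0))
  a <- array(0, dim = c(shape, nt))
  if (is.null(fill)) {
    set.seed(9)
    base <- array(stats::runif(prod(shape)), dim = shape)
    for (f in seq_len(nt)) a[, , , f] <- base * f / nt
  } else {
    for (f in seq_len(nt)) a[, , , f] <- fill(f)
  }
  temperature_field(grid, a, times = seq_len(nt) * dt - dt / 2,
                    frame_duration = dt)
}

test_that("the noiseless identity chain reduces to frame averaging", {
  tr <- make_truth()
  s <- synthesize_mrti(tr, noise_sigma = 0, drift_rate = 0,
                       trigger_delay = 0, replicates = 1, seed = 1,
                       native_spacing = c(1, 1, 1), out_spacing = 1,
                       frame_duration = 3.36)
  expect_equal(dim(s$data)[4], 2L)
  manual <- apply(tr$data[, , , 1:8], 1:3, mean)
  expect_equal(s$data[, , , 1, 1], manual, tolerance = 1e-12)
})

test_that("the trigger delay shifts heating into the acquisition raster", {
  tr <- make_truth(dt = 0.25, nt = 16, fill = function(f)
    array(f * 0.25, dim = c(6, 6, 4)))  # ramp T = t
  s <- synthesize_mrti(tr, noise_sigma = 0, drift_rate = 0,
                       trigger_delay = 0.5, replicates = 1, seed = 1,
                       native_spacing = c(1, 1, 1), out_spacing = 1,
                       frame_duration = 2.0)
  # first acquisition frame spans sim time [-0.5, 1.5]: six heated steps of 8
  expect_equal(s$data[1, 1, 1, 1, 1], sum((1:6) * 0.25) / 8,
               tolerance = 1e-12)
  # later frames are full eight-step averages shifted by the delay
  expect_equal(s$data[1, 1, 1, 2, 1], mean((7:14) * 0.25), tolerance = 1e-12)
})

test_that("resampling through the native acquisition grid preserves the mean", {
  tr <- make_truth(shape = c(8, 8, 6), spacing = 0.5, dt = 0.42, nt = 8)
  manual <- apply(tr$data[, , , 1:8], 1:3, mean)
  s <- synthesize_mrti(tr, noise_sigma = 0, drift_rate = 0,
                       trigger_delay = 0, replicates = 1, seed = 1,
                       native_spacing = c(1, 1, 3), out_spacing = 0.5,
                       frame_duration = 3.36, interp = "fourier")
  expect_equal(dim(s$data)[1:3], c(8L, 8L, 6L))
  # zero-fill interpolation preserves the DC component exactly
  expect_equal(mean(s$data[, , , 1, 1]), mean(manual), tolerance = 1e-9)
  s2 <- synthesize_mrti(tr, noise_sigma = 0, drift_rate = 0,
                        trigger_delay = 0, replicates = 1, seed = 1,
                        native_spacing = c(1, 1, 3), out_spacing = 0.5,
                        frame_duration = 3.36, interp = "linear")
  expect_equal(dim(s2$data)[1:3], c(8L, 8L, 6L))
  # trilinear fallback stays within the data range
  expect_lte(max(s2$data), max(manual) + 1e-9)
  expect_gte(min(s2$data), min(manual) - 1e-9)
})

test_that("a thermometry-coefficient miscalibration scales the measurement", {
  tr <- make_truth()
  s1 <- synthesize_mrti(tr, 0, 0, 0, 1, 1, c(1, 1, 1), 1, 3.36)
  s2 <- synthesize_mrti(tr, 0, 0, 0, 1, 1, c(1, 1, 1), 1, 3.36,
                        wpcs_scale = 1.1)
  expect_equal(s2$data, 1.1 * s1$data, tolerance = 1e-12)
})

test_that("an injected linear drift is recovered from a non-heated region", {
  tr <- make_truth(shape = c(8, 8, 2), spacing = 1, dt = 0.42, nt = 13 * 8,
                   fill = function(f) array(0, dim = c(8, 8, 2)))
  s <- synthesize_mrti(tr, noise_sigma = 0, drift_rate = -0.007,
                       trigger_delay = 0, replicates = 1, seed = 2,
                       native_spacing = c(1, 1, 1), out_spacing = 1,
                       frame_duration = 3.36)
  expect_equal(dim(s$data)[4], 13L)
  region <- as.matrix(expand.grid(i = 1:6, j = 1:6, k = 1))
  ref <- fusuq:::region_series(s$data[, , , , 1], region)
  slope <- unname(coef(lm(ref ~ s$times))[2])
  expect_lt(abs(slope / -0.007 - 1), 0.05)
  # pure drift is removed exactly by the correction
  corrected <- correct_drift(s, region)
  expect_lt(max(abs(corrected$data)), 1e-10)
})

test_that("drift correction leaves sub-0.001 C/s residual drift under noise", {
  tr <- make_truth(shape = c(12, 6, 1), spacing = 1, dt = 3.36, nt = 13,
                   fill = function(f) array(0, dim = c(12, 6, 1)))
  fitreg <- as.matrix(expand.grid(i = 1:6, j = 1:6, k = 1))
  testreg <- as.matrix(expand.grid(i = 7:12, j = 1:6, k = 1))
  slopes <- vapply(1:100, function(sd) {
    s <- synthesize_mrti(tr, noise_sigma = 0.2, drift_rate = -0.007,
                         trigger_delay = 0, replicates = 1, seed = sd,
                         native_spacing = c(1, 1, 1), out_spacing = 1,
                         frame_duration = 3.36)
    s <- correct_drift(s, fitreg)
    ref <- fusuq:::region_series(fusuq:::mrti_replicate(s, 1), testreg)
    unname(coef(lm(ref ~ s$times))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.001)
})

test_that("correct_drift warns when the reference region overlaps heating", {
  tr <- make_truth(fill = function(f) array(5, dim = c(6, 6, 4)))
  s <- synthesize_mrti(tr, 0, -0.007, 0, 1, 1, c(1, 1, 1), 1, 3.36)
  expect_warning(correct_drift(s, as.matrix(expand.grid(1:6, 1:6, 1))),
                 "overlaps heating")
})

test_that("SNR is the spatiotemporal peak over the reference-region noise", {
  grid <- voxel_grid(c(10, 6, 1), 1, origin = c(0, 0, 0))
  data <- array(0, dim = c(10, 6, 1, 2, 1))
  # reference block with exact unit temporal standard deviation
  data[1:6, 1:6, 1, 1, 1] <- 1 / sqrt(2)
  data[1:6, 1:6, 1, 2, 1] <- -1 / sqrt(2)
  data[10, 1, 1, , 1] <- 20
  s <- structure(list(grid = grid, data = data, times = c(1, 2),
                      frame_duration = 1, noise_sigma = NA, drift_rate = 0,
                      replicates = 1, truth = NULL), class = "mrti_series")
  region <- as.matrix(expand.grid(i = 1:6, j = 1:6, k = 1))
  rep <- compute_snr(s, region)
  expect_equal(rep$sigma, 1)
  expect_equal(rep$snr, 20)
  # scaled to a bench-measured noise level: peak 2.36, sigma 0.240
  s2 <- s
  s2$data[1:6, 1:6, 1, , ] <- s$data[1:6, 1:6, 1, , ] * 0.240
  s2$data[10, 1, 1, , 1] <- 2.36
  expect_equal(compute_snr(s2, region)$snr, 9.83, tolerance = 0.01)
  # degenerate constant series
  s3 <- s
  s3$data[1:6, 1:6, 1, , ] <- 0
  expect_error(compute_snr(s3, region), "SNR undefined")
})

test_that("replicate averaging shrinks measured noise by sqrt(n)", {
  tr <- make_truth(shape = c(8, 8, 1), spacing = 1, dt = 3.36, nt = 13,
                   fill = function(f) array(0, dim = c(8, 8, 1)))
  region <- as.matrix(expand.grid(i = 1:6, j = 1:6, k = 1))
  sig <- function(reps, seed) {
    s <- synthesize_mrti(tr, noise_sigma = 0.3, drift_rate = 0,
                         trigger_delay = 0, replicates = reps, seed = seed,
                         native_spacing = c(1, 1, 1), out_spacing = 1,
                         frame_duration = 3.36)
    avg <- mrti_average(s)
    mean(apply(region, 1, function(v) sd(avg[v[1], v[2], v[3], ])))
  }
  ratios <- vapply(1:8, function(sd) sig(4, sd) / sig(1, sd + 100),
                   numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})

test_that("the emulation chain is deterministic per seed", {
  tr <- make_truth()
  s1 <- synthesize_mrti(tr, 0.2, -0.007, 0, 3, 42, c(1, 1, 1), 1, 3.36)
  s2 <- synthesize_mrti(tr, 0.2, -0.007, 0, 3, 42, c(1, 1, 1), 1, 3.36)
  expect_identical(s1$data, s2$data)
  expect_error(synthesize_mrti(tr, -0.1, 0, 0, 1, 1, c(1, 1, 1), 1, 3.36),
               "non-negative")
})
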