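# Shared absorbing-slab setup: normally incident plane wave entering a
# homogeneous gelatin slab from water. The transverse window is kept wide
# (121 mm) so Fresnel edge diffraction from the finite plane does not reach
# the center column over the slab depth.
slab_setup <- function() {
  phantom <- medium_properties(alpha0 = 4.2, sos = 1560.3, rho = 1040,
                               kappa = 0.565, vhc = 3.371e6)
  grid <- voxel_grid(c(121, 121, 33), 1)
  model <- material_map(grid, array(1L, dim = grid$shape),
                        list(phantom))
  # cosine-tapered edges: the center column then carries a clean plane wave
  x <- grid_coords(grid, 1)
  tp <- ifelse(abs(x) <= 30, 1,
               ifelse(abs(x) >= 58, 0, cos(pi / 2 * (abs(x) - 30) / 28)^2))
  plane <- outer(tp, tp) * (1 + 0i)
  list(model = model, plane = plane, phantom = phantom)
}

test_that("plane-wave decay through an absorbing slab follows Beer-Lambert", {
  s <- slab_setup()
  pf <- has_propagate(s$plane, s$model, 1e6)
  c0 <- 61
  # slice planes sample midpoints: |p_k| = t * exp(-alpha (k - 1/2) dz)
  amp <- Mod(pf$p[c0, c0, ])
  ratio <- amp[33] / amp[1]
  expect_equal(ratio, exp(-4.2 * 0.032), tolerance = 0.002)
  # the 3.2-cm effective-path example: amplitude ratio 0.874
  expect_equal(round(ratio, 3), 0.874)
})

test_that("absorbed power in a 1-D column balances the incident intensity", {
  s <- slab_setup()
  pf <- has_propagate(s$plane, s$model, 1e6)
  qf <- compute_q(pf, s$model)
  c0 <- 61
  w <- water_properties()
  Z1 <- w$rho * w$sos
  Z2 <- s$phantom$rho * s$phantom$sos
  tcoef <- 2 * Z2 / (Z1 + Z2)
  I_T <- tcoef^2 / (2 * Z2)               # transmitted intensity, |p0| = 1
  alpha <- 4.2
  L <- 0.033
  deposited <- sum(qf$q[c0, c0, ]) * 1e-3 # integral Q dz over the column
  expect_equal(deposited, I_T * (1 - exp(-2 * alpha * L)), tolerance = 0.005)
})

test_that("the water-phantom interface reflects the normal-incidence fraction", {
  w <- water_properties()
  p70 <- phantom_properties(70)
  grid <- voxel_grid(c(21, 21, 10), 1)
  labels <- array(1L, dim = grid$shape)
  labels[, , 6:10] <- 2L
  model <- material_map(grid, labels, list(w, p70))
  pf <- has_propagate(matrix(1 + 0i, 21, 21), model, 940e3)
  expect_length(pf$reflected, 1L)
  refl <- pf$reflected[[1]]
  expect_equal(refl$k, 6L)
  R_expect <- reflection_coefficients(w, p70)$pressure
  # incident amplitude just before the interface
  inc <- Mod(pf$p[11, 11, 5])
  expect_equal(Mod(refl$plane[11, 11]) / inc, R_expect, tolerance = 1e-3)
  expect_lt(abs(R_expect - 0.05), 0.003)
})

test_that("Q vanishes for zero pressure and in lossless water", {
  w <- water_properties()
  grid <- voxel_grid(c(9, 9, 5), 1)
  model <- material_map(grid, array(1L, dim = grid$shape), list(w))
  p0 <- pressure_field(grid, array(0 + 0i, dim = grid$shape), 940e3)
  expect_true(all(compute_q(p0, model)$q == 0))
  p1 <- pressure_field(grid, array(1e6 + 0i, dim = grid$shape), 940e3)
  expect_true(all(compute_q(p1, model)$q == 0))
})

test_that("optional reflected-wave deposition adds at most the R^2 fraction", {
  s <- slab_setup()
  grid <- s$model$grid
  labels <- array(1L, dim = grid$shape)
  labels[, , 17:33] <- 2L
  model <- material_map(grid, labels,
                        list(water_properties(), s$phantom))
  pf <- has_propagate(s$plane, model, 1e6)
  q1 <- compute_q(pf, model)
  q2 <- compute_q(pf, model, include_reflections = TRUE)
  extra <- sum(q2$q) - sum(q1$q)
  expect_gte(extra, 0)
  expect_lt(extra / sum(q1$q), 0.01)
})

test_that("free-space propagation conserves plane-integrated power", {
  w <- water_properties()
  grid <- voxel_grid(c(61, 61, 61), 1)
  model <- material_map(grid, array(1L, dim = grid$shape), list(w))
  x <- grid_coords(grid, 1); y <- grid_coords(grid, 2)
  r2 <- outer(x^2, y^2, "+")
  k_mm <- 2 * pi / (w$sos / 940e3 * 1000)
  plane <- exp(-r2 / (2 * 5^2)) * exp(-1i * k_mm * r2 / (2 * 50))
  pf <- has_propagate(plane, model, 940e3)
  pw <- fusuq:::plane_power(pf, model)
  expect_lt(max(abs(pw / pw[1] - 1)), 0.001)
})

test_that("hybrid angular spectrum matches direct Rayleigh-Sommerfeld near the focus", {
  wp <- fx_water_prop()
  grid <- wp$grid
  zc <- grid_coords(grid, 3)
  c0 <- (grid$shape[1] + 1) / 2
  # scale: the driven plane is a power-normalized copy of the direct field
  pts0 <- as.matrix(expand.grid(x = grid_coords(grid, 1)[c0],
                                y = grid_coords(grid, 2),
                                z = grid$origin[3]))
  direct0 <- fusuq:::rs_direct_field(wp$xd, pts0)
  scale <- max(Mod(wp$plane[c0, ])) / max(Mod(direct0))
  # on-axis profile across the focal region
  sel <- which(abs(zc - 100) <= 5)
  onax <- fusuq:::rs_direct_field(wp$xd, cbind(0, 0, zc[sel]))
  has_prof <- Mod(wp$pf$p[c0, c0, sel])
  ratio <- has_prof / (scale * Mod(onax))
  expect_lt(max(abs(ratio - 1)), 0.02)
  # transverse profile at the focal plane
  kf <- which.min(abs(zc - 100))
  ys <- grid_coords(grid, 2)
  sely <- which(abs(ys) <= 3)
  tr <- fusuq:::rs_direct_field(wp$xd, cbind(0, ys[sely], zc[kf]))
  err <- Mod(wp$pf$p[c0, sely, kf]) - scale * Mod(tr)
  expect_lt(max(abs(err)) / max(scale * Mod(tr)), 0.02)
})

test_that("propagation rejects mismatched grids", {
  s <- slab_setup()
  expect_error(has_propagate(matrix(1 + 0i, 5, 5), s$model, 1e6),
               "transverse grid")
})
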