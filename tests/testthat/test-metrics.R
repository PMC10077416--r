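full_mask <- function(shape, spacing = 2)
  structure_mask(array(TRUE, shape), "roi", spacing = spacing)

test_that("cumulative DVH reproduces step functions and brute-force counts", {
  g <- voxel_grid(array(10, c(4, 4, 2)))
  cv <- dvh(g, full_mask(c(4, 4, 2)))
  expect_true(all(cv$volume_axis[cv$dose_axis <= 10] == 100))
  expect_equal(cv$volume_axis[1], 100)
  expect_true(all(diff(cv$volume_axis) <= 0))

  h <- voxel_grid(array(rep(c(4, 8), each = 16), c(4, 4, 2)))
  cvh <- dvh(h, full_mask(c(4, 4, 2)))
  v5 <- approx(cvh$dose_axis, cvh$volume_axis, xout = 5)$y
  expect_equal(v5, 50, tolerance = 1)

  set.seed(9)
  r <- rand_grid(c(5, 5, 5), fn = function(n) runif(n, 0, 30))
  cvr <- dvh(r, full_mask(c(5, 5, 5)), n_bins = 64)
  expect_equal(cvr$volume_axis,
               oracle_dvh_counts(as.vector(r$values), cvr$dose_axis))
  expect_error(dvh(r, structure_mask(array(FALSE, c(5, 5, 5)), "empty")),
               class = "structure_too_small")
})

test_that("near-maximum D0.1cc interpolates the cumulative hot volume", {
  # voxel volume 0.05 cc: two hottest voxels span exactly 0.1 cc
  vv_spacing <- (0.05 * 1000)^(1 / 3)
  m <- full_mask(c(10, 1, 1), spacing = vv_spacing)
  g <- voxel_grid(array(10:1, c(10, 1, 1)), spacing = vv_spacing)
  expect_equal(d_volume(g, m, 0.1), 9)
  # the full structure volume returns the minimum
  expect_equal(d_volume(g, m, mask_volume_cc(m)), 1)
  expect_error(d_volume(g, m, mask_volume_cc(m) + 1),
               class = "structure_too_small")

  set.seed(21)
  shape <- c(10, 10, 2)
  msk <- full_mask(shape)
  r <- voxel_grid(array(runif(prod(shape), 0, 25), shape))
  vv <- voxel_volume_cc(msk)
  for (vol in c(0.1, 0.25, 0.5, 1))
    expect_equal(d_volume(r, msk, vol),
                 oracle_d_volume(as.vector(r$values), vv, vol),
                 tolerance = 1e-12)
  # voxel-quantized convention sits at the bracketing voxel
  q <- d_volume(r, msk, 0.1, interpolate = FALSE)
  expect_equal(q, sort(as.vector(r$values), decreasing = TRUE)[13])
})

test_that("mean, VxGy and volumes agree with loop oracles", {
  set.seed(31)
  shape <- c(8, 8, 4)
  msk <- rand_mask(shape, p = 0.6)
  g <- rand_grid(shape, fn = function(n) runif(n, 0, 12))
  expect_equal(mean_in_mask(g, msk), oracle_mean(g$values[msk$values]))
  expect_equal(v_dose(g, msk, 5), oracle_vx(g$values[msk$values], 5))
  expect_equal(v_dose(g, msk, 0), 100)
  expect_equal(v_dose(g, msk, max(g$values) + 1), 0)
  u <- grid_like(g, 3.3)
  expect_equal(mean_in_mask(u, msk), 3.3)
  expect_error(mean_in_mask(g, structure_mask(array(FALSE, shape), "e")),
               class = "structure_too_small")
  # volumes in cc are exactly voxel count x voxel volume
  expect_equal(mask_volume_cc(msk), sum(msk$values) * prod(msk$spacing) / 1000)
})

test_that("Dmean <= D0.1cc <= Dmax on random structures", {
  set.seed(41)
  for (rep in 1:25) {
    shape <- c(8, 8, 6)
    msk <- rand_mask(shape, p = runif(1, 0.3, 0.9))
    if (sum(msk$values) * voxel_volume_cc(msk) < 0.2) next
    g <- rand_grid(shape, fn = function(n) rgamma(n, 2, 0.5))
    dm <- mean_in_mask(g, msk)
    d01 <- d_volume(g, msk, 0.1)
    expect_lte(dm, d01 + 1e-12)
    expect_lte(d01, max(g$values[msk$values]) + 1e-12)
  }
})

test_that("d_volume is non-increasing in the hot-volume parameter", {
  set.seed(51)
  msk <- full_mask(c(10, 10, 4))
  g <- rand_grid(c(10, 10, 4), fn = function(n) runif(n, 0, 40))
  vols <- seq(0.05, mask_volume_cc(msk), length.out = 30)
  vals <- vapply(vols, function(v) d_volume(g, msk, v), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("coverage check compares D98 against 95% of prescription", {
  msk <- full_mask(c(6, 6, 6))
  at_rx <- voxel_grid(array(19.8, c(6, 6, 6)))
  expect_true(coverage_check(at_rx, msk, 19.8)$pass)
  low <- voxel_grid(array(0.9 * 19.8, c(6, 6, 6)))
  expect_false(coverage_check(low, msk, 19.8)$pass)

  # graded dose vs an independent percentile computation
  set.seed(61)
  g <- voxel_grid(array(runif(216, 17, 21), c(6, 6, 6)))
  cov <- coverage_check(g, msk, 19.8)
  want <- oracle_d_volume(as.vector(g$values), voxel_volume_cc(msk),
                          0.98 * mask_volume_cc(msk))
  expect_equal(cov$d98, want, tolerance = 1e-12)
})

test_that("dose-difference maps subtract voxel-wise and honour sentinels", {
  set.seed(71)
  a <- rand_grid(c(5, 5, 3), quantity = "dose_Gy_rbe")
  expect_true(all(delta_dose_map(a, a)$values == 0))
  b <- grid_like(a, a$values * 1.25)
  dd <- delta_dose_map(b, a)
  expect_equal(dd$values, a$values * 0.25)
  excl <- array(FALSE, c(5, 5, 3)); excl[1:4] <- TRUE
  attr(b, "excluded") <- excl
  expect_true(all(is.na(delta_dose_map(b, a)$values[1:4])))

  dose <- rand_grid(c(5, 5, 3))
  fx <- vrbe_weighted_dose(dose, a, fractionation(), rbe_params(fixed_rbe = 1.1))
  expect_true(all(delta_dose_map(fx, fx)$values == 0))
})

test_that("threshold-volume and overlap metrics match loop oracles", {
  set.seed(81)
  shape <- c(6, 6, 4)
  delta <- rand_grid(shape, fn = function(n) runif(n, -1, 5),
                     quantity = "delta_Gy_rbe")
  vv <- voxel_volume_cc(delta)
  expect_equal(volume_above(delta, 3),
               oracle_volume_above(as.vector(delta$values), 3, vv))
  expect_equal(volume_above(grid_like(delta, -2), 3), 0)
  # n qualifying voxels of volume v -> n*v
  k <- voxel_grid(array(c(rep(4, 7), rep(0, 137)), shape))
  expect_equal(volume_above(k, 3), 7 * vv)
  msk <- rand_mask(shape, p = 0.5)
  expect_equal(volume_above(delta, 3, msk),
               oracle_volume_above(delta$values[msk$values], 3, vv))

  dose <- rand_grid(shape, fn = function(n) runif(n, 0, 10))
  let <- rand_grid(shape, quantity = "let_keVum",
                   fn = function(n) runif(n, 0, 12))
  ov <- overlap_volume(dose, let)
  expect_equal(ov$volume_cc,
               oracle_overlap(as.vector(dose$values), as.vector(let$values),
                              max(dose$values), 0.8, 6, vv))
  # disjoint high-dose and high-LET regions
  d2 <- voxel_grid(array(c(rep(10, 72), rep(0.1, 72)), shape))
  l2 <- voxel_grid(array(c(rep(1, 72), rep(9, 72)), shape),
                   quantity = "let_keVum")
  expect_equal(overlap_volume(d2, l2)$volume_cc, 0)
  # constructed 3-voxel intersection with 0.008 cc voxels
  sm <- voxel_grid(array(10, c(3, 1, 1)), spacing = 2)
  sl <- voxel_grid(array(c(7, 8, 9), c(3, 1, 1)), spacing = 2,
                   quantity = "let_keVum")
  expect_equal(overlap_volume(sm, sl)$volume_cc, 3 * 0.008)
  # component-structure reporting
  hit <- structure_mask(array(c(TRUE, rep(FALSE, 143)), shape), "vertebra")
  miss <- structure_mask(array(FALSE, shape), "carina")
  d3 <- grid_like(dose, 10); l3 <- grid_like(let, 9)
  ov3 <- overlap_volume(d3, l3, structures = list(vertebra = hit, carina = miss))
  expect_identical(ov3$component_structures, "vertebra")
})
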