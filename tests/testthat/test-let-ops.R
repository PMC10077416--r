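beam_pair <- function(doses, lets, shape = c(1, 1, 1)) {
  mapply(function(d, l) list(
    dose = voxel_grid(array(d, shape), quantity = "dose_Gy"),
    let = voxel_grid(array(l, shape), quantity = "let_keVum")),
    doses, lets, SIMPLIFY = FALSE)
}

test_that("LET mixing is the relative-dose weighted mean", {
  bs <- beam_pair(c(1, 3), c(2, 4))
  expect_equal(mix_let(bs)$values[1], 3.5)
  # identical per-beam LET is a fixed point regardless of the dose split
  bs2 <- beam_pair(c(0.3, 5, 1.2), c(7, 7, 7))
  expect_equal(mix_let(bs2)$values[1], 7)
  # single beam: identity on its LET grid wherever dose > 0
  set.seed(1)
  d <- rand_grid(c(8, 8, 4))
  l <- rand_grid(c(8, 8, 4), quantity = "let_keVum")
  expect_equal(mix_let(list(list(dose = d, let = l)))$values, l$values)
})

test_that("mixed LET is bounded by the per-voxel input extremes", {
  set.seed(11)
  for (rep in 1:20) {
    nb <- sample(2:4, 1)
    shape <- c(6, 5, 4)
    bs <- lapply(seq_len(nb), function(i) list(
      dose = rand_grid(shape, fn = function(n) runif(n, 0, 5)),
      let = rand_grid(shape, quantity = "let_keVum",
                      fn = function(n) runif(n, 1, 12))))
    mixed <- mix_let(bs)$values
    lets <- sapply(bs, function(b) as.vector(b$let$values))
    lo <- apply(lets, 1, min); hi <- apply(lets, 1, max)
    ok <- !is.na(as.vector(mixed))
    expect_true(all(mixed[ok] >= lo[ok] - 1e-12))
    expect_true(all(mixed[ok] <= hi[ok] + 1e-12))
  }
})

test_that("mixing is invariant under common dose rescaling and flags undosed voxels", {
  set.seed(3)
  shape <- c(5, 5, 3)
  bs <- lapply(1:2, function(i) list(
    dose = rand_grid(shape), let = rand_grid(shape, quantity = "let_keVum")))
  m1 <- mix_let(bs)
  bs_scaled <- lapply(bs, function(b) {
    b$dose$values <- b$dose$values * 17.3; b
  })
  expect_equal(mix_let(bs_scaled)$values, m1$values, tolerance = 1e-14)

  bs[[1]]$dose$values[] <- 0
  bs[[2]]$dose$values[] <- 0
  expect_true(all(is.na(mix_let(bs)$values)))
  bad <- list(bs[[1]], list(dose = rand_grid(c(2, 2, 2)),
                            let = rand_grid(c(2, 2, 2))))
  expect_error(mix_let(bad), "mismatch")
})

test_that("dose thresholding removes exactly the sub-threshold voxels", {
  d <- voxel_grid(array(c(20, 0.9, 5), c(3, 1, 1)))
  l <- voxel_grid(array(c(4, 5, 6), c(3, 1, 1)), quantity = "let_keVum")
  out <- threshold_let(l, d, fraction = 0.05)
  expect_equal(as.vector(out$values), c(4, NA, 6))

  u <- grid_like(d, 7)  # uniform dose: nothing removed
  expect_false(anyNA(threshold_let(l, u)$values))

  set.seed(5)
  dose <- rand_grid(c(10, 10, 5), fn = function(n) runif(n, 0, 20))
  let <- rand_grid(c(10, 10, 5), quantity = "let_keVum")
  thr <- threshold_let(let, dose, fraction = 0.05)
  # survival count vs an explicit loop
  cutoff <- 0.05 * max(dose$values)
  n_surv <- 0L
  for (v in as.vector(dose$values)) if (v >= cutoff) n_surv <- n_surv + 1L
  expect_equal(sum(!is.na(thr$values)), n_surv)
  # idempotent
  thr2 <- threshold_let(thr, dose, fraction = 0.05)
  expect_identical(thr2$values, thr$values)
})

test_that("thresholding an undosed grid warns and excludes everything", {
  l <- rand_grid(c(3, 3, 3), quantity = "let_keVum")
  z <- grid_like(l, 0, quantity = "dose_Gy")
  expect_warning(out <- threshold_let(l, z), "all-zero")
  expect_true(all(is.na(out$values)))
})

test_that("the reference maximum can be restricted to the body mask", {
  d <- voxel_grid(array(c(100, rep(1, 7)), c(2, 2, 2)))
  l <- grid_like(d, 5, quantity = "let_keVum")
  body <- structure_mask(array(c(FALSE, rep(TRUE, 7)), c(2, 2, 2)), "body")
  # against the global max (100) every 1-Gy voxel dies; against the in-body
  # max (1) they all survive
  expect_equal(sum(!is.na(threshold_let(l, d)$values)), 1L)
  expect_equal(sum(!is.na(threshold_let(l, d, body_mask = body)$values)), 8L)
})
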