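# Independent brute-force oracles, deliberately written as plain scalar
# loops and kept separate from the vectorised package implementations.

# McNamara RBE evaluated one voxel at a time from the closed form
oracle_mcnamara <- function(d, let, ab, c1 = 0.99064, c2 = 0.35605,
                            c3 = 1.1012, c4 = 0.0038703) {
  out <- numeric(length(d))
  for (i in seq_along(d)) {
    rmax <- c1 + c2 * let[i] / ab
    rmin <- max(c3 - c4 * sqrt(ab) * let[i], 0)
    disc <- ab * ab + 4 * d[i] * ab * rmax + 4 * d[i]^2 * rmin^2
    out[i] <- (sqrt(disc) - ab) / (2 * d[i])
  }
  out
}

# hot-volume metric by explicit cumulative sort + interpolation
oracle_d_volume <- function(vals, voxel_cc, volume_cc) {
  vals <- sort(vals[!is.na(vals)], decreasing = TRUE)
  cum <- 0
  for (i in seq_along(vals)) {
    cum <- cum + voxel_cc
    if (cum >= volume_cc - 1e-12) {
      if (i == 1L) return(vals[1])
      c_prev <- (i - 1) * voxel_cc
      frac <- (volume_cc - c_prev) / voxel_cc
      return(vals[i - 1] + frac * (vals[i] - vals[i - 1]))
    }
  }
  stop("volume larger than structure")
}

oracle_mean <- function(vals) {
  vals <- vals[!is.na(vals)]
  s <- 0
  for (v in vals) s <- s + v
  s / length(vals)
}

oracle_vx <- function(vals, thr) {
  vals <- vals[!is.na(vals)]
  n <- 0L
  for (v in vals) if (v >= thr) n <- n + 1L
  100 * n / length(vals)
}

oracle_dvh_counts <- function(vals, edges) {
  vals <- vals[!is.na(vals)]
  out <- numeric(length(edges))
  for (j in seq_along(edges)) {
    n <- 0L
    for (v in vals) if (v >= edges[j]) n <- n + 1L
    out[j] <- 100 * n / length(vals)
  }
  out
}

oracle_volume_above <- function(vals, thr, voxel_cc) {
  n <- 0L
  for (v in vals) if (!is.na(v) && v >= thr) n <- n + 1L
  n * voxel_cc
}

oracle_overlap <- function(dose, let, dmax, dose_fraction, let_thr, voxel_cc) {
  n <- 0L
  for (i in seq_along(dose))
    if (dose[i] >= dose_fraction * dmax && !is.na(let[i]) &&
        let[i] >= let_thr) n <- n + 1L
  n * voxel_cc
}

# --- fixture builders ------------------------------------------------------

rand_grid <- function(shape = c(10, 10, 8), spacing = 2, quantity = "dose_Gy",
                      fn = stats::runif) {
  voxel_grid(array(fn(prod(shape)), shape), spacing = spacing,
             quantity = quantity)
}

rand_mask <- function(shape = c(10, 10, 8), spacing = 2, p = 0.5,
                      name = "roi") {
  structure_mask(array(stats::runif(prod(shape)) < p, shape), name,
                 spacing = spacing)
}

# small, fast study configuration for end-to-end unit tests (the full-size
# default configuration is exercised in the acceptance suite)
small_config <- function(...) {
  cfg <- default_study_config()
  cfg$grid$shape <- c(60, 50, 20)
  cfg$grid$spacing <- c(4, 4, 4)
  cfg$plans <- list(`1F` = 0, `2F` = c(10, 350))
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}
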