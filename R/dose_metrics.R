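#' "Structure too small" condition
#'
#' Near-maximum metrics over a hot volume larger than the structure itself
#' are not extrapolated; they raise a classed error (condition class
#' `"structure_too_small"`), mirroring how very small structures are reported
#' as missing rather than estimated.
#' @param msg message.
#' @keywords internal
stop_too_small <- function(msg) {
  stop(structure(class = c("structure_too_small", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# structure values entering a statistic: inside mask, minus NA sentinels and
# any voxels flagged excluded by vrbe_weighted_dose()
eval_values <- function(grid, mask) {
  check_congruent(grid, mask)
  keep <- mask$values
  excl <- attr(grid, "excluded")
  if (!is.null(excl)) keep <- keep & !excl
  v <- grid$values[keep]
  v[!is.na(v)]
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure volume receiving at least each dose level, on a
#' regular dose axis from 0 to the structure maximum. Excluded-sentinel
#' voxels are omitted (they never enter LET or vRBE statistics); physical
#' dose grids carry no sentinels, so dose DVHs use every structure voxel.
#'
#' @param grid a [voxel_grid()] (dose, vRBE-weighted dose, or LET).
#' @param mask a [structure_mask()].
#' @param n_bins number of dose bins.
#' @return An object of class `dvh_curve` with `dose_axis` (ascending, first
#'   element 0) and `volume_axis` (% of structure volume, non-increasing,
#'   100 at dose 0).
#' @export
dvh <- function(grid, mask, n_bins = 200) {
  v <- eval_values(grid, mask)
  if (!length(v)) stop_too_small(sprintf("structure '%s' has no evaluable voxels",
                                         mask$name))
  top <- max(v)
  dose_axis <- seq(0, max(top, .Machine$double.eps), length.out = n_bins + 1)
  cnt <- length(v) - findInterval(dose_axis, sort(v), left.open = TRUE)
  structure(list(dose_axis = dose_axis,
                 volume_axis = 100 * cnt / length(v),
                 structure = mask$name, quantity = grid$quantity),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s (%s): %d bins, max %.4g\n", x$structure,
              x$quantity, length(x$dose_axis), max(x$dose_axis)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ..., xlab = NULL, ylab = "Volume [%]") {
  if (is.null(xlab))
    xlab <- if (grepl("let", x$quantity)) "LET [keV/um]" else "Dose [Gy]"
  graphics::plot(x$dose_axis, x$volume_axis, type = "s", xlab = xlab,
                 ylab = ylab, ylim = c(0, 100), main = x$structure, ...)
  invisible(x)
}

#' Near-maximum value over a hot volume (D0.1cc-style)
#'
#' The lowest dose (or LET) received by the hottest `volume_cc` of the
#' structure: voxels are sorted descending, voxel volumes accumulated, and
#' the value at cumulative volume `volume_cc` returned, linearly interpolated
#' between the bracketing voxels (set `interpolate = FALSE` for the
#' voxel-quantized convention). `volume_cc` equal to the full structure
#' volume returns the structure minimum. A structure smaller than the
#' requested hot volume raises a `"structure_too_small"` error rather than
#' extrapolating.
#'
#' @param grid a [voxel_grid()].
#' @param mask a [structure_mask()].
#' @param volume_cc hot volume in cc (default 0.1).
#' @param interpolate linear interpolation in cumulative volume (default) or
#'   the value of the bracketing voxel.
#' @return Gy (or keV/um for LET grids).
#' @export
d_volume <- function(grid, mask, volume_cc = 0.1, interpolate = TRUE) {
  v <- eval_values(grid, mask)
  vv <- voxel_volume_cc(mask)
  tot <- length(v) * vv
  if (!length(v) || tot < volume_cc)
    stop_too_small(sprintf(
      "structure '%s' (%.4g cc evaluable) smaller than requested hot volume %.4g cc",
      mask$name, tot, volume_cc))
  v <- sort(v, decreasing = TRUE, method = "radix")  # stable tie-break
  cum <- seq_along(v) * vv
  if (volume_cc <= cum[1]) return(v[1])
  if (!interpolate) return(v[which(cum >= volume_cc - 1e-12)[1]])
  stats::approx(cum, v, xout = volume_cc)$y
}

#' Mean value within a structure
#'
#' @inheritParams d_volume
#' @return Arithmetic mean over evaluable structure voxels.
#' @export
mean_in_mask <- function(grid, mask) {
  v <- eval_values(grid, mask)
  if (!length(v)) stop_too_small(sprintf("structure '%s' has no evaluable voxels",
                                         mask$name))
  mean(v)
}

#' Relative volume at or above a dose threshold (VxGy)
#'
#' @inheritParams d_volume
#' @param threshold dose threshold in Gy (or keV/um).
#' @return Percentage of evaluable structure volume with value >= threshold.
#' @export
v_dose <- function(grid, mask, threshold) {
  v <- eval_values(grid, mask)
  if (!length(v)) stop_too_small(sprintf("structure '%s' has no evaluable voxels",
                                         mask$name))
  100 * mean(v >= threshold)
}

#' CTV coverage check
#'
#' Evaluates the planning criterion that 98% of the CTV receives at least
#' 95% of the prescription dose. D98% is the dose exceeded by 98% of the
#' structure volume, i.e. [d_volume()] with the hot volume set to 98% of the
#' CTV volume.
#'
#' @param dose composite physical (or RBE-weighted) dose [voxel_grid()].
#' @param ctv_mask CTV [structure_mask()].
#' @param prescription prescription dose in Gy.
#' @return List with `d98` (Gy) and `pass` (logical).
#' @export
coverage_check <- function(dose, ctv_mask, prescription) {
  d98 <- d_volume(dose, ctv_mask, volume_cc = 0.98 * mask_volume_cc(ctv_mask))
  list(d98 = d98, pass = d98 >= 0.95 * prescription)
}

#' Voxel-wise dose-difference map
#'
#' Subtracts the fixed-RBE(1.1)-weighted dose from the variable-RBE-weighted
#' dose voxel by voxel. Voxels excluded in either input carry the `NA`
#' sentinel in the difference map. Nothing is clipped.
#'
#' @param vrbe_dose variable-RBE-weighted dose [voxel_grid()] in Gy(RBE).
#' @param fixed_dose fixed-RBE-weighted dose [voxel_grid()] in Gy(RBE).
#' @return A [voxel_grid()] with quantity `"delta_Gy_rbe"`.
#' @export
delta_dose_map <- function(vrbe_dose, fixed_dose) {
  check_congruent(vrbe_dose, fixed_dose)
  excl <- array(FALSE, dim(vrbe_dose$values))
  for (g in list(vrbe_dose, fixed_dose)) {
    e <- attr(g, "excluded")
    if (!is.null(e)) excl <- excl | e
    excl <- excl | is.na(g$values)
  }
  vals <- vrbe_dose$values - fixed_dose$values
  vals[excl] <- NA_real_
  grid_like(vrbe_dose, vals, quantity = "delta_Gy_rbe")
}

#' Volume with values at or above a threshold, in cc
#'
#' Total volume (voxel count times voxel volume) of voxels with
#' `delta >= threshold`, optionally restricted to a structure. `NA`-sentinel
#' voxels never qualify.
#'
#' @param delta a [voxel_grid()] (typically a [delta_dose_map()]).
#' @param threshold threshold in the grid's units (default 3 Gy(RBE)).
#' @param mask optional [structure_mask()] restriction.
#' @return Volume in cc.
#' @export
volume_above <- function(delta, threshold = 3.0, mask = NULL) {
  q <- !is.na(delta$values) & delta$values >= threshold
  if (!is.null(mask)) {
    check_congruent(delta, mask)
    q <- q & mask$values
  }
  sum(q) * voxel_volume_cc(delta)
}

#' High-dose / high-LET overlap volume
#'
#' Volume of voxels simultaneously receiving at least `dose_fraction` of the
#' maximum composite dose and an LET of at least `let_threshold`. The dose
#' maximum is taken within the body mask when supplied, consistent with the
#' LET thresholding convention. Optionally reports which structures the
#' overlap region intersects.
#'
#' @param dose composite physical dose [voxel_grid()].
#' @param let composite (thresholded) LET [voxel_grid()]; `NA` voxels never
#'   qualify.
#' @param dose_fraction fraction of maximum dose (default 0.8).
#' @param let_threshold LET threshold in keV/um (default 6).
#' @param body_mask optional reference mask for the dose maximum.
#' @param structures optional named list of [structure_mask()]s to intersect
#'   with the overlap region.
#' @return List with `volume_cc` and `component_structures` (names of
#'   intersecting structures, possibly empty).
#' @export
overlap_volume <- function(dose, let, dose_fraction = 0.8, let_threshold = 6.0,
                           body_mask = NULL, structures = NULL) {
  check_congruent(dose, let)
  ref <- if (is.null(body_mask)) dose$values
         else masked_values(dose, body_mask, drop_excluded = FALSE)
  mx <- suppressWarnings(max(ref, na.rm = TRUE))
  ov <- dose$values >= dose_fraction * mx &
    !is.na(let$values) & let$values >= let_threshold
  comps <- character(0)
  if (!is.null(structures))
    comps <- names(structures)[vapply(structures, function(m) {
      check_congruent(dose, m); any(ov & m$values)
    }, logical(1))]
  list(volume_cc = sum(ov) * voxel_volume_cc(dose),
       component_structures = comps)
}
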