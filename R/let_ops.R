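#' Combine per-beam LET grids by relative-dose weighting
#'
#' For a plan with several fields, the composite dose-averaged LET in a voxel
#' is the average of the per-beam LETs weighted by the relative dose each
#' beam delivers to that voxel:
#' \deqn{L = \sum_b d_b L_b / \sum_b d_b}
#' Voxels receiving no dose from any beam are undefined and carry the `NA`
#' sentinel. The same rule combines energy layers within a beam in the
#' simulator, so synthetic generation and analysis share one definition.
#'
#' @param beam_set list of beams, each a list with elements `dose` and `let`
#'   ([voxel_grid()]s of congruent geometry). A [assemble_plan()] result's
#'   `$beams` field is accepted directly.
#' @return Composite LET [voxel_grid()] (keV/um) with `NA` where total dose
#'   is zero.
#' @examples
#' g <- function(v, q) voxel_grid(array(v, c(1, 1, 2)), quantity = q)
#' b <- list(list(dose = g(1, "dose_Gy"), let = g(2, "let_keVum")),
#'           list(dose = g(3, "dose_Gy"), let = g(4, "let_keVum")))
#' mix_let(b)$values  # 3.5 keV/um in every voxel
#' @export
mix_let <- function(beam_set) {
  stopifnot(length(beam_set) >= 1L)
  ref <- beam_set[[1]]$dose
  dsum <- array(0, dim(ref$values))
  dlsum <- array(0, dim(ref$values))
  for (b in beam_set) {
    check_congruent(ref, b$dose)
    check_congruent(ref, b$let)
    dsum <- dsum + b$dose$values
    dlsum <- dlsum + b$dose$values * b$let$values
  }
  vals <- ifelse(dsum > 0, dlsum / dsum, NA_real_)
  grid_like(ref, vals, quantity = "let_keVum")
}

#' Threshold an LET grid to adequately dosed voxels
#'
#' Voxels whose total physical dose is below a fraction (default 5%) of the
#' maximum dose contain too few particles for a meaningful dose-averaged LET
#' and are excluded: they receive the `NA` sentinel. The reference maximum is
#' the composite-plan dose maximum, taken within the body mask when one is
#' supplied (otherwise over the whole grid). The operation is idempotent.
#'
#' @param let composite LET [voxel_grid()].
#' @param total_dose composite physical dose [voxel_grid()], congruent.
#' @param fraction dose threshold as a fraction of the maximum, in (0, 1).
#' @param body_mask optional [structure_mask()] restricting the reference
#'   maximum.
#' @return The LET grid with sub-threshold voxels set to `NA`.
#' @export
threshold_let <- function(let, total_dose, fraction = 0.05, body_mask = NULL) {
  check_congruent(let, total_dose)
  stopifnot(fraction > 0, fraction < 1)
  ref <- if (is.null(body_mask)) total_dose$values
         else masked_values(total_dose, body_mask, drop_excluded = FALSE)
  mx <- suppressWarnings(max(ref, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    warning("all-zero dose grid: every LET voxel excluded")
    return(grid_like(let, array(NA_real_, dim(let$values))))
  }
  vals <- let$values
  vals[total_dose$values < fraction * mx] <- NA_real_
  grid_like(let, vals)
}
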