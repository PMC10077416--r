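#' RBE model parameters
#'
#' Parameters of the McNamara linear-quadratic variable-RBE model for
#' protons, plus the degenerate fixed-RBE setting. The model expresses
#' RBEmax (the low-dose limit) as a linear function of dose-averaged LET and
#' RBEmin (the high-dose limit) as linear in LET times the square root of the
#' tissue alpha/beta ratio:
#'
#' \deqn{RBE_{max} = c_1 + c_2 \, LET_d / (\alpha/\beta)}
#' \deqn{RBE_{min} = c_3 - c_4 \sqrt{\alpha/\beta} \, LET_d}
#'
#' Default coefficients are the published McNamara fit values. `RBEmin` is
#' floored at 0 so that extreme LET outside the fitted range clamps rather
#' than producing a negative square-root argument downstream.
#'
#' When `fixed_rbe` is set (e.g. 1.1, the clinical constant), the variable
#' model is bypassed entirely and that constant is used everywhere.
#'
#' @param alpha_beta tissue (alpha/beta)_x in Gy; 2 Gy is typical for
#'   late-responding organs at risk.
#' @param c1,c2 RBEmax coefficients (unitless; c2 scales LET/(alpha/beta)).
#' @param c3,c4 RBEmin coefficients (c4 in um/keV per sqrt(Gy)).
#' @param fixed_rbe optional constant RBE that bypasses the variable model.
#' @return An object of class `rbe_params`.
#' @examples
#' rbe_params(alpha_beta = 2)
#' rbe_params(fixed_rbe = 1.1)
#' @export
rbe_params <- function(alpha_beta = 2, c1 = 0.99064, c2 = 0.35605,
                       c3 = 1.1012, c4 = 0.0038703, fixed_rbe = NULL) {
  stopifnot(alpha_beta > 0)
  if (!is.null(fixed_rbe)) stopifnot(is.numeric(fixed_rbe), fixed_rbe > 0)
  structure(list(alpha_beta = alpha_beta, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 fixed_rbe = fixed_rbe),
            class = "rbe_params")
}

#' @export
print.rbe_params <- function(x, ...) {
  if (!is.null(x$fixed_rbe))
    cat(sprintf("<rbe_params> fixed RBE = %g\n", x$fixed_rbe))
  else
    cat(sprintf(
      "<rbe_params> McNamara, alpha/beta = %g Gy (c1 %g, c2 %g, c3 %g, c4 %g)\n",
      x$alpha_beta, x$c1, x$c2, x$c3, x$c4))
  invisible(x)
}

#' Fractionation scheme
#'
#' @param total_dose prescription total dose in Gy (> 0).
#' @param n_fractions number of fractions (>= 1).
#' @return An object of class `fractionation`.
#' @export
fractionation <- function(total_dose = 19.8, n_fractions = 11) {
  stopifnot(total_dose > 0, n_fractions >= 1, n_fractions == round(n_fractions))
  structure(list(total_dose = total_dose, n_fractions = as.integer(n_fractions)),
            class = "fractionation")
}

#' Maximum RBE (low-dose limit)
#'
#' `RBEmax = c1 + c2 * LETd / (alpha/beta)`: the RBE in the limit of
#' vanishing dose per fraction, linear in dose-averaged LET.
#'
#' @param let_d dose-averaged LET in keV/um, `>= 0`.
#' @param params an [rbe_params()] object.
#' @return Unitless RBEmax, same length as `let_d`.
#' @export
rbe_max <- function(let_d, params = rbe_params()) {
  if (any(let_d < 0, na.rm = TRUE)) stop("let_d must be >= 0")
  params$c1 + params$c2 * let_d / params$alpha_beta
}

#' Minimum RBE (high-dose limit)
#'
#' `RBEmin = c3 - c4 * sqrt(alpha/beta) * LETd`, floored at 0.
#'
#' @inheritParams rbe_max
#' @return Unitless RBEmin, same length as `let_d`.
#' @export
rbe_min <- function(let_d, params = rbe_params()) {
  if (any(let_d < 0, na.rm = TRUE)) stop("let_d must be >= 0")
  pmax(params$c3 - params$c4 * sqrt(params$alpha_beta) * let_d, 0)
}

#' McNamara variable RBE
#'
#' Full linear-quadratic RBE at a given dose per fraction and dose-averaged
#' LET:
#' \deqn{RBE = \frac{1}{2d}\left[\sqrt{(\alpha/\beta)^2 +
#'   4d(\alpha/\beta)RBE_{max} + 4d^2 RBE_{min}^2} - (\alpha/\beta)\right]}
#' If `params$fixed_rbe` is set, that constant is returned regardless of dose
#' and LET. Forcing `RBEmax = RBEmin = c` (e.g. `c1 = c3 = c`,
#' `c2 = c4 = 0`) collapses the expression algebraically to the constant `c`.
#'
#' @param dose_per_fraction physical dose per fraction in Gy, `> 0`.
#' @param let_d dose-averaged LET in keV/um, `>= 0`.
#' @param params an [rbe_params()] object.
#' @return Unitless RBE, vectorised over inputs.
#' @examples
#' mcnamara_rbe(1.8, 6, rbe_params(alpha_beta = 2))
#' @export
mcnamara_rbe <- function(dose_per_fraction, let_d, params = rbe_params()) {
  if (!is.null(params$fixed_rbe))
    return(rep(params$fixed_rbe, max(length(dose_per_fraction), length(let_d))))
  if (any(dose_per_fraction <= 0, na.rm = TRUE))
    stop("dose_per_fraction must be > 0 (threshold zero-dose voxels first)")
  if (any(let_d < 0, na.rm = TRUE)) stop("let_d must be >= 0")
  ab <- params$alpha_beta
  d <- dose_per_fraction
  rmax <- rbe_max(let_d, params)
  rmin <- rbe_min(let_d, params)
  # algebraically (sqrt(ab^2 + 4 d ab RBEmax + 4 d^2 RBEmin^2) - ab) / (2d),
  # rationalised to avoid catastrophic cancellation at small d
  disc <- ab^2 + 4 * d * ab * rmax + 4 * d^2 * rmin^2
  (2 * ab * rmax + 2 * d * rmin^2) / (ab + sqrt(disc))
}

#' Variable-RBE-weighted dose grid
#'
#' Converts a physical total-dose grid and a (thresholded) LET grid into an
#' RBE-weighted dose grid. The dose per fraction is the voxel's total dose
#' divided by the fraction count (uniform fractionation). Voxels with
#' sentinel (`NA`) LET or zero dose receive the value 0 and are flagged as
#' excluded from the evaluable volume (attribute `"excluded"`, a logical
#' array); downstream LET/vRBE statistics omit them. With a fixed-RBE
#' parameter set the output is simply `fixed_rbe * total_dose` everywhere
#' and no voxel is excluded.
#'
#' @param total_dose physical dose [voxel_grid()] in Gy.
#' @param let_d dose-averaged LET [voxel_grid()], already thresholded
#'   ([threshold_let()]); ignored in fixed-RBE mode.
#' @param scheme a [fractionation()] object.
#' @param params an [rbe_params()] object.
#' @return A [voxel_grid()] in Gy(RBE) with attribute `"excluded"`.
#' @export
vrbe_weighted_dose <- function(total_dose, let_d, scheme = fractionation(),
                               params = rbe_params()) {
  if (!is.null(params$fixed_rbe)) {
    out <- grid_like(total_dose, params$fixed_rbe * total_dose$values,
                     quantity = "dose_Gy_rbe")
    attr(out, "excluded") <- array(FALSE, dim(total_dose$values))
    return(out)
  }
  check_congruent(total_dose, let_d)
  excl <- is.na(let_d$values) | total_dose$values <= 0
  vals <- array(0, dim(total_dose$values))
  if (any(!excl)) {
    d <- total_dose$values[!excl] / scheme$n_fractions
    vals[!excl] <- total_dose$values[!excl] *
      mcnamara_rbe(d, let_d$values[!excl], params)
  }
  out <- grid_like(total_dose, vals, quantity = "dose_Gy_rbe")
  attr(out, "excluded") <- excl
  out
}
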