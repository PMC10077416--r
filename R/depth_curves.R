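#' Parametric depth-dose and depth-LET curves
#'
#' Analytical stand-ins for Monte-Carlo proton depth curves in water. The
#' depth dose is a pseudo-Bortfeld pristine Bragg curve: a slowly rising
#' power-law plateau (proportional to 1/(R - z)^0.23), a near-range boost, and
#' a Gaussian-smoothed peak and distal falloff with sigma equal to the range
#' straggling. The depth LET is
#' `L(z) = let_plateau + let_scale * (1/(R - z + s) - 1/(R + s))` for
#' `z <= R` (entrance-anchored so `L(0) = let_plateau` exactly),
#' clipped at `let_cap` and held at the cap over the distal falloff
#' (`R < z < R + 3 sigma`), which reproduces the sharp LET increase at the
#' proton end of range with three interpretable parameters.
#'
#' @param plateau_dose entrance dose relative to the Bragg-peak dose.
#' @param peak_width_mm width of the near-range boost region (mm); the peak of
#'   the smoothed curve falls within this distance of the nominal range.
#' @param straggling_sigma_mm Gaussian sigma of the distal falloff (mm).
#' @param let_plateau plateau dose-averaged LET (keV/um).
#' @param let_scale scale of the distal LET rise (keV/um * mm).
#' @param let_softening_mm softening length preventing divergence at z = R.
#' @param let_cap maximum LET (keV/um).
#' @return An object of class `depth_curve_params`.
#' @export
depth_curve_params <- function(plateau_dose = 0.35, peak_width_mm = 5,
                               straggling_sigma_mm = 2.5,
                               let_plateau = 1.5, let_scale = 25,
                               let_softening_mm = 2, let_cap = 15) {
  stopifnot(plateau_dose > 0, peak_width_mm > 0, straggling_sigma_mm > 0,
            let_plateau >= 0, let_scale > 0, let_softening_mm > 0,
            let_cap > let_plateau)
  structure(list(plateau_dose = plateau_dose, peak_width_mm = peak_width_mm,
                 straggling_sigma_mm = straggling_sigma_mm,
                 let_plateau = let_plateau, let_scale = let_scale,
                 let_softening_mm = let_softening_mm, let_cap = let_cap),
            class = "depth_curve_params")
}

# pre-smoothing shape: power-law plateau up to R, plus a unit boxcar over the
# last peak_width mm that the Gaussian convolution turns into the Bragg peak;
# scale calibrates the entrance-to-peak ratio
pristine_raw_dose <- function(z, range_R, p, scale = p$plateau_dose) {
  plateau <- ifelse(z <= range_R,
                    scale *
                      ((range_R + p$peak_width_mm - z) /
                         (range_R + p$peak_width_mm))^(-0.23),
                    0)
  boost <- as.numeric(z >= range_R - p$peak_width_mm & z <= range_R)
  plateau + boost
}

#' Pristine Bragg-peak depth dose
#'
#' Relative dose of a single energy layer at depth `depth` for a layer of
#' residual range `range_R`, normalised to 1 at the Bragg peak.
#'
#' @param depth depth(s) in mm along the beam axis, `>= 0`.
#' @param range_R residual range of the layer in mm water, `> 0`.
#' @param p a [depth_curve_params()] object.
#' @return Relative dose, same length as `depth`; zero well beyond the range.
#' @examples
#' p <- depth_curve_params()
#' pristine_peak_dose(c(0, 100, 150, 180), 150, p)
#' @export
pristine_peak_dose <- function(depth, range_R, p = depth_curve_params()) {
  if (any(depth < 0)) stop("depth must be >= 0")
  if (range_R <= 0) stop("range_R must be > 0")
  crv <- bragg_curve(range_R, p)
  out <- stats::approx(crv$z, crv$dose, xout = depth, yleft = crv$dose[1],
                       yright = 0, rule = 2)$y
  out[depth > range_R + 8 * p$straggling_sigma_mm] <- 0
  pmax(out, 0)
}

# smoothed, peak-normalised curve on a fine grid; one evaluation per layer
bragg_curve <- function(range_R, p) {
  sg <- p$straggling_sigma_mm
  h <- min(sg, p$peak_width_mm) / 4
  pad <- 6 * sg
  z <- seq(-pad, range_R + 2 * pad, by = h)
  k <- stats::dnorm(seq(-4 * sg, 4 * sg, by = h), sd = sg)
  k <- k / sum(k)
  smooth_one <- function(scale) {
    raw <- pristine_raw_dose(pmax(z, 0), range_R, p, scale)
    raw[z < 0] <- raw[z == min(z[z >= 0])][1]  # flat extension, no edge dip
    stats::filter(raw, k, sides = 2)
  }
  # two fixed-point passes pin the entrance-to-peak ratio at plateau_dose
  scale <- p$plateau_dose
  for (pass in 1:2) {
    sm <- smooth_one(scale)
    keep <- !is.na(sm) & z >= 0
    zz <- z[keep]; dd <- as.numeric(sm[keep])
    r0 <- dd[1] / max(dd)
    scale <- scale * p$plateau_dose / r0
  }
  list(z = zz, dose = dd / max(dd))
}

#' Pristine Bragg-peak depth LET
#'
#' Dose-averaged LET of a single energy layer at depth `depth`: constant
#' `let_plateau` in the plateau, rising as `let_scale / (R - z + softening)`
#' towards the range, clipped at `let_cap` and held at the cap beyond `R`.
#' Monotone non-decreasing in depth.
#'
#' @inheritParams pristine_peak_dose
#' @return LET in keV/um, same length as `depth`.
#' @examples
#' p <- depth_curve_params()
#' pristine_peak_let(c(0, 100, 148, 152), 150, p)
#' @export
pristine_peak_let <- function(depth, range_R, p = depth_curve_params()) {
  if (any(depth < 0)) stop("depth must be >= 0")
  if (range_R <= 0) stop("range_R must be > 0")
  s <- p$let_softening_mm
  # entrance-anchored so L(0) is exactly let_plateau
  L <- p$let_plateau +
    p$let_scale * (1 / (range_R - depth + s) - 1 / (range_R + s))
  L[depth > range_R] <- p$let_cap
  pmin(pmax(L, p$let_plateau), p$let_cap)
}

#' Spread-out Bragg peak layer weights
#'
#' Finds nonnegative layer weights so that the weighted sum of pristine depth
#' doses is flat (value 1) across a target depth interval, by nonnegative
#' least squares on a fine depth grid. Warns if the achievable ripple exceeds
#' `ripple_tol`.
#'
#' @param target_interval numeric length-2, depth interval `[mm, mm]` to cover.
#' @param layer_ranges strictly increasing residual ranges of the available
#'   layers (mm); must cover the target interval.
#' @param p a [depth_curve_params()] object.
#' @param ripple_tol maximum allowed max/min dose ratio minus one over the
#'   target interval (default 0.03).
#' @param step depth-grid step for the fit (mm).
#' @return Numeric vector of nonnegative weights, one per layer, with the
#'   achieved ripple in attribute `"ripple"`.
#' @examples
#' p <- depth_curve_params()
#' w <- build_sobp(c(100, 130), seq(98, 134, by = 4), p)
#' @export
build_sobp <- function(target_interval, layer_ranges, p = depth_curve_params(),
                       ripple_tol = 0.03, step = 0.5) {
  stopifnot(length(target_interval) == 2L,
            target_interval[1] < target_interval[2])
  if (is.unsorted(layer_ranges, strictly = TRUE))
    stop("layer_ranges must be strictly increasing")
  if (min(layer_ranges) > target_interval[1] + p$peak_width_mm ||
      max(layer_ranges) < target_interval[2] - p$peak_width_mm)
    stop("layer ranges do not cover the target interval")
  z <- seq(target_interval[1], target_interval[2], by = step)
  A <- vapply(layer_ranges, function(R) pristine_peak_dose(z, R, p),
              numeric(length(z)))
  A <- matrix(A, nrow = length(z))
  w <- pracma::lsqnonneg(A, rep(1, length(z)))$x
  w[w < 0] <- 0
  achieved <- as.numeric(A %*% w)
  ripple <- max(achieved) / min(achieved) - 1
  if (!is.finite(ripple) || ripple > ripple_tol)
    warning(sprintf(
      "SOBP flatness %.1f%% exceeds tolerance %.1f%%; returning best-achievable weights",
      100 * ripple, 100 * ripple_tol))
  attr(w, "ripple") <- ripple
  w
}
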