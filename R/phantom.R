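#' Synthetic water-equivalent phantom
#'
#' Builds a mediastinal-style phantom on a regular voxel lattice: an
#' elliptical water body, a CTV in the anterior mediastinum, a heart with a
#' left-atrium-like substructure abutting the posterior-distal surface of the
#' CTV, two lungs, spinal cord and esophagus, plus a deliberately tiny
#' coronary-artery-like structure used to exercise the "structure too small"
#' path of near-maximum metrics. All geometry parameters come from the
#' configuration list (see [default_study_config()]), not from code.
#'
#' The phantom is uniform water inside the body: depth along a beam is the
#' geometric path length from body entry, so water-equivalent and geometric
#' depth coincide.
#'
#' @param config study configuration list; only `$grid` and `$phantom` are
#'   used. Defaults to the shipped configuration.
#' @return An object of class `phantom` with fields `grid_shape`, `spacing`,
#'   `origin`, `body_mask`, `ctv_mask` and `oar_masks` (named list of
#'   [structure_mask()] objects).
#' @examples
#' ph <- build_phantom()
#' names(ph$oar_masks)
#' @export
build_phantom <- function(config = default_study_config()) {
  gs <- config$grid
  shape <- as.integer(gs$shape)
  spacing <- as.numeric(gs$spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(shape) == 3L, all(shape > 0), all(spacing > 0))
  origin <- -(shape - 1) * spacing / 2  # lattice centred on the isocentre

  ax <- lapply(1:3, function(i) origin[i] + (seq_len(shape[i]) - 1) * spacing[i])
  # broadcast coordinates to the full lattice
  X <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)

  ellipsoid <- function(centre, semi) {
    (X - centre[1])^2 / semi[1]^2 + (Y - centre[2])^2 / semi[2]^2 +
      (Z - centre[3])^2 / semi[3]^2 <= 1
  }
  zcyl <- function(centre_xy, radius) {
    (X - centre_xy[1])^2 + (Y - centre_xy[2])^2 <= radius^2
  }
  msk <- function(values, name)
    structure_mask(values, name, spacing = spacing, origin = origin)

  ph <- config$phantom
  body <- (X / ph$body$semi_axes[1])^2 + (Y / ph$body$semi_axes[2])^2 <= 1
  ctv <- ellipsoid(ph$ctv$centre, ph$ctv$semi_axes) & body

  oars <- list()
  for (nm in names(ph$structures)) {
    st <- ph$structures[[nm]]
    m <- switch(st$shape,
      ellipsoid = ellipsoid(st$centre, st$semi_axes),
      zcylinder = zcyl(st$centre[1:2], st$radius) &
        abs(Z - st$centre[3]) <= st$half_length,
      stop("unknown structure shape: ", st$shape))
    oars[[nm]] <- msk(m & body, nm)
  }
  oars[["body"]] <- msk(body, "body")

  structure(
    list(grid_shape = shape, spacing = spacing, origin = origin,
         body_mask = msk(body, "body"), ctv_mask = msk(ctv, "ctv"),
         oar_masks = oars),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels at %s mm\n",
              paste(x$grid_shape, collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  body %.0f cc, CTV %.1f cc; OARs: %s\n",
              mask_volume_cc(x$body_mask), mask_volume_cc(x$ctv_mask),
              paste(names(x$oar_masks), collapse = ", ")))
  invisible(x)
}

#' Treatment field specification
#'
#' One proton field: gantry angle in the axial plane (0 = anterior, angles
#' increase clockwise viewed from the feet; 180 = posterior), the residual
#' ranges and weights of its energy layers, and the lateral aperture
#' parameters. Layer ranges/weights may be left `NULL` and filled in by the
#' simulator from the projected CTV extent via [build_sobp()].
#'
#' @param angle_deg gantry angle in degrees, `[0, 360)`.
#' @param layer_ranges strictly increasing residual ranges (mm water), or
#'   `NULL` to auto-select.
#' @param layer_weights nonnegative layer weights, or `NULL` to auto-solve.
#' @param aperture_margin_mm lateral margin added around the projected CTV.
#' @param penumbra_sigma_mm Gaussian penumbra sigma (mm).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(angle_deg, layer_ranges = NULL, layer_weights = NULL,
                      aperture_margin_mm = 10, penumbra_sigma_mm = 4) {
  stopifnot(is.numeric(angle_deg), length(angle_deg) == 1L,
            angle_deg >= 0, angle_deg < 360)
  if (!is.null(layer_ranges) && is.unsorted(layer_ranges, strictly = TRUE))
    stop("layer_ranges must be strictly increasing")
  if (!is.null(layer_weights) && any(layer_weights < 0))
    stop("layer_weights must be nonnegative")
  structure(list(angle_deg = angle_deg, layer_ranges = layer_ranges,
                 layer_weights = layer_weights,
                 aperture_margin_mm = aperture_margin_mm,
                 penumbra_sigma_mm = penumbra_sigma_mm),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> gantry %g deg, %s layers, margin %g mm, penumbra %g mm\n",
              x$angle_deg,
              if (is.null(x$layer_ranges)) "auto" else length(x$layer_ranges),
              x$aperture_margin_mm, x$penumbra_sigma_mm))
  invisible(x)
}

# beam-frame coordinates of every voxel: s along the beam, u lateral in the
# axial plane, plus the z index; angle 0 points in +y (anterior -> posterior)
beam_frame <- function(phantom, angle_deg) {
  th <- angle_deg * pi / 180
  d <- c(sin(th), cos(th))
  shape <- phantom$grid_shape
  ax <- lapply(1:3, function(i)
    phantom$origin[i] + (seq_len(shape[i]) - 1) * phantom$spacing[i])
  X <- rep(ax[[1]], times = shape[2] * shape[3])
  Y <- rep(rep(ax[[2]], each = shape[1]), times = shape[3])
  list(s = X * d[1] + Y * d[2],
       u = X * d[2] - Y * d[1],
       zi = rep(seq_len(shape[3]), each = shape[1] * shape[2]),
       z = rep(ax[[3]], each = shape[1] * shape[2]))
}

# depth from body entry along the beam for every voxel (NA outside the body);
# rays are discretised into lateral bins one voxel wide
beam_depth <- function(phantom, angle_deg) {
  fr <- beam_frame(phantom, angle_deg)
  inside <- as.vector(phantom$body_mask$values)
  if (!any(inside)) stop("beam does not intersect the phantom")
  ub <- as.integer(round(fr$u / phantom$spacing[1]))
  ray <- (ub - min(ub[inside])) * phantom$grid_shape[3] + fr$zi
  depth <- rep(NA_real_, length(fr$s))
  entry <- tapply(fr$s[inside], ray[inside], min)
  depth[inside] <- fr$s[inside] - entry[as.character(ray[inside])]
  list(depth = depth, u = fr$u, z = fr$z, inside = inside)
}

#' Per-beam dose and LET grids
#'
#' Computes the physical dose and dose-averaged LET of one field on the
#' phantom lattice. Voxel dose is the weighted sum of pristine layer doses at
#' the voxel's water depth times the lateral aperture profile; voxel LET is
#' the dose-weighted average of the pristine layer LETs, i.e. the same
#' relative-dose mixing rule used to combine beams ([mix_let()]) applied
#' across energy layers. Depth is the geometric path length from the body
#' surface along the beam direction; dose is zero outside the body and
#' outside the aperture plus three penumbra sigmas.
#'
#' @param phantom a [build_phantom()] object.
#' @param beam a [beam_spec()]; `NULL` layer ranges/weights are auto-filled
#'   from the projected CTV depth extent.
#' @param p a [depth_curve_params()] object.
#' @param layer_spacing_mm spacing of auto-selected layer ranges.
#' @return List with elements `dose` and `let` (two [voxel_grid()]s) and the
#'   completed `beam` spec.
#' @export
compute_beam_dose_let <- function(phantom, beam, p = depth_curve_params(),
                                  layer_spacing_mm = 3) {
  dp <- beam_depth(phantom, beam$angle_deg)
  ctv <- as.vector(phantom$ctv_mask$values)
  if (!any(dp$inside)) stop("beam does not intersect the phantom")
  dctv <- dp$depth[ctv]
  if (!length(dctv) || all(is.na(dctv)))
    stop("beam does not intersect the CTV")

  if (is.null(beam$layer_ranges)) {
    tgt <- range(dctv)
    # layers overshoot the target by ~6 mm on both sides so the NNLS solve
    # can hold the summed dose flat right up to the target edges
    beam$layer_ranges <- seq(tgt[1] - 6, tgt[2] + 6, by = layer_spacing_mm)
    beam$layer_weights <- build_sobp(tgt, beam$layer_ranges, p)
  } else if (is.null(beam$layer_weights)) {
    beam$layer_weights <- build_sobp(range(dctv), beam$layer_ranges, p)
  }

  # lateral profile: projected-CTV box + margin, convolved with a Gaussian
  uc <- dp$u[ctv]; zc <- dp$z[ctv]
  m <- beam$aperture_margin_mm
  sg <- beam$penumbra_sigma_mm
  ubox <- range(uc) + c(-m, m)
  zbox <- range(zc) + c(-m, m)
  edge <- function(t, lo, hi)
    stats::pnorm((hi - t) / sg) - stats::pnorm((lo - t) / sg)
  lat <- edge(dp$u, ubox[1], ubox[2]) * edge(dp$z, zbox[1], zbox[2])
  lat[dp$u < ubox[1] - 3 * sg | dp$u > ubox[2] + 3 * sg |
      dp$z < zbox[1] - 3 * sg | dp$z > zbox[2] + 3 * sg] <- 0

  idx <- which(dp$inside & lat > 0 & !is.na(dp$depth))
  dsum <- numeric(length(dp$depth))
  dlsum <- numeric(length(dp$depth))
  for (k in seq_along(beam$layer_ranges)) {
    wk <- beam$layer_weights[k]
    if (wk <= 0) next
    Rk <- beam$layer_ranges[k]
    dk <- wk * pristine_peak_dose(dp$depth[idx], Rk, p)
    dsum[idx] <- dsum[idx] + dk
    dlsum[idx] <- dlsum[idx] + dk * pristine_peak_let(dp$depth[idx], Rk, p)
  }
  dose <- dsum * lat
  let <- ifelse(dsum > 0, dlsum / dsum, 0)
  let[dose <= 0] <- 0

  shape <- phantom$grid_shape
  mk <- function(v, q) voxel_grid(array(v, shape), spacing = phantom$spacing,
                                  origin = phantom$origin, quantity = q,
                                  provenance = sprintf("beam %g deg", beam$angle_deg))
  list(dose = mk(dose, "dose_Gy"), let = mk(let, "let_keVum"), beam = beam)
}

#' Assemble a treatment plan from beams
#'
#' Computes per-beam dose/LET grids for every field and rescales all beam
#' doses by one global factor so that the median composite physical dose over
#' the CTV equals the prescription total dose. The normalisation convention
#' (CTV median = prescription) is a package design choice.
#'
#' @param phantom a [build_phantom()] object.
#' @param beams list of [beam_spec()] objects (at least one).
#' @param prescription list with `total_dose` (Gy) and `n_fractions`.
#' @param p a [depth_curve_params()] object.
#' @param layer_spacing_mm passed to [compute_beam_dose_let()].
#' @param noise_sd_frac optional relative standard deviation of multiplicative
#'   Gaussian voxel noise applied to each per-beam dose before normalisation
#'   (0 disables; uses the session RNG, so a fixed seed reproduces the plan
#'   bit-identically).
#' @return An object of class `plan_dose`: per-beam `$beams` (each with
#'   `dose`, `let`, `beam`), the `$composite_dose` grid (sum over beams),
#'   `$prescription` and the `$phantom`.
#' @export
assemble_plan <- function(phantom, beams, prescription = list(total_dose = 19.8,
                                                              n_fractions = 11),
                          p = depth_curve_params(), layer_spacing_mm = 3,
                          noise_sd_frac = 0) {
  stopifnot(length(beams) >= 1L, prescription$total_dose > 0,
            prescription$n_fractions >= 1)
  per_beam <- lapply(beams, function(b)
    compute_beam_dose_let(phantom, b, p, layer_spacing_mm))
  if (noise_sd_frac > 0)
    for (i in seq_along(per_beam)) {
      v <- per_beam[[i]]$dose$values
      per_beam[[i]]$dose$values <-
        v * pmax(1 + stats::rnorm(length(v), sd = noise_sd_frac), 0)
    }
  comp <- Reduce(`+`, lapply(per_beam, function(b) b$dose$values))
  med <- stats::median(comp[phantom$ctv_mask$values])
  if (!is.finite(med) || med <= 0)
    stop("CTV receives no dose; cannot normalise the plan")
  f <- prescription$total_dose / med
  for (i in seq_along(per_beam))
    per_beam[[i]]$dose$values <- per_beam[[i]]$dose$values * f
  comp_grid <- voxel_grid(comp * f, spacing = phantom$spacing,
                          origin = phantom$origin, quantity = "dose_Gy",
                          provenance = "composite physical dose")
  structure(list(beams = per_beam, composite_dose = comp_grid,
                 prescription = prescription, phantom = phantom),
            class = "plan_dose")
}

#' @export
print.plan_dose <- function(x, ...) {
  angs <- vapply(x$beams, function(b) b$beam$angle_deg, numeric(1))
  cat(sprintf("<plan_dose> %d field(s) at %s deg; %.4g Gy / %d fx\n",
              length(x$beams), paste(angs, collapse = "/"),
              x$prescription$total_dose, x$prescription$n_fractions))
  cat(sprintf("  CTV median dose %.4g Gy, max composite %.4g Gy\n",
              stats::median(x$composite_dose$values[x$phantom$ctv_mask$values]),
              max(x$composite_dose$values)))
  invisible(x)
}
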