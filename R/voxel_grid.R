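#' Voxel grids and structure masks
#'
#' A `voxel_grid` is a 3-D scalar field on a regular grid: dose in Gy, LET in
#' keV/um, RBE (unitless) or a dose difference in Gy(RBE). The array is stored
#' with x varying fastest (standard R array order with dim = c(nx, ny, nz)).
#' Voxels excluded from an analysis (e.g. below the LET dose threshold) carry
#' `NA`, the exclusion sentinel used throughout the package.
#'
#' @param values numeric array of dim `c(nx, ny, nz)` (a vector is accepted
#'   together with `dim`).
#' @param spacing voxel spacing in mm per axis, length 3 (or scalar, recycled).
#' @param origin coordinates (mm) of the centre of voxel `[1, 1, 1]`.
#' @param quantity one of `"dose_Gy"`, `"let_keVum"`, `"rbe"`,
#'   `"delta_Gy_rbe"` or another short label.
#' @param dim optional dimension when `values` is a plain vector.
#' @param provenance free-text provenance string carried through file I/O.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(1, c(4, 4, 2)), spacing = 2)
#' voxel_volume_cc(g)
#' @export
voxel_grid <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                       quantity = "dose_Gy", dim = NULL, provenance = "") {
  if (!is.null(dim)) dim(values) <- dim
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(is.finite(spacing)), all(spacing > 0),
            length(origin) == 3L)
  storage.mode(values) <- "double"
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), quantity = quantity,
         provenance = provenance),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %s  %d x %d x %d voxels, spacing %s mm\n",
              x$quantity, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x ")))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g], %d excluded (NA) voxels\n",
                min(v), max(v), sum(is.na(x$values))))
  else cat("  all voxels excluded (NA)\n")
  invisible(x)
}

#' @rdname voxel_grid
#' @param g a `voxel_grid` or `structure_mask`.
#' @return `voxel_volume_cc()`: the volume of one voxel in cc.
#' @export
voxel_volume_cc <- function(g) prod(g$spacing) / 1000

#' Test that two grids share the same geometry
#'
#' @param a,b `voxel_grid` or `structure_mask` objects.
#' @param tol tolerance on spacing/origin in mm.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
check_congruent <- function(a, b, tol = 1e-9) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grid geometry mismatch: shapes differ")
  if (max(abs(a$spacing - b$spacing)) > tol ||
      max(abs(a$origin - b$origin)) > tol)
    stop("grid geometry mismatch: spacing or origin differ")
  invisible(TRUE)
}

#' Structure mask
#'
#' A boolean voxel mask naming an anatomical structure, on the same lattice as
#' the dose/LET grids; carries the voxel spacing so volumes convert to cc.
#'
#' @param values logical array of dim `c(nx, ny, nz)`.
#' @param name structure name, e.g. `"heart"`.
#' @inheritParams voxel_grid
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, name, spacing = c(2, 2, 2),
                           origin = c(0, 0, 0), dim = NULL) {
  if (!is.null(dim)) dim(values) <- dim
  if (length(dim(values)) != 3L) stop("'values' must be a 3-D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask may not contain NA")
  structure(list(values = values, name = name,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels, %.3f cc\n",
              x$name, sum(x$values), sum(x$values) * voxel_volume_cc(x)))
  invisible(x)
}

#' @rdname structure_mask
#' @param mask a `structure_mask`.
#' @return `mask_volume_cc()`: total structure volume in cc.
#' @export
mask_volume_cc <- function(mask) sum(mask$values) * voxel_volume_cc(mask)

# voxel-centre coordinates along each axis (mm)
grid_axes <- function(g) {
  d <- dim(g$values)
  lapply(1:3, function(i) g$origin[i] + (seq_len(d[i]) - 1) * g$spacing[i])
}

# values inside a mask, honouring NA sentinels when drop_excluded is TRUE
masked_values <- function(grid, mask, drop_excluded = TRUE) {
  check_congruent(grid, mask)
  v <- grid$values[mask$values]
  if (drop_excluded) v <- v[!is.na(v)]
  v
}

# arithmetic helper: same-geometry grid with new values
grid_like <- function(g, values, quantity = g$quantity) {
  voxel_grid(array(values, dim(g$values)), spacing = g$spacing,
             origin = g$origin, quantity = quantity,
             provenance = g$provenance)
}
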