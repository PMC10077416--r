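#' Portable voxel-grid file format
#'
#' A plain-text, bit-exact format of record for dose/LET/RBE grids: a short
#' `key: value` header (shape, spacing, origin, quantity, sentinel,
#' provenance) followed by the flattened values, x varying fastest. Values
#' are written with 17 significant digits, which round-trips IEEE doubles
#' exactly; the exclusion sentinel is written as `NA`.
#'
#' @param grid a [voxel_grid()].
#' @param path file path.
#' @return `write_grid()` returns `path` invisibly; `read_grid()` returns
#'   the [voxel_grid()].
#' @examples
#' g <- voxel_grid(array(rnorm(8), c(2, 2, 2)), spacing = 2)
#' f <- tempfile(fileext = ".pgrid")
#' write_grid(g, f)
#' identical(read_grid(f)$values, g$values)
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  con <- file(path, open = "wb")  # binary mode fixes newline convention
  on.exit(close(con))
  d <- dim(grid$values)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c(
    "protonrbe-grid 1",
    sprintf("quantity: %s", grid$quantity),
    sprintf("shape: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacing: %s", num(grid$spacing)),
    sprintf("origin: %s", num(grid$origin)),
    "sentinel: NA",
    sprintf("provenance: %s", gsub("[\r\n]", " ", grid$provenance)),
    "values:"), con, sep = "\n")
  v <- sprintf("%.17g", as.vector(grid$values))
  v[is.na(as.vector(grid$values))] <- "NA"
  writeLines(v, con, sep = "\n")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 8L || lines[1] != "protonrbe-grid 1")
    stop("not a protonrbe grid file: ", path)
  hdr <- list()
  i <- 2L
  while (i <= length(lines) && lines[i] != "values:") {
    kv <- regmatches(lines[i], regexpr(": ?", lines[i]), invert = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed grid header line: ", lines[i])
    hdr[[kv[1]]] <- kv[2]
    i <- i + 1L
  }
  if (i > length(lines)) stop("grid file has no 'values:' section: ", path)
  for (k in c("quantity", "shape", "spacing", "origin"))
    if (is.null(hdr[[k]])) stop("grid header missing '", k, "': ", path)
  shape <- as.integer(strsplit(hdr$shape, " +")[[1]])
  vals <- lines[(i + 1L):length(lines)]
  vals <- vals[nzchar(vals)]
  if (length(vals) != prod(shape))
    stop(sprintf("truncated grid file: expected %d values, found %d",
                 prod(shape), length(vals)))
  num <- suppressWarnings(as.numeric(vals))
  if (any(is.na(num) & vals != "NA")) stop("non-numeric value in grid file")
  voxel_grid(array(num, shape),
             spacing = as.numeric(strsplit(hdr$spacing, " +")[[1]]),
             origin = as.numeric(strsplit(hdr$origin, " +")[[1]]),
             quantity = hdr$quantity,
             provenance = if (is.null(hdr$provenance)) "" else hdr$provenance)
}
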