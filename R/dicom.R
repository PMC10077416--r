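#' Minimal DICOM RT Dose import/export
#'
#' A small, self-contained codec for DICOM RT Dose objects (explicit VR
#' little endian), covering exactly the attributes this pipeline needs:
#' grid geometry (Rows/Columns/NumberOfFrames, PixelSpacing,
#' GridFrameOffsetVector, ImagePositionPatient), DoseGridScaling and 32-bit
#' pixel data. Quantities other than physical dose (LET, RBE, dose
#' difference) are tagged in the DoseComment attribute; exclusion-sentinel
#' (`NA`) voxels are encoded as 0 on export. Pixel values are scaled to the
#' 31-bit integer range, keeping the quantization error far below 0.01% of
#' the maximum. This is an interchange convenience: the text grid format
#' ([write_grid()]) is the package's format of record.
#' @name dicom_rtdose
NULL

RTDOSE_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.2"
TRANSFER_SYNTAX_LE <- "1.2.840.10008.1.2.1"

uid_new <- function()
  paste0("2.25.", sample(1:9, 1),
         paste0(sample(0:9, 29, replace = TRUE), collapse = ""))

# --- writing ---------------------------------------------------------------

dcm_elem <- function(group, element, vr, payload) {
  if (is.character(payload)) {
    payload <- charToRaw(payload)
    if (length(payload) %% 2L)  # DICOM values are even-length
      payload <- c(payload, as.raw(if (vr == "UI") 0L else 32L))
  }
  tag <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(payload), raw(), size = 4, endian = "little"), payload)
  } else {
    c(tag, charToRaw(vr),
      writeBin(as.integer(length(payload)), raw(), size = 2,
               endian = "little"), payload)
  }
}

dcm_us <- function(g, e, x)
  dcm_elem(g, e, "US", writeBin(as.integer(x), raw(), size = 2, endian = "little"))
dcm_ds <- function(g, e, x)
  dcm_elem(g, e, "DS", paste(sprintf("%.10g", x), collapse = "\\"))

#' @rdname dicom_rtdose
#' @param grid a [voxel_grid()] to export.
#' @param path file path.
#' @param template optional list of header overrides (`sop_instance_uid`,
#'   `dose_comment`).
#' @return `export_dicom_rtdose()` returns `path` invisibly.
#' @export
export_dicom_rtdose <- function(grid, path, template = list()) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$values)
  vals <- as.vector(grid$values)
  vals[is.na(vals)] <- 0
  if (any(vals < 0))
    stop("DICOM RT Dose export requires nonnegative values; offset the grid first")
  mx <- max(vals)
  scaling <- if (mx > 0) mx / (2^31 - 1) else 1
  ints <- as.integer(round(vals / scaling))

  sop_uid <- template$sop_instance_uid %||% uid_new()
  comment <- template$dose_comment %||% grid$quantity

  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0002, "UI", RTDOSE_SOP_CLASS),
    dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_LE),
    dcm_elem(0x0002, 0x0012, "UI", "2.25.826000109970"))
  meta <- c(dcm_elem(0x0002, 0x0000, "UL",
                     writeBin(length(meta), raw(), size = 4, endian = "little")),
            meta)

  offsets <- (seq_len(d[3]) - 1) * grid$spacing[3]
  body <- c(
    dcm_elem(0x0008, 0x0016, "UI", RTDOSE_SOP_CLASS),
    dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_ds(0x0018, 0x0050, grid$spacing[3]),
    dcm_ds(0x0020, 0x0032, grid$origin),
    dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x0028, 0x0002, 1),
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem(0x0028, 0x0008, "IS", as.character(d[3])),
    dcm_us(0x0028, 0x0010, d[2]),           # Rows = y
    dcm_us(0x0028, 0x0011, d[1]),           # Columns = x
    dcm_ds(0x0028, 0x0030, grid$spacing[c(2, 1)]),
    dcm_us(0x0028, 0x0100, 32),
    dcm_us(0x0028, 0x0101, 32),
    dcm_us(0x0028, 0x0102, 31),
    dcm_us(0x0028, 0x0103, 0),
    dcm_elem(0x3004, 0x0002, "CS", "GY"),
    dcm_elem(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_elem(0x3004, 0x0006, "LO", comment),
    dcm_ds(0x3004, 0x000C, offsets),
    dcm_ds(0x3004, 0x000E, scaling),
    dcm_elem(0x7FE0, 0x0010, "OW",
             writeBin(ints, raw(), size = 4, endian = "little")))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

read_dcm_elements <- function(bytes) {
  pos <- 1L
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    grp <- readBin(bytes[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
      len <- readBin(bytes[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      hdr <- 12L
    } else {
      len <- readBin(bytes[(pos + 6):(pos + 7)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      hdr <- 8L
    }
    if (len < 0 || pos + hdr + len - 1L > n)
      stop("truncated or malformed DICOM element")
    payload <- if (len > 0) bytes[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    out[[sprintf("%04X,%04X", grp, ele)]] <- list(vr = vr, bytes = payload)
    pos <- pos + hdr + len
  }
  out
}

dcm_str <- function(el) {
  b <- el$bytes  # strip trailing NUL/space padding before conversion
  while (length(b) && b[length(b)] %in% as.raw(c(0L, 32L)))
    b <- b[-length(b)]
  rawToChar(b)
}
dcm_nums <- function(el) as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])

#' @rdname dicom_rtdose
#' @return `import_dicom_rtdose()` returns a [voxel_grid()] in Gy (or the
#'   quantity recorded in DoseComment).
#' @export
import_dicom_rtdose <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140L ||
      rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  els <- read_dcm_elements(bytes[-(1:132)])
  need <- function(tag, what) {
    el <- els[[tag]]
    if (is.null(el)) stop("DICOM RT Dose missing ", what)
    el
  }
  modality <- dcm_str(need("0008,0060", "Modality"))
  if (modality != "RTDOSE")
    stop("not an RT Dose object (Modality = ", modality, ")")
  nx <- readBin(need("0028,0011", "Columns")$bytes, "integer", size = 2,
                signed = FALSE, endian = "little")
  ny <- readBin(need("0028,0010", "Rows")$bytes, "integer", size = 2,
                signed = FALSE, endian = "little")
  nz <- as.integer(dcm_str(need("0028,0008", "NumberOfFrames")))
  ps <- dcm_nums(need("0028,0030", "PixelSpacing"))          # row, col
  offs <- dcm_nums(need("3004,000C", "GridFrameOffsetVector"))
  scaling <- dcm_nums(need("3004,000E", "DoseGridScaling"))
  origin <- dcm_nums(need("0020,0032", "ImagePositionPatient"))
  sz <- if (length(offs) > 1) diff(offs[1:2]) else
    dcm_nums(need("0018,0050", "SliceThickness"))
  px <- need("7FE0,0010", "PixelData")$bytes
  if (length(px) != 4L * nx * ny * nz)
    stop("PixelData length inconsistent with grid shape")
  ints <- readBin(px, "integer", n = nx * ny * nz, size = 4, endian = "little")
  comment <- if (!is.null(els[["3004,0006"]])) dcm_str(els[["3004,0006"]])
             else "dose_Gy"
  voxel_grid(array(ints * scaling, c(nx, ny, nz)),
             spacing = c(ps[2], ps[1], sz),
             origin = origin + c(0, 0, offs[1]),
             quantity = comment,
             provenance = paste("DICOM RT Dose", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
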