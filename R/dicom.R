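# Minimal DICOM reader: uncompressed, explicit-VR, little-endian, monochrome.
# No installed R package parses DICOM, so the subset needed here (Rows,
# Columns, BitsAllocated, PixelRepresentation, PixelSpacing, PixelData) is
# decoded directly. Anything outside that subset raises an explicit error
# rather than returning a partial grid.

.DICOM_LONG_VR <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.EXPLICIT_LE_UID <- "1.2.840.10008.1.2.1"

read_uint16 <- function(con) readBin(con, "integer", 1L, size = 2L,
                                     signed = FALSE, endian = "little")
read_uint32 <- function(con) readBin(con, "integer", 1L, size = 4L,
                                     endian = "little")

#' Read an uncompressed explicit-VR little-endian DICOM file
#'
#' @param path file path.
#' @return A list with `intensities` (numeric matrix, row-major as displayed)
#'   and `spacing_mm` (numeric pair or `NULL` if the file has no PixelSpacing).
#' @export
read_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132L)
  if (length(preamble) < 132L ||
      rawToChar(preamble[129:132]) != "DICM") {
    abort(sprintf("'%s' is not a DICOM file (missing DICM magic)", path))
  }
  elems <- list()
  repeat {
    hdr <- readBin(con, "raw", 4L)
    if (length(hdr) < 4L) break
    group <- sum(as.integer(hdr[1:2]) * c(1L, 256L))
    elem <- sum(as.integer(hdr[3:4]) * c(1L, 256L))
    vr_raw <- readBin(con, "raw", 2L)
    if (length(vr_raw) < 2L) abort(sprintf("truncated DICOM file: %s", path))
    vr <- rawToChar(vr_raw)
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort("implicit-VR DICOM is not supported; re-export as explicit VR")
    }
    len <- if (vr %in% .DICOM_LONG_VR) {
      readBin(con, "raw", 2L)   # reserved
      read_uint32(con)
    } else {
      read_uint16(con)
    }
    if (len < 0L) abort("undefined-length DICOM elements are not supported")
    value <- readBin(con, "raw", len)
    if (length(value) < len) abort(sprintf("truncated DICOM file: %s", path))
    tag <- sprintf("%04x,%04x", group, elem)
    elems[[tag]] <- list(vr = vr, value = value)
    if (tag == "7fe0,0010") break
  }
  ts <- elems[["0002,0010"]]
  if (!is.null(ts)) {
    val <- ts$value[ts$value != as.raw(0L)]   # UI values are NUL-padded
    uid <- sub("\\s+$", "", rawToChar(val))
    if (uid != .EXPLICIT_LE_UID) {
      abort(sprintf("unsupported DICOM transfer syntax '%s'", uid))
    }
  }
  us <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    sum(as.integer(e$value[1:2]) * c(1L, 256L))
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  bits <- us("0028,0100") %||% 16L
  if (is.null(rows) || is.null(cols)) abort("DICOM file lacks Rows/Columns")
  px <- elems[["7fe0,0010"]]
  if (is.null(px)) abort("DICOM file lacks PixelData")
  n <- rows * cols
  v <- if (bits <= 8L) {
    as.integer(px$value[seq_len(n)])
  } else {
    if (length(px$value) < 2L * n) abort("PixelData shorter than Rows x Columns")
    readBin(px$value, "integer", n, size = 2L, signed = FALSE,
            endian = "little")
  }
  spacing <- NULL
  sp <- elems[["0028,0030"]]
  if (!is.null(sp)) {
    sval <- sp$value[sp$value != as.raw(0L)]
    parts <- strsplit(sub("\\s+$", "", rawToChar(sval)), "\\\\")[[1]]
    spacing <- as.numeric(parts)
  }
  # PixelData is stored row by row
  list(intensities = matrix(v, nrow = rows, ncol = cols, byrow = TRUE),
       spacing_mm = spacing)
}
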