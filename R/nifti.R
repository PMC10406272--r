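# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, little
# endian). No NIfTI package exists in the supported dependency set, so the
# 348-byte header is handled directly. Volumes are written as float64 for
# bit-exact round trips; common integer/float input types are read.

NIFTI_MAGIC <- "n+1"

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# raw bytes -> string up to the first NUL
raw_to_string <- function(r) {
  nul <- which(r == as.raw(0))
  if (length(nul)) r <- r[seq_len(nul[1] - 1L)]
  rawToChar(r)
}

write_padded_string <- function(con, s, width) {
  raw <- charToRaw(substr(s, 1, width))
  writeBin(c(raw, raw(width - length(raw))), con)
}

write_nifti_header <- function(con, dims, spacing, origin, descrip) {
  ndim <- length(dims)
  dimv <- c(ndim, dims, rep(1L, 7 - ndim))
  pixd <- c(1, spacing, rep(1, 7 - length(spacing)))
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(10 + 18 + 4 + 2 + 1 + 1), con)               # unused block
  writeBin(as.integer(dimv), con, size = 2, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")    # intent_p1..p3
  writeBin(0L, con, size = 2, endian = "little")            # intent_code
  writeBin(64L, con, size = 2, endian = "little")           # datatype float64
  writeBin(64L, con, size = 2, endian = "little")           # bitpix
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  writeBin(pixd, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope/inter
  writeBin(0L, con, size = 2, endian = "little")            # slice_end
  writeBin(raw(2), con)                                     # slice_code, xyzt_units
  writeBin(c(0, 0, 0, 0), con, size = 4, endian = "little") # cal/slice_dur/toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")     # glmax/glmin
  write_padded_string(con, descrip, 80)
  write_padded_string(con, "", 24)                          # aux_file
  writeBin(c(0L, 2L), con, size = 2, endian = "little")     # qform, sform=aligned
  writeBin(rep(0, 6), con, size = 4, endian = "little")     # quatern/qoffset
  srow <- rbind(c(spacing[1], 0, 0, origin[1]),
                c(0, spacing[2], 0, origin[2]),
                c(0, 0, spacing[3], origin[3]))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  write_padded_string(con, "", 16)                          # intent_name
  write_padded_string(con, NIFTI_MAGIC, 4)
  writeBin(raw(4), con)                                     # extension flag
}

read_nifti_raw <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 348L)) {
    stop_tabseg("read_nifti: '%s' is not a little-endian NIfTI-1 file", path)
  }
  readBin(con, "raw", 36)
  dimv <- readBin(con, "integer", 8, size = 2, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "integer", 2, size = 2, endian = "little")
  pixd <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl <- readBin(con, "numeric", 2, size = 4, endian = "little")
  readBin(con, "raw", 120 - 112 - 8 + 28)                   # through glmin (to 148)
  descrip <- raw_to_string(readBin(con, "raw", 80))
  readBin(con, "raw", 24 + 4 + 24)                          # aux, codes, quatern
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = "little"),
                 3, 4, byrow = TRUE)
  readBin(con, "raw", 16)
  magic <- raw_to_string(readBin(con, "raw", 4))
  if (!startsWith(magic, NIFTI_MAGIC)) {
    stop_tabseg("read_nifti: bad magic in '%s'", path)
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  ndim <- dimv[1]
  dims <- dimv[2:(1 + ndim)]
  n <- prod(dims)
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop_tabseg("read_nifti: unsupported datatype code %d", datatype))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) {
    vals <- vals * scl[1] + scl[2]
  }
  list(values = array(vals, dim = dims), spacing = pixd[2:4],
       origin = srow[, 4], descrip = descrip, ndim = ndim)
}

#' Write a volume as a NIfTI-1 file
#'
#' Single-file NIfTI-1 (.nii or .nii.gz by extension), float64 data so the
#' write/read round trip is bit-exact; spacing goes to pixdim and the
#' sform carries spacing and origin.
#'
#' @param volume a [volume3d()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  write_nifti_header(con, dim(volume$values), volume$spacing, volume$origin,
                     sprintf("tabseg volume; background=%g", volume$background_value))
  writeBin(as.numeric(volume$values), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @return a [volume3d()] with spacing and origin from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_tabseg("read_volume: no such file '%s'", path)
  raw <- read_nifti_raw(path)
  if (raw$ndim != 3L) {
    stop_tabseg("read_volume: expected a 3D image, got %dD ('%s')", raw$ndim, path)
  }
  bg <- 0
  m <- regmatches(raw$descrip, regexec("background=([-0-9.eE+]+)", raw$descrip))[[1]]
  if (length(m) == 2) bg <- as.numeric(m[2])
  volume3d(raw$values, spacing = raw$spacing, background_value = bg,
           origin = raw$origin)
}

#' Write a tissue probability map as a 4D NIfTI-1 file
#'
#' The channel axis becomes the 4th NIfTI dimension; the header description
#' field records the channel order string `GM,WM,CSF`.
#'
#' @param probmap a [tissue_prob_map()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_probmap <- function(probmap, path) {
  stopifnot(inherits(probmap, "tissue_prob_map"))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  vals <- aperm(probmap$values, c(2, 3, 4, 1))   # channels last on disk
  write_nifti_header(con, dim(vals), probmap$spacing, c(0, 0, 0),
                     paste0("tabseg probmap; channels=", paste(TISSUES, collapse = ",")))
  writeBin(as.numeric(vals), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a tissue probability map from a 4D NIfTI-1 file
#'
#' @param path NIfTI-1 file with 3 channels on the 4th axis.
#' @return a [tissue_prob_map()].
#' @export
read_probmap <- function(path) {
  if (!file.exists(path)) stop_tabseg("read_probmap: no such file '%s'", path)
  raw <- read_nifti_raw(path)
  if (raw$ndim != 4L) {
    stop_tabseg("read_probmap: expected a 4D image, got %dD ('%s')", raw$ndim, path)
  }
  if (dim(raw$values)[4] != 3L) {
    stop_tabseg("read_probmap: expected 3 channels on the 4th axis, got %d",
                dim(raw$values)[4])
  }
  tissue_prob_map(aperm(raw$values, c(4, 1, 2, 3)), spacing = raw$spacing,
                  check = FALSE)
}
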