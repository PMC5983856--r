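#' Read a CT volume from NIfTI or NRRD
#'
#' Supports single-file NIfTI-1 (\code{.nii}, \code{.nii.gz}) and NRRD
#' (\code{.nrrd}).  The payload must be 3-D; spacing and origin are taken
#' from the format's metadata (NIfTI pixdim + affine translation, NRRD
#' \code{spacings} + \code{axis mins}).  On-disk axis order is
#' fastest-first (x, y, z); arrays are returned in the package's
#' (slice, row, col) order.
#'
#' @param path file path with a recognized extension.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop("shape error: expected a 3-D payload, got ",
           length(dim(img)), "-D", call. = FALSE)
    sp <- RNifti::pixdim(img)
    xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
    org <- xf[1:3, 4]
    ct_volume(aperm(unclass(img)[, , , drop = FALSE], c(3, 2, 1)),
              spacing = rev(sp), origin = rev(org))
  } else {
    nr <- read_nrrd(path)
    ct_volume(aperm(nr$values, c(3, 2, 1)),
              spacing = rev(nr$spacing), origin = rev(nr$origin))
  }
}

#' Write a CT volume to NIfTI or NRRD
#'
#' @param volume a [ct_volume()].
#' @param path destination; extension selects the format.
#' @return Invisibly, \code{path}.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  write_grid(volume$values, volume$spacing, volume$origin, path,
             datatype = "double")
}

#' Read a binary mask from NIfTI or NRRD
#'
#' @param path file path.
#' @return A [voxel_mask()]; any nonzero stored value is foreground.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  voxel_mask(v$values != 0, v$spacing, v$origin)
}

#' Write a binary mask as an unsigned 8-bit labelled image (1 = nodule)
#'
#' @param mask a [voxel_mask()].
#' @param path destination; extension selects the format.
#' @return Invisibly, \code{path}.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  write_grid(array(as.integer(mask$values), dim = dim(mask$values)),
             mask$spacing, mask$origin, path, datatype = "uint8")
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("format error: unrecognized extension on '", path,
       "' (expected .nii, .nii.gz or .nrrd)", call. = FALSE)
}

write_grid <- function(values, spacing, origin, path, datatype) {
  fmt <- volume_format(path)
  # disk order is x fastest: reverse the (slice,row,col) axes
  disk <- aperm(values, c(3, 2, 1))
  if (fmt == "nifti") {
    img <- RNifti::asNifti(disk)
    mat <- diag(4)
    mat[1:3, 4] <- rev(origin)
    sf <- structure(mat, code = 2L)
    img <- RNifti::`sform<-`(img, sf)
    img <- RNifti::`qform<-`(img, sf)
    img <- RNifti::`pixdim<-`(img, rev(spacing))
    RNifti::writeNifti(img, path,
                       datatype = if (datatype == "uint8") "uint8" else "double")
  } else {
    write_nrrd(disk, rev(spacing), rev(origin), path,
               type = if (datatype == "uint8") "uint8" else "double")
  }
  invisible(path)
}

# --- minimal NRRD0004 codec (3-D, raw/gzip, little-endian) ---------------
# No NRRD support exists in the available R stack; this implements the
# subset of the format the package emits and consumes.

nrrd_types <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double",  size = 4L, signed = TRUE),
  double = list(what = "double",  size = 8L, signed = TRUE)
)

write_nrrd <- function(disk, spacing, origin, path, type = "double",
                       encoding = "gzip") {
  info <- nrrd_types[[type]]
  hdr <- c(
    "NRRD0004",
    "# generated by nodulesig",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(disk), collapse = " ")),
    paste0("spacings: ", paste(format(spacing, digits = 15), collapse = " ")),
    paste0("axis mins: ", paste(format(origin, digits = 15), collapse = " ")),
    "endian: little",
    paste0("encoding: ", encoding),
    ""
  )
  payload <- writeBin(
    if (info$what == "integer") as.integer(disk) else as.double(disk),
    raw(), size = info$size, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

read_raw_line <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, raw(), n = 1L)
    if (length(b) == 0L || b == as.raw(10L)) break
    out <- c(out, b)
  }
  rawToChar(out)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_raw_line(con)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop("format error: '", path, "' is not an NRRD file", call. = FALSE)
  fields <- list()
  repeat {
    line <- read_raw_line(con)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("shape error: expected a 3-D payload, got ", ndim, "-D",
         call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  type <- fields[["type"]]
  if (is.null(nrrd_types[[type]]))
    stop("format error: unsupported NRRD type '", type, "'", call. = FALSE)
  info <- nrrd_types[[type]]
  encoding <- fields[["encoding"]]
  endian <- if (is.null(fields[["endian"]])) "little" else fields[["endian"]]
  payload <- readBin(con, raw(), n = file.size(path))
  if (identical(encoding, "gzip"))
    payload <- memDecompress(payload, type = "gzip")
  else if (!identical(encoding, "raw"))
    stop("format error: unsupported NRRD encoding '", encoding, "'",
         call. = FALSE)
  n <- prod(sizes)
  vals <- readBin(payload, info$what, n = n, size = info$size,
                  signed = info$signed, endian = endian)
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], " +")[[1]]) else rep(1, 3)
  origin <- if (!is.null(fields[["axis mins"]]))
    as.numeric(strsplit(fields[["axis mins"]], " +")[[1]]) else rep(0, 3)
  list(values = array(as.double(vals), dim = sizes),
       spacing = spacing, origin = origin)
}
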