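# MetaImage (.mhd + .raw) reader/writer for scalar and 3-vector volumes.
# Only uncompressed, little-endian, axis-aligned (identity TransformMatrix)
# files are handled; anything else is refused rather than resampled.

MHD_TYPES <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

parse_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed MetaImage header line: ", lines[bad][1])
  hdr <- stats::setNames(
    lapply(kv, function(m) trimws(m[3])),
    vapply(kv, function(m) m[2], "")
  )
  hdr
}

hdr_num <- function(hdr, key, default = NULL) {
  if (is.null(hdr[[key]])) return(default)
  as.numeric(strsplit(hdr[[key]], "\\s+")[[1]])
}

check_mhd_supported <- function(hdr, path) {
  ndims <- hdr_num(hdr, "NDims")
  if (is.null(ndims) || !(ndims %in% c(2, 3)))
    stop("only 2D/3D MetaImage files are supported: ", path)
  if (!is.null(hdr$CompressedData) &&
      tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage data is not supported: ", path)
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      tolower(hdr$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage data is not supported: ", path)
  tm <- hdr_num(hdr, "TransformMatrix")
  if (!is.null(tm)) {
    n <- sqrt(length(tm))
    if (max(abs(tm - as.vector(diag(n)))) > 1e-9)
      stop("non-identity orientation in ", path,
           "; reorient the volume before loading (axis-aligned grids only)")
  }
}

read_mhd_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- parse_mhd_header(path)
  check_mhd_supported(hdr, path)
  dims <- hdr_num(hdr, "DimSize")
  nchan <- hdr_num(hdr, "ElementNumberOfChannels", 1)
  type <- hdr[["ElementType"]]
  tinfo <- MHD_TYPES[[type]]
  if (is.null(tinfo)) stop("unsupported ElementType '", type, "' in ", path)
  datafile <- hdr[["ElementDataFile"]]
  if (is.null(datafile)) stop("missing ElementDataFile in ", path)
  if (toupper(datafile) == "LOCAL")
    stop("embedded (LOCAL) MetaImage data is not supported: ", path)
  datapath <- file.path(dirname(path), datafile)
  if (!file.exists(datapath)) stop("raw data file not found: ", datapath)
  n <- prod(dims) * nchan
  con <- file(datapath, "rb")
  on.exit(close(con))
  vals <- readBin(con, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = "little")
  if (length(vals) != n)
    stop("raw file ", datapath, " holds ", length(vals),
         " values, expected ", n)
  if (length(dims) == 2L) dims <- c(dims, 1)
  spacing <- hdr_num(hdr, "ElementSpacing", rep(1, 3))[seq_len(3)]
  spacing[is.na(spacing)] <- 1
  origin <- hdr_num(hdr, "Offset", rep(0, 3))[seq_len(3)]
  origin[is.na(origin)] <- 0
  list(values = as.numeric(vals), dims = as.integer(dims),
       nchan = as.integer(nchan), spacing = spacing, origin = origin)
}

#' Read a scalar MetaImage volume
#'
#' @param path path to the `.mhd` header file.
#' @return an [image_volume()].
#' @export
read_metaimage <- function(path) {
  r <- read_mhd_raw(path)
  if (r$nchan != 1L)
    stop("expected a scalar volume but found ", r$nchan, " channels: ", path)
  image_volume(array(r$values, r$dims), spacing = r$spacing, origin = r$origin)
}

#' Write a scalar MetaImage volume
#'
#' @param volume an [image_volume()].
#' @param path output `.mhd` path; the raw file is written alongside with the
#'   same stem.
#' @param element_type on-disk type, `"MET_DOUBLE"` (lossless default),
#'   `"MET_FLOAT"` or `"MET_SHORT"`.
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(volume, path, element_type = "MET_DOUBLE") {
  stopifnot(inherits(volume, "image_volume"))
  write_mhd_raw(as.numeric(volume$voxels), dim(volume$voxels), 1L,
                volume$spacing, volume$origin, path, element_type)
}

#' Read a displacement field from a 3-channel MetaImage volume
#'
#' Channels are the (x, y, z) displacement components in mm. Both
#' component-interleaved (`"interleaved"`, the MetaImage default, channels
#' fastest) and component-planar (`"planar"`, one full volume per component)
#' raw layouts are accepted.
#'
#' @param path path to the `.mhd` header file.
#' @param direction direction tag recorded on the returned field.
#' @param layout `"interleaved"` or `"planar"` raw component layout.
#' @return a [vector_field()].
#' @export
read_vector_field_metaimage <- function(path, direction = "unspecified",
                                        layout = c("interleaved", "planar")) {
  layout <- match.arg(layout)
  r <- read_mhd_raw(path)
  if (r$nchan != 3L)
    stop("expected 3 displacement components but found ", r$nchan, ": ", path)
  vecs <- if (layout == "interleaved") {
    aperm(array(r$values, c(3L, r$dims)), c(2L, 3L, 4L, 1L))
  } else {
    array(r$values, c(r$dims, 3L))
  }
  vector_field(vecs, spacing = r$spacing, origin = r$origin,
               direction = direction)
}

#' Write a displacement field as a 3-channel MetaImage volume
#'
#' @inheritParams read_vector_field_metaimage
#' @param field a [vector_field()].
#' @param path output `.mhd` path.
#' @param element_type on-disk type (see [write_metaimage()]).
#' @return `path`, invisibly.
#' @export
write_vector_field_metaimage <- function(field, path,
                                         element_type = "MET_DOUBLE",
                                         layout = c("interleaved", "planar")) {
  stopifnot(inherits(field, "vector_field"))
  layout <- match.arg(layout)
  dims <- dim(field$vectors)[1:3]
  vals <- if (layout == "interleaved") {
    as.numeric(aperm(field$vectors, c(4L, 1L, 2L, 3L)))
  } else {
    as.numeric(field$vectors)
  }
  write_mhd_raw(vals, dims, 3L, field$spacing, field$origin, path,
                element_type)
}

write_mhd_raw <- function(values, dims, nchan, spacing, origin, path,
                          element_type) {
  tinfo <- MHD_TYPES[[element_type]]
  if (is.null(tinfo)) stop("unsupported element type: ", element_type)
  stem <- sub("\\.mhd$", "", path)
  if (identical(stem, path)) stop("output path must end in .mhd: ", path)
  rawname <- paste0(basename(stem), ".raw")
  hdr <- c(
    "ObjectType = Image",
    paste0("NDims = ", length(dims)),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste0("TransformMatrix = ",
           paste(as.vector(diag(length(dims))), collapse = " ")),
    paste0("Offset = ", paste(format(origin, digits = 17), collapse = " ")),
    paste0("ElementSpacing = ",
           paste(format(spacing, digits = 17), collapse = " ")),
    paste0("DimSize = ", paste(dims, collapse = " ")),
    if (nchan > 1L) paste0("ElementNumberOfChannels = ", nchan),
    paste0("ElementType = ", element_type),
    paste0("ElementDataFile = ", rawname)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  if (tinfo$what == "integer") {
    v <- as.integer(round(values))
    writeBin(v, con, size = tinfo$size, endian = "little")
  } else {
    writeBin(as.numeric(values), con, size = tinfo$size, endian = "little")
  }
  invisible(path)
}
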