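# Format dispatch between MetaImage, NIfTI and DICOM series, plus landmark
# text files. NIfTI goes through RNifti; only diagonal (axis-aligned,
# non-flipped) affines are accepted, matching the MetaImage policy.

nifti_geometry <- function(img, path) {
  aff <- try(RNifti::xform(img), silent = TRUE)
  d <- dim(img)
  if (inherits(aff, "try-error") || is.null(aff)) {
    sp <- RNifti::pixdim(img)
    return(list(spacing = sp[1:3], origin = c(0, 0, 0)))
  }
  rot <- aff[1:3, 1:3]
  offdiag <- rot - diag(diag(rot))
  if (max(abs(offdiag)) > 1e-6 || any(diag(rot) <= 0))
    stop("non-axis-aligned or flipped NIfTI orientation in ", path,
         "; axis-aligned grids only")
  list(spacing = as.numeric(diag(rot)), origin = as.numeric(aff[1:3, 4]))
}

make_nifti <- function(arr, spacing, origin) {
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- origin
  img <- RNifti::asNifti(arr)
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  g <- nifti_geometry(img, path)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) != 3L)
    stop("expected a scalar 3D NIfTI volume, got ", length(d), "D: ", path)
  image_volume(array(as.numeric(img), d), spacing = g$spacing,
               origin = g$origin)
}

read_nifti_vector_field <- function(path, direction) {
  img <- RNifti::readNifti(path)
  g <- nifti_geometry(img, path)
  d <- dim(img)
  if (length(d) == 5L && d[4] == 1L) {
    img <- array(as.numeric(img), d[c(1:3, 5)])
    d <- dim(img)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 3-component displacement NIfTI (x,y,z,[1,]3): ", path)
  vector_field(array(as.numeric(img), d), spacing = g$spacing,
               origin = g$origin, direction = direction)
}

guess_format <- function(path) {
  if (dir.exists(path)) return("dicom_series")
  low <- tolower(path)
  if (grepl("\\.mhd$", low)) "metaimage"
  else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else stop("cannot infer format of ", path,
            "; pass `format` explicitly")
}

#' Read a scalar image volume
#'
#' Dispatches on `format` (or the file extension / directory-ness of `path`):
#' MetaImage `.mhd`, NIfTI `.nii`/`.nii.gz`, or a directory of DICOM slices.
#' DICOM stored values are rescaled by the slope/intercept in the header so
#' the returned voxels are HU.
#'
#' @param path file (or directory, for DICOM) to read.
#' @param format one of `"auto"`, `"metaimage"`, `"nifti"`, `"dicom_series"`.
#' @return an [image_volume()].
#' @export
read_volume <- function(path,
                        format = c("auto", "metaimage", "nifti",
                                   "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format != "dicom_series" && !file.exists(path))
    stop("file not found: ", path)
  switch(format,
         metaimage = read_metaimage(path),
         nifti = read_nifti_volume(path),
         dicom_series = read_dicom_series(path))
}

#' Write a scalar image volume
#'
#' @param volume an [image_volume()].
#' @param path output path; `.mhd` selects MetaImage, `.nii`/`.nii.gz` NIfTI.
#' @param ... passed to the format writer (e.g. `element_type` for MetaImage).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, ...) {
  stopifnot(inherits(volume, "image_volume"))
  fmt <- guess_format(path)
  if (fmt == "metaimage") {
    write_metaimage(volume, path, ...)
  } else if (fmt == "nifti") {
    RNifti::writeNifti(make_nifti(volume$voxels, volume$spacing,
                                  volume$origin), path)
  } else stop("cannot write format: ", fmt)
  invisible(path)
}

#' Read a displacement vector field
#'
#' Accepts a 3-channel MetaImage volume or a 4D/5D NIfTI displacement image;
#' components are normalised to (x, y, z) displacement in mm.
#'
#' @inheritParams read_vector_field_metaimage
#' @param format `"auto"`, `"metaimage"` or `"nifti"`.
#' @return a [vector_field()].
#' @export
read_vector_field <- function(path, direction = "unspecified",
                              format = c("auto", "metaimage", "nifti"),
                              layout = c("interleaved", "planar")) {
  format <- match.arg(format); layout <- match.arg(layout)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         metaimage = read_vector_field_metaimage(path, direction, layout),
         nifti = read_nifti_vector_field(path, direction),
         stop("unsupported vector-field format: ", format))
}

#' Write a displacement vector field
#'
#' @param field a [vector_field()].
#' @param path output path (`.mhd` or `.nii`/`.nii.gz`).
#' @param ... passed to the MetaImage writer.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path, ...) {
  stopifnot(inherits(field, "vector_field"))
  fmt <- guess_format(path)
  if (fmt == "metaimage") {
    write_vector_field_metaimage(field, path, ...)
  } else if (fmt == "nifti") {
    d <- dim(field$vectors)
    arr <- array(field$vectors, c(d[1:3], 1L, 3L))
    RNifti::writeNifti(make_nifti(arr, field$spacing, field$origin), path)
  } else stop("cannot write format: ", fmt)
  invisible(path)
}

#' Read landmarks from a whitespace-delimited text file
#'
#' One point per line, `x y z`. With `units = "voxel"` the coordinates
#' are 0-based voxel indices converted to world mm through `reference`'s
#' spacing and origin; with `units = "mm"` they are taken as world
#' coordinates directly.
#'
#' @param path text file path.
#' @param units `"mm"` or `"voxel"`.
#' @param reference an [image_volume()] or [vector_field()], required for
#'   `units = "voxel"`.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, units = c("mm", "voxel"), reference = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no landmark lines in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nn <- vapply(toks, length, 1L)
  if (any(nn != 3L))
    stop("line ", which(nn != 3L)[1], " of ", path,
         " does not have exactly 3 coordinates")
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (any(is.na(vals)))
    stop("non-numeric coordinate in ", path)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  if (units == "voxel") {
    if (is.null(reference))
      stop("`reference` is required to convert voxel indices to mm")
    pts <- voxel_to_world(pts, reference)
  }
  landmark_set(pts)
}

#' Write landmarks as a whitespace-delimited text file
#'
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  writeLines(apply(landmarks$points, 1L, function(p)
    paste(format(p, digits = 17, trim = TRUE), collapse = " ")), path)
  invisible(path)
}

#' Read a binary structure mask from a 0/1 volume file
#'
#' @param path mask volume (`.mhd` or NIfTI).
#' @param name structure label.
#' @param reference optional grid to validate the shape against.
#' @return a [structure_mask()].
#' @export
read_structure_mask <- function(path, name = NULL, reference = NULL) {
  v <- read_volume(path)
  if (is.null(name))
    name <- sub("\\.(mhd|nii|nii\\.gz)$", "", basename(path))
  structure_mask(round(v$voxels), name = name, reference = reference)
}
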