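#' Scalar image volume in Hounsfield units
#'
#' The basic 3D container of the toolkit: a scalar grid in HU together with
#' its geometry. Voxels are stored as an R array indexed `[x, y, z]` (first
#' index varies fastest, matching the on-disk order of MetaImage and NIfTI
#' raster data); `spacing` and `origin` are length-3 numeric vectors ordered
#' `(x, y, z)` in mm. World coordinates place the centre of voxel
#' `(i, j, k)` (0-based) at `origin + c(i, j, k) * spacing`.
#'
#' @param voxels numeric 3D array of HU values (2D input is promoted to a
#'   single-slice volume).
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel's
#'   centre.
#' @return an object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), spacing = c(0.5, 0.5, 2))
#' dim(v$voxels)
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (or a matrix for a single slice)")
  if (length(voxels) == 0L) stop("`voxels` must be non-empty")
  if (!all(is.finite(voxels))) stop("voxel values must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, HU range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Per-voxel displacement field
#'
#' Stores one 3-vector of displacement (mm, ordered x/y/z) per voxel of a
#' reference grid, as a 4D array `[x, y, z, component]`. `direction` is a
#' free-form but mandatory tag declaring which image's points the field maps
#' from and to (e.g. `"EOT->SOT"`); operations that compare two fields refuse
#' mismatched tags rather than silently flipping signs.
#'
#' @param vectors numeric 4D array, last dimension of length 3 (x/y/z mm).
#' @param spacing,origin grid geometry as in [image_volume()].
#' @param direction character scalar direction tag.
#' @return an object of class `vector_field`.
#' @export
vector_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = "unspecified") {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4D array with 3 components in the last dimension")
  if (!all(is.finite(vectors))) stop("displacement components must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (!is.character(direction) || length(direction) != 1L)
    stop("`direction` must be a single string")
  structure(
    list(vectors = vectors, spacing = spacing, origin = origin,
         direction = direction),
    class = "vector_field"
  )
}

#' @export
print.vector_field <- function(x, ...) {
  d <- dim(x$vectors)
  mags <- sqrt(apply(x$vectors^2, seq_len(3), sum))
  cat(sprintf("<vector_field> %d x %d x %d, direction '%s'\n",
              d[1], d[2], d[3], x$direction))
  cat(sprintf("  |v| range [%.4g, %.4g] mm\n", min(mags), max(mags)))
  invisible(x)
}

#' Set of 3D landmark points
#'
#' @param points numeric matrix with 3 columns (x, y, z world mm), one row per
#'   point.
#' @param labels optional character vector of identifiers, one per point.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have 3 columns (x, y, z mm)")
  if (nrow(points) < 1L) stop("a landmark set needs at least one point")
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("`labels` must have one entry per point")
  structure(list(points = points, labels = labels), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points (mm)\n", nrow(x$points)))
  invisible(x)
}

#' Binary structure mask on a reference grid
#'
#' @param voxels 3D array of 0/1 (logical accepted) on the reference grid.
#' @param name structure label, e.g. `"brainstem"`.
#' @param reference optional [image_volume()] or [vector_field()] whose grid
#'   shape the mask must match.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, name = "structure", reference = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (is.logical(voxels)) {
    v <- array(as.integer(voxels), dim(voxels))
    voxels <- v
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!all(voxels %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  if (!is.null(reference)) {
    ref_dim <- grid_dim(reference)
    if (!identical(dim(voxels), ref_dim))
      stop("mask shape does not match the reference grid")
  }
  structure(list(voxels = voxels, name = as.character(name)[1]),
            class = "structure_mask")
}

grid_dim <- function(x) {
  if (inherits(x, "image_volume")) dim(x$voxels)
  else if (inherits(x, "vector_field")) dim(x$vectors)[1:3]
  else if (inherits(x, "structure_mask")) dim(x$voxels)
  else stop("no grid for objects of class ", paste(class(x), collapse = "/"))
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based continuous coordinates; the centre of voxel
#' `(0,0,0)` sits at `origin`. The two transforms are exact mutual inverses.
#'
#' @param idx,pts numeric matrix with 3 columns (or a length-3 vector).
#' @param geom an [image_volume()] or [vector_field()] supplying spacing and
#'   origin.
#' @return matrix with 3 columns: world mm for `voxel_to_world`, continuous
#'   0-based indices for `world_to_voxel`.
#' @export
voxel_to_world <- function(idx, geom) {
  idx <- rbind3(idx)
  sweep(sweep(idx, 2, geom$spacing, "*"), 2, geom$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(pts, geom) {
  pts <- rbind3(pts)
  sweep(sweep(pts, 2, geom$origin, "-"), 2, geom$spacing, "/")
}

rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L)
  if (ncol(x) != 3L) stop("expected 3 columns (x, y, z)")
  x
}
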