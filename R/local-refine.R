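# Computational core of user-guided registration refinement: exhaustive
# translation-only SSD alignment of a local box, and replacement of
# individual DVF vectors with user-asserted "locks". Propagating a lock's
# influence through a deformable solver is the job of the external DIR
# engine; here a lock is literally a vector substitution.

#' Local alignment box
#'
#' @param center 1-based voxel index `c(ix, iy, iz)` of the box centre on the
#'   fixed grid.
#' @param half_size box half-width per axis, voxels (box side `2*h + 1`).
#' @param search_radius exhaustive search range per axis, voxels.
#' @return an object of class `refine_box`.
#' @export
refine_box <- function(center, half_size, search_radius) {
  center <- as.integer(rep(center, length.out = 3L))
  half_size <- as.integer(rep(half_size, length.out = 3L))
  search_radius <- as.integer(rep(search_radius, length.out = 3L))
  if (any(half_size < 0) || any(search_radius < 0))
    stop("half_size and search_radius must be >= 0")
  structure(list(center = center, half_size = half_size,
                 search_radius = search_radius),
            class = "refine_box")
}

#' Box-based rigid alignment by SSD minimization
#'
#' Exhaustive integer-voxel search over translations within
#' `search_radius`, minimizing the mean squared intensity difference between
#' the fixed box and the translated moving box. Ties are broken by the
#' smallest translation L2 norm, then lexicographically on (z, y, x).
#'
#' @param fixed,moving [image_volume()]s on grids with equal spacing.
#' @param box a [refine_box()].
#' @return list with `translation` (mm, x/y/z: displacement from a fixed-grid
#'   point to its match on the moving grid), `translation_vox` (integer
#'   voxels) and `ssd` (mean squared difference, HU^2, at the optimum).
#' @export
box_ssd_align <- function(fixed, moving, box) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"),
            inherits(box, "refine_box"))
  if (max(abs(fixed$spacing - moving$spacing)) > 1e-9)
    stop("fixed and moving volumes must share voxel spacing")
  df <- dim(fixed$voxels); dm <- dim(moving$voxels)
  lo <- box$center - box$half_size
  hi <- box$center + box$half_size
  if (any(lo < 1L) || any(hi > df))
    stop("box exceeds the fixed volume bounds")
  if (any(lo - box$search_radius < 1L) ||
      any(hi + box$search_radius > dm))
    stop("box plus search range exceeds the moving volume bounds")
  patch <- fixed$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  cand <- expand.grid(
    tx = -box$search_radius[1]:box$search_radius[1],
    ty = -box$search_radius[2]:box$search_radius[2],
    tz = -box$search_radius[3]:box$search_radius[3])
  msd <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    t <- c(cand$tx[i], cand$ty[i], cand$tz[i])
    mv <- moving$voxels[(lo[1] + t[1]):(hi[1] + t[1]),
                        (lo[2] + t[2]):(hi[2] + t[2]),
                        (lo[3] + t[3]):(hi[3] + t[3])]
    msd[i] <- mean((patch - mv)^2)
  }
  best <- which(msd == min(msd))
  if (length(best) > 1L) {
    nrm <- cand$tx[best]^2 + cand$ty[best]^2 + cand$tz[best]^2
    best <- best[order(nrm, cand$tz[best], cand$ty[best], cand$tx[best])]
  }
  b <- best[1]
  tvox <- c(cand$tx[b], cand$ty[b], cand$tz[b])
  list(translation = tvox * fixed$spacing,
       translation_vox = as.integer(tvox),
       ssd = msd[b])
}

#' A locked DVF vector
#'
#' @param position 1-based voxel index `c(ix, iy, iz)` on the DVF grid.
#' @param displacement displacement in mm, `c(x, y, z)`.
#' @return an object of class `dvf_lock`.
#' @export
dvf_lock <- function(position, displacement) {
  position <- as.integer(rep(position, length.out = 3L))
  displacement <- as.numeric(rep(displacement, length.out = 3L))
  if (any(!is.finite(displacement))) stop("displacement must be finite")
  structure(list(position = position, displacement = displacement),
            class = "dvf_lock")
}

#' Replace DVF vectors at locked positions
#'
#' The output equals the input except at lock positions, where the vector is
#' replaced by the lock's displacement. Later locks at the same position win.
#' The operation is idempotent for a fixed lock set.
#'
#' @param field a [vector_field()].
#' @param locks list of [dvf_lock()]s, all inside the grid.
#' @return the modified [vector_field()].
#' @export
apply_locks <- function(field, locks) {
  stopifnot(inherits(field, "vector_field"))
  if (length(locks) == 0L) return(field)
  d <- grid_dim(field)
  vecs <- field$vectors
  for (lk in locks) {
    stopifnot(inherits(lk, "dvf_lock"))
    p <- lk$position
    if (any(p < 1L) || any(p > d))
      stop("lock position (", paste(p, collapse = ", "),
           ") is outside the grid")
    vecs[p[1], p[2], p[3], ] <- lk$displacement
  }
  vector_field(vecs, spacing = field$spacing, origin = field$origin,
               direction = field$direction)
}

#' Build a lock from a box alignment
#'
#' Runs [box_ssd_align()] and records its translation as the locked
#' displacement at the box centre.
#'
#' @inheritParams box_ssd_align
#' @return a [dvf_lock()].
#' @export
lock_from_alignment <- function(fixed, moving, box) {
  res <- box_ssd_align(fixed, moving, box)
  dvf_lock(box$center, res$translation)
}
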