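# Seed-deterministic synthetic inputs: uniform-phantom scan pairs for NPS
# measurement, analytic displacement fields, and ground-truth/test DVF pairs
# with closed-form expected error statistics. Every generator keeps an
# analytic truth so downstream measurements can be checked exactly.

#' Uniform-phantom scan specification
#'
#' Emulates the uniform module of a CT QA phantom scanned at isocenter: a
#' constant background plus an optional slowly-varying in-plane trend
#' (cupping-like), with stochastic noise on top. Defaults mirror a 512^2
#' head-protocol CBCT geometry (0.475 mm pixels) over 20 slices.
#'
#' @param shape grid size `c(nx, ny, nz)`.
#' @param spacing voxel size, mm.
#' @param background_hu constant background level.
#' @param trend optional length-5 coefficients `c(cx, cy, cxx, cxy, cyy)` of
#'   an in-plane quadratic surface (HU over unit-scaled centred coordinates),
#'   identical on every slice.
#' @param noise `NULL` for no noise, a single number for white Gaussian
#'   noise of that standard deviation (HU), or a [noise_spec()] for
#'   spectrum-shaped noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(512L, 512L, 20L),
                         spacing = c(0.475, 0.475, 1),
                         background_hu = 0,
                         trend = NULL,
                         noise = NULL) {
  shape <- as.integer(rep(shape, length.out = 3L))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(shape < 1L)) stop("shape must be positive")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!is.null(trend) && length(trend) != 5L)
    stop("`trend` must be 5 quadratic coefficients")
  if (!is.null(noise) && !inherits(noise, "noise_spec") &&
      !(is.numeric(noise) && length(noise) == 1L && noise >= 0))
    stop("`noise` must be NULL, a white-noise sigma, or a noise_spec")
  structure(list(shape = shape, spacing = spacing,
                 background_hu = background_hu, trend = trend, noise = noise),
            class = "phantom_spec")
}

phantom_trend_slice <- function(spec) {
  nx <- spec$shape[1]; ny <- spec$shape[2]
  base <- matrix(spec$background_hu, nx, ny)
  if (is.null(spec$trend)) return(base)
  B <- poly2d_basis(nx, ny)[, -1, drop = FALSE]
  base + matrix(B %*% spec$trend, nx, ny)
}

phantom_noise_volume <- function(spec, seed) {
  d <- spec$shape
  if (is.null(spec$noise)) return(array(0, d))
  if (is.numeric(spec$noise)) {
    set.seed(as.integer(seed))
    return(array(stats::rnorm(prod(d), 0, spec$noise), d))
  }
  nspec <- spec$noise
  nps2d <- resolve_noise_spectrum(nspec, d[1:2], spec$spacing[1:2])
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    out[, , k] <- synthesize_noise_slice(
      nps2d, seed = (seed + k - 1L) %% .Machine$integer.max)
  }
  out
}

#' Generate a repeat-scan pair of a uniform phantom
#'
#' Both scans share the same deterministic trend surface but carry
#' independent noise realizations, as in a repeat acquisition for
#' subtraction detrending.
#'
#' @param spec a [phantom_spec()].
#' @param seed base integer seed; the second scan is offset deterministically.
#' @return list of two [image_volume()]s, `scan1` and `scan2`.
#' @export
generate_uniform_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  trend <- phantom_trend_slice(spec)
  base <- array(trend, spec$shape)  # slice replicated along z
  n1 <- phantom_noise_volume(spec, seed)
  n2 <- phantom_noise_volume(spec, seed + 1000003L)
  list(scan1 = image_volume(base + n1, spec$spacing),
       scan2 = image_volume(base + n2, spec$spacing))
}

#' Analytic displacement-field specification
#'
#' The field is a sum of closed-form components, so its exact value is
#' available at any world point (see [evaluate_dvf_spec()]), not only on the
#' grid — every voxel has an analytic truth for oracle checks.
#'
#' Components:
#' \describe{
#'   \item{constant}{`value`: fixed displacement `c(x, y, z)` mm.}
#'   \item{affine}{`matrix` (3x3) and `offset` (mm): `D(p) = A p + b` with
#'     `p` in world mm.}
#'   \item{gaussian_bump}{`center` (mm), `sigma` (mm, scalar or length 3),
#'     `peak` (mm vector): `D(p) = peak * exp(-sum(((p-c)/sigma)^2) / 2)`;
#'     the displacement magnitude peaks at `|peak|` at the bump centre.}
#' }
#'
#' @param shape,spacing,origin grid geometry.
#' @param components list of component lists, each with a `type` field.
#' @param direction direction tag for the generated field.
#' @return an object of class `dvf_spec`.
#' @export
dvf_spec <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     components = list(), direction = "SOT->EOT") {
  shape <- as.integer(rep(shape, length.out = 3L))
  for (cmp in components) {
    if (!cmp$type %in% c("constant", "affine", "gaussian_bump"))
      stop("unknown component type: ", cmp$type)
    if (cmp$type == "gaussian_bump" && any(rep(cmp$sigma, 3) <= 0))
      stop("bump widths must be > 0")
  }
  structure(list(shape = shape, spacing = rep(as.numeric(spacing), 3)[1:3],
                 origin = rep(as.numeric(origin), 3)[1:3],
                 components = components, direction = direction),
            class = "dvf_spec")
}

#' Evaluate an analytic displacement spec at world points
#'
#' @param spec a [dvf_spec()].
#' @param pts matrix of world points (n x 3, mm).
#' @return n x 3 matrix of displacements (mm).
#' @export
evaluate_dvf_spec <- function(spec, pts) {
  stopifnot(inherits(spec, "dvf_spec"))
  pts <- rbind3(pts)
  out <- matrix(0, nrow(pts), 3L)
  for (cmp in spec$components) {
    out <- out + switch(cmp$type,
      constant = matrix(rep(cmp$value, 3)[1:3], nrow(pts), 3L, byrow = TRUE),
      affine = {
        A <- matrix(cmp$matrix, 3L, 3L)
        b <- rep(if (is.null(cmp$offset)) 0 else cmp$offset, 3)[1:3]
        sweep(pts %*% t(A), 2, b, "+")
      },
      gaussian_bump = {
        s <- rep(cmp$sigma, 3)[1:3]
        ctr <- rep(cmp$center, 3)[1:3]
        z2 <- sweep(pts, 2, ctr, "-")
        w <- exp(-rowSums(sweep(z2, 2, s, "/")^2) / 2)
        outer(w, rep(cmp$peak, 3)[1:3])
      })
  }
  out
}

#' Sample an analytic displacement spec on its grid
#'
#' @param spec a [dvf_spec()].
#' @return a [vector_field()].
#' @export
generate_dvf <- function(spec) {
  stopifnot(inherits(spec, "dvf_spec"))
  d <- spec$shape
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  pts <- sweep(sweep(idx, 2, spec$spacing, "*"), 2, spec$origin, "+")
  disp <- evaluate_dvf_spec(spec, pts)
  vector_field(array(disp, c(d, 3L)), spacing = spec$spacing,
               origin = spec$origin, direction = spec$direction)
}

# expected error statistics when test = gt + bias + N(0, sd^2 I):
# ||delta|| / sd follows a noncentral chi(3) with ncp (|bias|/sd)^2
expected_error_stats <- function(bias, sd, n, threshold = 2) {
  bmag <- sqrt(sum(bias^2))
  if (sd == 0) {
    return(list(mean = bmag, median = bmag, max = bmag,
                pct_lt_2mm = if (bmag < threshold) 100 else 0))
  }
  ncp <- (bmag / sd)^2
  mean_err <- sd * stats::integrate(
    function(q) sqrt(q) * stats::dchisq(q, 3, ncp), 0, Inf,
    rel.tol = 1e-10)$value
  med_err <- sd * sqrt(stats::qchisq(0.5, 3, ncp))
  # typical largest of n draws (median of the max order statistic)
  max_err <- sd * sqrt(stats::qchisq(0.5^(1 / n), 3, ncp))
  list(mean = mean_err, median = med_err, max = max_err,
       pct_lt_2mm = 100 * stats::pchisq((threshold / sd)^2, 3, ncp))
}

#' Generate a ground-truth / test DVF pair with known error statistics
#'
#' The test field is the ground truth plus a constant bias and iid Gaussian
#' perturbation per component, so the per-voxel error magnitude follows a
#' (noncentral) 3D chi distribution. The returned `expected` statistics come
#' from that distribution's closed forms (the `max` entry is the median of
#' the maximum order statistic, a typical-value guide rather than an exact
#' expectation).
#'
#' @param spec a [dvf_spec()] for the ground truth.
#' @param bias constant error, mm `c(x, y, z)`.
#' @param sd per-component Gaussian error SD, mm (>= 0).
#' @param seed integer seed for the perturbation.
#' @param threshold threshold (mm) for the expected `pct_lt_2mm`.
#' @return list with `gt`, `test` ([vector_field()]s) and `expected`
#'   (list: `mean`, `median`, `max`, `pct_lt_2mm`).
#' @export
generate_registration_case <- function(spec, bias = c(0, 0, 0), sd = 0,
                                       seed = 1L, threshold = 2) {
  stopifnot(inherits(spec, "dvf_spec"))
  if (sd < 0) stop("`sd` must be >= 0")
  bias <- rep(as.numeric(bias), 3)[1:3]
  gt <- generate_dvf(spec)
  pert <- array(0, dim(gt$vectors))
  if (sd > 0) {
    set.seed(as.integer(seed))
    pert <- array(stats::rnorm(length(gt$vectors), 0, sd), dim(gt$vectors))
  }
  vecs <- gt$vectors + pert
  for (comp in 1:3) vecs[, , , comp] <- vecs[, , , comp] + bias[comp]
  tgt <- direction_target(spec$direction)
  if (is.na(tgt)) tgt <- "EOT"
  test <- vector_field(vecs, spacing = spec$spacing, origin = spec$origin,
                       direction = paste0("dEOT->", tgt))
  n <- prod(spec$shape)
  list(gt = gt, test = test,
       expected = expected_error_stats(bias, sd, n, threshold))
}
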