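# Noise-power-spectrum measurement from uniform-phantom stacks: ROI sampling
# on a circle, detrending, periodogram averaging and radial reduction.

#' ROI sampling geometry for NPS measurement
#'
#' The measurement samples square ROIs at a fixed radius from the slice
#' centre, equally spaced in angle, over a set of slices. The defaults are
#' the standard CT protocol: 16 ROIs of 40 px on a circle of radius 80 px.
#'
#' @param roi_size_px side of each square ROI, pixels (>= 8).
#' @param n_rois_per_slice ROIs per slice (>= 1).
#' @param circle_radius_px radius of the sampling circle, pixels.
#' @param slice_indices 1-based slice numbers to sample.
#' @return an object of class `roi_sampling_spec`.
#' @export
roi_sampling_spec <- function(roi_size_px = 40L, n_rois_per_slice = 16L,
                              circle_radius_px = 80L,
                              slice_indices = 1:20) {
  if (roi_size_px < 8L) stop("`roi_size_px` must be at least 8")
  if (n_rois_per_slice < 1L) stop("`n_rois_per_slice` must be >= 1")
  if (circle_radius_px < 0) stop("`circle_radius_px` must be >= 0")
  if (length(slice_indices) < 1L) stop("`slice_indices` must be non-empty")
  structure(list(roi_size_px = as.integer(roi_size_px),
                 n_rois_per_slice = as.integer(n_rois_per_slice),
                 circle_radius_px = as.numeric(circle_radius_px),
                 slice_indices = as.integer(slice_indices)),
            class = "roi_sampling_spec")
}

#' Extract square ROI patches on a circle around the slice centre
#'
#' ROI centres sit on the circle of `circle_radius_px` around the continuous
#' slice centre, at angles `2*pi*(k-1)/n` measured from the +x axis
#' counter-clockwise (towards +y). Each patch's corner is rounded to the
#' nearest integer pixel. Adjacent ROIs are allowed to overlap.
#'
#' @param volume an [image_volume()].
#' @param spec an [roi_sampling_spec()].
#' @return list of `roi_size_px` x `roi_size_px` matrices, ordered slice by
#'   slice then by angle.
#' @export
extract_rois <- function(volume, spec) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(spec, "roi_sampling_spec"))
  d <- dim(volume$voxels)
  if (any(spec$slice_indices < 1L) || any(spec$slice_indices > d[3]))
    stop("slice indices out of range 1..", d[3])
  m <- spec$roi_size_px
  centre <- (d[1:2] + 1) / 2
  ang <- 2 * pi * (seq_len(spec$n_rois_per_slice) - 1) / spec$n_rois_per_slice
  cx <- centre[1] + spec$circle_radius_px * cos(ang)
  cy <- centre[2] + spec$circle_radius_px * sin(ang)
  x0 <- round(cx - (m - 1) / 2)
  y0 <- round(cy - (m - 1) / 2)
  if (any(x0 < 1) || any(y0 < 1) || any(x0 + m - 1 > d[1]) ||
      any(y0 + m - 1 > d[2]))
    stop("ROI of ", m, " px at radius ", spec$circle_radius_px,
         " px exceeds the ", d[1], "x", d[2], " slice bounds")
  out <- vector("list", length(spec$slice_indices) * spec$n_rois_per_slice)
  i <- 1L
  for (sl in spec$slice_indices) {
    for (k in seq_len(spec$n_rois_per_slice)) {
      out[[i]] <- volume$voxels[x0[k]:(x0[k] + m - 1L),
                                y0[k]:(y0[k] + m - 1L), sl]
      i <- i + 1L
    }
  }
  out
}

poly2d_basis <- function(nx, ny) {
  # order-2 bivariate basis on centred, scaled coordinates (conditioning)
  x <- rep(seq_len(nx) - (nx + 1) / 2, times = ny) / nx
  y <- rep(seq_len(ny) - (ny + 1) / 2, each = nx) / ny
  cbind(1, x, y, x * x, x * y, y * y)
}

#' Detrend an ROI patch
#'
#' `"poly2d"` subtracts the least-squares order-2 polynomial surface, leaving
#' a zero-mean residual; `"subtraction"` subtracts the co-located patch from a
#' repeat scan and divides by `sqrt(2)` so the noise power matches a single
#' scan.
#'
#' @param patch numeric matrix (HU).
#' @param method `"poly2d"` or `"subtraction"`.
#' @param paired_patch matching patch from the repeat scan (subtraction only).
#' @return detrended matrix of the same size.
#' @export
detrend_roi <- function(patch, method = c("poly2d", "subtraction"),
                        paired_patch = NULL) {
  method <- match.arg(method)
  if (!is.matrix(patch)) stop("`patch` must be a matrix")
  if (method == "subtraction") {
    if (is.null(paired_patch))
      stop("subtraction detrending needs `paired_patch` from the repeat scan")
    if (!identical(dim(patch), dim(paired_patch)))
      stop("paired patch size mismatch")
    return((patch - paired_patch) / sqrt(2))
  }
  B <- poly2d_basis(nrow(patch), ncol(patch))
  fit <- qr.fitted(qr(B), as.numeric(patch))
  matrix(as.numeric(patch) - fit, nrow(patch), ncol(patch))
}

fft_freq <- function(n, d = 1) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k / (n * d)
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1):n1, 1:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, 1:(n2 - floor(n2 / 2)))]
}

shifted_freqs <- function(n, d) (seq_len(n) - 1 - floor(n / 2)) / (n * d)

new_nps2d <- function(power, freq_spacing, n_averaged = 1L) {
  if (any(power < 0)) power[power < 0] <- 0
  structure(list(power = power, freq_spacing = as.numeric(freq_spacing),
                 n_averaged = as.integer(n_averaged)),
            class = "nps2d")
}

#' 2D noise power spectrum of detrended patches
#'
#' Averages the scaled periodogram `(dx*dy / (Nx*Ny)) * |DFT|^2` over all
#' patches. The result is DC-centred; with power in HU^2 mm^2 the Cartesian
#' integral `sum(power) * du * dv` equals the mean patch variance (Parseval).
#'
#' @param patches list of equally-sized detrended matrices (HU).
#' @param pixel_spacing in-plane pixel size, mm (length 2 or scalar).
#' @return an object of class `nps2d` with elements `power` (matrix,
#'   DC-centred), `freq_spacing` (mm^-1 per bin along x and y) and
#'   `n_averaged`.
#' @export
roi_nps_2d <- function(patches, pixel_spacing) {
  if (!is.list(patches) || length(patches) == 0L)
    stop("`patches` must be a non-empty list of matrices")
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive (mm)")
  d1 <- dim(patches[[1]])
  ok <- vapply(patches, function(p) identical(dim(p), d1), TRUE)
  if (!all(ok)) stop("patches have mixed sizes")
  acc <- matrix(0, d1[1], d1[2])
  for (p in patches) acc <- acc + Mod(stats::fft(p))^2
  scale <- prod(pixel_spacing) / prod(d1)
  power <- fftshift2(acc / length(patches) * scale)
  new_nps2d(power, 1 / (d1 * pixel_spacing), length(patches))
}

#' @export
print.nps2d <- function(x, ...) {
  cat(sprintf("<nps2d> %d x %d bins, df (%.5g, %.5g) mm^-1, %d ROI(s)\n",
              nrow(x$power), ncol(x$power), x$freq_spacing[1],
              x$freq_spacing[2], x$n_averaged))
  invisible(x)
}

#' Construct a 1D radial NPS profile
#'
#' @param frequency ascending frequencies (mm^-1) starting at 0.
#' @param power non-negative spectral power (HU^2 mm^2), same length.
#' @param n_averaged number of ROIs that contributed.
#' @return a tibble of class `nps_profile` with columns `frequency` and
#'   `power`.
#' @export
nps_profile <- function(frequency, power, n_averaged = 1L) {
  frequency <- as.numeric(frequency); power <- as.numeric(power)
  if (length(frequency) != length(power))
    stop("`frequency` and `power` lengths differ")
  if (length(frequency) < 2L) stop("a profile needs at least 2 points")
  if (frequency[1] != 0) stop("the first frequency must be 0")
  if (any(diff(frequency) <= 0)) stop("frequencies must be strictly increasing")
  if (any(power < -1e-12)) stop("power must be non-negative")
  power[power < 0] <- 0
  out <- tibble::tibble(frequency = frequency, power = power)
  attr(out, "n_averaged") <- as.integer(n_averaged)
  class(out) <- c("nps_profile", class(out))
  out
}

#' Reduce a 2D NPS to its 1D radial profile
#'
#' Bins the DC-centred 2D spectrum into annuli one DFT bin wide
#' (`1/(N*dx)` mm^-1) and averages within each annulus, from 0 out to the
#' Nyquist frequency (`floor(N/2) + 1` bins). Frequency bins in the corners
#' of the DFT square, beyond the Nyquist radius, are not covered by the
#' profile.
#'
#' @param nps2d an `nps2d` object (requires in-plane isotropic bins).
#' @return an [nps_profile()].
#' @export
radial_profile <- function(nps2d) {
  stopifnot(inherits(nps2d, "nps2d"))
  fs <- nps2d$freq_spacing
  if (abs(fs[1] - fs[2]) > 1e-9 * max(fs))
    stop("radial reduction requires isotropic frequency bins")
  df <- fs[1]
  n1 <- nrow(nps2d$power); n2 <- ncol(nps2d$power)
  u <- shifted_freqs(n1, 1 / (n1 * df))
  v <- shifted_freqs(n2, 1 / (n2 * df))
  r <- sqrt(outer(u^2, v^2, "+"))
  bin <- as.integer(round(r / df))
  nmax <- floor(min(n1, n2) / 2)
  keep <- bin <= nmax
  sums <- tapply(nps2d$power[keep], bin[keep], mean)
  prof <- numeric(nmax + 1L)
  prof[as.integer(names(sums)) + 1L] <- sums
  nps_profile(df * (0:nmax), prof, n_averaged = nps2d$n_averaged)
}

#' Total noise variance from a radial NPS profile
#'
#' Integrates the radially symmetric 2D spectrum in polar form,
#' `2*pi * integral of f * NPS(f) df`, by the trapezoidal rule. Equals the
#' noise variance (HU^2) for spectra supported inside the Nyquist disc.
#'
#' @param profile an [nps_profile()].
#' @return variance in HU^2.
#' @export
nps_variance <- function(profile) {
  stopifnot(inherits(profile, "nps_profile"))
  f <- profile$frequency; p <- profile$power
  2 * pi * sum(diff(f) * (f[-1] * p[-1] + f[-length(f)] * p[-length(p)]) / 2)
}

#' Cartesian integral of a 2D NPS
#'
#' `sum(power) * du * dv`: by Parseval this equals the mean variance of the
#' patches the spectrum was estimated from, including power in the DFT
#' corners that a radial profile truncated at Nyquist does not cover.
#'
#' @param nps2d an `nps2d` object.
#' @return variance in HU^2.
#' @export
nps2d_integral <- function(nps2d) {
  stopifnot(inherits(nps2d, "nps2d"))
  sum(nps2d$power) * prod(nps2d$freq_spacing)
}

#' Measure a 1D NPS profile from one or two phantom scans
#'
#' Convenience pipeline: ROI extraction, detrending (`"poly2d"` on single
#' scans; `"subtraction"` pairs co-located ROIs from `volume2`), periodogram
#' averaging and radial reduction.
#'
#' @param volume phantom scan, an [image_volume()].
#' @param spec an [roi_sampling_spec()].
#' @param detrend `"poly2d"` or `"subtraction"`.
#' @param volume2 repeat scan, required for subtraction detrending.
#' @return an [nps_profile()].
#' @export
estimate_nps <- function(volume, spec = roi_sampling_spec(),
                         detrend = c("poly2d", "subtraction"),
                         volume2 = NULL) {
  detrend <- match.arg(detrend)
  rois <- extract_rois(volume, spec)
  if (detrend == "subtraction") {
    if (is.null(volume2))
      stop("subtraction detrending needs the repeat scan `volume2`")
    rois2 <- extract_rois(volume2, spec)
    rois <- Map(function(a, b) detrend_roi(a, "subtraction", b), rois, rois2)
  } else {
    rois <- lapply(rois, detrend_roi, method = "poly2d")
  }
  radial_profile(roi_nps_2d(rois, volume$spacing[1:2]))
}
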