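# Inverse-FFT synthesis of noise with a prescribed power spectrum, and
# pseudo-CBCT creation by adding per-slice noise realizations to a CT.

#' Expand a 1D radial NPS profile to a 2D spectrum
#'
#' Fills a DC-centred DFT frequency grid by evaluating the profile at each
#' bin's radial frequency (linear interpolation). Radial frequencies beyond
#' the profile's range get zero power, so the resulting spectrum is
#' band-limited to the profile's support.
#'
#' @param profile an [nps_profile()].
#' @param shape 2D grid size `c(nx, ny)`.
#' @param spacing in-plane pixel size, mm (length 2 or scalar).
#' @return an `nps2d` object.
#' @export
profile_to_nps2d <- function(profile, shape, spacing) {
  stopifnot(inherits(profile, "nps_profile"))
  shape <- as.integer(rep(shape, length.out = 2L))
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  if (any(spacing <= 0)) stop("spacing must be positive (mm)")
  u <- shifted_freqs(shape[1], spacing[1])
  v <- shifted_freqs(shape[2], spacing[2])
  r <- sqrt(outer(u^2, v^2, "+"))
  pw <- stats::approx(profile$frequency, profile$power, xout = as.numeric(r),
                      rule = 1)$y
  pw[is.na(pw)] <- 0
  new_nps2d(matrix(pw, shape[1], shape[2]), 1 / (shape * spacing))
}

#' Synthesize one 2D noise realization from a 2D spectrum
#'
#' Builds a complex spectrum with fixed magnitude
#' `sqrt(power * Nx * Ny / (dx * dy))` and uniform random phases under
#' Hermitian symmetry, zeroes the DC bin, and inverse-transforms. Every
#' realization carries exactly the requested spectrum (amplitudes are fixed,
#' only phases are random), so the ensemble-average periodogram reproduces
#' the input and each slice has the spectrum's full variance.
#'
#' @param nps2d an `nps2d` object (non-negative power).
#' @param seed optional integer seed for the phase draw.
#' @return zero-mean noise matrix (HU) of the spectrum's grid size.
#' @export
synthesize_noise_slice <- function(nps2d, seed = NULL) {
  stopifnot(inherits(nps2d, "nps2d"))
  if (any(nps2d$power < 0)) stop("spectrum power must be non-negative")
  S <- ifftshift2(nps2d$power)
  n1 <- nrow(S); n2 <- ncol(S)
  dx <- 1 / (n1 * nps2d$freq_spacing[1])
  dy <- 1 / (n2 * nps2d$freq_spacing[2])
  A <- sqrt(S * n1 * n2 / (dx * dy))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ph <- stats::runif(n1 * n2, 0, 2 * pi)
  i1 <- rep(0:(n1 - 1L), times = n2)
  i2 <- rep(0:(n2 - 1L), each = n1)
  lin <- seq_len(n1 * n2)
  conj_lin <- ((n1 - i1) %% n1) + n1 * ((n2 - i2) %% n2) + 1L
  self <- conj_lin == lin
  ph[self] <- ifelse(ph[self] > pi, pi, 0)   # self-conjugate bins: +/- A
  upper <- lin > conj_lin
  ph[upper] <- -ph[conj_lin[upper]]
  X <- A * exp(1i * matrix(ph, n1, n2))
  X[1, 1] <- 0 + 0i
  out <- Re(stats::fft(X, inverse = TRUE)) / (n1 * n2)
  out
}

#' Noise recipe for pseudo-CBCT creation
#'
#' @param source an [nps_profile()] (measured spectrum) or [nps_params()]
#'   (fitted model).
#' @param target_sigma optional noise magnitude, HU; when given the spectrum
#'   is rescaled so the synthesized noise has this standard deviation.
#' @param seed base integer seed; slice `k` uses `seed + k - 1`.
#' @param clip optional `c(lo, hi)` HU range applied after noise addition.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(source, target_sigma = NULL, seed = 1L, clip = NULL) {
  if (!inherits(source, "nps_profile") && !inherits(source, "nps_params"))
    stop("`source` must be an nps_profile or nps_params")
  if (!is.null(target_sigma) &&
      (!is.finite(target_sigma) || target_sigma < 0))
    stop("`target_sigma` must be >= 0")
  if (!is.null(clip) && (length(clip) != 2L || clip[1] >= clip[2]))
    stop("`clip` must be c(lo, hi) with lo < hi")
  structure(list(source = source, target_sigma = target_sigma,
                 seed = as.integer(seed), clip = clip),
            class = "noise_spec")
}

# resolve a noise_spec to a gridded 2D spectrum for a given slice geometry;
# when a target magnitude is requested, the model/profile is first rescaled
# analytically and the gridded spectrum then renormalised so its discrete
# integral equals target_sigma^2 exactly (gridding is a quadrature of the
# radial profile; the final renormalisation removes its residual error)
resolve_noise_spectrum <- function(spec, shape, spacing) {
  f_nyq <- 1 / (2 * min(spacing))
  src <- spec$source
  prof <- if (inherits(src, "nps_params")) {
    if (!is.null(spec$target_sigma))
      src <- scale_to_sigma(src, spec$target_sigma, f_max = f_nyq)
    model_profile(src, f_nyq)
  } else {
    p <- src
    if (!is.null(spec$target_sigma)) {
      cur <- nps_variance(p)
      if (cur <= 0) {
        if (spec$target_sigma > 0)
          stop("zero-power spectrum cannot be scaled to a nonzero sigma")
      } else {
        p <- nps_profile(p$frequency,
                         p$power * spec$target_sigma^2 / cur,
                         attr(p, "n_averaged"))
      }
    }
    p
  }
  nps2d <- profile_to_nps2d(prof, shape, spacing)
  if (!is.null(spec$target_sigma)) {
    tot <- nps2d_integral(nps2d)
    if (tot <= 0) {
      if (spec$target_sigma > 0)
        stop("zero-power spectrum cannot be scaled to a nonzero sigma")
    } else {
      nps2d <- new_nps2d(nps2d$power * spec$target_sigma^2 / tot,
                         nps2d$freq_spacing, nps2d$n_averaged)
    }
  }
  nps2d
}

#' Create a pseudo-CBCT by adding spectrum-matched noise to a CT
#'
#' Each axial slice receives an independent zero-mean noise realization
#' synthesized from the requested spectrum (slice `k` is seeded with
#' `seed + k - 1`, so the result is fully reproducible). Geometry (spacing,
#' origin, shape) is untouched; HU are not clipped unless `clip` is set in
#' the spec.
#'
#' @param ct an [image_volume()].
#' @param spec a [noise_spec()].
#' @return an [image_volume()] with CBCT-like noise added.
#' @export
make_pseudo_cbct <- function(ct, spec) {
  stopifnot(inherits(ct, "image_volume"), inherits(spec, "noise_spec"))
  if (!is.null(spec$target_sigma) && spec$target_sigma == 0)
    return(ct)
  d <- dim(ct$voxels)
  nps2d <- resolve_noise_spectrum(spec, d[1:2], ct$spacing[1:2])
  out <- ct$voxels
  for (k in seq_len(d[3])) {
    slice_seed <- (spec$seed + k - 1L) %% .Machine$integer.max
    out[, , k] <- out[, , k] + synthesize_noise_slice(nps2d, seed = slice_seed)
  }
  if (!is.null(spec$clip)) {
    out[out < spec$clip[1]] <- spec$clip[1]
    out[out > spec$clip[2]] <- spec$clip[2]
  }
  image_volume(out, spacing = ct$spacing, origin = ct$origin)
}
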