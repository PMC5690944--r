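# Parametric model of the CT/CBCT radial NPS: a Gaussian bell multiplied by
# an exponential ramp-up, f(x) = a1 exp(-((x-a2)/a3)^2) (1 - exp(-a4 x)).
# The ramp-up reflects the suppression of low frequencies by the ramp filter
# during reconstruction; the bell carries the mid-frequency peak and the
# high-frequency roll-off of the apodisation.

#' Parameters of the parametric NPS model
#'
#' @param a1 peak-scale parameter (HU^2 mm^2), >= 0.
#' @param a2 centre frequency of the bell (mm^-1).
#' @param a3 width of the bell (mm^-1), > 0.
#' @param a4 ramp-up rate (mm), > 0.
#' @return an object of class `nps_params`.
#' @export
nps_params <- function(a1, a2, a3, a4) {
  if (!is.finite(a1) || a1 < 0) stop("`a1` must be >= 0")
  if (!is.finite(a2)) stop("`a2` must be finite")
  if (!is.finite(a3) || a3 <= 0) stop("`a3` must be > 0")
  if (!is.finite(a4) || a4 <= 0) stop("`a4` must be > 0")
  structure(list(a1 = a1, a2 = a2, a3 = a3, a4 = a4), class = "nps_params")
}

#' @export
print.nps_params <- function(x, ...) {
  cat(sprintf(
    "<nps_params> a1 = %.6g HU^2 mm^2, a2 = %.6g mm^-1, a3 = %.6g mm^-1, a4 = %.6g mm\n",
    x$a1, x$a2, x$a3, x$a4))
  invisible(x)
}

#' Evaluate the parametric NPS model
#'
#' `f(x) = a1 * exp(-((x - a2) / a3)^2) * (1 - exp(-a4 * x))`; zero at
#' `x = 0` and decaying to zero as `x` grows, non-negative throughout.
#'
#' @param params an [nps_params()].
#' @param x spatial frequencies, mm^-1 (>= 0).
#' @return spectral power (HU^2 mm^2), same length as `x`.
#' @export
eval_nps_model <- function(params, x) {
  stopifnot(inherits(params, "nps_params"))
  x <- as.numeric(x)
  if (any(x < 0)) stop("frequencies must be >= 0")
  params$a1 * exp(-((x - params$a2) / params$a3)^2) *
    (1 - exp(-params$a4 * x))
}

#' Sample the model on a regular frequency axis
#'
#' @param params an [nps_params()].
#' @param f_max top frequency (mm^-1), typically the grid Nyquist.
#' @param n number of samples from 0 to `f_max`.
#' @return an [nps_profile()].
#' @export
model_profile <- function(params, f_max, n = 512L) {
  f <- seq(0, f_max, length.out = n)
  nps_profile(f, eval_nps_model(params, f))
}

#' Fit the parametric NPS model to a measured profile
#'
#' Bounded Levenberg-Marquardt least squares with uniform weights.
#' Initialisation: `a2` at the peak frequency, `a1` at the peak power, `a3`
#' from the half width at half maximum, `a4 = 5 / a2`. Lower bounds keep
#' `a1 >= 0` and `a3, a4 > 0`.
#'
#' @param profile an [nps_profile()] with at least 8 points, not all zero.
#' @param max_eval cap on model evaluations.
#' @return an object of class `nps_fit`: `params`, `residual_rms`
#'   (HU^2 mm^2), `converged`, and the input `profile` with fitted values.
#' @export
fit_nps_model <- function(profile, max_eval = 2000L) {
  stopifnot(inherits(profile, "nps_profile"))
  f <- profile$frequency; p <- profile$power
  if (length(f) < 8L) stop("need at least 8 profile points to fit")
  if (all(p == 0)) stop("cannot fit an all-zero profile")
  imax <- which.max(p)
  a2_0 <- max(f[imax], f[2])
  a1_0 <- p[imax]
  above <- which(p >= a1_0 / 2)
  hwhm <- (f[max(above)] - f[min(above)]) / 2
  a3_0 <- max(hwhm, diff(f)[1])
  a4_0 <- 5 / a2_0
  dat <- data.frame(f = f, p = p)
  fit <- minpack.lm::nlsLM(
    p ~ a1 * exp(-((f - a2) / a3)^2) * (1 - exp(-a4 * f)),
    data = dat,
    start = list(a1 = a1_0, a2 = a2_0, a3 = a3_0, a4 = a4_0),
    lower = c(a1 = 0, a2 = 0, a3 = 1e-8, a4 = 1e-8),
    control = minpack.lm::nls.lm.control(
      maxiter = 1000L, maxfev = max_eval, ftol = 1e-10)
  )
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(
    list(params = nps_params(cf[["a1"]], cf[["a2"]], cf[["a3"]], cf[["a4"]]),
         residual_rms = sqrt(mean(res^2)),
         converged = isTRUE(fit$convInfo$isConv),
         profile = profile,
         fitted = as.numeric(stats::fitted(fit))),
    class = "nps_fit")
}

#' @export
print.nps_fit <- function(x, ...) {
  cat("<nps_fit>", if (x$converged) "converged" else "NOT converged", "\n")
  print(x$params)
  cat(sprintf("  residual RMS %.4g HU^2 mm^2 on %d points\n",
              x$residual_rms, nrow(x$profile)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted NPS model parameters
#'
#' @param x an `nps_fit`.
#' @param ... unused.
#' @return a tibble with columns `term` and `estimate`.
#' @export
tidy.nps_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "a2", "a3", "a4"),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' One-row fit summary
#'
#' @param x an `nps_fit`.
#' @param ... unused.
#' @return a tibble with `residual_rms`, `converged`, `n` and the model
#'   variance (`sigma_hu`, from the polar integral of the fitted profile).
#' @export
glance.nps_fit <- function(x, ...) {
  prof <- model_profile(x$params, max(x$profile$frequency))
  tibble::tibble(residual_rms = x$residual_rms,
                 converged = x$converged,
                 n = nrow(x$profile),
                 sigma_hu = sqrt(nps_variance(prof)))
}

#' Rescale the model amplitude to a target noise magnitude
#'
#' Multiplies `a1` by `target_sigma^2 / sigma_current^2`, where the current
#' variance is the polar integral of the model profile sampled on `n` points
#' out to `f_max` (the synthesis grid's Nyquist). Variance is linear in `a1`,
#' so the rescaled model's magnitude equals `target_sigma` exactly up to
#' quadrature error.
#'
#' @param params an [nps_params()].
#' @param target_sigma desired noise standard deviation, HU (>= 0).
#' @param f_max integration limit, mm^-1; defaults to `a2 + 12 * a3`, which
#'   covers the bell's support.
#' @param n quadrature points.
#' @return rescaled [nps_params()].
#' @export
scale_to_sigma <- function(params, target_sigma, f_max = NULL, n = 512L) {
  stopifnot(inherits(params, "nps_params"))
  if (!is.finite(target_sigma) || target_sigma < 0)
    stop("`target_sigma` must be >= 0")
  if (is.null(f_max)) f_max <- params$a2 + 12 * params$a3
  cur_var <- nps_variance(model_profile(params, f_max, n))
  if (cur_var <= 0) {
    if (target_sigma == 0) return(nps_params(0, params$a2, params$a3, params$a4))
    stop("model has zero variance; cannot scale to a nonzero sigma")
  }
  nps_params(params$a1 * target_sigma^2 / cur_var,
             params$a2, params$a3, params$a4)
}
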