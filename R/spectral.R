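#' Visual pigment spectral sensitivity template
#'
#' Evaluates the standard A1 visual-pigment absorbance template at a
#' wavelength, given the pigment's peak wavelength (lambda-max). The
#' alpha-band is
#' \deqn{S(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda}, constants A = 69.7, B = 28,
#' C = -14.9, D = 0.674, b = 0.922, c = 1.104, and
#' \eqn{a = 0.8795 + 0.0459\, e^{-(\lambda_{max}-300)^2/11940}}.
#' The returned value is peak-normalized so that sensitivity is exactly 1 at
#' \eqn{\lambda = \lambda_{max}}. The short-wavelength beta-band (a Gaussian
#' at \eqn{189 + 0.315\,\lambda_{max}} nm) can be added with `beta_band =
#' TRUE`; the default excludes it, which gives the familiar unimodal curves.
#'
#' @param lambda_nm Wavelength(s) at which to evaluate, nm, in [250, 900].
#' @param lambda_max_nm Peak wavelength of the pigment, nm, in [250, 900].
#' @param beta_band Include the beta-band contribution? Default `FALSE`.
#' @return Sensitivity in (0, 1], peak-normalized.
#' @examples
#' pigment_sensitivity(535, 535)  # 1
#' pigment_sensitivity(500, 535)
#' @export
pigment_sensitivity <- function(lambda_nm, lambda_max_nm, beta_band = FALSE) {
  if (any(lambda_nm < 250 | lambda_nm > 900) ||
      any(lambda_max_nm < 250 | lambda_max_nm > 900)) {
    stop("wavelengths must lie in [250, 900] nm", call. = FALSE)
  }
  raw <- .pigment_template(lambda_nm, lambda_max_nm, beta_band)
  peak <- .pigment_template(lambda_max_nm, lambda_max_nm, beta_band)
  raw / peak
}

.pigment_template <- function(lambda_nm, lambda_max_nm, beta_band) {
  x <- lambda_max_nm / lambda_nm
  a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  if (!beta_band) return(alpha)
  lmb <- 189 + 0.315 * lambda_max_nm
  bb <- -40.5 + 0.195 * lambda_max_nm
  alpha + 0.26 * exp(-((lambda_nm - lmb) / bb)^2)
}

#' Spectral curve container
#'
#' A wavelength grid with values normalized so the maximum is exactly 1;
#' holds either a photoreceptor sensitivity curve or a reflectance spectrum.
#'
#' @param wavelengths_nm Strictly ascending wavelength grid, nm.
#' @param values Non-negative values; normalized to max 1 on construction.
#' @return A `spectral_curve` object (list with `wavelengths_nm`, `values`).
#' @export
spectral_curve <- function(wavelengths_nm, values) {
  if (!length(wavelengths_nm) || length(wavelengths_nm) != length(values)) {
    stop("wavelengths and values must be non-empty and of equal length",
         call. = FALSE)
  }
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly ascending", call. = FALSE)
  }
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  mx <- max(values)
  if (mx <= 0) stop("curve must contain a positive value", call. = FALSE)
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 values = as.numeric(values) / mx),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve> %d points, %g-%g nm, peak at %g nm\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm),
              x$wavelengths_nm[which.max(x$values)]))
  invisible(x)
}

#' @export
as.data.frame.spectral_curve <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths_nm, value = x$values)
}

#' Photoreceptor sensitivity curve on a wavelength grid
#'
#' Evaluates the pigment template over a grid and returns a normalized
#' [spectral_curve()] whose maximum sits at the grid point nearest
#' lambda-max.
#'
#' @inheritParams pigment_sensitivity
#' @param grid_nm Ascending wavelength grid, nm, within [250, 900].
#' @return A `spectral_curve`.
#' @examples
#' sensitivity_curve(476, 300:700)
#' @export
sensitivity_curve <- function(lambda_max_nm, grid_nm = 300:700,
                              beta_band = FALSE) {
  if (!length(grid_nm)) stop("`grid_nm` must be non-empty", call. = FALSE)
  spectral_curve(grid_nm,
                 pigment_sensitivity(grid_nm, lambda_max_nm, beta_band))
}

#' Average replicate reflectance measurements into one normalized curve
#'
#' Spectrometer replicates of the same surface are interpolated to a common
#' 1 nm grid spanning the intersection of their wavelength ranges, averaged
#' pointwise, and max-normalized. Negative readings (instrument noise near
#' zero reflectance) are clamped to 0 with a warning.
#'
#' @param measurements A list of two-column data.frames (wavelength_nm,
#'   reflectance), or a character vector of CSV file paths with those two
#'   columns.
#' @param step_nm Grid step for interpolation, nm. Default 1.
#' @return A [spectral_curve()].
#' @export
load_and_average_reflectance <- function(measurements, step_nm = 1) {
  if (is.character(measurements)) {
    measurements <- lapply(measurements, utils::read.csv)
  }
  if (!length(measurements)) {
    stop("at least one measurement is required", call. = FALSE)
  }
  measurements <- lapply(measurements, function(m) {
    m <- as.data.frame(m)[, 1:2]
    names(m) <- c("wavelength_nm", "reflectance")
    m[order(m$wavelength_nm), ]
  })
  lo <- max(vapply(measurements, function(m) min(m$wavelength_nm), 0))
  hi <- min(vapply(measurements, function(m) max(m$wavelength_nm), 0))
  if (lo >= hi) {
    stop("measurements have disjoint wavelength ranges", call. = FALSE)
  }
  grid <- seq(ceiling(lo), floor(hi), by = step_nm)
  vals <- vapply(measurements, function(m) {
    stats::approx(m$wavelength_nm, m$reflectance, xout = grid)$y
  }, numeric(length(grid)))
  avg <- rowMeans(matrix(vals, nrow = length(grid)))
  if (any(avg < 0)) {
    warning("negative reflectance values clamped to 0")
    avg[avg < 0] <- 0
  }
  spectral_curve(grid, avg)
}

#' Receptor quantum catch (not implemented)
#'
#' Quantum-catch and receptor-contrast computation against an illuminant is
#' outside this package's scope: the toolkit overlays sensitivity and
#' reflectance curves but performs no color-choice modeling.
#'
#' @param ... Unused.
#' @export
quantum_catch <- function(...) {
  stop("quantum catch / receptor contrast computation is not implemented; ",
       "this package models spatial acuity, not color choice", call. = FALSE)
}
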