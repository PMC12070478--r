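#' Spatial-acuity geometry of a compound eye
#'
#' The resolution limit of a compound eye with interommatidial angle
#' \eqn{\alpha} determines the maximum distance \eqn{D} at which a stimulus of
#' size \eqn{R} is resolvable:
#' \deqn{D = (R/2) / \tan(\alpha/2)}
#' `resolvable_distance()` evaluates this directly; `resolvable_size()` is its
#' inverse \eqn{R = 2 D \tan(\alpha/2)}; `min_io_angle_to_resolve()` solves
#' for the angle, \eqn{\alpha = 2\,\mathrm{atan}(R/(2D))}. All angles in the
#' public interface are in degrees; conversion to radians is internal. The
#' equation is used as printed, with the single IO angle defining the
#' resolution limit (no Nyquist halving), because the published trap-size
#' tables this package reproduces were built that way.
#'
#' @param r_cm Stimulus size R in cm: the maximal linear extent of the
#'   pattern element.
#' @param d_cm Viewing distance D in cm.
#' @param alpha_deg Interommatidial angle in degrees, in (0, 180).
#'
#' @return `resolvable_distance()` and `resolvable_size()` return lengths in
#'   cm; `min_io_angle_to_resolve()` returns an angle in degrees;
#'   `is_resolvable()` returns a logical.
#'
#' @examples
#' resolvable_distance(2.46, 14)   # ~10 cm
#' resolvable_size(5, 14)          # 1.23 cm
#' min_io_angle_to_resolve(1.23, 5)
#' @name acuity
NULL

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
}

.check_angle <- function(alpha_deg) {
  if (!is.numeric(alpha_deg) || any(!is.finite(alpha_deg)) ||
      any(alpha_deg <= 0) || any(alpha_deg >= 180)) {
    stop("`alpha_deg` must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
}

#' @rdname acuity
#' @export
resolvable_distance <- function(r_cm, alpha_deg) {
  .check_positive(r_cm, "r_cm")
  .check_angle(alpha_deg)
  (r_cm / 2) / tan(alpha_deg / 2 * pi / 180)
}

#' @rdname acuity
#' @export
resolvable_size <- function(d_cm, alpha_deg) {
  .check_positive(d_cm, "d_cm")
  .check_angle(alpha_deg)
  2 * d_cm * tan(alpha_deg / 2 * pi / 180)
}

#' @rdname acuity
#' @export
min_io_angle_to_resolve <- function(r_cm, d_cm) {
  .check_positive(r_cm, "r_cm")
  .check_positive(d_cm, "d_cm")
  2 * atan(r_cm / (2 * d_cm)) * 180 / pi
}

#' @rdname acuity
#' @export
is_resolvable <- function(r_cm, d_cm, alpha_deg) {
  .check_positive(d_cm, "d_cm")
  resolvable_distance(r_cm, alpha_deg) >= d_cm
}

#' Resolvable-size interval over an IO-angle interval
#'
#' For a receiver whose IO angle is known only to an interval, the stimulus
#' size resolvable at a given distance is itself an interval: the lower bound
#' comes from the most acute assumed eye (smallest angle) and the upper bound
#' from the coarsest. This reproduces the published resolvable-size tables for
#' the western flower thrips preset.
#'
#' @param d_cm Viewing distance in cm.
#' @param vs A [visual_system()].
#' @return A `size_range` object: list with `r_min_cm` and `r_max_cm`.
#' @examples
#' size_range(10, wft_visual_system())  # 1.75 to 2.46 cm
#' @export
size_range <- function(d_cm, vs) {
  stopifnot(inherits(vs, "visual_system"))
  r_min <- resolvable_size(d_cm, vs$io_angle_min_deg)
  r_max <- resolvable_size(d_cm, vs$io_angle_max_deg)
  structure(list(r_min_cm = r_min, r_max_cm = r_max), class = "size_range")
}

#' @export
print.size_range <- function(x, ...) {
  cat(sprintf("<size_range> %.2f to %.2f cm\n", x$r_min_cm, x$r_max_cm))
  invisible(x)
}
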