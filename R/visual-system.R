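#' Define a receiver's visual system
#'
#' A visual system is described by its interommatidial (IO) angle -- either a
#' point value or an interval reflecting anatomical uncertainty -- together
#' with the peak sensitivities (lambda-max) of its photoreceptor classes. The
#' IO angle sets the anatomical limit of spatial resolution for a compound
#' eye; the lambda-max values feed the spectral-sensitivity template (see
#' [sensitivity_curve()]).
#'
#' @param io_angle_min_deg Lower bound of the IO angle interval, in degrees.
#' @param io_angle_max_deg Upper bound of the IO angle interval, in degrees.
#'   Defaults to `io_angle_min_deg` (a point estimate).
#' @param lambda_max_nm Numeric vector of photoreceptor peak wavelengths (nm).
#' @param design_angle_deg IO angle used when sizing stimuli with
#'   [design_trap()]. The conservative convention is the upper bound of the
#'   interval, so that a stimulus sized for a target distance is resolvable
#'   even by the coarsest assumed eye; that is the default.
#'
#' @return An object of class `visual_system`.
#'
#' @examples
#' # western flower thrips: coarse eyes, 60-70 ommatidia
#' visual_system(10, 14, lambda_max_nm = c(363, 476, 535))
#' @export
visual_system <- function(io_angle_min_deg,
                          io_angle_max_deg = io_angle_min_deg,
                          lambda_max_nm = numeric(),
                          design_angle_deg = io_angle_max_deg) {
  stopifnot(is.numeric(io_angle_min_deg), length(io_angle_min_deg) == 1,
            is.numeric(io_angle_max_deg), length(io_angle_max_deg) == 1)
  if (!(io_angle_min_deg > 0 && io_angle_min_deg <= io_angle_max_deg &&
        io_angle_max_deg < 180)) {
    stop("io_angle interval must satisfy 0 < min <= max < 180 degrees",
         call. = FALSE)
  }
  if (length(lambda_max_nm) &&
      any(lambda_max_nm < 300 | lambda_max_nm > 800)) {
    stop("lambda_max_nm values must lie in [300, 800] nm", call. = FALSE)
  }
  if (design_angle_deg < io_angle_min_deg || design_angle_deg > io_angle_max_deg) {
    stop("design_angle_deg must lie within the io_angle interval", call. = FALSE)
  }
  structure(
    list(io_angle_min_deg = io_angle_min_deg,
         io_angle_max_deg = io_angle_max_deg,
         lambda_max_nm = as.numeric(lambda_max_nm),
         design_angle_deg = design_angle_deg),
    class = "visual_system"
  )
}

#' Western flower thrips visual-system preset
#'
#' *Frankliniella occidentalis* has only 60-70 ommatidia per compound eye,
#' giving anatomical IO-angle estimates between 10 and 14 degrees -- around
#' five-fold coarser than typical flying insects. Its three photoreceptor
#' classes peak at 363, 476 and 535 nm. Stimulus sizing uses the 14-degree
#' upper bound.
#'
#' @return A `visual_system` object.
#' @examples
#' wft_visual_system()
#' @export
wft_visual_system <- function() {
  visual_system(10, 14, lambda_max_nm = c(363, 476, 535),
                design_angle_deg = 14)
}

#' @export
print.visual_system <- function(x, ...) {
  if (x$io_angle_min_deg == x$io_angle_max_deg) {
    cat(sprintf("<visual_system> IO angle %g deg", x$io_angle_min_deg))
  } else {
    cat(sprintf("<visual_system> IO angle %g-%g deg (design %g deg)",
                x$io_angle_min_deg, x$io_angle_max_deg, x$design_angle_deg))
  }
  if (length(x$lambda_max_nm)) {
    cat(sprintf("; lambda-max %s nm", paste(x$lambda_max_nm, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
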