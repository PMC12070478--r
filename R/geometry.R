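#' Visibility geometry of a trap hung above a crop canopy
#'
#' A trap hung `height_cm` above the canopy is viewed by insects sitting at
#' canopy level, so the viewing distance to a position a horizontal distance
#' `x` from the trap is the slant distance `sqrt(h^2 + x^2)`. If the trap's
#' pattern is resolvable out to a maximum distance `d_max`, the set of canopy
#' positions from which it can be resolved is a disc of radius
#' `sqrt(d_max^2 - h^2)` directly beneath the trap -- the visibility cone.
#' When `d_max < h` the pattern is resolvable nowhere; when `d_max == h` it is
#' resolvable only from directly below (the boundary counts as resolvable).
#'
#' @param height_cm Trap height above the canopy, cm.
#' @param horizontal_cm Horizontal offset along the canopy, cm.
#' @param d_max_cm Maximum resolvable distance of the trap's pattern element,
#'   cm (from [resolvable_distance()]).
#'
#' @return `slant_distance()`: a length in cm. `horizontal_visible_range()`:
#'   a `visibility_cone` object with fields `resolvable_below` (logical) and
#'   `horizontal_range_cm` (radius of the visibility disc; 0 when resolvable
#'   only directly below, `NA` when not resolvable at all).
#'
#' @examples
#' horizontal_visible_range(30, 15)  # 25.98 cm radius
#' horizontal_visible_range(15, 30)  # not resolvable anywhere
#' @name viewing_geometry
NULL

#' @rdname viewing_geometry
#' @export
slant_distance <- function(height_cm, horizontal_cm) {
  if (any(height_cm < 0) || any(horizontal_cm < 0)) {
    stop("heights and horizontal offsets must be non-negative", call. = FALSE)
  }
  sqrt(height_cm^2 + horizontal_cm^2)
}

#' @rdname viewing_geometry
#' @export
horizontal_visible_range <- function(d_max_cm, height_cm) {
  .check_positive(d_max_cm, "d_max_cm")
  .check_positive(height_cm, "height_cm")
  if (d_max_cm < height_cm) {
    cone <- list(resolvable_below = FALSE, horizontal_range_cm = NA_real_)
  } else {
    cone <- list(resolvable_below = TRUE,
                 horizontal_range_cm = sqrt(d_max_cm^2 - height_cm^2))
  }
  structure(cone, class = "visibility_cone")
}

#' @export
print.visibility_cone <- function(x, ...) {
  if (!x$resolvable_below) {
    cat("<visibility_cone> pattern not resolvable at this height\n")
  } else if (x$horizontal_range_cm == 0) {
    cat("<visibility_cone> resolvable only directly below the trap\n")
  } else {
    cat(sprintf("<visibility_cone> resolvable within %.2f cm of the trap\n",
                x$horizontal_range_cm))
  }
  invisible(x)
}

#' Maximum dimension of a rectangular trap card
#'
#' The diagonal of the card: the largest linear extent a neighbouring insect
#' could have to resolve to see the whole card as a single stimulus.
#'
#' @param width_cm,length_cm Card dimensions in cm.
#' @return The diagonal in cm.
#' @examples
#' card_max_dimension(12.5, 24.5)  # 27.50 cm
#' @export
card_max_dimension <- function(width_cm, length_cm) {
  .check_positive(width_cm, "width_cm")
  .check_positive(length_cm, "length_cm")
  sqrt(width_cm^2 + length_cm^2)
}

#' Classify a multi-trap layout as choice or no-choice
#'
#' A layout is effectively no-choice when, at the spacing between traps, even
#' the most acute assumed eye cannot resolve a neighbouring whole card: the
#' minimum resolvable stimulus size at that distance exceeds the card
#' diagonal, so no more than one trap is resolvable at a time. The boundary
#' (minimum resolvable size equal to the diagonal) is classified as choice.
#'
#' @param trap_spacing_cm Distance between neighbouring traps, cm.
#' @param card_width_cm,card_length_cm Card dimensions, cm.
#' @param vs A [visual_system()].
#' @return A list with `design` (`"choice"` or `"no_choice"`), the supporting
#'   `size_range` at the spacing, and the card diagonal.
#' @examples
#' classify_choice_design(250, 12.5, 24.5, wft_visual_system())
#' @export
classify_choice_design <- function(trap_spacing_cm, card_width_cm,
                                   card_length_cm, vs) {
  .check_positive(trap_spacing_cm, "trap_spacing_cm")
  rng <- size_range(trap_spacing_cm, vs)
  diag_cm <- card_max_dimension(card_width_cm, card_length_cm)
  design <- if (rng$r_min_cm > diag_cm) "no_choice" else "choice"
  list(design = design, size_range = rng, card_diagonal_cm = diag_cm)
}

#' Describe a trap placement
#'
#' Pairs a pattern element (by its size and maximum resolvable distance) with
#' the height the trap hangs above the canopy.
#'
#' @param height_above_canopy_cm Height above the canopy, cm (>= 0).
#' @param element_resolvable_distance_cm Maximum distance at which the card's
#'   pattern element is resolvable, cm (from [resolvable_distance()]).
#' @param element_size_cm Optional element size, carried through for
#'   reporting.
#' @param label Optional label (e.g. "small", "medium", "large").
#' @return A `trap_placement` object.
#' @export
trap_placement <- function(height_above_canopy_cm,
                           element_resolvable_distance_cm,
                           element_size_cm = NA_real_,
                           label = NA_character_) {
  if (height_above_canopy_cm < 0) {
    stop("height_above_canopy_cm must be >= 0", call. = FALSE)
  }
  .check_positive(element_resolvable_distance_cm,
                  "element_resolvable_distance_cm")
  structure(
    list(height_above_canopy_cm = height_above_canopy_cm,
         element_resolvable_distance_cm = element_resolvable_distance_cm,
         element_size_cm = element_size_cm,
         label = label),
    class = "trap_placement"
  )
}

#' Tabulate visibility over a set of trap placements
#'
#' One row per placement, recording whether the pattern is resolvable from
#' directly below and, if so, the radius of the canopy disc from which it is
#' resolvable. `max_resolvable_range_cm` is the covariate used by the
#' attraction-range analysis: the element's maximum resolvable distance when
#' the pattern is resolvable at the placement, 0 when it is not.
#'
#' @param placements A list of [trap_placement()] objects.
#' @return A data.frame with columns `label`, `height_cm`, `size_cm`,
#'   `d_max_cm`, `resolvable_below`, `horizontal_range_cm`,
#'   `max_resolvable_range_cm`.
#' @examples
#' visibility_table(polytunnel_placements())
#' @export
visibility_table <- function(placements) {
  if (inherits(placements, "trap_placement")) placements <- list(placements)
  if (!length(placements)) {
    stop("`placements` must contain at least one trap placement", call. = FALSE)
  }
  rows <- lapply(placements, function(p) {
    stopifnot(inherits(p, "trap_placement"))
    cone <- horizontal_visible_range(p$element_resolvable_distance_cm,
                                     p$height_above_canopy_cm)
    data.frame(
      label = p$label,
      height_cm = p$height_above_canopy_cm,
      size_cm = p$element_size_cm,
      d_max_cm = p$element_resolvable_distance_cm,
      resolvable_below = cone$resolvable_below,
      horizontal_range_cm = cone$horizontal_range_cm,
      max_resolvable_range_cm = if (cone$resolvable_below)
        p$element_resolvable_distance_cm else 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' The nine polytunnel trap placements
#'
#' Small, medium and large pattern elements sized to be resolvable at 15, 30
#' and 50 cm (at the visual system's design angle), each hung at 15, 30 and
#' 50 cm above the canopy: the full size-by-height grid of the polytunnel
#' experiment.
#'
#' @param vs A [visual_system()]; defaults to the western flower thrips
#'   preset.
#' @param design_distances_cm Distances the three element sizes are designed
#'   to be resolvable at, cm.
#' @param heights_cm Trap heights above the canopy, cm.
#' @return A list of [trap_placement()] objects (sizes vary fastest).
#' @export
polytunnel_placements <- function(vs = wft_visual_system(),
                                  design_distances_cm = c(15, 30, 50),
                                  heights_cm = c(15, 30, 50)) {
  labels <- c("small", "medium", "large")[seq_along(design_distances_cm)]
  out <- list()
  for (h in heights_cm) {
    for (i in seq_along(design_distances_cm)) {
      d <- design_distances_cm[i]
      out[[length(out) + 1L]] <- trap_placement(
        height_above_canopy_cm = h,
        element_resolvable_distance_cm = d,
        element_size_cm = resolvable_size(d, vs$design_angle_deg),
        label = labels[i]
      )
    }
  }
  out
}
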