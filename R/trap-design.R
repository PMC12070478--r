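#' Geometric flower pattern element
#'
#' The pattern element is a rosette defined in polar coordinates around its
#' center: \eqn{r(\theta) = (R/2)(c_0 + (1 - c_0)\cos(k\theta))} where R is
#' the element size (maximal linear extent, the diameter of the circumscribed
#' circle), k the petal count and \eqn{c_0 \in (0, 1]} a roundness parameter
#' (1 gives a circle, smaller values give deeper petals). Its area has the
#' closed form \eqn{\pi (R/2)^2 (c_0^2 + (1 - c_0)^2 / 2)}.
#'
#' The default roundness 0.98647 was calibrated once so that six small
#' (3.68 cm) elements cover 20.28% of a 24.5 x 12.5 cm card, the one
#' pattern-cover percentage that pins down the shape; it is close to a
#' circle, consistent with a compact flower silhouette.
#'
#' @param size_cm Element size R, cm (maximal linear extent).
#' @param center Numeric length-2, element center (x, y) on the card, cm.
#'   Origin at the card's lower-left corner, x rightward, y upward.
#' @param petals Number of petals k (>= 3).
#' @param roundness Roundness c0 in (0, 1].
#' @return A `pattern_element` object.
#' @export
pattern_element <- function(size_cm, center = c(0, 0), petals = 6L,
                            roundness = 0.98647) {
  .check_positive(size_cm, "size_cm")
  if (petals < 3) stop("`petals` must be >= 3", call. = FALSE)
  if (roundness <= 0 || roundness > 1) {
    stop("`roundness` must be in (0, 1]", call. = FALSE)
  }
  structure(list(shape = "geometric_flower", size_cm = size_cm,
                 center = as.numeric(center), petals = as.integer(petals),
                 roundness = roundness),
            class = "pattern_element")
}

# fraction of the circumscribed circle covered by the rosette
.fill_fraction <- function(el) el$roundness^2 + (1 - el$roundness)^2 / 2

# rosette radius at polar angle theta (relative to element center)
.flower_radius <- function(el, theta) {
  (el$size_cm / 2) * (el$roundness + (1 - el$roundness) * cos(el$petals * theta))
}

#' Area of a pattern element
#'
#' Closed-form area of the polar rosette:
#' \eqn{\pi (R/2)^2 (c_0^2 + (1-c_0)^2/2)}.
#'
#' @param el A [pattern_element()].
#' @return Area in cm^2.
#' @export
element_area <- function(el) {
  stopifnot(inherits(el, "pattern_element"))
  .fill_fraction(el) * pi * (el$size_cm / 2)^2
}

#' Compose a trap card
#'
#' A rectangular card with a background color and a set of flower pattern
#' elements. Elements must not overlap (checked on their circumscribed
#' circles). Elements extending past the card edge are rejected unless
#' `allow_clipping = TRUE`, in which case the clipping is reported via a
#' message and [percent_cover()] accounts for it by rasterization.
#'
#' @param width_cm,height_cm Card dimensions, cm.
#' @param elements List of [pattern_element()] objects (may be empty).
#' @param background_color,pattern_color Fill colors for rendering (any
#'   string a renderer understands; defaults are sRGB stand-ins for the
#'   trap blue and yellow).
#' @param allow_clipping Permit elements that extend past the card edge?
#' @return A `trap_card` object.
#' @export
trap_card <- function(width_cm, height_cm, elements = list(),
                      background_color = "#2E6DB4",
                      pattern_color = "#FFD447",
                      allow_clipping = FALSE) {
  .check_positive(width_cm, "width_cm")
  .check_positive(height_cm, "height_cm")
  if (inherits(elements, "pattern_element")) elements <- list(elements)
  clipped <- logical(length(elements))
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    stopifnot(inherits(el, "pattern_element"))
    rad <- el$size_cm / 2
    clipped[i] <- el$center[1] - rad < 0 || el$center[1] + rad > width_cm ||
      el$center[2] - rad < 0 || el$center[2] + rad > height_cm
  }
  if (any(clipped)) {
    if (!allow_clipping) {
      stop(sprintf("element(s) %s extend past the card edge; set allow_clipping = TRUE to accept",
                   paste(which(clipped), collapse = ", ")), call. = FALSE)
    }
    message(sprintf("trap_card: element(s) %s are clipped at the card edge",
                    paste(which(clipped), collapse = ", ")))
  }
  if (length(elements) > 1) {
    for (i in seq_len(length(elements) - 1)) {
      for (j in seq(i + 1, length(elements))) {
        d <- sqrt(sum((elements[[i]]$center - elements[[j]]$center)^2))
        if (d < (elements[[i]]$size_cm + elements[[j]]$size_cm) / 2) {
          stop(sprintf("elements %d and %d overlap", i, j), call. = FALSE)
        }
      }
    }
  }
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 elements = elements, background_color = background_color,
                 pattern_color = pattern_color, clipped = clipped),
            class = "trap_card")
}

#' @export
print.trap_card <- function(x, ...) {
  cat(sprintf("<trap_card> %g x %g cm, %d pattern element(s), %.2f%% pattern cover\n",
              x$width_cm, x$height_cm, length(x$elements), percent_cover(x)))
  invisible(x)
}

# fraction of grid points inside any element, restricted to the card
.raster_cover <- function(card, resolution_cm = 0.01) {
  xs <- seq(resolution_cm / 2, card$width_cm - resolution_cm / 2,
            by = resolution_cm)
  ys <- seq(resolution_cm / 2, card$height_cm - resolution_cm / 2,
            by = resolution_cm)
  inside_total <- 0
  for (el in card$elements) {
    # only scan the element's bounding box, clipped to the card
    rad <- el$size_cm / 2
    xi <- xs[xs >= el$center[1] - rad & xs <= el$center[1] + rad]
    yi <- ys[ys >= el$center[2] - rad & ys <= el$center[2] + rad]
    if (!length(xi) || !length(yi)) next
    dx <- outer(xi - el$center[1], rep(1, length(yi)))
    dy <- outer(rep(1, length(xi)), yi - el$center[2])
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    inside_total <- inside_total + sum(r <= .flower_radius(el, theta))
  }
  inside_total / (length(xs) * length(ys))
}

#' Percentage of the card covered by pattern
#'
#' For unclipped layouts this is the exact analytic element area summed over
#' elements; when an element is clipped at the card edge the cover is
#' computed by rasterizing the card at `resolution_cm`.
#'
#' @param card A [trap_card()].
#' @param resolution_cm Grid step for the rasterized fallback, cm.
#' @return Percentage of card area covered by pattern elements.
#' @export
percent_cover <- function(card, resolution_cm = 0.01) {
  stopifnot(inherits(card, "trap_card"))
  if (!length(card$elements)) return(0)
  if (any(card$clipped)) {
    return(100 * .raster_cover(card, resolution_cm))
  }
  100 * sum(vapply(card$elements, element_area, 0)) /
    (card$width_cm * card$height_cm)
}

#' Number of elements needed to hit a target pattern cover
#'
#' Rounds `target_percent` of the card area divided by the area of one
#' element, with a floor of one element, and reports the cover actually
#' achieved by that count. This is how element counts are varied across sizes
#' to hold the background:pattern color ratio roughly constant.
#'
#' @param width_cm,height_cm Card dimensions, cm.
#' @param size_cm Element size, cm.
#' @param target_percent Target pattern cover, percent, in (0, 100).
#' @param petals,roundness Element shape parameters, as in
#'   [pattern_element()].
#' @return List with `n` (integer count) and `achieved_percent`.
#' @export
choose_element_count <- function(width_cm, height_cm, size_cm, target_percent,
                                 petals = 6L, roundness = 0.98647) {
  if (target_percent <= 0 || target_percent >= 100) {
    stop("`target_percent` must be in (0, 100)", call. = FALSE)
  }
  if (size_cm > min(width_cm, height_cm)) {
    stop("element is larger than the card", call. = FALSE)
  }
  a_el <- element_area(pattern_element(size_cm, petals = petals,
                                       roundness = roundness))
  a_card <- width_cm * height_cm
  n <- max(1L, as.integer(round(target_percent / 100 * a_card / a_el)))
  list(n = n, achieved_percent = 100 * n * a_el / a_card)
}

#' Lay out element centers on a card
#'
#' Places `n` elements so that every element lies fully inside the card and
#' every pairwise edge-to-edge gap exceeds the element size (so each element
#' is independently resolvable at the design distance). A single element goes
#' to the card center; otherwise a grid spanning the card (edge margins of
#' half an element) is tried first, which is deterministic; if the grid
#' violates the gap constraint, seeded rejection sampling is used.
#'
#' @param width_cm,height_cm Card dimensions, cm.
#' @param n Number of elements (>= 1).
#' @param size_cm Element size, cm.
#' @param seed Integer seed for the rejection-sampling fallback.
#' @return A list of numeric length-2 centers (x, y), cm.
#' @export
layout_elements <- function(width_cm, height_cm, n, size_cm, seed = 1L) {
  .check_positive(size_cm, "size_cm")
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  margin <- size_cm / 2
  if (width_cm < size_cm || height_cm < size_cm) {
    stop("element does not fit inside the card", call. = FALSE)
  }
  if (n == 1) return(list(c(width_cm / 2, height_cm / 2)))

  gap_ok <- function(centers) {
    m <- do.call(rbind, centers)
    d <- stats::dist(m)
    all(d > 2 * size_cm)  # edge gap = center dist - size > size
  }

  cols <- max(1L, min(n, as.integer(round(sqrt(n * width_cm / height_cm)))))
  rows <- as.integer(ceiling(n / cols))
  xs <- if (cols == 1) width_cm / 2 else
    seq(margin, width_cm - margin, length.out = cols)
  ys <- if (rows == 1) height_cm / 2 else
    seq(margin, height_cm - margin, length.out = rows)
  grid <- expand.grid(x = xs, y = ys)[seq_len(n), ]
  centers <- lapply(seq_len(n), function(i) c(grid$x[i], grid$y[i]))
  if (gap_ok(centers)) return(centers)

  # seeded rejection sampling, preserving the caller's RNG state
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (restart in 1:200) {
    centers <- list()
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- c(stats::runif(1, margin, width_cm - margin),
                  stats::runif(1, margin, height_cm - margin))
        if (all(vapply(centers, function(ct)
          sqrt(sum((ct - cand)^2)) > 2 * size_cm, TRUE))) {
          centers[[i]] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(centers)
  }
  stop("cannot satisfy the spacing constraint (pairwise edge gap > element size) on this card",
       call. = FALSE)
}

#' Design a trap card for a target viewing distance
#'
#' Sizes the flower element to be exactly resolvable at `d_target_cm` for the
#' visual system's design angle, chooses the element count to approximate
#' `target_percent` pattern cover (or uses `n_elements` directly), lays the
#' elements out, and returns the card annotated with the achieved cover and
#' the predicted resolvable-distance interval of the element over the
#' IO-angle interval.
#'
#' @param d_target_cm Target viewing distance, cm.
#' @param vs A [visual_system()].
#' @param width_cm,height_cm Card dimensions, cm.
#' @param target_percent Target pattern cover, percent; ignored when
#'   `n_elements` is given.
#' @param n_elements Optional fixed element count.
#' @param petals,roundness Element shape parameters.
#' @param seed Seed for the layout fallback.
#' @return A [trap_card()] with attributes `achieved_percent`,
#'   `element_size_cm` and `resolvable_distance_cm` (named vector over the
#'   IO-angle interval).
#' @examples
#' design_trap(5, wft_visual_system(), 7, 7, n_elements = 1)
#' @export
design_trap <- function(d_target_cm, vs, width_cm, height_cm,
                        target_percent = NULL, n_elements = NULL,
                        petals = 6L, roundness = 0.98647, seed = 1L) {
  stopifnot(inherits(vs, "visual_system"))
  size <- resolvable_size(d_target_cm, vs$design_angle_deg)
  if (is.null(n_elements)) {
    if (is.null(target_percent)) {
      n_elements <- 1L
    } else {
      n_elements <- choose_element_count(width_cm, height_cm, size,
                                         target_percent, petals, roundness)$n
    }
  }
  centers <- layout_elements(width_cm, height_cm, n_elements, size, seed)
  elements <- lapply(centers, function(ct)
    pattern_element(size, center = ct, petals = petals, roundness = roundness))
  card <- trap_card(width_cm, height_cm, elements)
  attr(card, "achieved_percent") <- percent_cover(card)
  attr(card, "element_size_cm") <- size
  attr(card, "resolvable_distance_cm") <- c(
    at_min_angle = resolvable_distance(size, vs$io_angle_min_deg),
    at_design_angle = resolvable_distance(size, vs$design_angle_deg)
  )
  card
}

#' Render a trap card as SVG
#'
#' Physical-unit SVG: one user unit is one millimetre. The card is a filled
#' background rectangle; each flower element is a closed path sampled from
#' its polar outline. Card coordinates (origin lower-left, y up) are
#' converted to the SVG top-left convention.
#'
#' @param card A [trap_card()].
#' @param path Optional file to write to.
#' @return The SVG document as a single character string (invisibly, when
#'   `path` is given).
#' @export
render_svg <- function(card, path = NULL) {
  stopifnot(inherits(card, "trap_card"))
  w_mm <- card$width_cm * 10
  h_mm <- card$height_cm * 10
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%gmm" height="%gmm" viewBox="0 0 %g %g">',
            w_mm, h_mm, w_mm, h_mm),
    sprintf('<rect x="0" y="0" width="%g" height="%g" fill="%s"/>',
            w_mm, h_mm, card$background_color)
  )
  theta <- seq(0, 2 * pi, length.out = 361)[-361]
  for (el in card$elements) {
    r <- .flower_radius(el, theta)
    x_mm <- (el$center[1] + r * cos(theta)) * 10
    y_mm <- (card$height_cm - (el$center[2] + r * sin(theta))) * 10
    pts <- paste(sprintf("%.3f,%.3f", x_mm, y_mm), collapse = " ")
    lines <- c(lines, sprintf('<path d="M %s Z" fill="%s"/>',
                              gsub(" ", " L ", pts, fixed = FALSE),
                              card$pattern_color))
  }
  lines <- c(lines, "</svg>")
  svg <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(svg, path)
    return(invisible(svg))
  }
  svg
}
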