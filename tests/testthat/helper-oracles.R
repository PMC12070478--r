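# Independent oracles used to cross-check analytic results.

# Rasterization oracle for pattern cover: scans a point grid over the whole
# card and tests each point against the rosette outline directly. Written
# independently of the package's analytic area formula.
oracle_raster_percent <- function(card, res = 0.02) {
  xs <- seq(res / 2, card$width_cm - res / 2, by = res)
  ys <- seq(res / 2, card$height_cm - res / 2, by = res)
  covered <- 0
  for (el in card$elements) {
    R2 <- el$size_cm / 2
    c0 <- el$roundness
    k <- el$petals
    xi <- xs[abs(xs - el$center[1]) <= R2]
    yi <- ys[abs(ys - el$center[2]) <= R2]
    if (!length(xi) || !length(yi)) next
    g <- expand.grid(x = xi, y = yi)
    dx <- g$x - el$center[1]
    dy <- g$y - el$center[2]
    boundary <- R2 * (c0 + (1 - c0) * cos(k * atan2(dy, dx)))
    covered <- covered + sum(sqrt(dx^2 + dy^2) <= boundary)
  }
  100 * covered * res^2 / (card$width_cm * card$height_cm)
}

# A random valid card: random dims, element size, shape and count, laid out
# with the package's spacing-constrained layout.
random_card <- function(seed) {
  set.seed(seed)
  w <- runif(1, 10, 25)
  h <- runif(1, 10, 25)
  size <- runif(1, 1.5, min(w, h) / 3)
  n <- sample(1:4, 1)
  petals <- sample(3:8, 1)
  roundness <- runif(1, 0.7, 1)
  centers <- layout_elements(w, h, n, size, seed = seed)
  els <- lapply(centers, function(ct)
    pattern_element(size, center = ct, petals = petals, roundness = roundness))
  trap_card(w, h, els)
}
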