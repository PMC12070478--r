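test_that("element area has the closed-form circle and scaling limits", {
  circle <- pattern_element(2, roundness = 1)
  expect_equal(element_area(circle), pi)
  el1 <- pattern_element(3.68)
  el2 <- pattern_element(7.36)
  expect_equal(element_area(el2), 4 * element_area(el1))
})

test_that("analytic element area agrees with the rasterization oracle", {
  el <- pattern_element(3.68, center = c(5, 5))
  card <- trap_card(10, 10, list(el))
  raster <- oracle_raster_percent(card, res = 0.01) / 100 * 100  # cm^2 on 10x10
  expect_equal(element_area(el), raster, tolerance = 0.005)
  # a deeply petalled shape too
  el2 <- pattern_element(4, center = c(5, 5), petals = 5, roundness = 0.7)
  card2 <- trap_card(10, 10, list(el2))
  expect_equal(element_area(el2), oracle_raster_percent(card2, res = 0.01),
               tolerance = 0.005)
})

test_that("percent cover has its closed-form special cases", {
  expect_equal(percent_cover(trap_card(7, 7)), 0)
  disc <- pattern_element(7, center = c(3.5, 3.5), roundness = 1)
  expect_equal(percent_cover(trap_card(7, 7, list(disc))), 100 * pi / 4)
})

test_that("percent cover matches the rasterization oracle on random cards", {
  for (seed in 1:20) {
    card <- random_card(seed)
    expect_equal(percent_cover(card), oracle_raster_percent(card, res = 0.02),
                 tolerance = 0.005)
  }
})

test_that("percent cover scales quadratically with element size at fixed count", {
  centers <- list(c(10, 8), c(10, 22))
  base <- trap_card(20, 30, lapply(centers, function(ct)
    pattern_element(3.68, center = ct)))
  bigger <- trap_card(20, 30, lapply(centers, function(ct)
    pattern_element(3.68 * 1.5, center = ct)))
  expect_equal(percent_cover(bigger), percent_cover(base) * 1.5^2)
})

test_that("element counts reproduce the 6/2/1 polytunnel progression", {
  sizes <- c(3.68, 7.37, 12.28)
  ns <- vapply(sizes, function(s)
    choose_element_count(12.5, 24.5, s, target_percent = 21)$n, 1L)
  expect_identical(ns, c(6L, 2L, 1L))
  expect_true(all(diff(ns) < 0))
})

test_that("element count is floored at one and validates inputs", {
  expect_equal(choose_element_count(12.5, 24.5, 10, 0.1)$n, 1L)
  expect_error(choose_element_count(7, 7, 8, 20), "larger than the card")
  expect_error(choose_element_count(7, 7, 2, 0), "target_percent")
  # a target chosen to land exactly on k elements returns k
  a_el <- element_area(pattern_element(2))
  target <- 100 * 3 * a_el / (12.5 * 24.5)
  expect_equal(choose_element_count(12.5, 24.5, 2, target)$n, 3L)
})

test_that("layouts center a single element and respect the gap constraint", {
  expect_equal(layout_elements(7, 7, 1, 1.23), list(c(3.5, 3.5)))
  centers <- layout_elements(12.5, 24.5, 6, 3.68)
  expect_equal(length(centers), 6)
  m <- do.call(rbind, centers)
  # exhaustive pairwise audit: edge-to-edge gap > element size
  d <- as.matrix(dist(m))
  gaps <- d[upper.tri(d)] - 3.68
  expect_true(all(gaps > 3.68))
  # all elements inside the card
  expect_true(all(m[, 1] >= 3.68 / 2 & m[, 1] <= 12.5 - 3.68 / 2))
  expect_true(all(m[, 2] >= 3.68 / 2 & m[, 2] <= 24.5 - 3.68 / 2))
})

test_that("layout is deterministic per seed and errors when packing is infeasible", {
  a <- layout_elements(20, 20, 3, 2.5, seed = 99)
  b <- layout_elements(20, 20, 3, 2.5, seed = 99)
  expect_identical(a, b)
  expect_error(layout_elements(7, 7, 2, 7), "spacing|fit")
})

test_that("designed traps match the published card compositions", {
  wft <- wft_visual_system()
  small <- design_trap(5, wft, 7, 7, n_elements = 1)
  expect_equal(length(small$elements), 1)
  expect_equal(small$elements[[1]]$size_cm, 1.23, tolerance = 0.005 / 1.23)
  expect_equal(small$elements[[1]]$center, c(3.5, 3.5))
  large <- design_trap(50, wft, 12.5, 24.5, target_percent = 28)
  expect_equal(length(large$elements), 1)
  expect_equal(large$elements[[1]]$size_cm, 12.28, tolerance = 0.005 / 12.28)
})

test_that("design at the acute end of the IO interval gives smaller elements", {
  wft <- wft_visual_system()
  acute <- visual_system(10, 14, design_angle_deg = 10)
  s14 <- attr(design_trap(15, wft, 12.5, 24.5, n_elements = 1), "element_size_cm")
  s10 <- attr(design_trap(15, acute, 12.5, 24.5, n_elements = 1), "element_size_cm")
  expect_lt(s10, s14)
})

test_that("designed elements are resolvable at the target distance", {
  wft <- wft_visual_system()
  for (d in c(5, 15, 50)) {
    card <- design_trap(d, wft, 12.5, 24.5, n_elements = 1)
    expect_true(is_resolvable(attr(card, "element_size_cm"), d,
                              wft$design_angle_deg))
    expect_equal(attr(card, "resolvable_distance_cm")[["at_design_angle"]], d)
  }
})

test_that("cards validate overlap and clipping", {
  e1 <- pattern_element(4, center = c(5, 5))
  e2 <- pattern_element(4, center = c(7, 5))  # centers 2 cm apart: overlap
  expect_error(trap_card(20, 20, list(e1, e2)), "overlap")
  off <- pattern_element(4, center = c(1, 5))  # sticks out on the left
  expect_error(trap_card(20, 20, list(off)), "clipping")
  expect_message(clipped <- trap_card(20, 20, list(off), allow_clipping = TRUE),
                 "clipped")
  # clipped cover falls back to rasterization and is below the analytic area
  pc <- percent_cover(clipped, resolution_cm = 0.02)
  expect_lt(pc, 100 * element_area(off) / 400)
  expect_equal(pc, oracle_raster_percent(clipped, res = 0.02),
               tolerance = 0.01)
})

test_that("SVG rendering has the expected drawable structure", {
  empty <- render_svg(trap_card(7, 7))
  expect_equal(lengths(regmatches(empty, gregexpr("<rect", empty))), 1)
  expect_false(grepl("<path", empty))
  one <- render_svg(design_trap(5, wft_visual_system(), 7, 7, n_elements = 1))
  expect_equal(lengths(regmatches(one, gregexpr("<rect|<path", one))), 2)
  # physical units: 7 cm card is 70 mm
  expect_match(one, 'width="70mm"')
  # writes to disk
  p <- tempfile(fileext = ".svg")
  render_svg(trap_card(7, 7), p)
  expect_true(file.exists(p))
})
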