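test_that("treatment decisions use strict thresholds", {
  expect_equal(temp_decision(35.5), "WARM")
  expect_equal(temp_decision(35.6), "NONE")
  expect_equal(temp_decision(37.9), "NONE")
  expect_equal(temp_decision(38.0), "COOL")
  expect_equal(temp_decision(c(34, 36.5, 39)), c("WARM", "NONE", "COOL"))
})

test_that("worked pair examples land in their zones", {
  z <- function(r, d) as.character(classify_zone(r, d))
  expect_equal(z(36.5, 37.4), "B")  # error > 0.5 but no decision change
  expect_equal(z(36.5, 34.0), "C")  # device triggers unnecessary warming
  expect_equal(z(38.4, 35.3), "E")  # cooling needed, warming suggested
  expect_equal(z(35.0, 36.5), "D")  # warming needed, device says normal
  expect_equal(z(36.5, 36.8), "A")  # inside tolerance
  expect_equal(z(36.5, 37.0), "A")  # boundary: |diff| = 0.5 inclusive
})

test_that("the tolerance band takes precedence over threshold straddling", {
  # rec just below the hypothermia threshold, dhf just above, |diff| <= 0.5
  expect_equal(as.character(classify_zone(35.55, 35.95)), "A")
  expect_equal(as.character(classify_zone(35.55, 35.95,
                                          a_precedence = FALSE)), "D")
})

test_that("classification is an exhaustive partition and near-symmetric", {
  g <- seq(33, 40, by = 0.05)
  pts <- expand.grid(rec = g, dhf = g)
  zone <- classify_zone(pts$rec, pts$dhf)
  expect_false(anyNA(zone))
  swapped <- classify_zone(pts$dhf, pts$rec)
  in_band <- abs(pts$dhf - pts$rec) <= 0.5
  expect_true(all(zone[in_band] == "A" & swapped[in_band] == "A"))
  map <- c(A = "A", B = "B", C = "D", D = "C", E = "E")
  expect_true(all(as.character(swapped[!in_band]) ==
                  map[as.character(zone[!in_band])]))
  # shifting both temperatures equally preserves the zone when no
  # threshold is crossed
  base <- data.frame(rec = c(36.0, 36.5, 37.0), dhf = c(36.9, 34.8, 36.1))
  expect_equal(classify_zone(base$rec, base$dhf),
               classify_zone(base$rec + 0.3, base$dhf + 0.3))
})

test_that("grid summary counts, percentages and A+B tally", {
  perfect <- data.frame(t_rec = rep(36.5, 10), t_dhf = rep(36.5, 10))
  gs <- summarize_grid(perfect)
  expect_equal(unname(gs$percentages[["A"]]), 100)
  expect_equal(sum(gs$counts), 10)

  three <- data.frame(t_rec = c(36.5, 36.5, 38.4), t_dhf = c(37.4, 34.0, 35.3))
  gs3 <- summarize_grid(three)
  expect_equal(as.integer(gs3$counts[c("B", "C", "E")]), c(1L, 1L, 1L))
  expect_equal(unname(gs3$percentages[c("B", "C", "E")]),
               rep(100 / 3, 3), tolerance = 1e-12)

  # constructed {A, A, B, D} cohort
  four <- data.frame(t_rec = c(36.5, 36.8, 36.5, 35.0),
                     t_dhf = c(36.6, 36.7, 37.4, 36.5))
  gs4 <- summarize_grid(four)
  expect_equal(as.character(gs4$zone), c("A", "A", "B", "D"))
  expect_equal(gs4$percent_no_wrong_decision, 75.0)
  expect_equal(sum(gs4$percentages), 100)
  expect_error(summarize_grid(four[0, ]))
})

test_that("geometry pieces agree with the pointwise classifier on a lattice", {
  geom <- grid_geometry(axis_range = c(33, 40))
  g <- seq(33, 40, by = 0.05)
  pts <- expand.grid(rec = g, dhf = g)
  expect_equal(geometry_classify(geom, pts$rec, pts$dhf),
               classify_zone(pts$rec, pts$dhf))
  # the A band lies entirely inside A pieces
  band <- abs(pts$dhf - pts$rec) <= 0.5
  expect_true(all(geometry_classify(geom, pts$rec[band], pts$dhf[band]) == "A"))
  # E pieces only in the two opposite-decision corner blocks
  e_pieces <- geom$pieces[geom$pieces$zone == "E", ]
  expect_true(all((e_pieces$xhi <= 35.6 & e_pieces$ylo >= 37.9) |
                  (e_pieces$xlo >= 37.9 & e_pieces$yhi <= 35.6)))
  # polygons tile the square: areas sum to the full rectangle
  areas <- vapply(split(geom$polygons, geom$polygons$piece), function(pp) {
    n <- nrow(pp); j <- c(2:n, 1)
    abs(sum(pp$x * pp$y[j] - pp$x[j] * pp$y)) / 2
  }, numeric(1))
  expect_equal(sum(areas), 49, tolerance = 1e-9)
  expect_error(grid_geometry(axis_range = c(36, 36)), "degenerate")
  expect_error(grid_geometry(axis_range = c(36, 37)), "cover")
})

test_that("error-grid plot renders with a scatter overlay", {
  geom <- grid_geometry()
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); on.exit(grDevices::dev.off(), add = TRUE)
  expect_no_error(plot(geom, pairs = data.frame(t_rec = c(36, 37),
                                                t_dhf = c(36.4, 37.8))))
})
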