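test_that("closed forms: unit square and near-circular polygon", {
  # 1 mm square traced at pitch 0.012: area 1 mm^2, perimeter 4 mm, pi/4
  side_px <- 1 / 0.012
  sq <- make_fixture("square_polygon", side_px)
  fm <- faz_metrics(faz_trace(sq, 0.012))
  expect_equal(fm$faza, 1)
  expect_equal(fm$fazp, 4)
  expect_equal(fm$fazc, pi / 4)

  circ <- regular_polygon(360, 0.3 / 0.012)
  fmc <- faz_metrics(faz_trace(circ + 100, 0.012))
  expect_gte(fmc$fazc, 0.999)
  expect_lt(abs(fmc$faza - pi * 0.3^2), 0.001)
})

test_that("circularity is scale, rotation and translation invariant", {
  set.seed(21)
  poly <- random_star_polygon(24)
  base <- faz_metrics(faz_trace(poly + 2, 0.01))
  for (k in c(0.5, 2, 17.3)) {
    fm <- faz_metrics(faz_trace(poly * k + 2 * k, 0.01))
    expect_equal(fm$fazc, base$fazc, tolerance = 1e-10)
    expect_equal(fm$faza, base$faza * k^2, tolerance = 1e-10)
    expect_equal(fm$fazp, base$fazp * k, tolerance = 1e-10)
  }
  # pitch rescaling is the same scaling
  fm <- faz_metrics(faz_trace(poly + 2, 0.02))
  expect_equal(fm$fazc, base$fazc, tolerance = 1e-10)
  # rotation and translation
  th <- 0.83
  rot <- poly %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  fm <- faz_metrics(faz_trace(rot + 5, 0.01))
  expect_equal(fm$fazc, base$fazc, tolerance = 1e-10)
  expect_equal(fm$faza, base$faza, tolerance = 1e-10)
  expect_equal(fm$fazp, base$fazp, tolerance = 1e-10)
})

test_that("doubling the perimeter at fixed area quarters the circularity", {
  # fazc is proportional to P^-2 at fixed A
  sq <- make_fixture("square_polygon", 10)
  fm <- faz_metrics(faz_trace(sq, 0.1))
  expect_equal(4 * pi * fm$faza / (2 * fm$fazp)^2, fm$fazc / 4)
})

test_that("isoperimetric bound holds over random simple polygons", {
  set.seed(99)
  worst <- 0
  for (i in 1:10000) {
    poly <- random_star_polygon(sample(5:30, 1))
    a <- octasym:::shoelace_area(poly)
    p <- octasym:::polygon_perimeter(poly)
    worst <- max(worst, 4 * pi * a / p^2)
  }
  expect_lte(worst, 1)
})

test_that("trace validation rejects degenerate polygons", {
  expect_error(faz_trace(cbind(c(0, 1), c(0, 1)), 0.01), "3 vertices")
  bowtie <- cbind(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(faz_trace(bowtie, 0.01), "self-intersecting")
  # explicit closure row is accepted and dropped
  sq <- rbind(make_fixture("square_polygon", 5), c(0, 0))
  expect_equal(nrow(faz_trace(sq, 0.01)$polygon), 4L)
})

test_that("mask input path via marching squares matches polygon values", {
  disc <- make_fixture("filled_disc", 200)
  tr <- faz_trace_from_mask(disc, 0.01)
  fm <- faz_metrics(tr)
  r_mm <- (200 / 2 - 1) * 0.01
  expect_lt(abs(fm$faza - pi * r_mm^2) / (pi * r_mm^2), 0.02)
  # the stairstep contour inflates the perimeter slightly, so the
  # circularity of a pixelated disc sits a few percent below 1
  expect_gte(fm$fazc, 0.85)
  expect_error(faz_trace_from_mask(matrix(FALSE, 10, 10), 0.01), "empty")
})

test_that("synthetic FAZ circularity decreases with irregularity", {
  fazc_at <- function(irr) {
    p <- quick_gen_params(faz_irregularity = irr, seed = 13)
    gp <- generate_angiogram_pair(p)
    faz_metrics(faz_trace(gp$truth_right$faz_polygon, p$pixel_pitch))$fazc
  }
  vals <- vapply(c(0, 0.2, 0.45, 0.7), fazc_at, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_gte(vals[1], 0.99)  # circle limit
})
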