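test_that("generator parameters are validated", {
  expect_error(image_gen_params(capillary_fraction = 0), "capillary_fraction")
  expect_error(image_gen_params(capillary_fraction = 1.2), "capillary_fraction")
  expect_error(image_gen_params(faz_mean_radius = 1.6), "faz_mean_radius")
  expect_error(image_gen_params(image_size = 100, pixel_pitch = 0.012), "6 mm")
  expect_error(image_gen_params(faz_irregularity = 1), "faz_irregularity")
  expect_error(cohort_gen_params(n_per_stage = 1), "n_per_stage")
  expect_error(cohort_gen_params(residual_sd = 0), "residual_sd")
  expect_error(cohort_gen_params(patient_sd = -1), "patient_sd")
})

test_that("planted capillary fraction is realized in the ground truth", {
  p <- quick_gen_params(capillary_fraction = 0.25, seed = 2)
  gp <- generate_angiogram_pair(p)
  expect_lt(abs(gp$truth_right$true_capillary_fraction - 0.25), 0.02)
  expect_lt(abs(gp$truth_left$true_capillary_fraction - 0.25), 0.02)
})

test_that("ground truth is internally consistent", {
  gp <- generate_angiogram_pair(quick_gen_params(seed = 6))
  tr <- gp$truth_right
  # big vessels are a subset of all vessels; capillaries are the rest
  expect_true(all(tr$vessel_mask[tr$big_vessel_mask]))
  expect_false(any(tr$capillary_mask & tr$big_vessel_mask))
  # FAZ polygon is simple and the FAZ interior is capillary-free
  expect_true(octasym:::polygon_is_simple(tr$faz_polygon))
  expect_false(any(tr$capillary_mask & tr$faz_mask))
  # noise-free: every ground-truth vessel pixel exceeds the 0.5 threshold
  b <- binarize(gp$right, 0.5)
  expect_gte(sum(b$mask & tr$vessel_mask) / sum(tr$vessel_mask), 0.95)
})

test_that("a circular FAZ request yields near-unit circularity", {
  p <- quick_gen_params(faz_irregularity = 0, seed = 4)
  gp <- generate_angiogram_pair(p)
  fm <- faz_metrics(faz_trace(gp$truth_right$faz_polygon, p$pixel_pitch))
  expect_gte(fm$fazc, 0.99)
})

test_that("images and cohorts are bit-identical under the same seed", {
  p <- quick_gen_params(noise_sd = 8, seed = 123)
  g1 <- generate_angiogram_pair(p)
  g2 <- generate_angiogram_pair(p)
  expect_identical(g1$right$pixels, g2$right$pixels)
  expect_identical(g1$left$pixels, g2$left$pixels)
  expect_identical(g1$truth_right, g2$truth_right)

  cp <- cohort_gen_params(n_per_stage = 5, seed = 77)
  expect_identical(generate_metrics_cohort(cp), generate_metrics_cohort(cp))
})

test_that("left-eye deficit lowers only the left fraction", {
  p <- quick_gen_params(capillary_fraction = 0.25,
                        left_capillary_deficit = 0.05, seed = 9)
  gp <- generate_angiogram_pair(p)
  expect_lt(abs(gp$truth_right$true_capillary_fraction - 0.25), 0.02)
  expect_lt(abs(gp$truth_left$true_capillary_fraction - 0.20), 0.02)
})

test_that("degenerate noise makes fellow eyes equal in the cohort", {
  cp <- cohort_gen_params(n_per_stage = 3, side_effect = 0,
                          interaction_effects = rep(0, 5), patient_sd = 0,
                          residual_sd = 1e-12, seed = 5)
  co <- generate_metrics_cohort(cp)
  d <- tapply(co$response, co$patient_id, function(v) abs(diff(v)))
  expect_true(all(d < 1e-9))
})

test_that("cohort empirical moments converge to the configured values", {
  cp <- cohort_gen_params(n_per_stage = 100, grand_mean = 0.218,
                          stage_effects = rep(0, 5), side_effect = 0,
                          patient_sd = 0.015, residual_sd = 0.008, seed = 42)
  co <- generate_metrics_cohort(cp)
  n <- nrow(co)
  expect_lt(abs(mean(co$response) - 0.218), 3 * 0.008 / sqrt(n) + 0.015 / sqrt(500))
  # between-patient variance: var of eye means minus residual part
  pm <- tapply(co$response, co$patient_id, mean)
  v_between <- var(pm) - 0.008^2 / 2
  expect_lt(abs(v_between - 0.015^2), 0.25 * 0.015^2)
  # covariates match the cohort description
  pat <- co[!duplicated(co$patient_id), ]
  expect_lt(abs(mean(pat$age) - 57.2), 2)
  expect_lt(abs(mean(pat$hba1c) - 7.34), 0.2)
  expect_lt(abs(mean(pat$sex == "male") - 0.66), 0.07)
})

test_that("planted side effect is recovered by the paired means", {
  cp <- cohort_gen_params(n_per_stage = 30, side_effect = -0.009, seed = 3)
  co <- generate_metrics_cohort(cp)
  w <- reshape(co[, c("patient_id", "side", "response")],
               idvar = "patient_id", timevar = "side", direction = "wide")
  expect_lt(abs(mean(w$response.right - w$response.left) - 0.009), 0.003)
})

test_that("fixtures have their closed-form pixel counts", {
  carpet <- make_fixture("sierpinski_carpet", 243)
  expect_equal(sum(carpet), 8^5)
  expect_error(make_fixture("sierpinski_carpet", 100), "power of 3")

  disc <- make_fixture("filled_disc", 300)
  r <- 300 / 2 - 1
  expect_lt(abs(sum(disc) / (pi * r^2) - 1), 0.01)

  sq <- make_fixture("square_polygon", 7)
  expect_equal(octasym:::shoelace_area(sq), 49)
  expect_equal(octasym:::polygon_perimeter(sq), 28)

  expect_equal(sum(make_fixture("line", 64)), 64L)
  expect_equal(sum(make_fixture("checkerboard", 64)), 64^2 / 2)
})
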