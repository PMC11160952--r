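test_that("threshold is mean + std_coeff * population sd with strict inequality", {
  # constant image: sd = 0, threshold equals the constant, no pixel exceeds it
  const <- matrix(100, 8, 8)
  b <- binarize(const, 0.5)
  expect_equal(b$threshold, 100)
  expect_equal(sum(b$mask), 0)

  # hand-computed 2x2 fixture: mean 1, population sd sqrt(3), one vessel px
  m <- matrix(c(0, 0, 0, 4), 2, 2)
  b <- binarize(m, 0.5)
  expect_equal(b$threshold, 1 + 0.5 * sqrt(3))
  expect_equal(sum(b$mask), 1L)
  expect_true(b$mask[2, 2])
})

test_that("vessel count is monotone non-increasing in std_coeff", {
  set.seed(42)
  for (i in 1:5) {
    img <- matrix(runif(64 * 64, 0, 255), 64, 64)
    coeffs <- c(0.25, 0.5, 0.8, 1.3, 2)
    counts <- vapply(coeffs, function(k) sum(binarize(img, k)$mask), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("thresholding is invariant to mirroring (global statistics)", {
  set.seed(7)
  img <- matrix(runif(50 * 50, 0, 255), 50, 50)
  b <- binarize(img, 0.5)
  flipped <- img[nrow(img):1, ]
  bf <- binarize(flipped, 0.5)
  expect_equal(bf$threshold, b$threshold)
  expect_identical(bf$mask, b$mask[nrow(img):1, ])
  bt <- binarize(t(img), 0.5)
  expect_identical(bt$mask, t(b$mask))
})

test_that("big-vessel dilation uses an exact Euclidean disc", {
  m <- matrix(0, 21, 21); m[11, 11] <- 255
  # dilation_radius = 0 is the identity on the raw 1.3 threshold mask
  raw <- big_vessel_mask(m, dilation_radius = 0)
  expect_identical(raw$mask, binarize(m, 1.3)$mask)
  expect_equal(raw$source, "big_vessels")
  # radius 2 around one pixel: 13 pixels within Euclidean distance 2
  d2 <- big_vessel_mask(m, dilation_radius = 2)
  expect_equal(sum(d2$mask), 13L)
  # empty mask stays empty under dilation
  empty <- matrix(10, 9, 9)  # constant: no pixel above threshold
  expect_equal(sum(big_vessel_mask(empty, dilation_radius = 3)$mask), 0L)
  expect_error(big_vessel_mask(m, dilation_radius = -1), "non-negative")
})

test_that("analysis mask removes big vessels from SCP and respects DCP flag", {
  all_v <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  big <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  scp <- analysis_mask(all_v, big, plexus = "SCP")
  expect_equal(sum(scp$capillary_mask), sum(all_v) - sum(big))
  expect_identical(scp$excluded_area_mask, big)
  expect_false(any(scp$capillary_mask & scp$excluded_area_mask))

  # empty big mask: capillaries equal all vessels
  none <- matrix(FALSE, 2, 2)
  scp0 <- analysis_mask(all_v, none, plexus = "SCP")
  expect_identical(scp0$capillary_mask, all_v)
  expect_equal(sum(scp0$excluded_area_mask), 0L)

  # DCP keeps everything unless projection exclusion is requested
  dcp <- analysis_mask(all_v, big, plexus = "DCP", exclude_projection = FALSE)
  expect_identical(dcp$capillary_mask, all_v)
  expect_equal(sum(dcp$excluded_area_mask), 0L)
  dcp2 <- analysis_mask(all_v, big, plexus = "DCP", exclude_projection = TRUE)
  expect_identical(dcp2$excluded_area_mask, big)

  expect_error(analysis_mask(all_v, matrix(FALSE, 3, 3), "SCP"), "shape")
})

test_that("binarization at 0.5 recovers synthetic ground-truth vessels", {
  gp <- generate_angiogram_pair(quick_gen_params(noise_sd = 10, seed = 5))
  b <- binarize(gp$right, 0.5)
  truth <- gp$truth_right$vessel_mask
  recovery <- sum(b$mask & truth) / sum(truth)
  false_pos <- sum(b$mask & !truth) / sum(b$mask)
  jaccard <- sum(b$mask & truth) / sum(b$mask | truth)
  expect_gte(recovery, 0.95)
  expect_lte(false_pos, 0.05)
  expect_gte(jaccard, 0.85)
})
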