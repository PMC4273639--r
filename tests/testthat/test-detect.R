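# Microcolony detection: background subtraction, equalization, ROI mask,
# segmentation, whole-field counting, manual corrections.

test_that("background subtraction removes flat and ramp backgrounds, keeps blobs", {
  flat <- matrix(0.37, 120, 100)
  expect_true(all(subtract_background(flat) == 0))

  # bright 2 um-radius disk on a linear intensity ramp
  tr <- simple_truth(transconjugants = colony(60, 50, 2))
  disk <- generate_field(tr)$field$green - 0.1 * illumination_profile(tr)
  disk <- disk[1:120, 1:100]
  ramp <- matrix(rep(seq(0, 0.2, length.out = 120), 100), 120, 100)
  out <- subtract_background(ramp + disk)
  off_disk <- disk < 1e-6
  expect_lt(max(out[off_disk]), 0.05)               # ramp residual < 5% of peak
  expect_gt(max(out), 0.8)                          # disk peak preserved within 20%
  expect_true(all(out >= 0))
  expect_true(all(subtract_background(ramp + disk - 0.5) >= 0))

  expect_error(subtract_background(flat, detection_params(background_radius_um = 3),
                                   pixel_scale_um = 2),
               "degenerate")
})

test_that("equalization stretches to the full range, preserves order, is idempotent", {
  img <- matrix(c(10, 25, 40, 90, 55, 13), 2, 3)
  eq <- equalize(img)
  expect_equal(min(eq), 0)
  expect_equal(max(eq), 1)
  expect_equal(order(c(img)), order(c(eq)))  # monotone transform

  set.seed(8)
  noisy <- matrix(runif(5000), 100, 50)
  once <- equalize(noisy)
  expect_equal(equalize(once), once, tolerance = 1e-12)
  expect_equal(order(c(noisy)), order(c(once)))

  expect_warning(out <- equalize(matrix(2, 5, 5)), "constant")
  expect_true(isTRUE(attr(out, "equalize_warning")))
  expect_equal(unclass(out)[1, 1], 2)
})

test_that("the central ellipse mask matches the analytic ellipse", {
  m <- central_ellipse_mask(c(300, 300), 1)
  expect_lt(abs(sum(m) / length(m) - pi / 4), 0.01 * pi / 4)
  # vanishing fraction: empty mask
  expect_equal(sum(central_ellipse_mask(c(100, 100), 0.004)), 0)
  # corners are never inside, whatever the fraction
  for (fr in c(0.3, 0.9, 1)) {
    mk <- central_ellipse_mask(c(80, 60), fr)
    expect_false(any(mk[c(1, 80), c(1, 60)]))
  }
  expect_error(central_ellipse_mask(c(10, 10), 0), "0, 1")
})

test_that("segmentation reports only objects above the cutoff with centroid in the ROI", {
  empty <- segment_bright_objects(matrix(0, 60, 60),
                                  central_ellipse_mask(c(60, 60), 0.9))
  expect_equal(nrow(empty), 0)

  # 5 blobs >= 6 um^2 and 3 blobs <= 2 um^2, noise-free, inside the ROI
  big <- colony(c(60, 120, 60, 120, 90), c(40, 40, 100, 100, 70),
                sqrt(c(6, 8, 10, 12, 16) / pi))
  small <- colony(c(90, 40, 140), c(40, 70, 100), sqrt(c(1, 1.5, 2) / pi))
  tr <- simple_truth(transconjugants = rbind(big, small), noise_sd = 0)
  img <- equalize(subtract_background(generate_field(tr)$field$green))
  mask <- central_ellipse_mask(dim(img), 0.9)
  obj <- segment_bright_objects(img, mask, 1, min_area_um2 = 4)
  expect_equal(nrow(obj), 5)
  expect_true(all(obj$area_um2 > 4))

  # an 8 um^2 blob whose centroid falls outside the ellipse is not reported
  tr2 <- simple_truth(transconjugants = colony(197, 80, sqrt(8 / pi)),
                      noise_sd = 0)
  img2 <- equalize(subtract_background(generate_field(tr2)$field$green))
  mask2 <- central_ellipse_mask(dim(img2), 0.9)  # ellipse edge at x = 190
  expect_equal(nrow(segment_bright_objects(img2, mask2, 1, 4)), 0)
})

test_that("count_field recovers ground-truth counts at moderate noise", {
  # all donors inside the 0.9 ROI ellipse of a 200 x 160 field
  donors <- colony(c(60, 140, 100, 70), c(50, 110, 40, 120), c(5, 7, 6, 8))
  tcs <- colony(c(70, 130, 100, 60), c(60, 100, 120, 110),
                sqrt(c(6, 9, 12, 16) / pi))
  tr <- simple_truth(transconjugants = tcs, donors = donors,
                     noise_sd = 0.05, seed = 21)
  field <- generate_field(tr)$field
  res <- count_field(field)
  expect_lte(abs(res$green_count - 4), 1)
  expect_true(all(res$objects$area_um2 > 4))

  # zero noise, no transconjugants: (donor count, 0)
  tr0 <- simple_truth(donors = donors, noise_sd = 0)
  res0 <- count_field(generate_field(tr0)$field)
  expect_equal(res0$red_count, 4)
  expect_equal(res0$green_count, 0)

  # determinism
  res2 <- count_field(field)
  expect_identical(res$objects, res2$objects)
})

test_that("counting is invariant to global linear rescaling and to illumination", {
  tcs <- colony(c(70, 130, 100), c(60, 100, 120), sqrt(c(6, 9, 14) / pi))
  tr <- simple_truth(transconjugants = tcs, noise_sd = 0.05, seed = 9)
  field <- generate_field(tr)$field
  base <- count_field(field)

  scaled <- field
  scaled$red <- field$red * 3.7
  scaled$green <- field$green * 3.7
  res_scaled <- count_field(scaled)
  expect_equal(res_scaled$green_count, base$green_count)
  expect_equal(res_scaled$red_count, base$red_count)

  # same colonies under flat illumination: identical green count
  tr_flat <- simple_truth(transconjugants = tcs, noise_sd = 0.05, seed = 9,
                          illumination = list(center = c(0.5, 0.5),
                                              semi_axes = c(10, 10),
                                              flat_fraction = 1,
                                              falloff_power = 2))
  res_flat <- count_field(generate_field(tr_flat)$field)
  expect_equal(res_flat$green_count, base$green_count)
})

test_that("raising the area cutoff never increases a count", {
  tcs <- colony(c(50, 90, 130, 70, 110), c(50, 70, 90, 110, 40),
                sqrt(c(3, 5, 8, 12, 20) / pi))
  tr <- simple_truth(transconjugants = tcs, noise_sd = 0.03, seed = 14)
  field <- generate_field(tr)$field
  cuts <- c(1, 2, 4, 8, 16)
  counts <- vapply(cuts, function(a)
    count_field(field, detection_params(min_area_um2 = a))$green_count,
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("manual corrections adjust counts with an audit trail and guard zero", {
  counts <- data.frame(field_id = c("f1", "f2", "f3"),
                       red_count = c(10, 12, 9),
                       green_count = c(2, 0, 4))
  expect_identical(apply_corrections(counts, correction_ledger()), counts)

  led <- correction_ledger("f3", "green", -1L, "merged pair split by eye")
  expect_message(out <- apply_corrections(counts, led), "1 count correction")
  expect_equal(out$green_count[3], 3)
  expect_match(attr(out, "audit_trail"), "f3 green: 4 -> 3")

  expect_error(apply_corrections(counts, correction_ledger("f3", "green", -5L)),
               "below zero")
  expect_error(apply_corrections(counts, correction_ledger("nope", "red", 1L)),
               "unknown field")
  expect_error(correction_ledger("f1", "blue", 1L), "red")
})
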