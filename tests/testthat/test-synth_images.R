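# Synthetic field-image generator: rendering, placement, experiment assembly.

test_that("a colony-free noiseless field is exactly background times illumination", {
  tr <- simple_truth(noise_sd = 0)
  out <- generate_field(tr)
  expected <- tr$background_level * illumination_profile(tr)
  expect_equal(out$field$red, expected)
  expect_equal(out$field$green, expected)
  expect_identical(out$truth, tr)  # ground truth returned unchanged
})

test_that("rendered blob area matches the analytic disk area (pixel-count oracle)", {
  # one green colony, radius 2 um, at the field centre, zero noise, 1 um/px:
  # pixels at >= half the peak must count the lattice disk of radius r,
  # which lies within the +/- half-pixel ring around pi r^2
  r <- 2
  tr <- simple_truth(transconjugants = colony(100, 80, r), noise_sd = 0)
  f <- generate_field(tr)$field
  illum <- illumination_profile(tr)
  lit <- illum > 0.5  # leave out the dark corners where nothing renders
  blob <- f$green[lit] / illum[lit] - tr$background_level
  n_above <- sum(blob >= 0.5)
  expect_gte(n_above, pi * (r - 0.5)^2)
  expect_lte(n_above, pi * (r + 0.5)^2)
  # red channel untouched by a green colony
  expect_equal(max(abs(f$red - tr$background_level * illumination_profile(tr))), 0)
})

test_that("rendering is bit-identical under a fixed seed, including the TIFF", {
  tr <- simple_truth(transconjugants = colony(50, 50, 1.5),
                     donors = colony(c(20, 120), c(30, 100), c(5, 7)),
                     noise_sd = 0.05, seed = 7)
  f1 <- generate_field(tr)$field
  f2 <- generate_field(tr)$field
  expect_identical(f1$red, f2$red)
  expect_identical(f1$green, f2$green)
  p1 <- tempfile(fileext = ".tiff"); p2 <- tempfile(fileext = ".tiff")
  write_field_tiff(f1, p1); write_field_tiff(f2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # and the round trip preserves intensities to 16-bit quantization
  back <- read_field_tiff(p1, pixel_scale_um = 1)
  expect_lt(max(abs(back$green - pmin(f1$green, 2))), 2 / 65535 + 1e-9)
})

test_that("a colony outside the field bounds is rejected with its index", {
  expect_error(
    simple_truth(transconjugants = colony(c(50, 500), c(50, 50), c(1, 1))),
    "transconjugants colony 2")
  expect_error(simple_truth(donors = colony(10, -5, 3)), "donors colony 1")
})

test_that("transconjugants are placed near donors, clipped to bounds", {
  donors <- colony(c(30, 150, 80), c(40, 120, 20), c(6, 8, 5))
  set.seed(3)
  tcs <- place_transconjugants_near_donors(5, donors, max_offset_um = 10,
                                           field_width_um = 200,
                                           field_height_um = 160)
  expect_equal(nrow(tcs), 5)
  for (k in seq_len(5)) {
    d <- sqrt((tcs$x_um[k] - donors$x_um)^2 + (tcs$y_um[k] - donors$y_um)^2)
    expect_lte(min(d), 10)
  }
  # donor at the field corner: all placements stay inside the bounds
  set.seed(4)
  tc2 <- place_transconjugants_near_donors(3, colony(0, 0, 5), 30, 200, 160)
  expect_true(all(tc2$x_um >= 0 & tc2$x_um <= 200))
  expect_true(all(tc2$y_um >= 0 & tc2$y_um <= 160))
  expect_equal(nrow(place_transconjugants_near_donors(0, donors, 10, 200, 160)), 0)
  expect_error(
    place_transconjugants_near_donors(2, empty_colonies(), 10, 200, 160),
    "empty")
})

test_that("filter experiments honour the frequency and are seed-deterministic", {
  geom <- assay_geometry()
  ex0 <- generate_filter_experiment(0, geom, seed = 5, render = FALSE)
  expect_true(all(ex0$counts$n_transconjugants == 0))
  expect_equal(sum(ex0$truth$channel == "green"), 0)
  expect_error(generate_filter_experiment(-1e-5, geom), "\\[0, 1\\]")

  ex1 <- generate_filter_experiment(1e-4, geom, seed = 12, render = FALSE)
  ex2 <- generate_filter_experiment(1e-4, geom, seed = 12, render = FALSE)
  expect_identical(ex1$counts$n_transconjugants, ex2$counts$n_transconjugants)
  expect_identical(ex1$truth, ex2$truth)
  expect_equal(sum(ex1$counts$n_transconjugants), ex1$total_true)
})

test_that("per-field counts follow the configured Poisson law (Monte Carlo)", {
  geom <- assay_geometry()
  f <- 1.16e-4
  lambda <- f * recipients_per_field(geom) * geom$n_fields
  totals <- vapply(1:200, function(s)
    generate_filter_experiment(f, geom, seed = s, render = FALSE)$total_true,
    numeric(1))
  se <- sqrt(lambda / 200)  # Poisson variance = mean
  expect_lt(abs(mean(totals) - lambda), 3 * se)
})

test_that("writing an experiment produces one TIFF per field plus truth tables", {
  geom <- small_geometry(n_fields = 2)
  im <- imaging_defaults(donor_count = 10)
  ex <- generate_filter_experiment(0.002, geom, imaging = im, seed = 2)
  outdir <- withr::local_tempdir()
  paths <- write_filter_experiment(ex, outdir)
  expect_length(paths$tiffs, 2)
  expect_true(all(file.exists(paths$tiffs)))
  truth <- read.delim(paths$truth)
  expect_setequal(names(truth), c("field_id", "channel", "x_um", "y_um",
                                  "radius_um", "area_um2", "peak"))
  ex_nr <- generate_filter_experiment(0.002, geom, imaging = im, seed = 2,
                                      render = FALSE)
  expect_error(write_filter_experiment(ex_nr, outdir), "render")
})
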