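test_that("cutoff radius calibration inverts the pixels-per-degree algebra", {
  # independent oracle: SF = (px/deg)/(px/cycle); solve for the radius that
  # reproduces the stated cutoff
  oracle_radius <- function(cutoff_cpd, n_px, angle) {
    px_per_deg <- n_px / angle
    # find r such that px_per_deg / (n_px / r) == cutoff_cpd
    cutoff_cpd * n_px / px_per_deg
  }
  cases <- data.frame(cpd = c(0.1, 0.3, 0.5, 0.8, 0.17),
                      expected = c(6, 18, 30, 48, 10.2))
  for (i in seq_len(nrow(cases))) {
    sp <- filterSpec(cases$cpd[i], 224)
    expect_equal(cutoffRadius(sp), cases$expected[i], tolerance = 1e-12)
    expect_equal(oracle_radius(cases$cpd[i], 224, 60), cases$expected[i],
                 tolerance = 1e-12)
  }
  # calibration is independent of pixel size
  expect_equal(cutoffRadius(filterSpec(0.1, 64)), 6)
})

test_that("invalid filter specifications name the offending field", {
  expect_error(filterSpec(-0.1, 224), "cutoff_cpd")
  expect_error(filterSpec(0.1, 224, order_n = 0), "order_n")
  expect_error(filterSpec(0.1, 1), "image_size_px")
  expect_error(filterSpec(0.1, 224, visual_angle_deg = 0),
               "visual_angle_deg")
})

test_that("Butterworth gain has unit DC and half-power at the cutoff", {
  expect_identical(butterworthGain(0, 6, 4), 1)
  for (n in c(1, 2, 4, 8))
    expect_equal(butterworthGain(5, 5, n), 2^(-1 / 2), tolerance = 1e-12)
  # direct scalar evaluation at D = 2r, n = 4
  expect_equal(butterworthGain(12, 6, 4), 1 / (1 + (sqrt(2) - 1) * 2^8),
               tolerance = 1e-12)
  # strictly decreasing in D
  g <- butterworthGain(seq(0, 20, by = 0.5), 6, 4)
  expect_true(all(diff(g) < 0))
  expect_error(butterworthGain(1, -1, 4), "positive")
})

test_that("mask equals brute-force gain evaluation and satisfies invariants", {
  sp <- filterSpec(2 / 60, 8, order_n = 4)  # r = 2 on an 8x8 grid
  m <- maskValues(buildMask(sp))
  expect_equal(m, bruteMask(8, 2, 4), tolerance = 1e-12)
  for (n_px in c(8, 9, 16)) {
    spec <- filterSpec(0.1, n_px)
    v <- maskValues(buildMask(spec))
    dc <- floor(n_px / 2) + 1
    expect_identical(v[dc, dc], 1)
    expect_true(all(v > 0 & v <= 1))
    # radial monotonicity along both axis-aligned rays through DC
    expect_true(all(diff(v[dc, dc:n_px]) <= 0))
    expect_true(all(diff(v[dc:n_px, dc]) <= 0))
    expect_true(all(diff(rev(v[dc, 1:dc])) <= 0))
  }
  # mask at on-axis offset r from DC is the half-power point
  sp2 <- filterSpec(2 / 60, 8)
  v2 <- maskValues(buildMask(sp2))
  expect_equal(v2[5, 5 + 2], 2^(-1 / 2), tolerance = 1e-12)
})

test_that("lowpass matches the direct-DFT oracle and preserves constants", {
  sp <- filterSpec(2 / 60, 8, order_n = 4)
  x <- rampImage(8)
  expect_equal(lowpass(x, sp, clip = FALSE), bruteLowpass(x, 2, 4),
               tolerance = 1e-8)
  y <- mixedImage(16)
  sp16 <- filterSpec(3 / 60, 16)
  expect_equal(lowpass(y, sp16, clip = FALSE), bruteLowpass(y, 3, 4),
               tolerance = 1e-8)
  expect_equal(highpass(y, sp16, clip = FALSE),
               bruteLowpass(y, 3, 4, complement = TRUE), tolerance = 1e-8)
  # constant image is a pure DC signal: identity under lowpass
  const <- matrix(0.4, 8, 8)
  expect_equal(lowpass(const, sp), const, tolerance = 1e-12)
  expect_equal(max(abs(highpass(const, sp, clip = FALSE))), 0,
               tolerance = 1e-12)
})

test_that("near-identity filtering beyond the Nyquist corner", {
  x <- mixedImage(16)
  sp <- filterSpec(1, 16)  # r = 60 >> 16*sqrt(2)/2
  expect_lt(max(abs(lowpass(x, sp, clip = FALSE) - x)), 1e-4)
})

test_that("complement identity and spectral energy contraction hold", {
  set.seed(7)
  for (n_px in c(8, 16)) {
    x <- matrix(runif(n_px^2), n_px)
    sp <- filterSpec(0.05, n_px)
    lp <- lowpass(x, sp, clip = FALSE)
    hp <- highpass(x, sp, clip = FALSE)
    expect_lt(max(abs(lp + hp - x)), 1e-8)
    expect_lte(sum(Mod(fft(lp))^2), sum(Mod(fft(x))^2))
  }
})

test_that("RGB channels are filtered independently", {
  set.seed(3)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  sp <- filterSpec(0.1, 16)
  out <- lowpass(x, sp, clip = FALSE)
  for (c in 1:3)
    expect_equal(out[, , c], lowpass(x[, , c], sp, clip = FALSE),
                 tolerance = 1e-12)
})

test_that("image validation rejects bad shapes and ranges", {
  sp <- filterSpec(0.1, 16)
  expect_error(lowpass(matrix(0.5, 16, 8), sp), "square")
  expect_error(lowpass(matrix(0.5, 8, 8), sp), "does not match")
  expect_error(lowpass(matrix(2, 16, 16), sp), "intensities")
  expect_error(lowpass(array(0.5, c(16, 16, 2)), sp), "channel")
})

test_that("distortion decreases monotonically as the cutoff rises", {
  img <- generateDataset(
    suppressWarnings(synthSpec(n_classes = 3, images_per_class = 1,
                               seed = 5)))@images[, , 1]
  bank <- sflBank()
  cutoffs <- bank$cutoff_cpd[!is.na(bank$cutoff_cpd)]
  mad <- vapply(cutoffs, function(cpd) {
    mean(abs(lowpass(img, filterSpec(cpd, 64)) - img))
  }, numeric(1))
  expect_true(all(diff(mad) < 0))
})

test_that("filterDataset writes one filtered copy per level with a manifest", {
  src <- withr::local_tempdir()
  out <- withr::local_tempdir()
  ds <- generateDataset(
    suppressWarnings(synthSpec(n_classes = 2, images_per_class = 1,
                               seed = 9)))
  for (i in 1:2)
    EBImage::writeImage(EBImage::Image(ds@images[, , i]),
                        file.path(src, sprintf("img%d.png", i)))
  man <- filterDataset(src, out, image_size = 32L)
  expect_equal(nrow(man), 2 * 5)
  expect_setequal(unique(man$level), sflBank()$label)
  expect_true(all(file.exists(man$path)))
  expect_identical(attr(man, "n_skipped"), 0L)
  # deterministic re-run: byte-identical manifest file
  h1 <- tools::md5sum(file.path(out, "manifest.csv"))
  filterDataset(src, out, image_size = 32L)
  expect_identical(unname(tools::md5sum(file.path(out, "manifest.csv"))),
                   unname(h1))
  # empty input: warning and empty manifest
  empty <- withr::local_tempdir()
  expect_warning(m0 <- filterDataset(empty, out), "empty manifest")
  expect_equal(nrow(m0), 0)
})
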