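test_that("top-percent mask keeps strictly supra-percentile pixels", {
  img <- matrix(1:100, 10, 10)          # 100 distinct intensities
  m <- top_percent_mask(img, percent = 1)
  expect_equal(sum(m), 1L)
  expect_true(m[img == 100])
  expect_false(any(top_percent_mask(matrix(7, 5, 5), 1)))   # uniform: empty
  m100 <- top_percent_mask(img, percent = 100)
  expect_equal(sum(m100), 99L)          # everything above the minimum
})

test_that("vessels are rings with a lumen, not filled blobs", {
  blank <- matrix(0, 60, 60)
  expect_length(detect_vessels(blank > 0), 0)
  d <- sqrt(outer((1:60) - 30, (1:60) - 30, function(a, b) a^2 + b^2))
  ring <- d >= 10 & d <= 13
  vs <- detect_vessels(ring)
  expect_length(vs, 1)
  expect_gte(vs[[1]]$lumen_px, 4)
  disk <- d <= 13                        # filled: no vacuole
  expect_length(detect_vessels(disk), 0)
  # an intensity channel defaults to the half-maximum threshold
  chan <- matrix(0, 60, 60); chan[ring] <- 50000
  expect_length(detect_vessels(chan), 1)
})

test_that("fully coated and uncoated vessels hit the boundaries", {
  f1 <- generate_if_field(1, 1.0, noise_sd = 0, dim = c(120, 120), seed = 3)
  vs <- detect_vessels(f1$cd31)
  res <- quantify_coating(vs, top_percent_mask(f1$aqp4, 1))
  expect_equal(res$per_vessel$coated_fraction, 1.0)
  expect_true(res$per_vessel$coated)
  f0 <- generate_if_field(1, 0.0, noise_sd = 0, dim = c(120, 120), seed = 3)
  expect_false(any(top_percent_mask(f0$aqp4, 1) |
                     f0$aqp4 > 0))        # truly no AQP4 signal
  res0 <- quantify_coating(detect_vessels(f0$cd31), f0$aqp4 > 0)
  expect_equal(res0$per_vessel$coated_fraction, 0.0)
  expect_false(res0$per_vessel$coated)
})

test_that("the quarter rule is strict at the boundary", {
  ringmask <- square_ring_mask()
  vs <- detect_vessels(ringmask, min_lumen_px = 4)
  n <- nrow(vs[[1]]$perimeter)
  expect_equal(n %% 4, 0)
  paint <- function(k) {
    idx <- aqpolar:::choose_arc(vs[[1]], k, seed_start = 3)
    m <- matrix(FALSE, nrow(ringmask), ncol(ringmask))
    m[vs[[1]]$perimeter[idx, , drop = FALSE]] <- TRUE
    m
  }
  quarter <- quantify_coating(vs, paint(n %/% 4))
  expect_equal(quarter$per_vessel$coated_fraction, 0.25)
  expect_false(quarter$per_vessel$coated)          # strict "more than"
  above <- quantify_coating(vs, paint(n %/% 4 + 3)) # ~30 percent arc
  expect_gt(above$per_vessel$coated_fraction, 0.25)
  expect_true(above$per_vessel$coated)
})

test_that("coating is monotone in the pairing radius", {
  f <- generate_if_field(3, c(0.5, 0.3, 0.1), noise_sd = 0,
                         dim = c(200, 200), seed = 9)
  vs <- detect_vessels(f$cd31)
  am <- top_percent_mask(f$aqp4, 1)
  fr <- sapply(c(1, 2, 3, 5, 8), function(rad)
    quantify_coating(vs, am, pairing_radius_px = rad)$per_vessel$coated_fraction)
  expect_true(all(apply(fr, 1, function(v) all(diff(v) >= 0))))
  expect_error(quantify_coating(vs, am, pairing_radius_px = 0), ">= 1")
})

test_that("rotating the field leaves fractions invariant", {
  f <- generate_if_field(3, c(0.6, 0.3, 0.1), noise_sd = 0,
                         dim = c(200, 200), seed = 12)
  am <- top_percent_mask(f$aqp4, 1)
  res <- quantify_coating(detect_vessels(f$cd31), am)
  rot <- function(m) t(m)[, nrow(m):1]              # 90-degree rotation
  res_r <- quantify_coating(detect_vessels(rot(f$cd31)), rot(am))
  expect_equal(sort(res_r$per_vessel$coated_fraction),
               sort(res$per_vessel$coated_fraction), tolerance = 1e-12)
  expect_equal(res_r$proportion_coated, res$proportion_coated)
})

test_that("region sampling validates size and reports per-region counts", {
  f <- generate_if_field(6, rep(c(0.5, 0.1), 3), noise_sd = 0,
                         dim = c(420, 420), seed = 15)
  vs <- detect_vessels(f$cd31)
  am <- top_percent_mask(f$aqp4, 1)
  expect_error(quantify_coating(vs, am, n_regions = 1,
                                region_size_um = 500), "smaller")
  res <- quantify_coating(vs, am, n_regions = 4, region_size_um = 100,
                          seed = 2)
  expect_equal(nrow(res$regions), 4)
  expect_true(all(res$regions$n_coated <= res$regions$n_vessels))
  def <- !is.na(res$regions$proportion)
  if (any(def))
    expect_equal(res$region_mean, mean(res$regions$proportion[def]))
})

test_that("fields round-trip through 16-bit TIFF plus JSON annotations", {
  f <- generate_if_field(2, c(0.4, 0.8), noise_sd = 0, dim = c(150, 150),
                         seed = 21)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_if_field(f, tf)
  back <- read_if_field(tf)
  expect_equal(back$cd31, f$cd31, tolerance = 1)   # 16-bit quantization
  expect_equal(back$aqp4, f$aqp4, tolerance = 1)
  expect_equal(back$annotations$requested_fraction,
               f$annotations$requested_fraction)
  expect_equal(back$um_per_px, f$um_per_px)
})

test_that("impossible vessel placements raise a generation error", {
  expect_error(generate_if_field(40, rep(0.5, 40), dim = c(100, 100),
                                 seed = 1), "could not place")
  expect_error(generate_if_field(2, c(0.5), seed = 1), "length")
  expect_error(generate_if_field(1, 1.5, seed = 1), "\\[0, 1\\]")
})
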