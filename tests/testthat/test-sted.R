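# Image pipeline: detection, sizing, active zones, classification.

test_that("detection finds isolated peaks with a strict threshold", {
  im <- single_spot_image(60, peak = 100)
  det <- detectMaxima(im, window_px = 9)
  expect_equal(nrow(det), 1)
  expect_equal(det$row, 150)  # peak pixel (0-based) at the center
  expect_equal(det$col, 150)
  # a peak of exactly the threshold is not a center
  im25 <- single_spot_image(60, peak = 25)
  expect_equal(nrow(detectMaxima(im25, window_px = 9)), 0)
  # two equal spots 200 nm apart resolved by the 9-px window
  img <- matrix(0, 201, 201)
  img <- SyxDynamics:::.render_spot(img, 10, 800, 1000, 80, 50, "gaussian")
  img <- SyxDynamics:::.render_spot(img, 10, 1000, 1000, 80, 50, "gaussian")
  expect_equal(nrow(detectMaxima(stedImage(img, 10, "syntaxin"),
                                 window_px = 9)), 2)
  expect_error(detectMaxima(single_spot_image(60, n = 21), window_px = 31),
               "larger than image")
})

test_that("detection equals the brute-force windowed scan", {
  set.seed(41)
  for (rep in 1:5) {
    # continuous intensities: ties (and thus plateau collapsing, which the
    # oracle does not model) have probability zero
    img <- matrix(rpois(40 * 40, 18) + runif(1600, 0, 0.01), 40, 40)
    got <- SyxDynamics:::.cpp_detect_maxima(img, 7L, 25)
    want <- brute_maxima(img, 7L, 25)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("FWHM sizing recovers known spot sizes and invariances", {
  im <- single_spot_image(60, profile = "gaussian")
  det <- detectMaxima(im)
  s <- fwhmSize(im, c(det$row[1], det$col[1]))
  expect_equal(s$diameter_nm, 60, tolerance = 10 / 60)
  # degenerate spot: a single bright pixel
  img <- matrix(0, 51, 51); img[26, 26] <- 100
  s1 <- fwhmSize(stedImage(img, 10, "syntaxin"), c(25, 25))
  expect_equal(s1$area_px2, 1)
  expect_equal(s1$diameter_nm, 2 * sqrt(100 / pi), tolerance = 1e-6)
  # intensity scaling leaves the area unchanged
  im2 <- stedImage(im@intensity * 2, 10, "syntaxin")
  s2 <- fwhmSize(im2, c(det$row[1], det$col[1]))
  expect_equal(s2$area_px2, s$area_px2)
  # translation invariance up to pixel quantization
  im3 <- single_spot_image(60, center_nm = 1200)
  det3 <- detectMaxima(im3)
  s3 <- fwhmSize(im3, c(det3$row[1], det3$col[1]))
  expect_equal(s3$area_px2, s$area_px2, tolerance = 0.1)
  # a center too close to the border is flagged
  imb <- single_spot_image(60, center_nm = 10)
  sb <- fwhmSize(imb, c(1, 1))
  expect_true(sb$border)
  expect_true(is.na(sb$diameter_nm))
})

test_that("BRP rings define padded active zones", {
  mkcenters <- function(cx, cy, r_nm = 115, k = 5) {
    ang <- 2 * pi * seq_len(k) / k
    data.frame(row = round((cy + r_nm * sin(ang)) / 10),
               col = round((cx + r_nm * cos(ang)) / 10),
               x_nm = cx + r_nm * cos(ang), y_nm = cy + r_nm * sin(ang),
               peak = 200)
  }
  img <- stedImage(matrix(0, 200, 200), 10, "brp")
  az <- defineActiveZones(mkcenters(1000, 1000), img)
  expect_equal(nrow(az@rings), 1)
  # 230-nm ring + 25-nm pad: mask diameter ~280 nm
  expect_equal(2 * az@rings$mask_radius_nm, 280, tolerance = 0.02)
  # an isolated spot forms no ring
  single <- data.frame(row = 50, col = 50, x_nm = 500, y_nm = 500,
                       peak = 180)
  expect_equal(nrow(defineActiveZones(single, img)@rings), 0)
  # two well-separated rings give two disjoint masks
  two <- rbind(mkcenters(500, 500), mkcenters(1500, 1500))
  az2 <- defineActiveZones(two, img)
  expect_equal(nrow(az2@rings), 2)
  expect_equal(sort(unique(as.vector(az2@zone_px))), c(0, 1, 2))
  # a collinear spot group with a poor circular fit is rejected
  loose <- data.frame(row = rep(10, 4), col = c(0, 6, 12, 18),
                      x_nm = c(0, 60, 120, 180),
                      y_nm = rep(100, 4), peak = 150)
  expect_equal(nrow(defineActiveZones(loose, img)@rings), 0)
})

test_that("classification uses closed masks and reports densities", {
  img <- stedImage(matrix(0, 200, 200), 10, "brp")
  ang <- 2 * pi * (1:5) / 5
  brp <- data.frame(row = round((1000 + 115 * sin(ang)) / 10),
                    col = round((1000 + 115 * cos(ang)) / 10),
                    x_nm = 1000 + 115 * cos(ang),
                    y_nm = 1000 + 115 * sin(ang), peak = 200)
  az <- defineActiveZones(brp, img)
  mask_r <- az@rings$mask_radius_nm[1]
  cx <- az@rings$cx_px[1] * 10; cy <- az@rings$cy_px[1] * 10
  # one detection on the mask edge (inside, closed region), one far out
  edge_col <- floor((cx + mask_r) / 10)  # pixel center still inside
  det <- data.frame(row = c(round(cy / 10), 10),
                    col = c(edge_col, 10),
                    x_nm = c(edge_col * 10, 100),
                    y_nm = c(round(cy / 10) * 10, 100),
                    peak = c(90, 80), area_px2 = c(30, 28),
                    diameter_nm = c(70, 62), border = FALSE)
  cm <- classifyAndMeasure(det, az, brp,
                           membrane_mask = matrix(TRUE, 200, 200))
  expect_true(cm$detections$at_AZ[1])
  expect_false(cm$detections$at_AZ[2])
  expect_equal(cm$summary$n_az + cm$summary$n_outside, 2)
  expect_gt(cm$summary$density_az_um2, 0)
  expect_gt(cm$summary$density_out_um2, 0)
  expect_true(all(cm$detections$dist_brp_nm >= 0))
  # missing membrane mask: outside density omitted with a warning
  expect_warning(cm2 <- classifyAndMeasure(det, az, brp), "membrane mask")
  expect_true(is.na(cm2$summary$density_out_um2))
  # empty detection table
  cm3 <- classifyAndMeasure(det[0, ], az, brp,
                            membrane_mask = matrix(TRUE, 200, 200))
  expect_equal(cm3$summary$n_az, 0)
})

test_that("group comparison calibrates its false-positive rate", {
  expect_identical(compareGroups(c(1, 2, 3), c(1, 2, 3))$stars, "ns")
  expect_warning(out <- compareGroups(rep(2, 5), rep(2, 6)), "variance")
  expect_identical(out$stars, "ns")
  # strongly separated groups reach the highest significance level
  set.seed(42)
  strong <- compareGroups(rnorm(100, 80, 15), rnorm(100, 64, 15))
  expect_identical(strong$stars, "***")
  # null calibration: ~5% rejections at alpha = 0.05
  set.seed(43)
  p <- replicate(1000, compareGroups(rnorm(50, 70, 15),
                                     rnorm(50, 70, 15))$p_value)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.5)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("TIFF round trip preserves integer intensities", {
  img <- matrix(sample(0:300, 400, replace = TRUE), 20, 20)
  im <- stedImage(img, 10, "syntaxin")
  f <- withr::local_tempfile(fileext = ".tif")
  writeStedImage(im, f)
  back <- readStedImage(f, 10, "syntaxin")
  expect_equal(back@intensity, img)
})

test_that("background subtraction clips at zero and shifts the median", {
  img <- matrix(10, 30, 30); img[15, 15] <- 100
  out <- subtractBackground(stedImage(img, 10, "syntaxin"))
  expect_equal(out@intensity[15, 15], 90)
  expect_equal(out@intensity[1, 1], 0)
})
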