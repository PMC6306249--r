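test_that("pixel-edge extraction is exact for degenerate and multi-component masks", {
  m <- matrix(0L, 10, 10)
  m[6, 6] <- 1L  # 0-based pixel (5, 5)
  ct <- extract_contour(binary_mask(m), smooth = 0)
  expect_equal(nrow(ct), 4L)
  expect_setequal(ct[, "row"], c(4.5, 5.5))
  expect_setequal(ct[, "col"], c(4.5, 5.5))
  expect_equal(abs(contour_area(ct)), 1)

  # largest-component contract: area-100 component wins over area-10
  m2 <- matrix(0L, 40, 40)
  m2[3:12, 3:12] <- 1L     # area 100
  m2[25:29, 25:26] <- 1L   # area 10
  ct2 <- extract_contour(binary_mask(m2), smooth = 0)
  expect_equal(abs(contour_area(ct2)), 100)

  expect_error(extract_contour(binary_mask(matrix(0L, 5, 5))), "foreground")
})

test_that("subpixel extraction recovers analytic disk geometry", {
  d <- disk_mask(50, H = 128, W = 128, cr = 64.5, cc = 64.5)
  ct <- extract_contour(d)
  expect_lt(abs(contour_length(ct) / (2 * pi * 50) - 1), 0.02)
  # turning-number theorem
  prof <- curvature_profile(resample_arclength(ct, 512))
  expect_lt(abs(sum(prof$turning) - 2 * pi), 1e-3)
})

test_that("arc-length resampling spaces vertices uniformly and preserves length", {
  # analytic circle: chord spacings must come out equal
  th <- seq(0, 2 * pi, length.out = 3601L)[-3601L]
  circ <- contour(cbind(64 + 50 * sin(th), 64 + 50 * cos(th)))
  for (n in c(200L, 360L)) {
    rs <- resample_arclength(circ, n)
    seg <- sqrt(rowSums((as.matrix(rs)[c(2:n, 1), ] - as.matrix(rs))^2))
    expect_lt(diff(range(seg)) / mean(seg), 1e-6)
    expect_lt(abs(contour_length(rs) / contour_length(circ) - 1), 1e-3)
    if (n == 360L)  # each chord ~ one degree of arc
      expect_lt(abs(mean(seg) - 2 * pi * 50 / 360), 0.01)
  }
  # extracted contours keep their total length through resampling
  ct <- extract_contour(disk_mask(50, H = 128, W = 128, cr = 64.5, cc = 64.5))
  expect_lt(abs(contour_length(resample_arclength(ct, 512)) /
                  contour_length(ct) - 1), 1e-3)
  expect_error(resample_arclength(ct, 2), "n")
})

test_that("square resampled to 8 vertices hits corners and edge midpoints", {
  sq <- contour(rbind(c(0, 0), c(0, 40), c(40, 40), c(40, 0)))
  rs <- as.matrix(resample_arclength(sq, 8L))
  want <- rbind(c(0, 0), c(0, 20), c(0, 40), c(20, 40), c(40, 40),
                c(40, 20), c(40, 0), c(20, 0))
  match_rows <- vapply(seq_len(8), function(i)
    min(sqrt(rowSums(sweep(want, 2, rs[i, ])^2))), numeric(1))
  expect_lt(max(match_rows), 1e-9)
})

test_that("curvature is 1/r on circles, 0 on straight edges, sums to one turn", {
  d <- disk_mask(50, H = 128, W = 128, cr = 64.5, cc = 64.5)
  prof <- curvature_profile(resample_arclength(extract_contour(d), 512))
  expect_lt(abs(mean(prof$kappa) - 1 / 50), 5e-4)
  expect_true(all(abs(prof$kappa - 1 / 50) < 0.05))
  expect_lt(abs(sum(prof$kappa * prof$ds) - 2 * pi), 1e-3)

  sq <- square_mask(70, H = 128)
  prof_sq <- curvature_profile(resample_arclength(extract_contour(sq), 512))
  expect_lt(abs(sum(prof_sq$turning) - 2 * pi), 1e-3)
  # most of the boundary is straight edge; corners carry the full turn
  expect_gt(mean(abs(prof_sq$kappa) < 0.02), 0.7)
})

test_that("degenerate duplicate vertices are removed with a warning", {
  p <- rbind(c(0, 0), c(0, 10), c(0, 10), c(10, 10), c(10, 0))
  expect_warning(prof <- curvature_profile(contour(p)), "degenerate")
  expect_equal(length(prof$kappa), 4L)
})

test_that("curvature histograms are normalized, concentrated, rotation invariant", {
  d <- disk_mask(50, H = 128, W = 128, cr = 64.5, cc = 64.5)
  prof <- curvature_profile(resample_arclength(extract_contour(d), 512),
                            sigma = 4)
  # coarse bins around 1/r: all mass in the bin containing 0.02
  h <- curvature_histogram(prof, bins = c(-0.5, -0.1, 0, 0.1, 0.5))
  expect_equal(as.numeric(h[3]), 1)
  h32 <- curvature_histogram(prof)
  expect_lt(abs(sum(h32) - 1), 1e-9)

  # square vs the same square rotated 90 degrees (exact on the grid)
  sq <- square_mask(70, H = 128)
  rot <- binary_mask(t(unclass(sq))[ncol(sq):1, ])
  hp <- function(m) curvature_histogram(
    curvature_profile(resample_arclength(extract_contour(m), 512)))
  expect_lt(local_feature_distance(hp(sq), hp(rot)), 1e-3)

  expect_warning(curvature_histogram(list(kappa = c(0, 2), ds = c(1, 1))),
                 "clipped")
  expect_error(curvature_histogram(prof, bins = c(1, 0)), "increasing")
})

test_that("soft binning is continuous where hard binning jumps", {
  # mass exactly at a bin edge: hard binning flips wholly across the edge
  # under an infinitesimal shift, soft binning moves it infinitesimally
  eps <- 1e-6
  h_lo <- curvature_histogram(list(kappa = -eps, ds = 1), soft = TRUE)
  h_hi <- curvature_histogram(list(kappa = eps, ds = 1), soft = TRUE)
  expect_lt(local_feature_distance(h_lo, h_hi), 1e-3)
})

test_that("chi-square histogram distance has metric-like properties and bound", {
  mk <- function(v) structure(v / sum(v), bins = seq(-0.5, 0.5, length.out = length(v) + 1),
                              class = "curvature_histogram")
  h1 <- mk(c(1, 2, 3, 4))
  expect_equal(local_feature_distance(h1, h1), 0)
  # disjoint support attains the upper bound of 2
  expect_equal(local_feature_distance(mk(c(1, 1, 0, 0)), mk(c(0, 0, 1, 1))), 2)
  # direct-summation oracle on random pairs
  set.seed(4)
  for (i in 1:5) {
    a <- mk(runif(8)); b <- mk(runif(8))
    s <- as.numeric(a) + as.numeric(b)
    oracle <- sum(((as.numeric(a) - as.numeric(b))^2 / s)[s > 0])
    expect_equal(local_feature_distance(a, b), oracle, tolerance = 1e-12)
    expect_equal(local_feature_distance(a, b), local_feature_distance(b, a))
  }
  expect_error(local_feature_distance(mk(c(1, 1)), mk(c(1, 1, 1))), "bin")
})

test_that("rasterization fills interiors and rejects bad inputs", {
  sq <- contour(rbind(c(9.5, 9.5), c(9.5, 30.5), c(30.5, 30.5), c(30.5, 9.5)))
  m <- rasterize(sq, 40, 40)
  expect_equal(mask_area(m), 21L * 21L)
  expect_equal(sum(unclass(m)[11:31, 11:31]), 21L * 21L)

  bowtie <- contour(rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0)))
  expect_error(rasterize(bowtie, 20, 20), "self-intersecting")
  big <- contour(rbind(c(0, 0), c(0, 50), c(50, 50), c(50, 0)))
  expect_error(rasterize(big, 20, 20), "canvas")
})

test_that("extract-rasterize round trip is stable on random blobs", {
  masks <- blob_batch(20, seed = 11)
  for (msk in masks) {
    ct <- extract_contour(msk)
    back <- rasterize(ct, nrow(msk), ncol(msk), check = FALSE)
    d <- global_shape_distance(efd(ct, 10), efd(extract_contour(back), 10))
    expect_lt(d, 1e-2)
  }
})

test_that("contours serialize to JSON and back", {
  ct <- extract_contour(disk_mask(20))
  path <- tempfile(fileext = ".json")
  write_contour_json(ct, path)
  ct2 <- read_contour_json(path)
  expect_equal(as.matrix(ct), as.matrix(ct2), tolerance = 1e-12)
})
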