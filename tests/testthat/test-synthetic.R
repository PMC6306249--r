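test_that("shape class generation is seeded and respects the amplitude budget", {
  s1 <- gen_shape_class(42, "blob")
  s2 <- gen_shape_class(42, "blob")
  expect_identical(s1[names(s1) != "jitter"], s2[names(s2) != "jitter"])
  # zero amplitudes give a circle spec
  circ <- gen_shape_class(1, "blob", amplitudes = rep(0, 7))
  expect_true(all(circ$a == 0))
  expect_error(gen_shape_class(1, "blob", amplitudes = rep(0.2, 7)), "budget")
  # sampled amplitudes respect the bound over many seeds
  sums <- vapply(1:1000, function(s) sum(abs(gen_shape_class(s, "blob")$a)),
                 numeric(1))
  expect_true(all(sums < 0.9))
})

turning_angles_of <- function(ct) {
  p <- as.matrix(ct)
  n <- nrow(p)
  e <- p[c(2:n, 1), ] - p
  e2 <- e[c(2:n, 1), ]
  atan2(e[, 1] * e2[, 2] - e[, 2] * e2[, 1], rowSums(e * e2))
}

test_that("sampled masks are simple, jittered, and circle specs give 1/r0 curvature", {
  circ <- gen_shape_class(1, "blob", amplitudes = rep(0, 7), tex_kappa = 0,
                          jitter = list(radius = 0, amplitude = 0,
                                        rotation = 0, center = 0))
  circ$aspect <- 1
  m <- sample_mask(circ, 1)
  prof <- curvature_profile(resample_arclength(extract_contour(m), 512))
  expect_lt(abs(mean(prof$kappa) - 1 / 60), 2e-3)

  spec <- gen_shape_class(7, "blob")
  m1 <- sample_mask(spec, 1); m2 <- sample_mask(spec, 2)
  expect_lt(mask_iou(m1, m2), 1)       # jitter active
  expect_identical(unclass(sample_mask(spec, 1)), unclass(m1))  # seeded

  # every sampled mask yields a clean simple contour (no repair), batch check
  specs <- lapply(1:10, function(i)
    gen_shape_class(i, if (i %% 2) "blob" else "polygon"))
  for (sp in specs) for (s in 1:10) {
    ct <- extract_contour(sample_mask(sp, s))
    expect_true(is_simple_contour(ct))
    expect_lt(abs(sum(turning_angles_of(ct)) - 2 * pi), 1e-3)
  }
  expect_error(sample_mask(spec, 1, canvas = c(60L, 60L)), "canvas")
})

test_that("procedural textures are periodic, spectral, and seeded", {
  chk <- gen_texture(texture_spec("checkerboard", period = 16), c(64L, 64L))
  expect_identical(chk[1:48, , ], chk[17:64, , ])   # exact 8-px half-period tiling
  expect_false(all(chk == chk[1, 1, 1]))

  gr <- gen_texture(texture_spec("grating", period = 16, orientation = 0), c(64L, 64L))
  row_sig <- gr[1, , 1]
  spec_pow <- Mod(fft(row_sig - mean(row_sig)))[2:32]
  expect_equal(which.max(spec_pow), 4L)  # 64/16 = 4 cycles

  d1 <- gen_texture(texture_spec("dots", seed = 3), c(64L, 64L))
  d2 <- gen_texture(texture_spec("dots", seed = 3), c(64L, 64L))
  expect_identical(d1, d2)
  d3 <- gen_texture(texture_spec("dots", seed = 4), c(64L, 64L))
  expect_false(identical(d1, d3))

  const <- gen_texture(texture_spec("grating", constant = TRUE), c(32L, 32L))
  expect_true(all(const[, , 1] == const[1, 1, 1]))
})

test_that("catalogs have the right shape, determinism and learnable structure", {
  cat_ <- build_catalog(C = 10L, E = 20L, seed = 3)
  expect_equal(length(cat_$vocabulary), 10L)
  expect_equal(nrow(cat_$manifest), 200L)
  expect_equal(sum(cat_$manifest$split == "train"), 100L)
  expect_equal(sum(cat_$manifest$split == "test"), 100L)
  # every class appears in both splits
  expect_true(all(table(cat_$manifest$class, cat_$manifest$split) == 10L))

  cat2 <- build_catalog(C = 10L, E = 20L, seed = 3)
  expect_identical(lapply(cat_$masks, lapply, unclass),
                   lapply(cat2$masks, lapply, unclass))

  expect_error(build_catalog(C = 1L, E = 5L), "C >= 2")

  # between-class mean EFD distance exceeds within-class (learnability)
  sub <- cat_$manifest[cat_$manifest$exemplar <= 4, ]
  feats <- lapply(seq_len(nrow(sub)), function(i)
    efd_features(efd(extract_contour(
      cat_$masks[[sub$class[i]]][[sub$exemplar[i]]]), 10)))
  F_ <- do.call(rbind, feats)
  D <- as.matrix(dist(F_))
  same <- outer(sub$class, sub$class, "==") & upper.tri(D)
  diff_ <- !outer(sub$class, sub$class, "==") & upper.tri(D)
  expect_gt(mean(D[diff_]), mean(D[same]))
})

test_that("catalogs round-trip to disk as PNGs plus manifest", {
  cat_ <- build_catalog(C = 2L, E = 2L, seed = 8)
  dir <- tempfile()
  write_catalog(cat_, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4L)
  m <- read_mask_png(file.path(dir, man$file[1]))
  expect_identical(unclass(m), unclass(cat_$masks[[man$class[1]]][[man$exemplar[1]]]))
})
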