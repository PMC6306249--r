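small_catalog <- function(seed = 5) build_catalog(C = 4L, E = 6L, seed = seed)

test_that("toy fitting is deterministic and reduces to single exemplars", {
  cat_ <- small_catalog()
  tr <- catalog_split(cat_, "train")
  placed <- lapply(tr$mask, place_mask, out_size = cat_$canvas)
  m1 <- fit_toy(placed, tr$class, "curvature_histogram")
  m2 <- fit_toy(placed, tr$class, "curvature_histogram")
  expect_identical(m1$centroids, m2$centroids)
  # single exemplar per class: centroid equals that exemplar's feature
  one <- fit_toy(placed[1], tr$class[1], "efd")
  f <- shapecue:::mask_features(placed[[1]])$efd
  expect_equal(unname(one$centroids[1, ]), f)
  expect_error(fit_toy(placed, tr$class, vocabulary = c(unique(tr$class), "ghost")),
               "zero exemplars")
  expect_error(fit_toy(placed, tr$class, temperature = 0), "temperature")
})

test_that("toy predictions are valid, deterministic probability vectors", {
  cat_ <- small_catalog()
  tr <- catalog_split(cat_, "train")
  te <- catalog_split(cat_, "test")
  placed <- lapply(tr$mask, place_mask, out_size = cat_$canvas)
  for (kind in c("curvature_histogram", "efd")) {
    model <- fit_toy(placed, tr$class, kind)
    p <- predict_toy(model, place_mask(te$mask[[1]], cat_$canvas))
    expect_true(validate_probs(p, names(p))$ok)
    expect_identical(p, predict_toy(model, place_mask(te$mask[[1]], cat_$canvas)))
  }
  # K = 1 vocabulary gives probability 1
  m1 <- fit_toy(placed[tr$class == tr$class[1]],
                tr$class[tr$class == tr$class[1]], "efd")
  expect_equal(unname(predict_toy(m1, te$mask[[1]])), 1)
  expect_error(predict_toy(m1, binary_mask(matrix(0L, 8, 8))), "foreground")
})

test_that("held-out exemplars are classified nearly perfectly by both channels", {
  cat_ <- build_catalog(C = 6L, E = 10L, seed = 19)
  tr <- catalog_split(cat_, "train")
  te <- catalog_split(cat_, "test")
  placed <- lapply(tr$mask, place_mask, out_size = cat_$canvas)
  for (kind in c("curvature_histogram", "efd")) {
    model <- fit_toy(placed, tr$class, kind)
    pred <- vapply(te$mask, function(m)
      names(which.max(predict_toy(model, place_mask(m, cat_$canvas)))), character(1))
    expect_gte(mean(pred == te$class), 0.9)
  }
})

test_that("image-to-mask reduction recovers the placed object from any colorway", {
  d <- disk_mask(40)
  placed <- place_mask(d, c(224L, 224L))
  for (cw in names(standard_colorways())) {
    s <- render_silhouette(d, standard_colorways(cw), c(224L, 224L))
    expect_gt(mask_iou(image_to_mask(s$pixels), placed), 0.999)
  }
  expect_error(image_to_mask(array(255L, c(10, 10, 3))), "uniform")
})

test_that("toy classifiers serialize to JSON and back without drift", {
  cat_ <- small_catalog()
  tr <- catalog_split(cat_, "train")
  placed <- lapply(tr$mask, place_mask, out_size = cat_$canvas)
  model <- fit_toy(placed, tr$class, "efd")
  path <- tempfile(fileext = ".json")
  write_toy_classifier(model, path)
  back <- read_toy_classifier(path)
  te <- catalog_split(cat_, "test")
  p1 <- predict_toy(model, place_mask(te$mask[[1]], cat_$canvas))
  p2 <- predict_toy(back, place_mask(te$mask[[1]], cat_$canvas))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the external-adapter contract is documented and enforceable", {
  contract <- external_adapter_contract()
  expect_true(all(c("input", "output", "validation") %in% names(contract)))
  # a mock adapter drives the pipeline end to end
  mock <- function(pixels) {
    v <- setNames(rep(0, 4), sprintf("%s_%02d", c("blob", "blob", "polygon", "polygon"), 1:4))
    v[1] <- 1
    v
  }
  cfg <- experiment_config("silhouette", catalog = list(C = 4L, E = 4L),
                           classifier = mock, seed = 2)
  rep <- run_experiment(cfg)
  expect_equal(nrow(rep$manifest), 8L)
  # an adapter emitting an invalid vector is rejected
  bad <- function(pixels) setNames(c(0.5, 0.4, 0, 0), names(mock(NULL)))
  cfg_bad <- experiment_config("silhouette", catalog = list(C = 4L, E = 4L),
                               classifier = bad, seed = 2)
  expect_error(run_experiment(cfg_bad), "probability contract")
  # vocabulary mismatch with the manifest is a join error
  off <- function(pixels) setNames(c(0.5, 0.5), c("foo", "bar"))
  cfg_off <- experiment_config("silhouette", catalog = list(C = 4L, E = 4L),
                               classifier = off, seed = 2)
  expect_error(run_experiment(cfg_off), "manifest-join")
})
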