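#' Probability-vector contract
#'
#' Any classifier plugged into the pipeline must return, for an input image,
#' a probability vector aligned to a fixed label vocabulary: entries
#' nonnegative and summing to 1 within 1e-6. `validate_probs` checks the
#' contract and returns diagnostics rather than throwing.
#'
#' @param probs numeric vector of class probabilities.
#' @param labels character vector of the vocabulary (optional but
#'   recommended; checked for length agreement and uniqueness).
#' @return list with `ok` (logical) and `problems` (character vector;
#'   includes the sum deficit when the total misses 1).
#' @export
validate_probs <- function(probs, labels = NULL) {
  problems <- character(0)
  if (!is.numeric(probs) || !length(probs))
    problems <- c(problems, "probs must be a nonempty numeric vector")
  if (any(probs < 0))
    problems <- c(problems, sprintf("%d negative entries", sum(probs < 0)))
  s <- sum(probs)
  if (abs(s - 1) > 1e-6)
    problems <- c(problems, sprintf("sum is %.8f (deficit %.8f)", s, 1 - s))
  if (!is.null(labels)) {
    if (length(labels) != length(probs))
      problems <- c(problems, "probs length does not match vocabulary")
    if (anyDuplicated(labels))
      problems <- c(problems, "vocabulary labels are not unique")
  }
  list(ok = length(problems) == 0L, problems = problems)
}

# Feature extraction embodies the two hypotheses' different commitments:
# local curvature statistics are pooled over the contours of *all* visible
# object pieces (a local-feature observer does not care how pieces relate),
# while the global-shape descriptor is computed from the single outline of
# the largest piece (a configural observer needs one object boundary).
#
# The local channel additionally ignores featureless contour stretches:
# maximal runs with |kappa| below one bin width lasting >= `straight_min`
# px of arc, widened by a guard band, are excluded before pooling. Genuine
# object boundary carries curvature almost everywhere, whereas the straight
# cut edges introduced by part rearrangement (and the spurious corners where
# they meet the true boundary) would otherwise masquerade as class evidence.
mask_features <- function(mask, bins = default_curvature_bins(), m = 10L,
                          min_frac = 0.01, straight_eps = 0.02,
                          straight_min = 12, guard = 12) {
  mask <- as_binary_mask(mask)
  stopifnot_nonempty(mask)
  lab <- label_components(mask)
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_frac * sum(counts))
  kap <- numeric(0); wts <- numeric(0)
  kap_all <- numeric(0); wts_all <- numeric(0)
  for (ci in keep) {
    ct_i <- extract_contour(binary_mask(lab == ci))
    n_i <- max(256L, as.integer(round(2 * contour_length(ct_i))))
    # sigma = 4 px: rasterization-phase noise lives at 2-8 px wavelengths,
    # class texture above ~20 px, so heavier smoothing buys signal-to-noise
    prof <- curvature_profile(resample_arclength(ct_i, n_i), sigma = 4)
    sel <- !straight_run_mask(prof$kappa, prof$ds, straight_eps,
                              straight_min, guard)
    kap <- c(kap, prof$kappa[sel])
    wts <- c(wts, prof$ds[sel])
    kap_all <- c(kap_all, prof$kappa)
    wts_all <- c(wts_all, prof$ds)
  }
  if (sum(wts) < 0.25 * sum(wts_all)) {
    # genuinely featureless shape: nothing to ignore
    kap <- kap_all; wts <- wts_all
  }
  ct_main <- extract_contour(binary_mask(lab == which.max(counts)))
  # the global-shape feature down-weights harmonic k by 1/sqrt(k): class
  # identity lives mostly in the coarse configuration, while fine-contour
  # perturbations (serration, micro-texture leakage) concentrate in the
  # upper harmonics
  desc <- efd(ct_main, m)
  list(curvature_histogram = as.numeric(suppressWarnings(
         curvature_histogram(list(kappa = kap, ds = wts), bins, soft = TRUE))),
       efd = as.numeric(desc$coef / sqrt(seq_len(m))))
}

# TRUE where the vertex lies in (or within `guard` px of) a maximal run of
# |kappa| < eps whose arc length reaches `run_min` px; circular
straight_run_mask <- function(kappa, ds, eps, run_min, guard) {
  n <- length(kappa)
  flat <- abs(kappa) < eps
  if (!any(flat)) return(logical(n))
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(starts, ends, val = r$values)
  # merge a circular wrap-around flat run
  wrap <- r$values[1] && r$values[length(r$values)] && length(r$values) > 1L
  out <- logical(n)
  step <- mean(ds)
  g <- max(1L, round(guard / step))
  for (i in seq_len(nrow(runs))) {
    if (!runs$val[i]) next
    s <- runs$starts[i]; e <- runs$ends[i]
    len <- sum(ds[s:e])
    if (wrap && (i == 1L || i == nrow(runs))) {
      len <- sum(ds[runs$starts[nrow(runs)]:n]) + sum(ds[1:runs$ends[1]])
    }
    if (len >= run_min) {
      idx <- ((s - g - 1L):(e + g - 1L)) %% n + 1L
      out[idx] <- TRUE
    }
  }
  out
}

#' Fit a toy nearest-centroid classifier
#'
#' Two deliberately simple classifiers embody the competing recognition
#' hypotheses: `feature_kind = "curvature_histogram"` recognises objects from
#' the distribution of local contour curvature (the local-feature
#' hypothesis), ignoring where on the object each feature sits;
#' `feature_kind = "efd"` recognises them from the first `m` normalized
#' elliptic Fourier harmonics (the global-shape hypothesis), ignoring fine
#' contour detail. Each class is represented by the mean feature vector of
#' its training exemplars; prediction is softmax over negative Euclidean
#' distances to the centroids.
#'
#' @param masks list of binary masks (training exemplars).
#' @param labels character vector of class labels, one per mask.
#' @param feature_kind `"curvature_histogram"` or `"efd"`.
#' @param temperature softmax temperature (> 0).
#' @param m EFD harmonic count (efd features).
#' @param bins curvature bin edges (curvature features).
#' @param vocabulary optional explicit label vocabulary; every vocabulary
#'   class must have at least one exemplar.
#' @return a `toy_classifier` with per-class centroids.
#' @export
fit_toy <- function(masks, labels,
                    feature_kind = c("curvature_histogram", "efd"),
                    temperature = 1, m = 10L,
                    bins = default_curvature_bins(), vocabulary = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (temperature <= 0) stop("temperature must be positive")
  stopifnot(length(masks) == length(labels))
  vocab <- vocabulary %||% unique(labels)
  counts <- table(factor(labels, vocab))
  if (any(counts == 0))
    stop("class with zero exemplars: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  feats <- t(vapply(masks, function(msk)
    mask_features(msk, bins, m)[[feature_kind]],
    numeric(if (feature_kind == "efd") 4L * m else length(bins) - 1L)))
  centroids <- do.call(rbind, lapply(vocab, function(cl) {
    fc <- feats[labels == cl, , drop = FALSE]
    if (feature_kind == "efd" && nrow(fc) > 1L) {
      # the rotation/start-point normalization of the shape descriptor has a
      # residual four-fold sign ambiguity that can flip between exemplars of
      # near-point-symmetric (elongated) shapes; align every exemplar to the
      # first before averaging
      for (r in 2:nrow(fc)) {
        vs <- efd_variants(fc[r, ], m)
        fc[r, ] <- vs[[which.min(vapply(vs, function(v)
          sum((v - fc[1, ])^2), numeric(1)))]]
      }
    }
    colMeans(fc)
  }))
  rownames(centroids) <- vocab
  structure(list(feature_kind = feature_kind, centroids = centroids,
                 temperature = temperature, m = as.integer(m), bins = bins,
                 vocabulary = vocab),
            class = "toy_classifier")
}

#' @export
print.toy_classifier <- function(x, ...) {
  cat(sprintf("<toy_classifier: %s features, %d classes, temperature %g>\n",
              x$feature_kind, nrow(x$centroids), x$temperature))
  invisible(x)
}

#' Reduce a stimulus image to a binary object mask
#'
#' The generators always place a single object on a uniform background, so
#' foreground is simply every pixel that differs from the modal border
#' color; the largest 8-connected component is kept.
#'
#' @param pixels `H x W x 3` array of 0..255 values.
#' @return a `binary_mask`.
#' @export
image_to_mask <- function(pixels) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  border <- rbind(pixels[1, , ], pixels[H, , ],
                  pixels[, 1, ], pixels[, W, ])
  key <- apply(border, 1, paste, collapse = ",")
  modal <- as.numeric(strsplit(names(which.max(table(key))), ",")[[1]])
  fg <- (pixels[, , 1] != modal[1]) | (pixels[, , 2] != modal[2]) |
    (pixels[, , 3] != modal[3])
  if (!any(fg)) stop("no foreground: image is uniform")
  largest_component(binary_mask(fg))
}

#' Predict with a toy classifier
#'
#' @param model a `toy_classifier`.
#' @param input a `binary_mask`, a `stimulus_image`, or an `H x W x 3` pixel
#'   array (reduced to a mask via [image_to_mask()]).
#' @return named probability vector over the model's vocabulary
#'   (softmax of negative centroid distances / temperature); always passes
#'   [validate_probs()]. Deterministic: repeated calls are bit-identical.
#' @export
predict_toy <- function(model, input) {
  stopifnot(inherits(model, "toy_classifier"))
  mask <- if (is_binary_mask(input)) input
  else if (inherits(input, "stimulus_image")) image_to_mask(input$pixels)
  else if (is.array(input) && length(dim(input)) == 3L) image_to_mask(input)
  else as_binary_mask(input)
  f <- mask_features(mask, model$bins, model$m)[[model$feature_kind]]
  d <- if (model$feature_kind == "curvature_histogram") {
    # straight contour stretches are uninformative filler: compare the query
    # against each centroid mixed with an arbitrary share of zero-curvature
    # mass, so cut edges introduced by part manipulations cannot masquerade
    # as class evidence (dilution-invariant nearest centroid)
    g <- zero_spike(model$bins)
    apply(model$centroids, 1, function(cen) {
      dir <- g - cen
      alpha <- min(max(sum((f - cen) * dir) / sum(dir^2), 0), 0.7)
      sqrt(sum((f - (1 - alpha) * cen - alpha * g)^2))
    })
  } else {
    # distance modulo the descriptor's four-fold normalization ambiguity
    vs <- efd_variants(f, model$m)
    apply(model$centroids, 1, function(cen)
      sqrt(min(vapply(vs, function(v) sum((v - cen)^2), numeric(1)))))
  }
  z <- -d / model$temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  names(p) <- model$vocabulary
  p
}

# the four sign variants of a flattened m x 4 EFD coefficient block under
# the residual normalization ambiguity: start-point shift by half a period
# (negates odd harmonics) and spatial rotation by pi (negates everything)
efd_variants <- function(v, m) {
  flip_odd <- rep(ifelse(seq_len(m) %% 2 == 1L, -1, 1), 4L)
  list(v, v * flip_odd, -v, -v * flip_odd)
}

# unit histogram concentrated at kappa = 0 (soft binning splits it between
# the two bins whose shared edge is zero)
zero_spike <- function(bins) {
  h <- numeric(length(bins) - 1L)
  ctr <- (bins[-1] + bins[-length(bins)]) / 2
  i <- which.min(abs(ctr))
  j <- which.min(abs(ctr) + (seq_along(ctr) == i))
  h[c(i, j)] <- 0.5
  h
}

#' Serialize / restore a toy classifier as JSON
#' @param model a `toy_classifier`.
#' @param path JSON file path.
#' @export
write_toy_classifier <- function(model, path) {
  jsonlite::write_json(list(feature_kind = model$feature_kind,
                            centroids = model$centroids,
                            vocabulary = model$vocabulary,
                            temperature = model$temperature,
                            m = model$m, bins = model$bins),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_toy_classifier
#' @export
read_toy_classifier <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- if (is.matrix(o$centroids)) o$centroids
  else matrix(unlist(o$centroids), nrow = length(o$vocabulary), byrow = TRUE)
  rownames(cent) <- o$vocabulary
  structure(list(feature_kind = o$feature_kind, centroids = cent,
                 temperature = o$temperature, m = as.integer(o$m),
                 bins = as.numeric(o$bins), vocabulary = o$vocabulary),
            class = "toy_classifier")
}

#' The external-classifier adapter contract
#'
#' Pretrained networks are delegated to, never re-implemented: an adapter is
#' any R function `f(pixels)` taking an `H x W x 3` RGB array of 0..255
#' values and returning a named probability vector over the adapter's own
#' vocabulary that passes [validate_probs()]. Adapters are looked up by
#' config key in [run_experiment()]; the core package and its tests never
#' require one.
#'
#' @return a specification record (list) documenting the callable contract:
#'   input/output types, the validation applied, and how manifest labels are
#'   joined to the adapter vocabulary.
#' @export
external_adapter_contract <- function() {
  list(input = "H x W x 3 numeric array, RGB, 0..255",
       output = "named numeric probability vector over the adapter's vocabulary",
       validation = "validate_probs(): entries >= 0, sum within 1e-6 of 1",
       vocabulary_join = paste("manifest shape/texture labels must be present",
                               "in the adapter vocabulary or the run fails",
                               "with a manifest-join error"),
       registration = "pass as `classifier = function(pixels) ...` or via adapters list in run_experiment")
}
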