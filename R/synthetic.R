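#' Seeded synthetic shape classes
#'
#' Shape classes emulate the two superordinate stimulus groups of
#' silhouette-recognition experiments: smooth "animal-like" blobs whose
#' radius is a low-order radial Fourier series,
#' `r(theta) = r0 * (1 + sum_k a_k * cos(k * theta + phi_k))`, k = 2..8, and
#' straight-edged "artifact-like" irregular polygons. The amplitude budget
#' `sum |a_k| < 0.9` keeps `r(theta) > 0`, so every sampled outline is a
#' simple closed curve. Harmonics stop at k = 8 so that serration (high
#' frequency) and part-scrambling (configural) act on scales clearly
#' separated from the class-defining geometry.
#'
#' @param seed integer seed for the class-level draw.
#' @param kind `"blob"` or `"polygon"`.
#' @param r0 base radius in pixels.
#' @param amplitudes optional fixed `a_k` for k = 2..8 (blobs); drawn
#'   randomly when `NULL`.
#' @param n_vertices polygon template vertex count (polygons); drawn in 4..10
#'   when `NULL`.
#' @param tex_kappa,tex_lambda contour micro-texture peak curvature
#'   (radians/pixel) and nominal wavelength (px); drawn randomly when
#'   `NULL`. The ripple amplitude is derived per exemplar from the actual
#'   outline perimeter so that the peak curvature -- the quantity a local
#'   curvature histogram resolves -- is the class invariant.
#'   [build_catalog()] spreads these evenly over its classes so local
#'   contour character separates classes by construction.
#' @param wiggle_total,wiggle_tilt blob configural wiggliness: total radial
#'   amplitude `sum |a_k|` and the spectral tilt exponent; drawn randomly
#'   when `NULL`.
#' @param a2_frac share of the wiggliness budget on the k = 2 harmonic;
#'   drawn randomly when `NULL`.
#' @param corner_sigma polygon corner-rounding sigma in pixels; drawn
#'   randomly when `NULL`.
#' @param aspect class elongation (major/minor axis ratio); drawn randomly
#'   when `NULL`.
#' @param jitter list of exemplar jitter magnitudes: `radius` (relative sd),
#'   `amplitude` (relative sd on each `a_k`), `rotation` (max |angle| in
#'   radians), `center` (max offset in pixels).
#' @return a `shape_class_spec`.
#' @export
gen_shape_class <- function(seed, kind = c("blob", "polygon"), r0 = 60,
                            amplitudes = NULL, n_vertices = NULL,
                            tex_kappa = NULL, tex_lambda = NULL,
                            wiggle_total = NULL, wiggle_tilt = NULL,
                            a2_frac = NULL,
                            corner_sigma = NULL, aspect = NULL,
                            jitter = list(radius = 0.02, amplitude = 0.03,
                                          rotation = pi / 18, center = 4)) {
  kind <- match.arg(kind)
  spec <- with_seed(seed, {
    if (kind == "blob") {
      k <- 2:8
      a <- if (is.null(amplitudes)) {
        # class identity lives both in the configuration (which harmonics,
        # which phases) and in the local contour character: total
        # wiggliness and its spectral tilt vary between classes
        tilt <- wiggle_tilt %||% stats::runif(1, -1.5, 1.5)
        total <- wiggle_total %||% stats::runif(1, 0.15, 0.45)
        f2 <- a2_frac %||% stats::runif(1, 0.2, 0.6)
        raw <- stats::runif(length(k) - 1L, 0.05, 1) * (k[-1] / 5)^tilt
        # the k = 2 share of the wiggliness budget is a class parameter:
        # it dominates the coarse configuration the shape descriptor sees
        c(f2 * total, raw * ((1 - f2) * total / max(sum(raw), 1e-9)))
      } else amplitudes
      if (sum(abs(a)) >= 0.9) stop("amplitude budget violated: sum |a_k| >= 0.9")
      list(kind = kind, r0 = r0, k = k, a = a,
           phi = stats::runif(length(k), 0, 2 * pi),
           tex_kappa = tex_kappa %||% stats::runif(1, 0.1, 0.55),
           tex_lambda = tex_lambda %||% stats::runif(1, 16, 36),
           tex_phase = stats::runif(1, 0, 2 * pi),
           aspect = aspect %||% stats::runif(1, 1.15, 1.5),
           axis = stats::runif(1, 0, pi))
    } else {
      nv <- if (is.null(n_vertices)) sample(4:10, 1) else n_vertices
      # irregular but strictly increasing vertex angles spanning one turn:
      # built from positive gaps so the star polygon can never self-cross
      gaps <- stats::runif(nv, 0.4, 1)
      ang <- 2 * pi * (cumsum(gaps) - gaps) / sum(gaps)
      list(kind = kind, r0 = r0, angles = ang,
           radii = stats::runif(nv, 0.5, 1) * r0,
           # class-fixed corner rounding: sharp vs rounded corners is a
           # local contour feature
           corner_sigma = corner_sigma %||% stats::runif(1, 2, 6),
           tex_kappa = tex_kappa %||% stats::runif(1, 0.1, 0.55),
           tex_lambda = tex_lambda %||% stats::runif(1, 16, 36),
           tex_phase = stats::runif(1, 0, 2 * pi),
           aspect = aspect %||% stats::runif(1, 1, 1.3),
           axis = stats::runif(1, 0, pi))
    }
  })
  spec$seed <- as.integer(seed)
  spec$jitter <- jitter
  if (spec$kind == "polygon") {
    # the texture ripple displaces the contour along its normal by up to
    # its amplitude; concave corners whose radius is below that depth would
    # pinch off loops, so furrier classes get correspondingly rounder
    # corners (amplitude estimated at the nominal 1.35x placement scale)
    amp_nom <- 1.35 * spec$tex_kappa * (spec$tex_lambda / (2 * pi))^2
    spec$corner_sigma <- max(spec$corner_sigma, 1.15 * amp_nom)
  }
  # Shape repairs are decided once per class on the jitter-free reference
  # outline and then applied identically to every exemplar: a per-exemplar
  # repair would itself become within-class variation. Heavy corner
  # rounding of small concave polygons can pinch off a tiny
  # self-intersection loop, which even-odd rasterization includes or drops
  # depending on subpixel phase; so can an over-deep texture ripple.
  if (spec$kind == "polygon") {
    while (spec$corner_sigma >= 0.5 &&
           !is_simple_contour(contour(base_outline(spec, r0, 0, c(0, 0)))))
      spec$corner_sigma <- spec$corner_sigma / 1.5
  }
  ref <- base_outline(spec, scale = r0, rot = 0, ctr = c(0, 0))
  L_ref <- sum(sqrt(rowSums((ref[c(2:nrow(ref), 1), ] - ref)^2)))
  # whole-cycle texture count is class-level too, so exemplar perimeter
  # jitter cannot flip it and change the ripple's harmonic content
  spec$tex_ncyc <- max(12L, as.integer(round(L_ref / spec$tex_lambda)))
  spec$tex_scale <- 1
  if (spec$tex_kappa > 0) {
    while (spec$tex_scale > 0.1 &&
           !is_simple_contour(contour(apply_texture(spec, ref, 224, 224))))
      spec$tex_scale <- spec$tex_scale / 1.5
  }
  structure(spec, class = "shape_class_spec")
}

# jitter-free construction of a class outline at the given scale/pose
# (texture not applied); `a` / `radii` override the class parameters with
# exemplar-jittered values
base_outline <- function(spec, scale, rot, ctr, a = NULL, radii = NULL) {
  off <- if (spec$kind == "blob") {
    a <- a %||% spec$a
    theta <- seq(0, 2 * pi, length.out = 721L)[-721L]
    r <- scale * (1 + as.numeric(cos(outer(theta, spec$k, "*") +
                                       rep(spec$phi, each = length(theta))) %*% a))
    cbind(r * sin(theta), r * cos(theta))
  } else {
    radii <- (radii %||% spec$radii) / spec$r0 * scale
    cbind(radii * sin(spec$angles), radii * cos(spec$angles))
  }
  # class-fixed elongation along the class axis, then the requested rotation
  off <- cbind(off[, 1] * sqrt(spec$aspect), off[, 2] / sqrt(spec$aspect))
  al <- spec$axis + rot
  off <- cbind(off[, 1] * cos(al) - off[, 2] * sin(al),
               off[, 1] * sin(al) + off[, 2] * cos(al))
  pts <- cbind(ctr[1] + off[, 1], ctr[2] + off[, 2])
  if (spec$kind == "polygon" && spec$corner_sigma > 0) {
    pts <- resample_closed(pts, 720L)
    L <- sum(sqrt(rowSums((pts[c(2:720, 1), ] - pts)^2)))
    pts <- smooth_closed_xy(pts, sigma_idx = spec$corner_sigma * 720 / L)
  }
  pts
}

# Class-specific contour micro-texture: a fine sinusoidal ripple along the
# outward normal, parameterized by arc length with a whole-cycle count kept
# >= 12 so it sits above the 10 configural EFD harmonics -- the silhouette
# analogue of a surface texture such as curly fur. tex_kappa is pinned at
# *presentation* scale: renderers place objects at 80% of the shorter canvas
# side, and curvature scales inversely with that magnification, which
# differs between shapes (bounding-box vs perimeter geometry); compensating
# here keeps the class grid exact. Phase and cycle count are class-level:
# how the texture aligns with the configural outline is part of an object's
# identity, not exemplar noise.
apply_texture <- function(spec, pts, H, W) {
  ctr <- colMeans(pts)
  pts <- resample_closed(pts, 720L)
  seg <- sqrt(rowSums((pts[c(2:720, 1), ] - pts)^2))
  L <- sum(seg)
  s <- cumsum(seg) - seg
  n_cyc <- spec$tex_ncyc
  bbox <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  s_place <- 0.8 * min(H, W) / bbox
  amp <- (spec$tex_scale %||% 1) * spec$tex_kappa * s_place *
    (L / (2 * pi * n_cyc))^2
  tang <- pts[c(2:720, 1), ] - pts[c(720, 1:719), ]
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(tang[, 2], -tang[, 1])
  # star-shaped base: orient normals outward via the radial direction
  rel <- sweep(pts, 2, ctr)
  flip <- sign(rowSums(nrm * rel))
  flip[flip == 0] <- 1
  pts + amp * sin(2 * pi * n_cyc * s / L + spec$tex_phase) * flip * nrm
}

#' @export
print.shape_class_spec <- function(x, ...) {
  cat(sprintf("<shape_class_spec: %s, r0 = %g, seed = %d>\n", x$kind, x$r0, x$seed))
  invisible(x)
}

#' Sample one exemplar mask from a shape class
#'
#' Applies seeded exemplar jitter (radius scale, radial-amplitude or vertex
#' perturbation, rotation, center offset), evaluates the outline, and
#' rasterizes it on the canvas.
#'
#' @param spec a `shape_class_spec`.
#' @param seed exemplar seed.
#' @param canvas `(height, width)` in pixels.
#' @return a `binary_mask`.
#' @export
sample_mask <- function(spec, seed, canvas = c(224L, 224L)) {
  stopifnot(inherits(spec, "shape_class_spec"))
  H <- canvas[1]; W <- canvas[2]
  jit <- spec$jitter
  p <- with_seed(seed, {
    scale <- spec$r0 * exp(stats::rnorm(1, 0, jit$radius))
    rot <- stats::runif(1, -jit$rotation, jit$rotation)
    ctr <- c(H, W) / 2 - 0.5 + stats::runif(2, -jit$center, jit$center)
    a <- radii <- NULL
    if (spec$kind == "blob") {
      a <- spec$a * (1 + stats::rnorm(length(spec$a), 0, jit$amplitude))
      if (sum(abs(a)) >= 0.9) a <- a * 0.89 / sum(abs(a))
    } else {
      radii <- spec$radii * (1 + stats::rnorm(length(spec$radii), 0, jit$amplitude / 3))
    }
    pts <- base_outline(spec, scale, rot, ctr, a = a, radii = radii)
    if (spec$tex_kappa > 0) pts <- apply_texture(spec, pts, H, W)
    pts
  })
  if (any(p[, 1] < 0 | p[, 1] > H - 1 | p[, 2] < 0 | p[, 2] > W - 1))
    stop("canvas too small for this shape class")
  rasterize(contour(p), H, W, check = FALSE)
}

#' Procedural textures
#'
#' Deterministic texture rasters standing in for natural object surfaces in
#' cue-conflict (chimera) stimuli: oriented sinusoidal gratings,
#' checkerboards, or random dots.
#'
#' @param kind `"grating"`, `"checkerboard"`, or `"dots"`.
#' @param period spatial period in pixels (grating wavelength, checker cell
#'   size * 2, or mean dot spacing).
#' @param colors list of two RGB triples in 0..255 (`fg`, `bg`).
#' @param orientation grating orientation in radians.
#' @param density dot density (dots per pixel^2, `"dots"` only).
#' @param radius dot radius in pixels.
#' @param seed RNG seed (`"dots"` only).
#' @param constant if `TRUE` returns a constant `bg`-colored raster.
#' @return a `texture_spec`.
#' @export
texture_spec <- function(kind = c("grating", "checkerboard", "dots"),
                         period = 16, colors = list(fg = c(30, 30, 30),
                                                    bg = c(220, 220, 220)),
                         orientation = pi / 4, density = 0.01, radius = 2,
                         seed = 1L, constant = FALSE) {
  structure(list(kind = match.arg(kind), period = period, colors = colors,
                 orientation = orientation, density = density, radius = radius,
                 seed = as.integer(seed), constant = constant),
            class = "texture_spec")
}

#' @rdname texture_spec
#' @param spec a `texture_spec`.
#' @param size `(height, width)` of the output raster.
#' @return `gen_texture` returns an `height x width x 3` array of 0..255
#'   integers.
#' @export
gen_texture <- function(spec, size = c(224L, 224L)) {
  stopifnot(inherits(spec, "texture_spec"))
  H <- size[1]; W <- size[2]
  fg <- spec$colors$fg; bg <- spec$colors$bg
  rr <- matrix(0:(H - 1), H, W)
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE)
  wmap <- if (spec$constant) {
    matrix(0, H, W)
  } else if (spec$kind == "grating") {
    u <- rr * sin(spec$orientation) + cc * cos(spec$orientation)
    (1 + sin(2 * pi * u / spec$period)) / 2
  } else if (spec$kind == "checkerboard") {
    half <- spec$period / 2
    (floor(rr / half) + floor(cc / half)) %% 2
  } else {
    n_dots <- max(1L, round(spec$density * H * W))
    pts <- with_seed(spec$seed,
                     cbind(stats::runif(n_dots, 0, H - 1), stats::runif(n_dots, 0, W - 1)))
    w <- matrix(0, H, W)
    for (i in seq_len(n_dots)) {
      r0 <- max(1, ceiling(pts[i, 1] - spec$radius + 1))
      r1 <- min(H, floor(pts[i, 1] + spec$radius + 1))
      c0 <- max(1, ceiling(pts[i, 2] - spec$radius + 1))
      c1 <- min(W, floor(pts[i, 2] + spec$radius + 1))
      if (r1 < r0 || c1 < c0) next
      sub_r <- r0:r1; sub_c <- c0:c1
      d2 <- outer((sub_r - 1 - pts[i, 1])^2, (sub_c - 1 - pts[i, 2])^2, "+")
      w[sub_r, sub_c][d2 <= spec$radius^2] <- 1
    }
    w
  }
  px <- array(0L, c(H, W, 3))
  for (ch in 1:3)
    px[, , ch] <- as.integer(round(bg[ch] + (fg[ch] - bg[ch]) * wmap))
  px
}

#' Build a seeded shape catalog
#'
#' Generates `C` shape classes (a `blob_fraction` of smooth blobs, the rest
#' polygons), samples `E` exemplar masks per class, and splits them into
#' disjoint train/test halves. Everything derives from the single top-level
#' seed; per-class and per-exemplar sub-seeds are recorded in the manifest.
#' The default emulation of a 40-category silhouette study is `C = 40`,
#' `E = 20`, `blob_fraction = 0.5` on a 224 x 224 canvas.
#'
#' @param C number of classes (>= 2).
#' @param E exemplars per class (>= 2).
#' @param seed top-level integer seed.
#' @param blob_fraction fraction of classes drawn as blobs.
#' @param canvas `(height, width)` canvas.
#' @param r0 base radius passed to the class generator.
#' @param jitter exemplar jitter magnitudes, see [gen_shape_class()].
#' @return a `catalog`: list with `vocabulary`, `classes` (specs), `masks`
#'   (named list per class of mask lists), `manifest` (data.frame with class,
#'   exemplar, split, sub-seeds), `seed`, `canvas`.
#' @export
build_catalog <- function(C = 40L, E = 20L, seed = 1L, blob_fraction = 0.5,
                          canvas = c(224L, 224L), r0 = 60,
                          jitter = list(radius = 0.02, amplitude = 0.03,
                                        rotation = pi / 18, center = 4)) {
  if (C < 2 || E < 2) stop("need C >= 2 classes and E >= 2 exemplars")
  C <- as.integer(C); E <- as.integer(E)
  n_blob <- round(C * blob_fraction)
  kinds <- c(rep("blob", n_blob), rep("polygon", C - n_blob))
  vocabulary <- sprintf("%s_%02d", kinds, seq_len(C))
  class_seeds <- derive_seed(seed, seq_len(C))
  # spread contour micro-texture parameters evenly over the classes (with a
  # seeded shuffle) so local contour character separates classes by
  # construction, the way surface texture separates real object categories
  tex <- with_seed(derive_seed(seed, 0L), {
    # Texture peak curvature is spread geometrically: what the curvature
    # histogram discriminates is the relative (Weber-like) difference, so
    # equal ratios spread classes evenly in discriminability. The
    # wavelength band is kept narrow because contour smoothing attenuates
    # short wavelengths more, and a wide band would let the attenuation
    # gradient cancel the curvature spread. Configural parameters (blob
    # wiggliness and tilt, polygon vertex count and corner rounding) are
    # likewise spread over their ranges so the global-shape channel
    # separates classes by construction; all assignments are shuffled.
    ord <- sample(C)
    n_blob_ <- sum(kinds == "blob")
    n_poly_ <- C - n_blob_
    spread <- function(lo, hi, n) {
      if (n == 0L) return(NULL)
      v <- seq(lo, hi, length.out = max(n, 2L))[seq_len(n)]
      if (n > 1L) sample(v) else v
    }
    list(kappa = exp(seq(log(0.12), log(0.45), length.out = C))[ord],
         lambda = seq(32, 24, length.out = C)[ord],
         wiggle = spread(0.18, 0.42, n_blob_),
         tilt = spread(-1.2, 1.2, n_blob_),
         nv = if (n_poly_) {
           v <- rep(4:10, length.out = n_poly_)
           if (n_poly_ > 1L) sample(v) else v
         },
         csig = spread(2, 6, n_poly_),
         # every class is clearly elongated: a near-circular first ellipse
         # makes the rotation normalization of the shape descriptor
         # ill-conditioned
         asp_b = spread(1.15, 1.5, n_blob_),
         asp_p = spread(1.18, 1.48, n_poly_),
         a2f = spread(0.2, 0.6, n_blob_))
  })
  blob_idx <- cumsum(kinds == "blob")
  poly_idx <- cumsum(kinds == "polygon")
  classes <- lapply(seq_len(C), function(i) {
    if (kinds[i] == "blob")
      gen_shape_class(class_seeds[i], kind = "blob", r0 = r0,
                      tex_kappa = tex$kappa[i], tex_lambda = tex$lambda[i],
                      wiggle_total = tex$wiggle[blob_idx[i]],
                      wiggle_tilt = tex$tilt[blob_idx[i]],
                      a2_frac = tex$a2f[blob_idx[i]],
                      aspect = tex$asp_b[blob_idx[i]], jitter = jitter)
    else
      gen_shape_class(class_seeds[i], kind = "polygon", r0 = r0,
                      tex_kappa = tex$kappa[i], tex_lambda = tex$lambda[i],
                      n_vertices = tex$nv[poly_idx[i]],
                      corner_sigma = tex$csig[poly_idx[i]],
                      aspect = tex$asp_p[poly_idx[i]], jitter = jitter)
  })
  names(classes) <- vocabulary
  manifest <- do.call(rbind, lapply(seq_len(C), function(i) {
    ex_seeds <- derive_seed(class_seeds[i], seq_len(E) + 100L)
    split <- rep(c("train", "test"), length.out = E)
    data.frame(class = vocabulary[i], kind = kinds[i], exemplar = seq_len(E),
               split = split, class_seed = class_seeds[i],
               exemplar_seed = ex_seeds, stringsAsFactors = FALSE)
  }))
  masks <- lapply(seq_len(C), function(i) {
    rows <- manifest[manifest$class == vocabulary[i], ]
    lapply(seq_len(E), function(j) sample_mask(classes[[i]], rows$exemplar_seed[j], canvas))
  })
  names(masks) <- vocabulary
  structure(list(vocabulary = vocabulary, classes = classes, masks = masks,
                 manifest = manifest, seed = as.integer(seed), canvas = canvas),
            class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf("<catalog: %d classes x %d exemplars, canvas %dx%d, seed %d>\n",
              length(x$vocabulary), nrow(x$manifest) / length(x$vocabulary),
              x$canvas[1], x$canvas[2], x$seed))
  invisible(x)
}

#' Subset a catalog by split
#' @param catalog a `catalog`.
#' @param split `"train"` or `"test"`.
#' @return data.frame with columns `class`, `exemplar` plus a `mask` list
#'   column.
#' @export
catalog_split <- function(catalog, split = c("train", "test")) {
  split <- match.arg(split)
  man <- catalog$manifest[catalog$manifest$split == split, ]
  man$mask <- lapply(seq_len(nrow(man)), function(i)
    catalog$masks[[man$class[i]]][[man$exemplar[i]]])
  man
}

#' Write a catalog to disk (PNG masks + manifest CSV + seed record)
#' @param catalog a `catalog`.
#' @param dir output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- catalog$manifest
  man$file <- sprintf("%s_e%02d.png", man$class, man$exemplar)
  for (i in seq_len(nrow(man)))
    write_mask_png(catalog$masks[[man$class[i]]][[man$exemplar[i]]],
                   file.path(dir, man$file[i]))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = catalog$seed, canvas = catalog$canvas,
                            vocabulary = catalog$vocabulary),
                       file.path(dir, "catalog.json"), auto_unbox = TRUE)
  invisible(dir)
}
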