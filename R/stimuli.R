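#' Colorways and stimulus provenance
#'
#' A colorway is a foreground/background RGB pair (e.g. the classic black
#' figure on white, white on black, or red on white sweeps used to test
#' whether silhouette classification survives contrast-polarity changes).
#'
#' @param fg,bg RGB triples in 0..255; must differ.
#' @export
colorway <- function(fg = c(0, 0, 0), bg = c(255, 255, 255)) {
  fg <- as.integer(fg); bg <- as.integer(bg)
  stopifnot(length(fg) == 3L, length(bg) == 3L)
  if (all(fg == bg)) stop("colorway foreground and background must differ")
  structure(list(fg = fg, bg = bg), class = "colorway")
}

#' @rdname colorway
#' @param name one of `"black_on_white"`, `"white_on_black"`, `"red_on_white"`.
#' @export
standard_colorways <- function(name = NULL) {
  all <- list(black_on_white = colorway(c(0, 0, 0), c(255, 255, 255)),
              white_on_black = colorway(c(255, 255, 255), c(0, 0, 0)),
              red_on_white = colorway(c(255, 0, 0), c(255, 255, 255)))
  if (is.null(name)) all else all[[match.arg(name, names(all))]]
}

#' Provenance record for one generated stimulus
#'
#' Captures everything needed to regenerate a stimulus: shape (and, for
#' chimeras, texture) category labels, the manipulation applied, colorway,
#' manipulation parameters, and the RNG seed for stochastic manipulations.
#'
#' @param shape_label category name of the shape.
#' @param manipulation one of `"silhouette"`, `"outline"`, `"chimera"`,
#'   `"part_scramble"`, `"serrate"`.
#' @param texture_label category name of the overlaid texture; required for
#'   (and only for) chimeras.
#' @param colorway a [colorway()] or `NULL`.
#' @param params named list of manipulation parameters.
#' @param seed RNG seed; required for (and only for) stochastic
#'   manipulations (`part_scramble`).
#' @param item_id optional stable item identifier.
#' @export
stimulus_record <- function(shape_label,
                            manipulation = c("silhouette", "outline", "chimera",
                                             "part_scramble", "serrate"),
                            texture_label = NULL, colorway = NULL,
                            params = list(), seed = NULL, item_id = NULL) {
  manipulation <- match.arg(manipulation)
  if (manipulation == "chimera" && is.null(texture_label))
    stop("chimera stimuli need a texture_label")
  if (manipulation != "chimera" && !is.null(texture_label))
    stop("texture_label only applies to chimera stimuli")
  if (manipulation == "part_scramble" && is.null(seed))
    stop("stochastic manipulations need a seed")
  structure(list(shape_label = shape_label, texture_label = texture_label,
                 manipulation = manipulation, colorway = colorway,
                 params = params, seed = seed,
                 item_id = item_id %||% shape_label),
            class = "stimulus_record")
}

#' @export
print.stimulus_record <- function(x, ...) {
  cat(sprintf("<stimulus: shape %s%s, %s>\n", x$shape_label,
              if (!is.null(x$texture_label)) paste0(" | texture ", x$texture_label) else "",
              x$manipulation))
  invisible(x)
}

stimulus_image <- function(pixels, record) {
  structure(list(pixels = pixels, record = record), class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stimulus_image %dx%d>\n", d[1], d[2])); print(x$record)
  invisible(x)
}

#' Write a stimulus as PNG plus a provenance JSON sidecar
#' @param stim a `stimulus_image`.
#' @param path PNG path; the sidecar gets extension `.json`.
#' @export
write_stimulus_png <- function(stim, path) {
  png::writePNG(stim$pixels / 255, path)
  rec <- stim$record
  rec$colorway <- if (!is.null(rec$colorway)) unclass(rec$colorway)
  jsonlite::write_json(unclass(rec), sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Canonical placement of a mask on a canvas
#'
#' Centers the mask and scales it isotropically so its larger bounding-box
#' side spans `fill` of the shorter canvas side (nearest-neighbour sampling
#' keeps the result binary). All renderers use this placement; manipulations
#' meant to preserve local curvature should be applied after it.
#'
#' @param mask a binary mask.
#' @param out_size `(height, width)` canvas.
#' @param fill fraction of the shorter canvas side to occupy.
#' @return a placed `binary_mask` of size `out_size`.
#' @export
place_mask <- function(mask, out_size, fill = 0.8) {
  mask <- as_binary_mask(mask)
  stopifnot_nonempty(mask)
  H <- out_size[1]; W <- out_size[2]
  if (mask_area(mask) == 1L) {
    # degenerate single-pixel object: nearest-neighbour placement
    idx <- which(unclass(mask) == 1L, arr.ind = TRUE)
    out <- matrix(0L, H, W)
    out[round((H + 1) / 2), round((W + 1) / 2)] <- 1L
    return(binary_mask(out))
  }
  # transform the subpixel bounding contour and re-rasterize: avoids the
  # aliasing that nearest-neighbour scaling of the raster would introduce
  ct <- extract_contour(mask)
  p <- as.matrix(ct)
  r_rng <- range(p[, 1]); c_rng <- range(p[, 2])
  scale <- fill * min(H, W) / max(diff(r_rng), diff(c_rng))
  ctr_in <- c(mean(r_rng), mean(c_rng))
  ctr_out <- c(H - 1, W - 1) / 2
  q <- sweep(sweep(p, 2, ctr_in), 2, c(scale, scale), "*")
  q <- sweep(q, 2, ctr_out, "+")
  q[, 1] <- pmin(pmax(q[, 1], -0.49), H - 0.51)
  q[, 2] <- pmin(pmax(q[, 2], -0.49), W - 0.51)
  largest_component(rasterize(contour(q), H, W, check = FALSE))
}

paint <- function(H, W, fg_mask, fg, bg) {
  px <- array(0L, c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], H, W)
    plane[fg_mask] <- fg[ch]
    px[, , ch] <- as.integer(plane)
  }
  px
}

#' Render a silhouette stimulus
#'
#' The mask, centered and isotropically scaled to occupy 80% of the shorter
#' canvas side, painted in the colorway's foreground color on its uniform
#' background. Shape is conveyed only by the bounding contour.
#'
#' @param mask a binary mask.
#' @param colorway a [colorway()].
#' @param out_size `(height, width)` canvas.
#' @param record optional pre-built [stimulus_record()]; one is synthesized
#'   otherwise.
#' @param shape_label label stored in the synthesized record.
#' @param place center-and-scale the mask onto the canvas; set `FALSE` for
#'   masks already at presentation scale (e.g. scrambled arrangements of an
#'   already-placed figure, where re-scaling would distort local curvature).
#' @return a `stimulus_image`.
#' @export
render_silhouette <- function(mask, colorway = standard_colorways("black_on_white"),
                              out_size = c(224L, 224L), record = NULL,
                              shape_label = "unknown", place = TRUE) {
  placed <- if (place) place_mask(mask, out_size) else {
    mask <- as_binary_mask(mask)
    stopifnot(identical(dim(mask), as.integer(out_size)))
    stopifnot_nonempty(mask)
    mask
  }
  px <- paint(out_size[1], out_size[2], unclass(placed) == 1L,
              colorway$fg, colorway$bg)
  rec <- record %||% stimulus_record(shape_label, "silhouette", colorway = colorway)
  stimulus_image(px, rec)
}

#' Render an outline stimulus
#'
#' Black stroke of width `stroke_px` centered on the bounding contour;
#' interior and exterior are the identical uniform white, so the only
#' contrast in the image lies on the object contour.
#'
#' @inheritParams render_silhouette
#' @param stroke_px stroke width in pixels (>= 1).
#' @export
render_outline <- function(mask, stroke_px = 2L, out_size = c(224L, 224L),
                           record = NULL, shape_label = "unknown") {
  if (stroke_px < 1) stop("stroke_px must be >= 1")
  placed <- largest_component(place_mask(mask, out_size))
  d_in <- mask_distance(placed)
  d_out <- mask_distance(binary_mask(1L - unclass(placed)))
  band <- (unclass(placed) == 1L & d_in <= ceiling(stroke_px / 2)) |
    (unclass(placed) == 0L & d_out <= floor(stroke_px / 2))
  if (!any(unclass(placed) == 1L & !band))
    stop("stroke so wide the interior vanishes")
  px <- paint(out_size[1], out_size[2], band, c(0L, 0L, 0L), c(255L, 255L, 255L))
  rec <- record %||% stimulus_record(shape_label, "outline",
                                     params = list(stroke_px = stroke_px))
  stimulus_image(px, rec)
}

#' Render a texture-chimera (cue-conflict) stimulus
#'
#' The silhouette geometry of one category filled with the surface texture
#' of another: inside the placed mask the pixels come from the texture
#' raster (tiled if smaller than the mask bounding box, center-cropped if
#' larger), outside they are uniform white. Shape and texture labels then
#' conflict, which is what makes the stimulus diagnostic.
#'
#' @inheritParams render_silhouette
#' @param texture `h x w x 3` array of 0..255 RGB values.
#' @param texture_label label of the texture's category.
#' @export
render_texture_chimera <- function(mask, texture, out_size = c(224L, 224L),
                                   record = NULL, shape_label = "unknown",
                                   texture_label = "unknown_texture") {
  if (is.null(dim(texture)) || length(dim(texture)) != 3L)
    stop("texture must be an h x w x 3 array")
  placed <- place_mask(mask, out_size)
  H <- out_size[1]; W <- out_size[2]
  idx <- which(unclass(placed) == 1L, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  bh <- r1 - r0 + 1L; bw <- c1 - c0 + 1L
  th <- dim(texture)[1]; tw <- dim(texture)[2]
  # tile up to bbox size, then center-crop to exactly the bbox
  reps_r <- ceiling(bh / th); reps_c <- ceiling(bw / tw)
  tiled_idx_r <- rep(seq_len(th), reps_r)
  tiled_idx_c <- rep(seq_len(tw), reps_c)
  off_r <- floor((length(tiled_idx_r) - bh) / 2)
  off_c <- floor((length(tiled_idx_c) - bw) / 2)
  sel_r <- tiled_idx_r[off_r + seq_len(bh)]
  sel_c <- tiled_idx_c[off_c + seq_len(bw)]
  px <- array(255L, c(H, W, 3))
  inside <- unclass(placed) == 1L
  for (ch in 1:3) {
    tex_bbox <- texture[sel_r, sel_c, ch, drop = TRUE]
    plane <- matrix(255L, H, W)
    sub <- plane[r0:r1, c0:c1]
    sub[inside[r0:r1, c0:c1]] <- as.integer(tex_bbox[inside[r0:r1, c0:c1]])
    plane[r0:r1, c0:c1] <- sub
    px[, , ch] <- plane
  }
  rec <- record %||% stimulus_record(shape_label, "chimera",
                                     texture_label = texture_label)
  stimulus_image(px, rec)
}
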