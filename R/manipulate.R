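#' Manipulation reports
#'
#' Quantifies what a contour manipulation did: `global_distance` is the
#' rotation-normalized elliptic-Fourier distance between the original and
#' manipulated outlines (configural change), `local_distance` the symmetric
#' chi-square distance between their arc-length-weighted curvature histograms
#' (local-edge change), and `area_ratio` the foreground-area ratio
#' new/original. Part-scrambling should score high globally and low locally;
#' serration the reverse.
#'
#' @name manipulation_report
NULL

#' @export
print.manipulation_report <- function(x, ...) {
  cat(sprintf("<manipulation_report: global %.4f, local %.4f, area ratio %.3f>\n",
              x$global_distance, x$local_distance, x$area_ratio))
  invisible(x)
}

new_report <- function(global_distance, local_distance, area_ratio) {
  structure(list(global_distance = global_distance,
                 local_distance = local_distance,
                 area_ratio = area_ratio),
            class = "manipulation_report")
}

# curvature histogram of a full contour at fine, fixed sampling
full_histogram <- function(ct, bins) {
  n <- max(512L, as.integer(round(2 * contour_length(ct))))
  suppressWarnings(curvature_histogram(
    curvature_profile(resample_arclength(ct, n)), bins))
}

#' Part-scramble a silhouette
#'
#' Cuts the figure into `n_parts` pieces along straight chords (seeded), then
#' rigidly rearranges the pieces (translations plus rotations in 90-degree
#' steps, which are exact on the pixel grid; mirroring optional and off by
#' default) into a non-overlapping, non-touching arrangement on the same
#' canvas. This destroys the global configuration while preserving local
#' contour curvature everywhere except along the cut chords, which are
#' therefore excluded from the local-feature histogram in the report.
#'
#' @param mask a binary mask (single object).
#' @param n_parts number of pieces, 1..8 (1 is the degenerate rigid-motion
#'   control).
#' @param seed integer seed; the operation is bit-deterministic given
#'   (mask, parameters, seed).
#' @param mirror allow mirror flips of pieces.
#' @param report also compute a [manipulation_report] (slower).
#' @param m,bins report parameters: EFD harmonics and curvature bins.
#' @param max_restarts placement restarts before giving up.
#' @return list with `mask` (scrambled `binary_mask`) and `report`
#'   (`manipulation_report` or `NULL`).
#' @export
part_scramble <- function(mask, n_parts = 4L, seed = 1L, mirror = FALSE,
                          report = TRUE, m = 10L,
                          bins = default_curvature_bins(),
                          max_restarts = 10L) {
  mask <- largest_component(mask)
  if (n_parts < 1 || n_parts > 8) stop("n_parts must be in 1..8")
  H <- nrow(mask); W <- ncol(mask)
  res <- with_seed(seed, {
    out <- NULL
    for (attempt in seq_len(max_restarts)) {
      # placement failures are usually an unlucky cut (one huge or very
      # elongated piece); redraw the chords and try again
      pieces <- split_into_parts(mask, n_parts)
      out <- tryCatch(place_pieces(pieces, H, W, mirror, max_restarts = 5L),
                      error = function(e) NULL)
      if (!is.null(out)) break
    }
    if (is.null(out))
      stop("piece placement failed after retries; use a larger canvas")
    out
  })
  out <- binary_mask(res$canvas)
  rep_obj <- NULL
  if (report) {
    ct0 <- extract_contour(mask)
    d0 <- efd(ct0, m)
    ct1 <- extract_contour(out)
    h0 <- full_histogram(ct0, bins)
    h1 <- pooled_piece_histogram(res$pieces, ct0, bins)
    rep_obj <- new_report(global_shape_distance(d0, efd(ct1, m)),
                          local_feature_distance(h0, h1),
                          mask_area(out) / mask_area(mask))
  }
  list(mask = out, report = rep_obj)
}

# cut the foreground pixel set into n parts along straight random chords;
# repeatedly splits the largest current piece through a jittered centroid
split_into_parts <- function(mask, n_parts) {
  idx <- which(unclass(mask) == 1L, arr.ind = TRUE)
  pieces <- list(idx)
  while (length(pieces) < n_parts) {
    sizes <- vapply(pieces, nrow, integer(1))
    target <- which.max(sizes)
    p <- pieces[[target]]
    done <- FALSE
    for (try in 1:40) {
      phi <- stats::runif(1, 0, pi)
      span <- max(diff(range(p[, 1])), diff(range(p[, 2])))
      anchor <- colMeans(p) + stats::runif(2, -0.15, 0.15) * span
      s <- (p[, 1] - anchor[1]) * cos(phi) + (p[, 2] - anchor[2]) * sin(phi)
      left <- s < 0
      if (mean(left) >= 0.2 && mean(left) <= 0.8) {
        pieces[[target]] <- p[left, , drop = FALSE]
        pieces[[length(pieces) + 1L]] <- p[!left, , drop = FALSE]
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not find an admissible cut chord")
  }
  pieces
}

rot90_coords <- function(rc, k) {
  # 0-based coordinate rotation by k * 90 degrees: (r, c) -> (c, -r)
  for (i in seq_len(k %% 4L)) rc <- cbind(rc[, 2], -rc[, 1])
  rc
}

# top-left positions whose ph x pw window of `occ` is empty (via a
# summed-area table); conservative (bounding-box) feasibility
free_windows <- function(occ, ph, pw) {
  H <- nrow(occ); W <- ncol(occ)
  if (ph > H || pw > W) return(NULL)
  S <- rbind(0, cbind(0, apply(apply(occ * 1L, 2, cumsum), 1, cumsum)))
  S <- t(S)  # restore orientation: S[i+1, j+1] = sum occ[1:i, 1:j]
  ii <- seq_len(H - ph + 1); jj <- seq_len(W - pw + 1)
  win <- S[ii + ph, jj + pw, drop = FALSE] - S[ii, jj + pw, drop = FALSE] -
    S[ii + ph, jj, drop = FALSE] + S[ii, jj, drop = FALSE]
  which(win == 0, arr.ind = TRUE)
}

place_pieces <- function(pieces, H, W, mirror, max_restarts) {
  ord <- order(vapply(pieces, nrow, integer(1)), decreasing = TRUE)
  for (restart in seq_len(max_restarts)) {
    occ <- matrix(FALSE, H, W)        # dilated occupancy (enforces a 1-px gap)
    canvas <- matrix(0L, H, W)
    placed <- vector("list", length(pieces))
    ok_all <- TRUE
    for (pi_ in ord) {
      p0 <- pieces[[pi_]] - 1  # 0-based
      placed_ok <- FALSE
      for (try in 1:8) {
        k <- sample(0:3, 1)
        flip <- mirror && stats::runif(1) < 0.5
        q <- p0
        if (flip) q <- cbind(q[, 1], -q[, 2])
        q <- rot90_coords(q, k)
        mn <- c(min(q[, 1]), min(q[, 2]))
        q <- q - rep(mn, each = nrow(q))         # bbox at origin
        ph <- max(q[, 1]) + 1; pw <- max(q[, 2]) + 1
        # prefer positions whose whole bounding box is free, then fall back
        # to pixel-exact random probes (interlocking placements)
        cand <- free_windows(occ, ph, pw)
        tls <- if (!is.null(cand) && nrow(cand))
          cand[sample.int(nrow(cand), min(20L, nrow(cand))), , drop = FALSE] - 1L
        else if (ph <= H && pw <= W)
          cbind(sample.int(H - ph + 1, 60, replace = TRUE),
                sample.int(W - pw + 1, 60, replace = TRUE)) - 1L
        else NULL
        if (is.null(tls)) next
        for (t_ in seq_len(nrow(tls))) {
          cells <- q + rep(tls[t_, ], each = nrow(q)) + 1L  # 1-based indices
          if (any(occ[cells])) next
          canvas[cells] <- 1L
          for (dr in -1:1) for (dc in -1:1) {
            rr <- pmin(pmax(cells[, 1] + dr, 1L), H)
            cc <- pmin(pmax(cells[, 2] + dc, 1L), W)
            occ[cbind(rr, cc)] <- TRUE
          }
          placed[[pi_]] <- list(cells = cells, k = k, flip = flip,
                                shift = tls[t_, ] - mn)
          placed_ok <- TRUE
          break
        }
        if (placed_ok) break
      }
      if (!placed_ok) { ok_all <- FALSE; break }
    }
    if (ok_all) return(list(canvas = canvas, pieces = placed))
  }
  stop("piece placement failed after retries; use a larger canvas")
}

# pooled curvature histogram over placed pieces, excluding vertices whose
# back-transformed position does not lie on the original bounding contour
# (i.e. the cut chords), with a 3-vertex guard band around exclusions
pooled_piece_histogram <- function(placed, ct0, bins, tol = 2.0) {
  ref <- as.matrix(resample_arclength(ct0, max(512L, round(2 * contour_length(ct0)))))
  kap <- numeric(0); wts <- numeric(0)
  for (pc in placed) {
    pm <- matrix(0L, max(pc$cells[, 1]) + 1L, max(pc$cells[, 2]) + 1L)
    pm[pc$cells] <- 1L
    ct <- extract_contour(binary_mask(pm))
    n <- max(128L, as.integer(round(4 * contour_length(ct))))
    rp <- resample_arclength(ct, n)
    prof <- curvature_profile(rp)
    v <- as.matrix(rp) - rep(pc$shift, each = n)          # undo translation
    v <- rot90_coords(v, (4L - pc$k %% 4L) %% 4L)          # undo rotation
    if (pc$flip) v <- cbind(v[, 1], -v[, 2])
    d2 <- outer(rowSums(v^2), rep(1, nrow(ref))) +
      matrix(rowSums(ref^2), nrow(v), nrow(ref), byrow = TRUE) -
      2 * v %*% t(ref)
    keep <- sqrt(pmax(apply(d2, 1, min), 0)) <= tol
    keep <- erode_runs(keep, 3L)
    kap <- c(kap, prof$kappa[keep])
    wts <- c(wts, prof$ds[keep])
  }
  if (!length(kap)) stop("no original-boundary vertices survive exclusion")
  suppressWarnings(curvature_histogram(list(kappa = kap, ds = wts), bins))
}

erode_runs <- function(keep, w) {
  n <- length(keep)
  out <- keep
  for (off in c(-(seq_len(w)), seq_len(w)))
    out <- out & keep[((seq_len(n) - 1 + off) %% n) + 1]
  out
}

#' Serrate a silhouette's bounding contour
#'
#' Displaces a uniformly resampled bounding contour along its outward normal
#' by a triangular ("sawtooth") wave in arc length, then re-rasterizes. The
#' wave period is snapped to divide the perimeter a whole number of times so
#' the serration closes on itself. Self-intersections introduced by the wave
#' are repaired by even-odd rasterization followed by largest-component
#' extraction. Serration destroys local contour curvature while leaving the
#' low-order global configuration essentially untouched; the triangular wave
#' adds and removes approximately equal area.
#'
#' @param mask a binary mask.
#' @param amplitude_px wave amplitude in pixels; default 3% of the contour
#'   bounding-box diagonal. Must be below half the shape's minimal feature
#'   width (distance-transform estimate). 0 is allowed as identity control.
#' @param period_px wave arc-length period in pixels (>= 4); default 5% of
#'   the perimeter.
#' @param report,m,bins as in [part_scramble()].
#' @return list with `mask`, `report`, and `params` (resolved amplitude and
#'   period).
#' @export
serrate <- function(mask, amplitude_px = NULL, period_px = NULL,
                    report = TRUE, m = 10L, bins = default_curvature_bins()) {
  mask <- largest_component(mask)
  H <- nrow(mask); W <- ncol(mask)
  ct <- extract_contour(mask)
  p0 <- as.matrix(ct)
  diag_px <- sqrt(diff(range(p0[, 1]))^2 + diff(range(p0[, 2]))^2)
  L <- contour_length(ct)
  A <- amplitude_px %||% (0.03 * diag_px)
  P <- period_px %||% (0.05 * L)
  if (P < 4) stop("period_px must be >= 4")
  if (A < 0) stop("amplitude_px must be nonnegative")
  if (A > 0) {
    mfw <- min_feature_width(mask)
    if (A >= mfw / 2)
      stop(sprintf("amplitude %.2f px exceeds half the minimal feature width (%.2f px)",
                   A, mfw / 2))
  }
  n <- max(512L, as.integer(round(2 * L)))
  rp <- as.matrix(resample_arclength(ct, n))
  s <- (seq_len(n) - 1) * L / n
  P <- L / max(1, round(L / P))          # integer number of periods
  tri <- 2 * abs(2 * (s / P - floor(s / P + 0.5))) - 1
  tang <- rp[c(2:n, 1), ] - rp[c(n, 1:(n - 1)), ]
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(tang[, 2], -tang[, 1])
  probe <- seq(1, n, length.out = 32)
  frac_out <- mean(!points_in_contour(rp[probe, ] + 2 * nrm[probe, ], ct))
  if (frac_out < 0.5) nrm <- -nrm
  p1 <- rp + A * tri * nrm
  p1[, 1] <- pmin(pmax(p1[, 1], -0.49), H - 0.51)
  p1[, 2] <- pmin(pmax(p1[, 2], -0.49), W - 0.51)
  out <- largest_component(rasterize(contour(p1), H, W, check = FALSE))
  rep_obj <- NULL
  if (report) {
    d0 <- efd(ct, m)
    ct1 <- extract_contour(out)
    rep_obj <- new_report(global_shape_distance(d0, efd(ct1, m)),
                          local_feature_distance(full_histogram(ct, bins),
                                                 full_histogram(ct1, bins)),
                          mask_area(out) / mask_area(mask))
  }
  list(mask = out, report = rep_obj, params = list(amplitude_px = A, period_px = P))
}
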