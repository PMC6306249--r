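#' Binary silhouette masks
#'
#' A binary mask is an integer matrix of 0/1 values in which 1 marks object
#' foreground. Rows increase downward; pixel `[i, j]` (1-based matrix index)
#' sits at coordinate `(i - 1, j - 1)` in the 0-based `(row, col)` frame used
#' by all contour operations.
#'
#' @param grid numeric or logical matrix; nonzero/`TRUE` entries become
#'   foreground.
#' @return an integer 0/1 matrix of class `binary_mask`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' mask_area(m)
#' @export
binary_mask <- function(grid) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  m <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  class(m) <- c("binary_mask", class(m))
  m
}

#' @rdname binary_mask
#' @param x object to test or coerce.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @rdname binary_mask
#' @export
as_binary_mask <- function(x) if (is_binary_mask(x)) x else binary_mask(x)

#' @rdname binary_mask
#' @export
mask_area <- function(x) sum(unclass(as_binary_mask(x)))

stopifnot_nonempty <- function(mask) {
  if (mask_area(mask) == 0L) stop("no foreground: mask has no foreground pixels")
}

#' Connected-component labeling (8-connected)
#'
#' Labels foreground components under 8-connectivity. EBImage's `bwlabel`
#' is 4-connected; labels touching diagonally are merged by union-find.
#'
#' @param mask a binary mask.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  mask <- as_binary_mask(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  roots <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- roots[lab[lab > 0L]]
  lab
}

#' Largest 8-connected foreground component
#'
#' @param mask a binary mask with at least one foreground pixel.
#' @return a `binary_mask` retaining only the component of greatest pixel area
#'   (ties broken by lowest label, i.e. scan order).
#' @export
largest_component <- function(mask) {
  mask <- as_binary_mask(mask)
  stopifnot_nonempty(mask)
  lab <- label_components(mask)
  if (max(lab) == 1L) return(mask)
  counts <- tabulate(lab[lab > 0L])
  binary_mask(lab == which.max(counts))
}

#' Intersection-over-union of two masks
#'
#' @param a,b binary masks of identical dimensions.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  a <- unclass(as_binary_mask(a)) == 1L
  b <- unclass(as_binary_mask(b)) == 1L
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Distance to background for every foreground pixel
#'
#' Thin wrapper over `EBImage::distmap`; boundary foreground pixels get 1.
#' @param mask a binary mask.
#' @return numeric matrix of distances (0 on background).
#' @keywords internal
mask_distance <- function(mask) {
  mask <- as_binary_mask(mask)
  d <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Minimal feature width of a shape
#'
#' Estimated from the distance transform: medial points are taken as 2-D
#' local maxima of the distance map whose radius is at least a quarter of the
#' largest inscribed radius (sub-part-scale bumps are treated as contour
#' texture, not parts), and the width is twice the smallest such radius.
#' Used to bound admissible serration amplitudes.
#'
#' @param mask a binary mask.
#' @return width estimate in pixels.
#' @export
min_feature_width <- function(mask) {
  mask <- as_binary_mask(mask)
  stopifnot_nonempty(mask)
  d <- mask_distance(mask)
  H <- nrow(d); W <- ncol(d)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- d
  nb_max <- pmax(pad[1:H, 1:W], pad[1:H, 2:(W + 1)], pad[1:H, 3:(W + 2)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)],
                 pad[3:(H + 2), 1:W], pad[3:(H + 2), 2:(W + 1)],
                 pad[3:(H + 2), 3:(W + 2)])
  medial <- d >= nb_max & d >= 0.25 * max(d) & d > 0
  2 * min(d[medial])
}

#' Read / write masks as single-channel PNG
#'
#' Foreground is stored as 255, background as 0; any nonzero grey level on
#' read becomes foreground.
#'
#' @param path PNG file path.
#' @param mask a binary mask (for writing).
#' @return `read_mask_png` returns a `binary_mask`; `write_mask_png` returns
#'   `path` invisibly.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  binary_mask(a > 0.5)
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
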