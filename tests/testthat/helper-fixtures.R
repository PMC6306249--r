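# fixture builders shared across test files

disk_mask <- function(r, H = 2 * r + 28, W = H, cr = (H + 1) / 2, cc = (W + 1) / 2) {
  rr <- matrix(seq_len(H), H, W)
  cc_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  binary_mask((rr - cr)^2 + (cc_ - cc)^2 <= r^2)
}

square_mask <- function(side, H = side + 28, W = H) {
  m <- matrix(0L, H, W)
  r0 <- floor((H - side) / 2) + 1L
  m[r0:(r0 + side - 1L), r0:(r0 + side - 1L)] <- 1L
  binary_mask(m)
}

# seeded batch of smooth synthetic blobs (no contour micro-texture, so the
# local damage of serration is not masked by pre-existing texture), used by
# the geometry round-trip and manipulation-dissociation checks
blob_batch <- function(n, seed = 1, canvas = c(224L, 224L)) {
  lapply(seq_len(n), function(i) {
    spec <- gen_shape_class(seed + i, "blob", tex_kappa = 0)
    sample_mask(spec, seed + 1000L + i, canvas)
  })
}

# uniform random probability vector
runif_probs <- function(K) {
  p <- stats::runif(K)
  p / sum(p)
}
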