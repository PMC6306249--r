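#' Elliptic Fourier shape descriptors
#'
#' Expands a closed contour into elliptic Fourier harmonics (the
#' Kuhl-Giardina coefficients `a_k, b_k, c_k, d_k`), the standard
#' operationalization of global shape for closed outlines: low-order
#' harmonics capture the configuration of an object's parts as a whole and
#' are insensitive to fine contour detail.
#'
#' Translation is always removed and the coefficients scaled so the first
#' harmonic has unit Frobenius magnitude. With `normalize_rotation = TRUE`
#' the starting point and spatial orientation are also normalized (first
#' ellipse phase and major-axis rotation), with the residual two-fold
#' ambiguities resolved by a deterministic canonical choice among the four
#' candidates, so descriptors of rotated/re-started copies of a contour
#' coincide.
#'
#' @param contour a `contour` (closed, simple).
#' @param m number of harmonics, `1 <= m <= n/2` for an n-vertex contour.
#' @param normalize_rotation also normalize rotation and starting point.
#' @return an object of class `shape_descriptor`: list with `coef`
#'   (m x 4 matrix, columns a, b, c, d), `m`, and `normalization` flags.
#' @export
efd <- function(contour, m = 10L, normalize_rotation = TRUE) {
  p <- as_contour_matrix(contour)
  n <- nrow(p)
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("`m` must be a positive integer")
  m <- as.integer(m)
  if (m > n / 2) stop("`m` exceeds n/2 for this contour")
  e <- edge_vectors(p)
  dt <- sqrt(rowSums(e^2))
  keep <- dt > 1e-12
  e <- e[keep, , drop = FALSE]; dt <- dt[keep]
  t2 <- cumsum(dt)
  t1 <- c(0, t2[-length(t2)])
  TT <- t2[length(t2)]
  k <- seq_len(m)
  w <- 2 * pi * outer(k, t2, "*") / TT   # m x P
  w0 <- 2 * pi * outer(k, t1, "*") / TT
  dcos <- cos(w) - cos(w0)
  dsin <- sin(w) - sin(w0)
  fac <- TT / (2 * pi^2 * k^2)
  vx <- e[, 1] / dt; vy <- e[, 2] / dt
  a <- fac * as.numeric(dcos %*% vx)
  b <- fac * as.numeric(dsin %*% vx)
  cc <- fac * as.numeric(dcos %*% vy)
  d <- fac * as.numeric(dsin %*% vy)
  coef <- cbind(a = a, b = b, c = cc, d = d)
  coef <- normalize_efd(coef, normalize_rotation)
  structure(list(coef = coef, m = m,
                 normalization = list(translation = TRUE, scale = TRUE,
                                      rotation = normalize_rotation)),
            class = "shape_descriptor")
}

rotate_start <- function(coef, theta) {
  k <- seq_len(nrow(coef))
  ck <- cos(k * theta); sk <- sin(k * theta)
  cbind(a = coef[, 1] * ck + coef[, 2] * sk,
        b = -coef[, 1] * sk + coef[, 2] * ck,
        c = coef[, 3] * ck + coef[, 4] * sk,
        d = -coef[, 3] * sk + coef[, 4] * ck)
}

rotate_space <- function(coef, psi) {
  cp <- cos(psi); sp <- sin(psi)
  cbind(a = cp * coef[, 1] + sp * coef[, 3],
        b = cp * coef[, 2] + sp * coef[, 4],
        c = -sp * coef[, 1] + cp * coef[, 3],
        d = -sp * coef[, 2] + cp * coef[, 4])
}

normalize_efd <- function(coef, normalize_rotation) {
  if (normalize_rotation) {
    a1 <- coef[1, 1]; b1 <- coef[1, 2]; c1 <- coef[1, 3]; d1 <- coef[1, 4]
    theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 - b1^2 + c1^2 - d1^2)
    cands <- list()
    for (th in c(theta, theta + pi)) {
      cs <- rotate_start(coef, th)
      psi <- atan2(cs[1, 3], cs[1, 1])
      for (ps in c(psi, psi + pi)) {
        cr <- rotate_space(cs, ps)
        cands[[length(cands) + 1L]] <- cr / sqrt(sum(cr[1, ]^2))
      }
    }
    coef <- canonical_pick(cands)
  } else {
    coef <- coef / sqrt(sum(coef[1, ]^2))
  }
  coef
}

# deterministic, perturbation-stable choice among equivalent normalizations:
# tolerant lexicographic maximum over the flattened coefficient vectors
canonical_pick <- function(cands, tol = 1e-7) {
  best <- 1L
  for (i in seq_along(cands)[-1]) {
    u <- as.numeric(cands[[best]]); v <- as.numeric(cands[[i]])
    dif <- v - u
    j <- which(abs(dif) > tol)
    if (length(j) && dif[j[1]] > 0) best <- i
  }
  cands[[best]]
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf("<shape_descriptor: m = %d harmonics, rotation-normalized: %s>\n",
              x$m, x$normalization$rotation))
  invisible(x)
}

#' Euclidean distance between matched shape descriptors
#'
#' L2 norm over the flattened harmonic coefficients. For rotation-normalized
#' descriptors the distance is taken on the quotient space modulo the
#' normalization's residual four-fold sign ambiguity (start-point shift by
#' half a period and spatial rotation by pi), so equivalent normalizations
#' of the same outline are at distance zero. Zero iff the coefficients are
#' equivalent; symmetric; satisfies the triangle inequality.
#'
#' @param d1,d2 `shape_descriptor`s with equal `m` and normalization flags.
#' @return nonnegative distance.
#' @export
global_shape_distance <- function(d1, d2) {
  if (d1$m != d2$m) stop("descriptors have different harmonic counts")
  if (!identical(d1$normalization, d2$normalization))
    stop("descriptors use different normalizations")
  if (!isTRUE(d1$normalization$rotation))
    return(sqrt(sum((d1$coef - d2$coef)^2)))
  s_odd <- ifelse(seq_len(d2$m) %% 2 == 1L, -1, 1)
  sqrt(min(vapply(list(d2$coef, d2$coef * s_odd, -d2$coef, -d2$coef * s_odd),
                  function(v) sum((d1$coef - v)^2), numeric(1))))
}

#' Flatten a shape descriptor into a feature vector
#' @param d a `shape_descriptor`.
#' @return numeric vector of length `4 * m`.
#' @export
efd_features <- function(d) as.numeric(d$coef)
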