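# Vectorized algebra on collections of small d x d matrices.
#
# A collection of n matrices is stored as an n x d^2 numeric matrix in
# column-major order: entry (r, c) of particle p lives at [p, (c-1)*d + r].
# All solver hot loops run on these, so everything here must stay free of
# per-particle R-level loops.

pm_col <- function(r, c, d) (c - 1L) * d + r

pm_identity <- function(n, d) {
  out <- matrix(0, n, d * d)
  for (r in seq_len(d)) out[, pm_col(r, r, d)] <- 1
  out
}

pm_from_matrix <- function(M) {
  matrix(as.vector(M), nrow = 1L)
}

pm_to_matrix <- function(A, p = 1L) {
  d <- as.integer(round(sqrt(ncol(A))))
  matrix(A[p, ], d, d)
}

pm_transpose <- function(A, d) {
  out <- A
  for (r in seq_len(d)) for (c in seq_len(d)) {
    out[, pm_col(r, c, d)] <- A[, pm_col(c, r, d)]
  }
  out
}

# C = A %*% B, rowwise
pm_mul <- function(A, B, d) {
  out <- matrix(0, nrow(A), d * d)
  for (r in seq_len(d)) for (c in seq_len(d)) {
    acc <- 0
    for (k in seq_len(d)) {
      acc <- acc + A[, pm_col(r, k, d)] * B[, pm_col(k, c, d)]
    }
    out[, pm_col(r, c, d)] <- acc
  }
  out
}

pm_det <- function(A, d) {
  if (d == 2L) {
    A[, 1L] * A[, 4L] - A[, 2L] * A[, 3L]
  } else if (d == 3L) {
    a11 <- A[, 1L]; a21 <- A[, 2L]; a31 <- A[, 3L]
    a12 <- A[, 4L]; a22 <- A[, 5L]; a32 <- A[, 6L]
    a13 <- A[, 7L]; a23 <- A[, 8L]; a33 <- A[, 9L]
    a11 * (a22 * a33 - a23 * a32) -
      a12 * (a21 * a33 - a23 * a31) +
      a13 * (a21 * a32 - a22 * a31)
  } else {
    stop("pm_det: only d = 2 or 3 supported")
  }
}

# Inverse via closed-form adjugate; caller guarantees non-singularity.
pm_inv <- function(A, d, det = NULL) {
  if (is.null(det)) det <- pm_det(A, d)
  out <- matrix(0, nrow(A), d * d)
  if (d == 2L) {
    out[, 1L] <- A[, 4L] / det
    out[, 2L] <- -A[, 2L] / det
    out[, 3L] <- -A[, 3L] / det
    out[, 4L] <- A[, 1L] / det
  } else if (d == 3L) {
    a11 <- A[, 1L]; a21 <- A[, 2L]; a31 <- A[, 3L]
    a12 <- A[, 4L]; a22 <- A[, 5L]; a32 <- A[, 6L]
    a13 <- A[, 7L]; a23 <- A[, 8L]; a33 <- A[, 9L]
    out[, pm_col(1L, 1L, 3L)] <- (a22 * a33 - a23 * a32) / det
    out[, pm_col(1L, 2L, 3L)] <- (a13 * a32 - a12 * a33) / det
    out[, pm_col(1L, 3L, 3L)] <- (a12 * a23 - a13 * a22) / det
    out[, pm_col(2L, 1L, 3L)] <- (a23 * a31 - a21 * a33) / det
    out[, pm_col(2L, 2L, 3L)] <- (a11 * a33 - a13 * a31) / det
    out[, pm_col(2L, 3L, 3L)] <- (a13 * a21 - a11 * a23) / det
    out[, pm_col(3L, 1L, 3L)] <- (a21 * a32 - a22 * a31) / det
    out[, pm_col(3L, 2L, 3L)] <- (a12 * a31 - a11 * a32) / det
    out[, pm_col(3L, 3L, 3L)] <- (a11 * a22 - a12 * a21) / det
  } else {
    stop("pm_inv: only d = 2 or 3 supported")
  }
  out
}

# trace(t(A) %*% A) rowwise: sum of squared entries
pm_frob2 <- function(A) rowSums(A * A)
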