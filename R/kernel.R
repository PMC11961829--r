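#' Quadratic B-spline transfer weights at one position
#'
#' Evaluates the quadratic B-spline interpolation weights linking a position
#' to its 3^d-node grid stencil. The weights form a partition of unity and
#' have zero first moment about the particle
#' (`sum w_i (x_i - x) = 0`), the two identities the affine transfers rely on.
#'
#' @param x Position (m), numeric vector of length d.
#' @param dx Grid spacing (m).
#' @return A list with `base` (0-based grid coordinate of the stencil's first
#'   node per axis), `axis_weights` (d x 3 matrix of per-axis weights),
#'   `offsets` (3^d x d matrix of stencil node 0-based grid coordinates),
#'   `positions` (3^d x d node positions, m) and `weights` (3^d tensor-product
#'   weights).
#' @examples
#' w <- kernel_weights(c(0.01, 0.01), dx = 0.005)
#' sum(w$weights)  # 1
#' @export
kernel_weights <- function(x, dx) {
  d <- length(x)
  if (dx <= 0) stop("kernel_weights: 'dx' must be > 0", call. = FALSE)
  xs <- x / dx
  base <- floor(xs - 0.5)
  fx <- xs - base
  aw <- rbind(0.5 * (1.5 - fx)^2,
              0.75 - (fx - 1)^2,
              0.5 * (fx - 0.5)^2)        # 3 x d
  ko <- as.matrix(expand.grid(rep(list(0:2), d)))
  colnames(ko) <- NULL
  w <- rep(1, nrow(ko))
  for (a in seq_len(d)) w <- w * aw[ko[, a] + 1L, a]
  offsets <- sweep(ko, 2L, base, "+")
  list(base = base,
       axis_weights = t(aw),
       offsets = offsets,
       positions = offsets * dx,
       weights = w)
}

# Per-frame stencil for a particle collection (vectorized).
#
# Returns, for each of the 3^d stencil offsets: `w[[o]]` (n weights),
# `idx[[o]]` (n 1-based linear grid node indices), `dp[[o]]` (length-d list of
# n-vectors of node offsets x_i - x_p in meters). Errors if any particle's
# stencil leaves the grid.
make_stencil <- function(x, cfg) {
  d <- cfg$d
  n <- nrow(x)
  dx <- cfg$dx
  nn <- cfg$nn
  meta <- stencil_meta(d, nn)
  ko <- meta$ko
  strides <- meta$strides
  xs <- vector("list", d)
  base <- vector("list", d)
  bad <- rep(FALSE, n)
  for (a in seq_len(d)) {
    xsa <- x[, a] / dx
    ba <- floor(xsa - 0.5)
    bad <- bad | ba < 0 | ba + 2 > nn[a] - 1 | !is.finite(ba)
    xs[[a]] <- xsa
    base[[a]] <- ba
  }
  if (any(bad)) {
    stop(sprintf("particle(s) %s left the valid grid domain",
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  aw <- vector("list", d)
  for (a in seq_len(d)) {
    fx <- xs[[a]] - base[[a]]
    aw[[a]] <- list(0.5 * (1.5 - fx)^2,
                    0.75 - (fx - 1)^2,
                    0.5 * (fx - 0.5)^2)
  }
  no <- nrow(ko)
  w <- vector("list", no)
  idx <- vector("list", no)
  dp <- vector("list", no)
  for (o in seq_len(no)) {
    wo <- aw[[1L]][[ko[o, 1L] + 1L]]
    id <- base[[1L]] + (ko[o, 1L] + 1)
    dpo <- vector("list", d)
    dpo[[1L]] <- (base[[1L]] + ko[o, 1L] - xs[[1L]]) * dx
    for (a in seq_len(d)[-1L]) {
      wo <- wo * aw[[a]][[ko[o, a] + 1L]]
      id <- id + (base[[a]] + ko[o, a]) * strides[a]
      dpo[[a]] <- (base[[a]] + ko[o, a] - xs[[a]]) * dx
    }
    w[[o]] <- wo
    idx[[o]] <- as.integer(id)
    dp[[o]] <- dpo
  }
  list(w = w, idx = idx, dp = dp, n_offsets = no)
}

# cached stencil offset table and grid strides per (d, nn)
.stencil_cache <- new.env(parent = emptyenv())

stencil_meta <- function(d, nn) {
  key <- paste(c(d, nn), collapse = "_")
  m <- .stencil_cache[[key]]
  if (is.null(m)) {
    ko <- as.matrix(expand.grid(rep(list(0:2), d)))
    colnames(ko) <- NULL
    m <- list(ko = ko, strides = cumprod(c(1L, nn[-d])))
    .stencil_cache[[key]] <- m
  }
  m
}
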