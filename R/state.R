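STATUS_FREE <- 0L
STATUS_FIXED <- 1L
STATUS_CAPTURED <- 2L

status_labels <- function(code) {
  c("free", "fixed", "captured")[code + 1L]
}

# Particle collection constructor (internal). x: n x d positions. Fills the
# remaining per-particle state with rest-state defaults.
make_particles <- function(x, m, V0, d,
                           v = NULL, status = NULL, vpre = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(m) == 1L) m <- rep(m, n)
  if (length(V0) == 1L) V0 <- rep(V0, n)
  if (any(m <= 0)) stop("make_particles: particle masses must be > 0", call. = FALSE)
  if (any(V0 <= 0)) stop("make_particles: particle volumes must be > 0", call. = FALSE)
  list(
    n = n, d = d,
    x = x,
    v = if (is.null(v)) matrix(0, n, d) else as.matrix(v),
    C = matrix(0, n, d * d),
    F = pm_identity(n, d),
    Jp = rep(1, n),
    J = rep(1, n),
    Je = rep(1, n),
    m = as.numeric(m),
    V0 = as.numeric(V0),
    status = if (is.null(status)) rep(STATUS_FREE, n) else as.integer(status),
    vpre = if (is.null(vpre)) matrix(0, n, d) else as.matrix(vpre),
    rel = matrix(NA_real_, n, d),
    dv = matrix(0, n, d),
    P = matrix(0, n, d * d),
    f_ext = NULL
  )
}

#' Build a rectangular slab specimen as an MPM particle collection
#'
#' Samples the slab described by a [specimen_spec()] on a regular particle
#' lattice (with optional uniform jitter), assigns per-particle mass and rest
#' volume so the total mass equals `density * slab volume` exactly, and flags
#' the fixed band. The low-x band of width `fixed_frac * length` is held
#' fixed; indices of the load band (high-x band of width `load_frac * length`)
#' and of the stress-measurement set (all particles: the specimen-mean axial
#' stress is the most robust engineering-stress readout, since plastic zones
#' localize at the grip edges) are attached as attributes `load_idx` and
#' `measure_idx`.
#'
#' @param spec A [specimen_spec()].
#' @param cfg A [sim_config()].
#' @param seed RNG seed for the jitter; defaults to `cfg$seed`. Sampling is
#'   deterministic given the seed.
#' @return A particle collection (list) ready for [mpm_state()].
#' @examples
#' cfg <- sim_config(nn = c(64, 16))
#' p <- make_slab(specimen_spec(extents = c(0.05, 0.01)), cfg)
#' sum(p$m)  # density * 0.05 * 0.01
#' @export
make_slab <- function(spec, cfg, seed = NULL) {
  d <- cfg$d
  if (length(spec$extents) != d) {
    stop("make_slab: specimen 'extents' must match the configured dimension",
         call. = FALSE)
  }
  k <- round(spec$particles_per_cell^(1 / d))
  if (k^d != spec$particles_per_cell) {
    stop("make_slab: 'particles_per_cell' must be a perfect d-th power",
         call. = FALSE)
  }
  h_target <- cfg$dx / k
  np <- pmax(1L, as.integer(round(spec$extents / h_target)))
  h <- spec$extents / np
  corner <- spec$corner
  if (is.null(corner)) {
    corner <- numeric(d)
    corner[1L] <- (cfg$bc_margin + 2) * cfg$dx
    for (a in seq_len(d)[-1L]) {
      corner[a] <- ((cfg$nn[a] - 1) * cfg$dx - spec$extents[a]) / 2
    }
  }
  hi_limit <- (cfg$nn - 1 - cfg$bc_margin) * cfg$dx
  lo_limit <- cfg$bc_margin * cfg$dx
  if (any(corner < lo_limit) || any(corner + spec$extents > hi_limit)) {
    stop("make_slab: slab does not fit inside the grid domain minus margins",
         call. = FALSE)
  }
  axes <- lapply(seq_len(d), function(a) corner[a] + (seq_len(np[a]) - 0.5) * h[a])
  x <- as.matrix(expand.grid(axes))
  colnames(x) <- NULL
  n <- nrow(x)
  if (spec$jitter > 0) {
    if (is.null(seed)) seed <- cfg$seed
    set.seed(seed)
    jit <- matrix(stats::runif(n * d, -spec$jitter, spec$jitter), n, d)
    x <- x + sweep(jit, 2L, h, "*")
  }
  V0 <- prod(h)
  m <- spec$density * V0
  p <- make_particles(x, m = m, V0 = V0, d = d)
  x1 <- x[, 1L]
  L <- spec$extents[1L]
  p$status[x1 < corner[1L] + spec$fixed_frac * L] <- STATUS_FIXED
  attr(p, "load_idx") <- which(x1 > corner[1L] + (1 - spec$load_frac) * L)
  attr(p, "measure_idx") <- seq_len(n)
  attr(p, "corner") <- corner
  attr(p, "extents") <- spec$extents
  p
}

#' Assemble a simulation state
#'
#' Combines a particle collection, grid configuration and material parameters
#' into the state object consumed by [advance_frame()]. The background grid
#' fields (mass, momentum, velocity, and the velocity-increment field carried
#' between frames) are allocated and zeroed; the velocity-increment field
#' starts at zero by the frame-0 convention.
#'
#' @param particles A particle collection, e.g. from [make_slab()].
#' @param cfg A [sim_config()].
#' @param params A [material_params()].
#' @return An object of class `mpm_state`.
#' @export
mpm_state <- function(particles, cfg, params) {
  d <- cfg$d
  N <- prod(cfg$nn)
  coords <- as.matrix(expand.grid(lapply(cfg$nn, function(k) 0:(k - 1L))))
  colnames(coords) <- NULL
  grid <- list(
    mass = numeric(N),
    mom = matrix(0, N, d),
    vel = matrix(0, N, d),
    dv = matrix(0, N, d),
    active = rep(FALSE, N),
    coords = coords
  )
  structure(
    list(p = particles, grid = grid, cfg = cfg, params = params,
         frame = 0L, t = 0, cfl_warned = FALSE),
    class = "mpm_state")
}

#' @export
print.mpm_state <- function(x, ...) {
  cat(sprintf("MPM state: %d particles (d = %d), frame %d, t = %.6g s\n",
              x$p$n, x$p$d, x$frame, x$t))
  tab <- table(status_labels(x$p$status))
  cat("  status:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
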