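#' Constitutive parameters for the viscoelastic-plastic Neo-Hookean model
#'
#' Bundles the material constants of the tissue model: initial Lame
#' coefficients `mu0` and `lambda0`, the plastic hardening coefficient `xi`
#' (Lame coefficients scale as `exp(xi * (1 - J_P))` with the plastic volume
#' ratio `J_P`), the elastic volume-ratio limits `theta_c` (compression) and
#' `theta_s` (extension) that confine the elastic volume ratio `J_E` to
#' `[1 - theta_c, 1 + theta_s]`, and the per-frame viscosity constants `k_c`,
#' `k_s` that control how fast volume ratios beyond the limits relax back
#' toward them (and hence how fast the material creeps and relaxes stress).
#'
#' `k_c` and `k_s` are defined per simulation frame: an elastic volume excess
#' beyond `1 + theta_s` decays by the factor `1 - k_s` every time step, so
#' their effect is tied to the configured `dt`.
#'
#' @param mu0 Initial shear Lame coefficient (Pa), > 0.
#' @param lambda0 Initial second Lame coefficient (Pa), >= 0.
#' @param xi Plastic hardening coefficient (dimensionless).
#' @param theta_c Compression limit ratio, in (0, 1).
#' @param theta_s Extension limit ratio, > 0.
#' @param k_c Compression viscosity constant, in \[0, 1\].
#' @param k_s Extension viscosity constant, in \[0, 1\].
#' @param plasticity_mode `"stateful"` (default): a per-particle plastic volume
#'   ratio persists between frames and the elastic candidate `det(F) / J_P` is
#'   relaxed toward the limits each frame, producing stress relaxation and
#'   creep. `"stateless"`: the limit map is applied to the total volume ratio
#'   each frame with no memory (no relaxation under constant strain).
#' @return An object of class `material_params`.
#' @examples
#' material_params()                      # documented defaults (E = 10 kPa, nu = 0.4)
#' material_params(mu0 = 1e3, xi = 0)     # hardening disabled
#' @seealso [lame_coefficients()] to derive `mu0`, `lambda0` from `E`, `nu`.
#' @export
material_params <- function(mu0 = 10000 / (2 * 1.4),
                            lambda0 = 10000 * 0.4 / (1.4 * 0.2),
                            xi = 10,
                            theta_c = 0.05,
                            theta_s = 0.10,
                            k_c = 0.05,
                            k_s = 0.05,
                            plasticity_mode = c("stateful", "stateless")) {
  plasticity_mode <- match.arg(plasticity_mode)
  chk_num(mu0, "mu0"); chk_num(lambda0, "lambda0"); chk_num(xi, "xi")
  chk_num(theta_c, "theta_c"); chk_num(theta_s, "theta_s")
  chk_num(k_c, "k_c"); chk_num(k_s, "k_s")
  if (mu0 <= 0) stop("material_params: 'mu0' must be > 0", call. = FALSE)
  if (lambda0 < 0) stop("material_params: 'lambda0' must be >= 0", call. = FALSE)
  if (theta_c <= 0 || theta_c >= 1) {
    stop("material_params: 'theta_c' must lie in (0, 1)", call. = FALSE)
  }
  if (theta_s <= 0) stop("material_params: 'theta_s' must be > 0", call. = FALSE)
  if (k_c < 0 || k_c > 1) stop("material_params: 'k_c' must lie in [0, 1]", call. = FALSE)
  if (k_s < 0 || k_s > 1) stop("material_params: 'k_s' must lie in [0, 1]", call. = FALSE)
  structure(
    list(mu0 = mu0, lambda0 = lambda0, xi = xi,
         theta_c = theta_c, theta_s = theta_s, k_c = k_c, k_s = k_s,
         plasticity_mode = plasticity_mode),
    class = "material_params")
}

#' Lame coefficients from Young's modulus and Poisson ratio
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio, in (-1, 0.5).
#' @return A list with elements `mu0` and `lambda0`.
#' @examples
#' lame_coefficients(1e4, 0.4)
#' @export
lame_coefficients <- function(E, nu) {
  if (E <= 0) stop("lame_coefficients: 'E' must be > 0", call. = FALSE)
  if (nu <= -1 || nu >= 0.5) {
    stop("lame_coefficients: 'nu' must lie in (-1, 0.5)", call. = FALSE)
  }
  list(mu0 = E / (2 * (1 + nu)),
       lambda0 = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

#' @export
print.material_params <- function(x, ...) {
  cat("Viscoelastic-plastic Neo-Hookean material\n")
  cat(sprintf("  mu0 = %.6g Pa, lambda0 = %.6g Pa, xi = %.4g (%s plasticity)\n",
              x$mu0, x$lambda0, x$xi, x$plasticity_mode))
  cat(sprintf("  elastic volume range [%.4g, %.4g], k_c = %.4g, k_s = %.4g per frame\n",
              1 - x$theta_c, 1 + x$theta_s, x$k_c, x$k_s))
  invisible(x)
}

#' Simulation configuration for the MPM solver
#'
#' Defines the background grid and the time integration: spatial dimension,
#' grid spacing, time step, per-axis node counts, the boundary margin in which
#' inward velocity components are zeroed, and optional gravity and per-frame
#' velocity damping. The quadratic B-spline transfer kernel needs a stencil of
#' 3 nodes per axis, so `bc_margin` must be at least 2 cells.
#'
#' @param d Spatial dimension, 2 or 3.
#' @param dx Grid spacing (m), > 0.
#' @param dt Time step (s), > 0.
#' @param nn Integer vector of grid node counts per axis (length `d`).
#' @param bc_margin Boundary margin thickness in cells, >= 2.
#' @param gravity Per-axis acceleration (m/s^2); default zero.
#' @param bc_type `"slip"` (zero only the component directed into the face) or
#'   `"sticky"` (zero all components in the margin).
#' @param damping Per-frame grid velocity damping factor in \[0, 1); velocities
#'   are multiplied by `1 - damping` each frame. Used by the quasi-static
#'   characterization experiments; 0 disables it.
#' @param paper_literal_scaling If `TRUE`, use the literal elastic rescaling
#'   `F_E = (J_E / J) F`, under which `det(F_E) != J_E` for `d > 1`; the
#'   default applies the exponent `1/d` so that `det(F_E) = J_E`.
#' @param seed RNG seed recorded with the run and used for particle sampling.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(dx = 0.002, dt = 1e-4, nn = c(128, 32))
#' @export
sim_config <- function(d = 2L,
                       dx = 0.002,
                       dt = 1e-4,
                       nn = c(128L, 32L),
                       bc_margin = 2L,
                       gravity = NULL,
                       bc_type = c("slip", "sticky"),
                       damping = 0,
                       paper_literal_scaling = FALSE,
                       seed = 0L) {
  bc_type <- match.arg(bc_type)
  d <- as.integer(d)
  if (!d %in% c(2L, 3L)) stop("sim_config: 'd' must be 2 or 3", call. = FALSE)
  chk_num(dx, "dx"); chk_num(dt, "dt")
  if (dx <= 0) stop("sim_config: 'dx' must be > 0", call. = FALSE)
  if (dt <= 0) stop("sim_config: 'dt' must be > 0", call. = FALSE)
  nn <- as.integer(nn)
  if (length(nn) != d || any(nn < 6L)) {
    stop("sim_config: 'nn' must give >= 6 nodes for each of the d axes",
         call. = FALSE)
  }
  bc_margin <- as.integer(bc_margin)
  if (bc_margin < 2L) {
    stop("sim_config: 'bc_margin' must be >= 2 cells (quadratic B-spline support)",
         call. = FALSE)
  }
  if (is.null(gravity)) gravity <- rep(0, d)
  if (length(gravity) != d) {
    stop("sim_config: 'gravity' must have one component per axis", call. = FALSE)
  }
  if (damping < 0 || damping >= 1) {
    stop("sim_config: 'damping' must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(d = d, dx = dx, dt = dt, nn = nn, bc_margin = bc_margin,
         gravity = as.numeric(gravity), bc_type = bc_type,
         damping = as.numeric(damping),
         paper_literal_scaling = isTRUE(paper_literal_scaling),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("MPM grid: d = %d, dx = %g m, dt = %g s, nodes %s, margin %d cells (%s BC)\n",
              x$d, x$dx, x$dt, paste(x$nn, collapse = " x "), x$bc_margin, x$bc_type))
  invisible(x)
}

#' Specimen description for the characterization experiments
#'
#' Describes the rectangular thin-layer slab used by the tear, creep and
#' stress-relaxation experiments: its physical extents, particle sampling
#' density per grid cell, lattice jitter, mass density, and the fractions of
#' its length designated as the fixed band (grip) and the load band (pulled or
#' loaded end).
#'
#' @param extents Slab dimensions per axis (m), length `d`.
#' @param particles_per_cell Particles sampled per grid cell; must be a perfect
#'   `d`-th power (lattice sampling), e.g. 4 or 16 in 2-D.
#' @param jitter Uniform jitter amplitude as a fraction of the particle lattice
#'   spacing, in \[0, 0.5\].
#' @param density Mass density (kg/m^3), > 0.
#' @param fixed_frac Fraction of the slab length (axis 1) held fixed at the
#'   low-x end.
#' @param load_frac Fraction of the slab length loaded/pulled at the high-x end.
#' @param corner Optional lower-corner position of the slab (m); default
#'   centers the slab on the off axes and offsets it past the boundary margin
#'   on axis 1.
#' @return An object of class `specimen_spec`.
#' @examples
#' specimen_spec(extents = c(0.1, 0.01))
#' @export
specimen_spec <- function(extents = c(0.1, 0.01),
                          particles_per_cell = 16L,
                          jitter = 0,
                          density = 1040,
                          fixed_frac = 0.08,
                          load_frac = 0.08,
                          corner = NULL) {
  if (any(extents <= 0)) stop("specimen_spec: 'extents' must be > 0", call. = FALSE)
  particles_per_cell <- as.integer(particles_per_cell)
  if (particles_per_cell < 1L) {
    stop("specimen_spec: 'particles_per_cell' must be >= 1", call. = FALSE)
  }
  if (jitter < 0 || jitter > 0.5) {
    stop("specimen_spec: 'jitter' must lie in [0, 0.5]", call. = FALSE)
  }
  if (density <= 0) stop("specimen_spec: 'density' must be > 0", call. = FALSE)
  if (fixed_frac < 0 || load_frac < 0 || fixed_frac + load_frac >= 1) {
    stop("specimen_spec: 'fixed_frac' and 'load_frac' must be disjoint fractions of the length",
         call. = FALSE)
  }
  structure(
    list(extents = as.numeric(extents),
         particles_per_cell = particles_per_cell,
         jitter = as.numeric(jitter),
         density = as.numeric(density),
         fixed_frac = as.numeric(fixed_frac),
         load_frac = as.numeric(load_frac),
         corner = if (is.null(corner)) NULL else as.numeric(corner)),
    class = "specimen_spec")
}

#' @export
print.specimen_spec <- function(x, ...) {
  cat(sprintf("Slab specimen: %s m, %d particles/cell, jitter %.2g, density %g kg/m^3\n",
              paste(signif(x$extents, 4), collapse = " x "),
              x$particles_per_cell, x$jitter, x$density))
  invisible(x)
}

chk_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(TRUE)
}
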