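# Shared fixtures: small configs, slabs and oracle helpers, built in code.

tiny_cfg <- function(nn = c(64, 16), dx = 0.002, dt = 1e-4, ...) {
  sim_config(dx = dx, dt = dt, nn = nn, ...)
}

tiny_slab_state <- function(extents = c(0.05, 0.01), ppc = 4L,
                            cfg = tiny_cfg(), params = material_params(),
                            all_free = FALSE, jitter = 0, seed = 1L) {
  spec <- specimen_spec(extents = extents, particles_per_cell = ppc,
                        jitter = jitter)
  p <- make_slab(spec, cfg, seed)
  if (all_free) p$status[] <- 0L
  st <- mpm_state(p, cfg, params)
  st$load_idx <- attr(p, "load_idx")
  st$measure_idx <- attr(p, "measure_idx")
  st$L0 <- max(p$x[, 1L]) - min(p$x[, 1L])
  st$cross_section <- prod(extents[-1L])
  st
}

# random deformation gradient with volume ratio inside [Jlo, Jhi]
random_F <- function(d = 2L, Jlo = 0.96, Jhi = 1.05) {
  repeat {
    F <- diag(d) + matrix(stats::runif(d * d, -0.05, 0.05), d, d)
    J <- det(F)
    if (J > 0) break
  }
  target_J <- stats::runif(1L, Jlo, Jhi)
  F * (target_J / J)^(1 / d)
}

# central-difference gradient of the energy density with respect to F
numeric_pk <- function(F, params, h = 1e-6) {
  d <- nrow(F)
  G <- matrix(0, d, d)
  for (r in seq_len(d)) for (c in seq_len(d)) {
    Fp <- F; Fp[r, c] <- Fp[r, c] + h
    Fm <- F; Fm[r, c] <- Fm[r, c] - h
    ep <- energy_density(split_deformation(Fp, 1, params), params)
    em <- energy_density(split_deformation(Fm, 1, params), params)
    G[r, c] <- (ep - em) / (2 * h)
  }
  G
}

pm_identity_pub <- function(n, d = 2L) npsim:::pm_identity(n, d)
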