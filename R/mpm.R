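# The four-step MLS-MPM frame loop. Each step is exposed for testing;
# advance_frame() chains them. The per-frame stencil (weights, node indices,
# node offsets) is computed once from x^n and shared by all steps.

#' Particle-to-grid transfer
#'
#' Step 1 of the frame loop. Gathers the previous frame's grid
#' velocity-increment field into a per-particle affine-velocity increment
#' `dC`, updates each deformation gradient as `F <- (I + dt (C + dC)) F`,
#' evaluates the constitutive stress `P(F)` through the elastic-plastic
#' split (ratcheting the per-particle plastic volume ratio in stateful mode),
#' and scatters mass and momentum to the grid. The momentum carried to node
#' `i` from particle `p` is
#' `w_ip (m_p v_p + (m_p C_p - (4 dt / dx^2) V0_p P F^T) (x_i - x_p))`,
#' plus `w_ip dt f_ext` when an external load is attached.
#'
#' @param state An [mpm_state()].
#' @param stencil Optional precomputed stencil (internal use).
#' @return The state with updated particle `F`, `Jp`, `P` and grid `mass`,
#'   `mom`.
#' @export
p2g <- function(state, stencil = NULL) {
  cfg <- state$cfg
  p <- state$p
  d <- cfg$d
  n <- p$n
  dt <- cfg$dt
  if (is.null(stencil)) stencil <- make_stencil(p$x, cfg)
  no <- stencil$n_offsets

  # -- affine-velocity increment from last frame's grid dv (Eq. 15 role)
  dC <- NULL
  dv_active <- state$grid$dv_active %||% any(state$grid$dv != 0)
  if (dv_active) {
    dC <- matrix(0, n, d * d)
    gdvc <- lapply(seq_len(d), function(r) state$grid$dv[, r])
    for (o in seq_len(no)) {
      w <- stencil$w[[o]]; idx <- stencil$idx[[o]]; dp <- stencil$dp[[o]]
      for (r in seq_len(d)) {
        wdv <- w * gdvc[[r]][idx]
        for (c in seq_len(d)) {
          j <- pm_col(r, c, d)
          dC[, j] <- dC[, j] + wdv * dp[[c]]
        }
      }
    }
    dC <- dC * (4 / cfg$dx^2)
  }

  # -- deformation gradient update with the incremented affine matrix
  A <- pm_identity(n, d) + if (is.null(dC)) dt * p$C else dt * (p$C + dC)
  Fn1 <- pm_mul(A, p$F, d)
  J <- pm_det(Fn1, d)
  if (any(!is.finite(J)) || any(J <= 0)) {
    bad <- which(!is.finite(J) | J <= 0)
    stop(sprintf("deformation gradient of particle(s) %s became non-positive",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  sp <- split_deformation_vec(Fn1, p$Jp, state$params, d,
                              paper_literal = cfg$paper_literal_scaling)
  P <- pk_stress_vec(sp$F_E, sp$J_E, sp$J_P, state$params, d)
  p$F <- Fn1
  p$J <- sp$J
  p$Je <- sp$J_E
  if (identical(state$params$plasticity_mode, "stateful")) p$Jp <- sp$J_P
  p$P <- P

  # -- affine + stress fused scatter coefficient (Eq. 17 role)
  Q <- p$C * p$m - pm_mul(P, pm_transpose(Fn1, d), d) * (4 * dt / cfg$dx^2 * p$V0)
  Qc <- lapply(seq_len(d * d), function(j) Q[, j])
  mv <- lapply(seq_len(d), function(r) p$m * p$v[, r])
  fe <- p$f_ext

  idx_all <- integer(no * n)
  vals <- matrix(0, no * n, 1L + d)
  for (o in seq_len(no)) {
    w <- stencil$w[[o]]; dp <- stencil$dp[[o]]
    rows <- ((o - 1L) * n + 1L):(o * n)
    idx_all[rows] <- stencil$idx[[o]]
    vals[rows, 1L] <- w * p$m
    for (r in seq_len(d)) {
      adv <- mv[[r]]
      for (c in seq_len(d)) adv <- adv + Qc[[pm_col(r, c, d)]] * dp[[c]]
      if (!is.null(fe)) adv <- adv + dt * fe[, r]
      vals[rows, 1L + r] <- w * adv
    }
  }
  acc <- rowsum(vals, idx_all)
  ids <- as.integer(rownames(acc))
  N <- prod(cfg$nn)
  mass <- numeric(N)
  mom <- matrix(0, N, d)
  mass[ids] <- acc[, 1L]
  mom[ids, ] <- acc[, -1L, drop = FALSE]

  state$p <- p
  state$grid$mass <- mass
  state$grid$mom <- mom
  state
}

#' Grid momentum-to-velocity update with boundary conditions
#'
#' Step 2 of the frame loop. On active nodes (mass above
#' `1e-12 * mean(particle mass)`) the velocity is `momentum / mass`, plus the
#' optional gravity increment and per-frame damping. Within `bc_margin` cells
#' of a domain face the velocity component directed into that face is zeroed
#' (slip condition; `bc_type = "sticky"` zeroes all components there).
#'
#' @param state An [mpm_state()] after [p2g()].
#' @return The state with grid `vel` and `active` set.
#' @export
grid_update <- function(state) {
  cfg <- state$cfg
  d <- cfg$d
  g <- state$grid
  thresh <- 1e-12 * mean(state$p$m)
  active <- g$mass > thresh
  vel <- matrix(0, length(g$mass), d)
  vel[active, ] <- g$mom[active, , drop = FALSE] / g$mass[active]
  if (any(cfg$gravity != 0)) {
    vel[active, ] <- vel[active, , drop = FALSE] +
      matrix(cfg$dt * cfg$gravity, sum(active), d, byrow = TRUE)
  }
  if (cfg$damping > 0) vel <- vel * (1 - cfg$damping)
  cc <- g$coords
  for (a in seq_len(d)) {
    low <- cc[, a] < cfg$bc_margin
    high <- cc[, a] > cfg$nn[a] - 1L - cfg$bc_margin
    if (cfg$bc_type == "sticky") {
      vel[(low | high) & active, ] <- 0
    } else {
      sel <- low & active & vel[, a] < 0
      vel[sel, a] <- 0
      sel <- high & active & vel[, a] > 0
      vel[sel, a] <- 0
    }
  }
  state$grid$vel <- vel
  state$grid$active <- active
  state
}

#' Grid-to-particle transfer
#'
#' Step 3 of the frame loop. Interpolates the temporary particle velocity
#' `v~ = sum w_ip v_i`, rebuilds the affine velocity matrix
#' `C = (4/dx^2) sum w_ip v_i (x_i - x_p)^T`, and proposes the position
#' `x~ = x + dt v~`. Particles with fixed status receive their prescribed
#' velocity instead (zero for a plain grip), implementing Dirichlet
#' constraints at the particle level.
#'
#' @param state An [mpm_state()] after [grid_update()].
#' @param stencil Optional precomputed stencil (internal use).
#' @return A list with `state` (updated particle `C`), `v_tilde` (n x d) and
#'   `x_tilde` (n x d).
#' @export
g2p <- function(state, stencil = NULL) {
  cfg <- state$cfg
  p <- state$p
  d <- cfg$d
  n <- p$n
  if (is.null(stencil)) stencil <- make_stencil(p$x, cfg)
  velc <- lapply(seq_len(d), function(r) state$grid$vel[, r])
  vt <- matrix(0, n, d)
  Cn <- matrix(0, n, d * d)
  for (o in seq_len(stencil$n_offsets)) {
    w <- stencil$w[[o]]; idx <- stencil$idx[[o]]; dp <- stencil$dp[[o]]
    for (r in seq_len(d)) {
      wv <- w * velc[[r]][idx]
      vt[, r] <- vt[, r] + wv
      for (c in seq_len(d)) {
        j <- pm_col(r, c, d)
        Cn[, j] <- Cn[, j] + wv * dp[[c]]
      }
    }
  }
  Cn <- Cn * (4 / cfg$dx^2)
  fixed <- p$status == STATUS_FIXED
  if (any(fixed)) vt[fixed, ] <- p$vpre[fixed, , drop = FALSE]
  xt <- p$x + cfg$dt * vt
  state$p$C <- Cn
  list(state = state, v_tilde = vt, x_tilde = xt)
}

#' Finalize a frame: particle update and next-frame grid increments
#'
#' Step 4 of the frame loop (after collision resolution). Sets the new
#' particle velocity `v = (x^{n+1} - x^n)/dt` for particles whose position
#' was altered by the clamp and `v = v~` for the rest (so their velocity
#' increment is exactly zero), stores the per-particle increment
#' `dv = v - v~`, and scatters `grid.dv_i = (1/m_i) sum w_ip m_p dv_p`
#' for use in the next frame's affine-increment gather.
#'
#' @param state An [mpm_state()].
#' @param x_new n x d resolved positions.
#' @param v_tilde n x d temporary velocities from [g2p()].
#' @param altered Logical n-vector: which particles the clamp moved.
#' @param stencil Optional precomputed stencil (internal use).
#' @return The state with particles advanced and `grid$dv` stored.
#' @export
finalize_frame <- function(state, x_new, v_tilde, altered = NULL,
                           stencil = NULL) {
  cfg <- state$cfg
  p <- state$p
  d <- cfg$d
  n <- p$n
  if (is.null(altered)) altered <- rep(FALSE, n)
  if (is.null(stencil)) stencil <- make_stencil(p$x, cfg)
  v <- v_tilde
  dv <- matrix(0, n, d)
  if (any(altered)) {
    v[altered, ] <- (x_new[altered, , drop = FALSE] -
                       p$x[altered, , drop = FALSE]) / cfg$dt
    dv[altered, ] <- v[altered, , drop = FALSE] -
      v_tilde[altered, , drop = FALSE]
  }
  p$x <- x_new
  p$v <- v
  p$dv <- dv
  N <- prod(cfg$nn)
  gdv <- matrix(0, N, d)
  if (any(altered)) {
    sub <- which(altered)
    no <- stencil$n_offsets
    idx_all <- integer(no * length(sub))
    vals <- matrix(0, no * length(sub), d)
    for (o in seq_len(no)) {
      rows <- ((o - 1L) * length(sub) + 1L):(o * length(sub))
      idx_all[rows] <- stencil$idx[[o]][sub]
      vals[rows, ] <- stencil$w[[o]][sub] * p$m[sub] * dv[sub, , drop = FALSE]
    }
    acc <- rowsum(vals, idx_all)
    ids <- as.integer(rownames(acc))
    mass_ok <- state$grid$mass[ids] > 0
    gdv[ids[mass_ok], ] <- acc[mass_ok, , drop = FALSE] /
      state$grid$mass[ids[mass_ok]]
  }
  state$p <- p
  state$grid$dv <- gdv
  state$grid$dv_active <- any(altered)
  state
}

#' Impulse-based clamp force output
#'
#' The force reported to a force-feedback device is the negative rate of
#' momentum change the clamp imposed on the particles this frame:
#' `Force = sum_p -m_p (v_p - v~_p) / dt`. It is exactly zero when no
#' particle's velocity was altered by the clamp.
#'
#' @param state An [mpm_state()] after [finalize_frame()].
#' @return A d-vector force (N).
#' @export
output_force <- function(state) {
  -colSums(state$p$dv * state$p$m) / state$cfg$dt
}

#' Advance the simulation by one frame
#'
#' Runs the four-step loop in order: [p2g()], [grid_update()], [g2p()],
#' clamp collision resolution ([collide()]), [finalize_frame()], and
#' [output_force()]. Deterministic given its inputs; errors from the
#' sub-steps are re-raised with the frame index attached.
#'
#' @param state An [mpm_state()].
#' @param clamp_n,clamp_n1 Optional [clamp_state()] poses at frames n and
#'   n+1; `NULL` runs without a tool.
#' @return A list with `state` (advanced one frame) and `force` (d-vector, N).
#' @examples
#' cfg <- sim_config(nn = c(48, 16))
#' st <- mpm_state(make_slab(specimen_spec(extents = c(0.04, 0.01)), cfg),
#'                 cfg, material_params())
#' out <- advance_frame(st)
#' out$force  # zero: nothing touched the specimen
#' @export
advance_frame <- function(state, clamp_n = NULL, clamp_n1 = NULL) {
  frame <- state$frame
  res <- tryCatch({
    cfg <- state$cfg
    vmax <- max(abs(state$p$v), abs(state$p$vpre))
    if (!state$cfl_warned && cfg$dt * vmax > 0.5 * cfg$dx) {
      warning(sprintf("CFL guard: dt * max|v| = %.3g exceeds dx/2 = %.3g",
                      cfg$dt * vmax, cfg$dx / 2), call. = FALSE)
      state$cfl_warned <- TRUE
    }
    stencil <- make_stencil(state$p$x, cfg)
    state <- p2g(state, stencil)
    state <- grid_update(state)
    gp <- g2p(state, stencil)
    state <- gp$state
    col <- collide(state, gp$x_tilde, clamp_n, clamp_n1)
    state$p$status <- col$status
    state$p$rel <- col$rel
    state <- finalize_frame(state, col$x_new, gp$v_tilde, col$altered, stencil)
    state$frame <- frame + 1L
    state$t <- state$t + cfg$dt
    list(state = state, force = output_force(state))
  }, error = function(e) {
    stop(sprintf("frame %d: %s", frame, conditionMessage(e)), call. = FALSE)
  })
  res
}

# Constitutive-only update: advance the plastic recursion on the current,
# frozen deformation field (used by the static relaxation hold). No particle
# moves; J_P ratchets and the stored stress decays accordingly.
constitutive_relax <- function(state) {
  p <- state$p
  d <- state$cfg$d
  sp <- split_deformation_vec(p$F, p$Jp, state$params, d,
                              paper_literal = state$cfg$paper_literal_scaling)
  state$p$Je <- sp$J_E
  if (identical(state$params$plasticity_mode, "stateful")) state$p$Jp <- sp$J_P
  state$p$P <- pk_stress_vec(sp$F_E, sp$J_E, sp$J_P, state$params, d)
  state$frame <- state$frame + 1L
  state$t <- state$t + state$cfg$dt
  state
}
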