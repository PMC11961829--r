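# Scripted characterization experiments on the slab specimen: tear at
# constant pull rate, creep under constant load, and stress relaxation at
# held strain. All three use the same observables: engineering strain from
# the specimen's particle bounding extent along the pull axis, and
# engineering stress as the rest-volume-weighted mean axial first
# Piola-Kirchhoff component over the measurement set (whole specimen).

experiment_curve <- function(time, strain, stress, force, experiment,
                             extra = list()) {
  if (any(diff(time) <= 0)) {
    stop("experiment_curve: time must be strictly increasing", call. = FALSE)
  }
  cur <- data.frame(time = time, strain = strain, stress = stress, force = force)
  attr(cur, "experiment") <- experiment
  for (nm in names(extra)) attr(cur, nm) <- extra[[nm]]
  class(cur) <- c("experiment_curve", "data.frame")
  cur
}

#' @export
print.experiment_curve <- function(x, ...) {
  cat(sprintf("%s experiment curve: %d samples over %.4g s\n",
              attr(x, "experiment"), nrow(x), max(x$time) - min(x$time)))
  cat(sprintf("  strain range [%.4g, %.4g], stress range [%.6g, %.6g] Pa\n",
              min(x$strain), max(x$strain), min(x$stress), max(x$stress)))
  invisible(x)
}

measure_strain <- function(state, L0) {
  (max(state$p$x[, 1L]) - min(state$p$x[, 1L]) - L0) / L0
}

measure_stress <- function(state, idx) {
  V <- state$p$V0[idx]
  sum(state$p$P[idx, 1L] * V) / sum(V)
}

check_finite_frame <- function(state, value) {
  if (any(!is.finite(value)) || any(!is.finite(state$p$x))) {
    stop(sprintf("non-finite field at frame %d; simulation aborted",
                 state$frame), call. = FALSE)
  }
  invisible(TRUE)
}

prepare_specimen_state <- function(spec, cfg, params, seed = NULL) {
  p <- make_slab(spec, cfg, seed)
  st <- mpm_state(p, cfg, params)
  st$load_idx <- attr(p, "load_idx")
  st$measure_idx <- attr(p, "measure_idx")
  # gauge length = initial particle extent, so strain starts at exactly 0
  st$L0 <- max(p$x[, 1L]) - min(p$x[, 1L])
  st$cross_section <- prod(spec$extents[-1L])
  st
}

record_loop <- function(state, frames, record_every, force_fun,
                        step_fun = function(s) advance_frame(s)$state,
                        progress = FALSE) {
  rec_at <- unique(c(seq(record_every, frames, by = record_every), frames))
  nr <- length(rec_at)
  prog_at <- max(1L, frames %/% 10L)
  time <- strain <- stress <- force <- numeric(nr)
  j <- 1L
  for (k in seq_len(frames)) {
    state <- step_fun(state)
    if (k == rec_at[j]) {
      time[j] <- state$t
      strain[j] <- measure_strain(state, state$L0)
      stress[j] <- measure_stress(state, state$measure_idx)
      force[j] <- force_fun(state, stress[j])
      check_finite_frame(state, c(strain[j], stress[j]))
      if (progress && (k %% prog_at < record_every)) {
        message(sprintf("[npsim] frame %d/%d t=%.4gs strain=%.4g stress=%.6gPa",
                        k, frames, time[j], strain[j], stress[j]))
      }
      j <- j + 1L
    }
  }
  list(state = state,
       rec = data.frame(time = time, strain = strain, stress = stress,
                        force = force))
}

#' Tear experiment: constant-rate pull to failure
#'
#' One end of the slab is held fixed and the other is displaced kinematically
#' at a constant rate until the specimen tears. The recorded stress-strain
#' curve passes through the four stages of the tearing process: near-linear
#' elastic rise, nonlinear plastic plateau, tearing with stress oscillation,
#' and collapse toward zero after complete separation
#' (see [segment_stages()]).
#'
#' @param spec A [specimen_spec()].
#' @param cfg A [sim_config()].
#' @param params A [material_params()].
#' @param pull_rate Pull velocity of the load band (m/s).
#' @param duration Simulated time (s).
#' @param record_every Record one curve sample every this many frames.
#' @param damping Per-frame grid velocity damping applied during the run
#'   (dynamic-relaxation factor keeping the fast pull quasi-static); `NULL`
#'   keeps the value in `cfg`.
#' @param soft_start Ramp-in time (s) over which the prescribed velocity or
#'   applied force rises linearly from zero, avoiding a startup shock; 0
#'   disables it.
#' @param seed Sampling seed, defaults to `cfg$seed`.
#' @param progress Emit progress messages while running.
#' @return An `experiment_curve` data frame (time, strain, stress, force).
#'   The force column is the engineering reaction estimate
#'   `stress * cross-section`.
#' @export
run_tear <- function(spec, cfg, params, pull_rate = 0.2, duration = 0.3,
                     record_every = 10L, damping = 0.005, soft_start = 0.02,
                     seed = NULL, progress = FALSE) {
  if (!is.null(damping)) cfg$damping <- damping
  state <- prepare_specimen_state(spec, cfg, params, seed)
  li <- state$load_idx
  state$p$status[li] <- STATUS_FIXED
  t0 <- state$t
  step <- function(s) {
    fac <- if (soft_start > 0) min(1, (s$t - t0) / soft_start) else 1
    s$p$vpre[li, 1L] <- pull_rate * fac
    advance_frame(s)$state
  }
  frames <- max(1L, round(duration / cfg$dt))
  out <- record_loop(state, frames, record_every,
                     function(s, stress) stress * s$cross_section,
                     step_fun = step, progress = progress)
  experiment_curve(out$rec$time, out$rec$strain, out$rec$stress, out$rec$force,
                   "tear",
                   extra = list(pull_rate = pull_rate, final_state = out$state))
}

#' Creep experiment: constant load, strain observed over time
#'
#' The low-x end is fixed and a constant total force (applied engineering
#' stress times the initial cross-section) is distributed uniformly over the
#' load-band particles and added to the grid momentum every frame. Under the
#' stateful plastic-flow model the strain grows quickly at first and then
#' approaches a steady state, the characteristic creep response of
#' viscoelastic tissue.
#'
#' @inheritParams run_tear
#' @param applied_stress Constant engineering stress applied to the load end
#'   (Pa).
#' @return An `experiment_curve`; the force column is the constant applied
#'   total force (N).
#' @export
run_creep <- function(spec, cfg, params, applied_stress = 500, duration = 0.3,
                      record_every = 10L, damping = 0.02, soft_start = 0.02,
                      seed = NULL, progress = FALSE) {
  if (!is.null(damping)) cfg$damping <- damping
  state <- prepare_specimen_state(spec, cfg, params, seed)
  li <- state$load_idx
  total_force <- applied_stress * state$cross_section
  f_ext <- matrix(0, state$p$n, cfg$d)
  f_ext[li, 1L] <- total_force / length(li)
  t0 <- state$t
  step <- function(s) {
    fac <- if (soft_start > 0) min(1, (s$t - t0) / soft_start) else 1
    s$p$f_ext <- f_ext * fac
    advance_frame(s)$state
  }
  frames <- max(1L, round(duration / cfg$dt))
  out <- record_loop(state, frames, record_every,
                     function(s, stress) total_force, step_fun = step,
                     progress = progress)
  experiment_curve(out$rec$time, out$rec$strain, out$rec$stress, out$rec$force,
                   "creep",
                   extra = list(applied_stress = applied_stress,
                                final_state = out$state))
}

#' Stress-relaxation experiment: held strain, stress observed over time
#'
#' The low-x end is fixed; the load end is pulled at `pull_rate` until the
#' prescribed displacement `target_strain * L0` is reached, then the strain
#' is maintained for `hold_duration`. With the default stateful plasticity
#' the stress decreases during the hold with a per-frame geometric decay of
#' the elastic volume excess (ratio `1 - k_s`) and levels off at a plateau;
#' in stateless mode no relaxation occurs.
#'
#' Two hold implementations are available. `"static"` (default) freezes the
#' deformation field at the end of the ramp and advances only the
#' constitutive plastic recursion each frame -- the strain is maintained
#' exactly and the recorded decay is the pure viscoelastic response.
#' `"dynamic"` pins the load band and keeps time-stepping the full solver;
#' residual elastic waves from the ramp then ring on top of the decay.
#'
#' @inheritParams run_tear
#' @param target_strain Engineering strain to introduce before the hold.
#' @param hold_duration Hold time (s).
#' @param pull_rate Ramp speed (m/s).
#' @param hold_mode `"static"` or `"dynamic"` (see Details).
#' @return An `experiment_curve` with attribute `hold_start` (the time at
#'   which the hold begins).
#' @export
run_relaxation <- function(spec, cfg, params, target_strain = 0.10,
                           hold_duration = 0.2, pull_rate = 0.1,
                           hold_mode = c("static", "dynamic"),
                           record_every = 10L, damping = 0.005,
                           soft_start = 0.02, seed = NULL,
                           progress = FALSE) {
  hold_mode <- match.arg(hold_mode)
  if (!is.null(damping)) cfg$damping <- damping
  state <- prepare_specimen_state(spec, cfg, params, seed)
  li <- state$load_idx
  state$p$status[li] <- STATUS_FIXED
  t0 <- state$t
  step <- function(s) {
    fac <- if (soft_start > 0) min(1, (s$t - t0) / soft_start) else 1
    s$p$vpre[li, 1L] <- pull_rate * fac
    advance_frame(s)$state
  }
  ramp_time <- target_strain * state$L0 / pull_rate + soft_start / 2
  ramp_frames <- max(1L, round(ramp_time / cfg$dt))
  ramp <- record_loop(state, ramp_frames, record_every,
                      function(s, stress) stress * s$cross_section,
                      step_fun = step, progress = progress)
  state <- ramp$state
  hold_start <- state$t
  state$p$vpre[li, 1L] <- 0
  hold_frames <- max(1L, round(hold_duration / cfg$dt))
  step_fun <- if (hold_mode == "static") {
    function(s) constitutive_relax(s)
  } else {
    function(s) advance_frame(s)$state
  }
  hold <- record_loop(state, hold_frames, record_every,
                      function(s, stress) stress * s$cross_section,
                      step_fun = step_fun, progress = progress)
  rec <- rbind(ramp$rec, hold$rec)
  experiment_curve(rec$time, rec$strain, rec$stress, rec$force, "relaxation",
                   extra = list(hold_start = hold_start,
                                hold_mode = hold_mode,
                                target_strain = target_strain,
                                final_state = hold$state))
}
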