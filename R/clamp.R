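#' Rigid clamp pose
#'
#' The surgical clamp is modeled as two cubic collision boxes at the tool tip,
#' placed symmetrically at `+/- opening` along the jaw axis (local axis 2) of
#' the clamp frame. When the jaws close to `opening <= closed_threshold`,
#' particles inside either box are captured and thereafter carried rigidly by
#' their stored clamp-frame coordinates; opening past the threshold releases
#' them.
#'
#' @param position Tip origin (m), d-vector.
#' @param opening Jaw half-separation (m), >= 0.
#' @param half_extent Per-axis half-sizes of each cubic box (m), length d.
#' @param closed_threshold Opening at or below which the jaws grip (m).
#' @param angle Rotation angle in radians (2-D).
#' @param orientation Optional d x d rotation matrix (overrides `angle`).
#' @return An object of class `clamp_state`.
#' @examples
#' clamp_state(position = c(0.05, 0.02), opening = 0.004,
#'             half_extent = c(0.003, 0.002))
#' @export
clamp_state <- function(position, opening, half_extent,
                        closed_threshold = 0.5 * min(half_extent),
                        angle = 0, orientation = NULL) {
  d <- length(position)
  if (is.null(orientation)) {
    if (d == 2L) {
      orientation <- matrix(c(cos(angle), sin(angle),
                              -sin(angle), cos(angle)), 2L, 2L)
    } else {
      orientation <- diag(d)
    }
  }
  orientation <- as.matrix(orientation)
  if (!isTRUE(all.equal(crossprod(orientation), diag(d), tolerance = 1e-8)) ||
      det(orientation) < 0) {
    stop("clamp_state: 'orientation' must be a proper rotation", call. = FALSE)
  }
  if (opening < 0) stop("clamp_state: 'opening' must be >= 0", call. = FALSE)
  if (length(half_extent) == 1L) half_extent <- rep(half_extent, d)
  if (any(half_extent <= 0)) {
    stop("clamp_state: 'half_extent' must be > 0", call. = FALSE)
  }
  structure(
    list(position = as.numeric(position), orientation = orientation,
         opening = as.numeric(opening),
         half_extent = as.numeric(half_extent),
         closed_threshold = as.numeric(closed_threshold)),
    class = "clamp_state")
}

#' @export
print.clamp_state <- function(x, ...) {
  cat(sprintf("Clamp at (%s) m, opening %.4g m (%s), box half-extents (%s) m\n",
              paste(signif(x$position, 4), collapse = ", "), x$opening,
              if (x$opening <= x$closed_threshold) "closed" else "open",
              paste(signif(x$half_extent, 4), collapse = ", ")))
  invisible(x)
}

#' Jaw collision boxes of a clamp pose
#'
#' @param clamp A [clamp_state()].
#' @return A list of two boxes, each with `center` (world, m), `orientation`
#'   (the clamp rotation) and `half_extent`.
#' @export
jaw_boxes <- function(clamp) {
  d <- length(clamp$position)
  centers_local <- list(numeric(d), numeric(d))
  centers_local[[1L]][2L] <- clamp$opening
  centers_local[[2L]][2L] <- -clamp$opening
  lapply(centers_local, function(cl) {
    list(center = as.numeric(clamp$position + clamp$orientation %*% cl),
         orientation = clamp$orientation,
         half_extent = clamp$half_extent)
  })
}

#' Resolve particle-clamp collisions for one frame
#'
#' Applies the clamp interaction rules to the proposed particle positions:
#' captured particles are carried rigidly (world position = clamp pose applied
#' to their stored clamp-frame offset) while the jaws stay closed, and
#' released (keeping the proposed position) once the jaws open past the
#' threshold; free particles inside a closed jaw box are captured, recording
#' their clamp-frame coordinates; free particles inside an open jaw box are
#' pushed to the nearest box face (non-penetration); everything else passes
#' through untouched. Fixed particles are exempt.
#'
#' @param state An [mpm_state()].
#' @param x_tilde n x d proposed positions from [g2p()].
#' @param clamp_n,clamp_n1 [clamp_state()] poses at frames n and n+1 (`NULL`
#'   for no tool; `clamp_n` is accepted for signature symmetry, resolution
#'   uses the frame-(n+1) pose).
#' @return A list with `x_new`, `altered` (logical: clamp changed the
#'   position), `status`, `rel`.
#' @export
collide <- function(state, x_tilde, clamp_n = NULL, clamp_n1 = NULL) {
  p <- state$p
  d <- p$d
  n <- p$n
  x_new <- x_tilde
  altered <- rep(FALSE, n)
  status <- p$status
  rel <- p$rel
  if (is.null(clamp_n1)) {
    freed <- status == STATUS_CAPTURED
    status[freed] <- STATUS_FREE
    rel[freed, ] <- NA_real_
    return(list(x_new = x_new, altered = altered, status = status, rel = rel))
  }
  cl <- clamp_n1
  R <- cl$orientation
  closed <- cl$opening <= cl$closed_threshold

  cap <- which(status == STATUS_CAPTURED)
  if (length(cap) > 0L) {
    if (!closed) {
      status[cap] <- STATUS_FREE
      rel[cap, ] <- NA_real_
    } else {
      x_new[cap, ] <- rel[cap, , drop = FALSE] %*% t(R) +
        matrix(cl$position, length(cap), d, byrow = TRUE)
      altered[cap] <- TRUE
    }
  }

  free <- which(status == STATUS_FREE)
  if (length(free) > 0L) {
    L <- sweep(x_tilde[free, , drop = FALSE], 2L, cl$position) %*% R
    he <- cl$half_extent
    inside <- rep(FALSE, length(free))
    box_delta <- matrix(0, length(free), d)
    for (s in c(1, -1)) {
      delta <- L
      delta[, 2L] <- delta[, 2L] - s * cl$opening
      inb <- rep(TRUE, length(free))
      for (a in seq_len(d)) inb <- inb & abs(delta[, a]) <= he[a]
      newly <- inb & !inside
      box_delta[newly, ] <- delta[newly, , drop = FALSE]
      inside <- inside | inb
    }
    if (any(inside)) {
      hit <- free[inside]
      if (closed) {
        status[hit] <- STATUS_CAPTURED
        rel[hit, ] <- L[inside, , drop = FALSE]
        # captured at the intersection point itself: position unchanged
      } else {
        # push to the nearest face of the penetrated box, along one local axis
        dl <- box_delta[inside, , drop = FALSE]
        exit_dist <- sweep(-abs(dl), 2L, he, "+")
        ax <- max.col(-exit_dist, ties.method = "first")
        shift_local <- matrix(0, nrow(dl), d)
        ii <- cbind(seq_len(nrow(dl)), ax)
        sgn <- ifelse(dl[ii] >= 0, 1, -1)
        shift_local[ii] <- sgn * (he[ax] - abs(dl[ii]))
        x_new[hit, ] <- x_tilde[hit, , drop = FALSE] + shift_local %*% t(R)
        altered[hit] <- TRUE
      }
    }
  }
  list(x_new = x_new, altered = altered, status = status, rel = rel)
}

#' Read a clamp trajectory file
#'
#' Reads a CSV of time-stamped clamp keyframes with columns `time`, `px`,
#' `py` (and `pz` in 3-D), `angle` (2-D, radians), and `opening`.
#'
#' @param path CSV file path.
#' @param d Spatial dimension.
#' @return A data frame of class `clamp_trajectory`, sorted by time.
#' @export
read_clamp_trajectory <- function(path, d = 2L) {
  tr <- utils::read.csv(path)
  need <- c("time", paste0("p", c("x", "y", "z")[seq_len(d)]), "opening")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0L) {
    stop(sprintf("clamp trajectory is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"angle" %in% names(tr)) tr$angle <- 0
  tr <- tr[order(tr$time), , drop = FALSE]
  structure(tr, class = c("clamp_trajectory", "data.frame"))
}

#' Interpolate a clamp pose from a trajectory
#'
#' Piecewise-linear interpolation of position, opening and (2-D) angle
#' between keyframes; times outside the keyframe range clamp to the ends.
#'
#' @param traj A [read_clamp_trajectory()] data frame (or one built in code).
#' @param t Time (s).
#' @param half_extent,closed_threshold Passed to [clamp_state()].
#' @return A [clamp_state()].
#' @export
clamp_at <- function(traj, t, half_extent, closed_threshold) {
  tt <- traj$time
  t <- min(max(t, tt[1L]), tt[length(tt)])
  lin <- function(col) stats::approx(tt, traj[[col]], xout = t,
                                     ties = "ordered")$y
  d <- if ("pz" %in% names(traj)) 3L else 2L
  pos <- vapply(paste0("p", c("x", "y", "z")[seq_len(d)]), lin, numeric(1L))
  clamp_state(position = unname(pos), opening = lin("opening"),
              half_extent = half_extent, closed_threshold = closed_threshold,
              angle = lin("angle"))
}

#' Run a scripted clamp trajectory against a specimen
#'
#' Advances the simulation for `frames` frames, interpolating the clamp pose
#' from the trajectory at each frame boundary, and records the impulse-based
#' output force per frame.
#'
#' @param state An [mpm_state()].
#' @param traj A clamp trajectory data frame (see [read_clamp_trajectory()]).
#' @param frames Number of frames to run.
#' @param half_extent,closed_threshold Clamp box geometry.
#' @return A list with `state` (final) and `force_log` (data frame with
#'   `frame`, `time` and one force column per axis).
#' @export
run_clamp_trajectory <- function(state, traj, frames, half_extent,
                                 closed_threshold = 0.5 * min(half_extent)) {
  d <- state$cfg$d
  dt <- state$cfg$dt
  log <- matrix(0, frames, d)
  times <- numeric(frames)
  for (k in seq_len(frames)) {
    c_n <- clamp_at(traj, state$t, half_extent, closed_threshold)
    c_n1 <- clamp_at(traj, state$t + dt, half_extent, closed_threshold)
    out <- advance_frame(state, c_n, c_n1)
    state <- out$state
    log[k, ] <- out$force
    times[k] <- state$t
  }
  force_log <- data.frame(frame = seq_len(frames), time = times)
  for (a in seq_len(d)) force_log[[paste0("force_", c("x", "y", "z")[a])]] <- log[, a]
  list(state = state, force_log = force_log)
}
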