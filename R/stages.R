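#' Segment a tear curve into its deformation stages
#'
#' Partitions a tearing stress-strain curve into up to four stages:
#' elastic (A), plastic (B), tearing (C), and broken (D). The boundaries are
#' operational definitions of the qualitative stage descriptions:
#' \itemize{
#'   \item A/B: first persistent departure of the stress from the initial
#'     linear fit by more than 5\% relative residual (with an absolute floor
#'     of 1\% of the peak stress to avoid near-origin noise);
#'   \item B/C: end of the stress peak/plateau -- the last sample at or above
#'     99.5\% of the global maximum;
#'   \item C/D: first subsequent sample with stress below 10\% of the peak.
#' }
#' Fewer stages are returned when a boundary is never reached (for example a
#' purely linear curve is a single elastic stage).
#'
#' @param curve An `experiment_curve` (or any data frame with `strain` and
#'   `stress` columns), at least 20 samples.
#' @param smooth Width (samples) of the centered rolling mean applied to the
#'   stress before detection; 1 disables smoothing. Default 5, which rides
#'   out frame-scale oscillation without moving the stage boundaries by more
#'   than the window.
#' @return An object of class `stage_segmentation`: a data frame with one row
#'   per detected stage (`stage`, `label`, `start_strain`, `end_strain`) and
#'   attribute `breakpoints` (the strain values separating stages).
#' @examples
#' cur <- data.frame(strain = seq(0, 1, 0.01), stress = seq(0, 1, 0.01))
#' segment_stages(cur, smooth = 1)  # single elastic stage
#' @export
segment_stages <- function(curve, smooth = 5L) {
  if (!all(c("strain", "stress") %in% names(curve))) {
    stop("segment_stages: curve must have 'strain' and 'stress' columns",
         call. = FALSE)
  }
  n <- nrow(curve)
  if (n < 20L) {
    stop("segment_stages: curve too short (< 20 samples)", call. = FALSE)
  }
  strain <- curve$strain
  stress <- curve$stress
  s <- if (smooth > 1L) {
    stats::filter(stress, rep(1 / smooth, smooth), sides = 2L)
  } else {
    stress
  }
  s <- as.numeric(s)
  # rolling mean leaves NAs at the ends; fall back to raw values there
  s[is.na(s)] <- stress[is.na(s)]
  peak <- max(s)
  if (peak <= 0) {
    stop("segment_stages: curve has no positive stress; nothing to segment",
         call. = FALSE)
  }

  # initial linear fit over the low-stress window
  w_end <- which(s >= 0.3 * peak)[1L]
  if (is.na(w_end)) w_end <- n
  w_end <- max(w_end, 5L)
  fit <- stats::lm(y ~ x, data = data.frame(x = strain[seq_len(w_end)],
                                            y = s[seq_len(w_end)]))
  pred <- stats::predict(fit, newdata = data.frame(x = strain))

  resid <- abs(s - pred)
  thresh <- pmax(0.05 * abs(pred), 0.01 * peak)
  exceed <- resid > thresh
  exceed[seq_len(w_end)] <- FALSE
  # persistent departure: two consecutive exceedances
  run2 <- which(exceed & c(exceed[-1L], FALSE))
  i_ab <- if (length(run2) > 0L) run2[1L] - 1L else NA_integer_

  i_bc <- NA_integer_
  i_cd <- NA_integer_
  if (!is.na(i_ab)) {
    near_peak <- which(s >= 0.995 * peak)
    i_bc <- near_peak[length(near_peak)]
    if (i_bc <= i_ab) i_bc <- NA_integer_
  }
  if (!is.na(i_bc)) {
    post <- which(s < 0.10 * peak)
    post <- post[post > i_bc]
    if (length(post) > 0L) i_cd <- post[1L]
  }

  bounds <- c(i_ab, i_bc, i_cd)
  bounds <- bounds[!is.na(bounds)]
  labels <- c("elastic", "plastic", "tearing", "broken")[seq_len(length(bounds) + 1L)]
  starts <- strain[c(1L, bounds)]
  ends <- c(strain[bounds], strain[n])
  out <- data.frame(stage = LETTERS[seq_along(labels)],
                    label = labels,
                    start_strain = starts,
                    end_strain = ends)
  attr(out, "breakpoints") <- strain[bounds]
  class(out) <- c("stage_segmentation", "data.frame")
  out
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat(sprintf("Tear curve stages (%d detected):\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s (%s): strain %.4g to %.4g\n",
                x$stage[i], x$label[i], x$start_strain[i], x$end_strain[i]))
  }
  invisible(x)
}
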