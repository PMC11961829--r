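#' Hardened Lame coefficients
#'
#' The Lame coefficients are not constants but functions of the plastic volume
#' ratio `J_P = det(F_P)`: compaction (`J_P < 1`) stiffens the material and
#' dilatational plastic flow (`J_P > 1`) softens it, through
#' `mu = mu0 * exp(xi * (1 - J_P))` and likewise for `lambda`.
#'
#' @param J_P Plastic volume ratio(s), > 0. Vectorized.
#' @param params A [material_params()] object.
#' @return A list with numeric elements `mu` and `lambda` (Pa).
#' @examples
#' hardened_lame(1, material_params())         # returns (mu0, lambda0)
#' hardened_lame(0.9, material_params(xi = 10))
#' @export
hardened_lame <- function(J_P, params) {
  if (any(!is.finite(J_P)) || any(J_P <= 0)) {
    stop("hardened_lame: 'J_P' must be positive and finite", call. = FALSE)
  }
  h <- exp(params$xi * (1 - J_P))
  list(mu = params$mu0 * h, lambda = params$lambda0 * h)
}

#' Limit map for the elastic volume ratio
#'
#' Confines the elastic volume ratio to `[1 - theta_c, 1 + theta_s]` with a
#' viscous relaxation outside the range: the map is the identity inside the
#' range, and outside it moves `J` a fraction `k_c` (below) or `k_s` (above)
#' of the way back toward the nearest limit. Applied once per frame to the
#' elastic volume candidate, this yields a geometric per-frame decay of the
#' elastic excess -- the mechanism behind the model's creep and stress
#' relaxation. The map is continuous and, for `k_c, k_s` in \[0, 1\], monotone
#' non-decreasing.
#'
#' @param J Volume ratio(s), > 0. Vectorized.
#' @param params A [material_params()] object.
#' @return The limited elastic volume ratio(s) `J_E`.
#' @examples
#' p <- material_params(theta_c = 0.05, theta_s = 0.1, k_c = 0.5, k_s = 0.5)
#' clamp_volume_ratio(c(0.9, 1.0, 1.2), p)   # 0.925, 1.0, 1.15
#' @export
clamp_volume_ratio <- function(J, params) {
  if (any(!is.finite(J)) || any(J <= 0)) {
    stop("clamp_volume_ratio: 'J' must be positive and finite", call. = FALSE)
  }
  lo <- 1 - params$theta_c
  hi <- 1 + params$theta_s
  J_E <- J
  below <- J < lo
  above <- J > hi
  J_E[below] <- J[below] + params$k_c * (lo - J[below])
  J_E[above] <- J[above] - params$k_s * (J[above] - hi)
  J_E
}

#' Elastic-plastic split of the deformation gradient
#'
#' Decomposes a total deformation gradient `F` multiplicatively into an
#' elastic part `F_E` and a plastic part `F_P` (`F = F_E F_P`). The elastic
#' volume ratio is obtained by applying [clamp_volume_ratio()] to the elastic
#' candidate: the total volume ratio `J = det(F)` in stateless mode, or
#' `J / prior_J_P` in stateful mode, where `prior_J_P` is the particle's
#' persistent plastic volume ratio from the previous frame. The elastic
#' gradient is the volume-rescaled total gradient
#' `F_E = (J_E / J)^(1/d) F`, so that `det(F_E) = J_E` (set
#' `paper_literal = TRUE` for the unscaled-exponent variant `(J_E/J) F`),
#' and `F_P = F_E^{-1} F` is purely volumetric.
#'
#' @param F A d x d deformation gradient with positive determinant.
#' @param prior_J_P Plastic volume ratio carried from the previous frame
#'   (ignored in stateless mode).
#' @param params A [material_params()] object.
#' @param paper_literal Use the literal rescaling `F_E = (J_E/J) F`.
#' @return An object of class `deformation_split` with elements `F_E`, `F_P`,
#'   `J`, `J_E`, `J_P`.
#' @examples
#' split_deformation(diag(2), 1, material_params())
#' @export
split_deformation <- function(F, prior_J_P = 1, params = material_params(),
                              paper_literal = FALSE) {
  F <- as.matrix(F)
  d <- nrow(F)
  if (ncol(F) != d || !d %in% c(2L, 3L)) {
    stop("split_deformation: 'F' must be a 2x2 or 3x3 matrix", call. = FALSE)
  }
  if (any(!is.finite(F))) stop("split_deformation: non-finite 'F'", call. = FALSE)
  J <- det(F)
  if (J <= 0) stop("split_deformation: 'F' must have positive determinant", call. = FALSE)
  if (prior_J_P <= 0) stop("split_deformation: 'prior_J_P' must be > 0", call. = FALSE)
  s <- split_deformation_vec(pm_from_matrix(F), prior_J_P, params, d,
                             paper_literal = paper_literal)
  structure(
    list(F_E = pm_to_matrix(s$F_E),
         F_P = pm_to_matrix(s$F_P),
         J = s$J, J_E = s$J_E, J_P = s$J_P),
    class = "deformation_split")
}

#' @export
print.deformation_split <- function(x, ...) {
  cat(sprintf("Deformation split: J = %.6g, J_E = %.6g, J_P = %.6g\n",
              x$J, x$J_E, x$J_P))
  invisible(x)
}

# Vectorized split over an n x d^2 collection. Returns F_E, F_P, J, J_E, J_P.
split_deformation_vec <- function(F, prior_J_P, params, d, paper_literal = FALSE) {
  J <- pm_det(F, d)
  stateful <- identical(params$plasticity_mode, "stateful")
  cand <- if (stateful) J / prior_J_P else J
  cand <- pmax(cand, 1e-6)
  J_E <- clamp_volume_ratio(cand, params)
  scale <- if (paper_literal) J_E / J else (J_E / J)^(1 / d)
  F_E <- F * scale
  J_P <- J / J_E
  # F_P = F_E^{-1} F = (1/scale) I, purely volumetric by construction
  F_P <- pm_identity(nrow(F), d) / scale
  list(F_E = F_E, F_P = F_P, J = J, J_E = J_E, J_P = J_P)
}

#' Strain-energy density of the viscoelastic-plastic Neo-Hookean model
#'
#' Evaluates `psi = mu(J_P)/2 (tr(F_E' F_E) - d) - mu(J_P) log(J_E)
#' + lambda(J_P)/2 log^2(J_E)` per unit reference volume, with the hardened
#' Lame coefficients of [hardened_lame()]. With `F_P = I` this reduces to the
#' plain compressible Neo-Hookean energy.
#'
#' @param split A `deformation_split` from [split_deformation()].
#' @param params A [material_params()] object.
#' @return Energy density (J/m^3 in 3-D; per unit depth in 2-D).
#' @examples
#' energy_density(split_deformation(diag(2)), material_params())  # 0 at rest
#' @export
energy_density <- function(split, params) {
  d <- nrow(split$F_E)
  if (split$J_E <= 0) stop("energy_density: 'J_E' must be > 0", call. = FALSE)
  lam <- hardened_lame(split$J_P, params)
  frob <- sum(split$F_E^2)
  lam$mu / 2 * (frob - d) - lam$mu * log(split$J_E) +
    lam$lambda / 2 * log(split$J_E)^2
}

#' First Piola-Kirchhoff stress
#'
#' The stress conjugate to the deformation gradient,
#' `P = mu(J_P) (F_E - F_E^{-T}) + lambda(J_P) log(J_E) F_E^{-T}`, the
#' gradient of [energy_density()] with respect to `F` within the elastic
#' (identity) branch of the volume-ratio limit map. At the rest state
#' (`F = I`) the stress vanishes exactly.
#'
#' @param split A `deformation_split` from [split_deformation()].
#' @param params A [material_params()] object.
#' @return A d x d first Piola-Kirchhoff stress matrix (Pa).
#' @examples
#' pk_stress(split_deformation(diag(2)), material_params())  # zero at rest
#' @export
pk_stress <- function(split, params) {
  d <- nrow(split$F_E)
  detE <- det(split$F_E)
  if (!is.finite(detE) || abs(detE) < 1e-300) {
    stop("pk_stress: singular elastic deformation gradient", call. = FALSE)
  }
  P <- pk_stress_vec(pm_from_matrix(split$F_E), split$J_E, split$J_P, params, d)
  pm_to_matrix(P)
}

# Vectorized stress over an n x d^2 elastic gradient collection.
pk_stress_vec <- function(F_E, J_E, J_P, params, d) {
  lam <- hardened_lame(J_P, params)
  FinvT <- pm_transpose(pm_inv(F_E, d), d)
  logJE <- log(pmax(J_E, 1e-6))
  lam$mu * (F_E - FinvT) + (lam$lambda * logJE) * FinvT
}
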