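# Particle-based elastic tissue: MLS displacement gradients,
# Green-Saint-Venant strain, Hooke stress, elastic and volume-conservation
# forces, and the rheological viscosity coefficient.

#' Elastic tissue parameter set
#'
#' @param young_E Young's modulus (Pa).
#' @param poisson_eta Poisson's ratio, in `[0, 0.5)`.
#' @param kv volume-conservation stiffness (Pa).
#' @param beta1,beta2 rheological viscosity constants of the elastic phase.
#' @param h_e elastic smoothing length (m), used for the reference-frame MLS
#'   neighborhoods (support `2 h_e`).
#' @return An `elastic_params` list.
#' @export
elastic_params <- function(young_E = 13e3, poisson_eta = 0.47, kv = 1.3e3,
                           beta1 = 1, beta2 = 0.5, h_e = 2e-5) {
  stopifnot_scalar_pos(young_E, "young_E")
  stopifnot_scalar_pos(h_e, "h_e")
  if (poisson_eta < 0 || poisson_eta >= 0.5) {
    abort("`poisson_eta` must lie in [0, 0.5)")
  }
  if (kv < 0) abort("`kv` must be >= 0")
  if (beta1 < 0) abort("`beta1` must be >= 0")
  structure(list(young_E = young_E, poisson_eta = poisson_eta, kv = kv,
                 beta1 = beta1, beta2 = beta2, h_e = h_e),
            class = "elastic_params")
}

#' Lame constants from Young's modulus and Poisson's ratio
#'
#' `lambda = E eta / ((1 + eta)(1 - 2 eta))`, `mu = E / (2 (1 + eta))`.
#'
#' @param young_E Young's modulus (Pa).
#' @param poisson_eta Poisson's ratio (`eta = 0.5` is singular and an error).
#' @return Named vector `c(lambda = ..., mu = ...)`.
#' @export
lame_constants <- function(young_E, poisson_eta) {
  if (poisson_eta >= 0.5) abort("poisson_eta = 0.5 makes lambda singular")
  c(lambda = young_E * poisson_eta / ((1 + poisson_eta) * (1 - 2 * poisson_eta)),
    mu = young_E / (2 * (1 + poisson_eta)))
}

#' Green-Saint-Venant strain (unhalved form)
#'
#' `eps = grad_u + grad_u^T + grad_u^T grad_u = J^T J - I` with
#' `J = I + grad_u` (the displacement Jacobian). The conventional 1/2
#' factor is deliberately absent; the effective stiffness difference is
#' absorbed into the estimated Young's modulus.
#'
#' @param grad_u `d x d` displacement Jacobian `du/dx`.
#' @return The symmetric `d x d` strain matrix.
#' @export
green_strain <- function(grad_u) {
  J <- diag(nrow(grad_u)) + grad_u
  t(J) %*% J - diag(nrow(grad_u))
}

#' Isotropic Hooke stress
#'
#' `sigma = lambda tr(eps) I + 2 mu eps` with the Lame constants of
#' [lame_constants()].
#'
#' @param eps symmetric strain matrix.
#' @param params an [elastic_params()] object.
#' @return The symmetric stress matrix (Pa).
#' @export
stress <- function(eps, params) {
  lc <- lame_constants(params$young_E, params$poisson_eta)
  lc["lambda"] * sum(diag(eps)) * diag(nrow(eps)) + 2 * lc["mu"] * eps
}

# Reference-configuration neighbor pairs for an elastic body.
elastic_pairs <- function(ref, h_e) {
  neighbor_pairs_cpp(ref, 2 * h_e)
}

# Full elastic pass over a body; the other operations are views into this.
elastic_state <- function(ref, disp, params, volumes, pairs = NULL,
                          reaction = TRUE) {
  ref <- as.matrix(ref); disp <- as.matrix(disp)
  if (is.null(pairs)) pairs <- elastic_pairs(ref, params$h_e)
  lc <- lame_constants(params$young_E, params$poisson_eta)
  volumes <- rep_len(volumes, nrow(ref))
  st <- elastic_compute_cpp(ref, disp, pairs, params$h_e, lc[["lambda"]],
                            lc[["mu"]], params$kv, volumes, ncol(ref),
                            reaction)
  st$pairs <- pairs
  st
}

#' MLS displacement gradient of one particle
#'
#' Moving least squares fit of the displacement Jacobian over the
#' reference-configuration neighborhood of particle `i`:
#' `grad_u = (sum_j du x_ij^T w_ij) A_i^{-1}` with
#' `A_i = sum_j x_ij x_ij^T w_ij`, `w_ij = W(|x_ij|, h_e)`. `A_i` receives a
#' Tikhonov ridge `1e-6 tr(A)/d I` when ill-conditioned; particles with
#' fewer than `d + 1` neighbors (or rank-deficient `A`) are flagged
#' degenerate and return a zero gradient.
#'
#' @param ref `n x d` reference positions.
#' @param disp `n x d` displacements.
#' @param i particle index (1-based).
#' @param params an [elastic_params()] object.
#' @return A list with `grad_u` (`d x d`) and `degenerate` (flag).
#' @export
mls_displacement_gradient <- function(ref, disp, i, params) {
  st <- elastic_state(ref, disp, params, volumes = 1, reaction = FALSE)
  d <- ncol(ref)
  list(grad_u = matrix(st$grad_u[i, ], d, d, byrow = TRUE),
       degenerate = st$degenerate[i])
}

#' Elastic forces of a particle body
#'
#' Per particle `f_i = -2 v_i J_i sigma_i d_i` with `d_i = A_i^{-1} b_i`,
#' `b_i = -sum_j x_ij w_ij`. With `reaction = TRUE` (default) each
#' neighborhood also applies the exact energy-gradient reactions
#' `f_j += -2 v_i J_i sigma_i A_i^{-1} x_ij w_ij`, so the body's total
#' elastic force vanishes (Newton's third law) and the forces are the
#' gradient of [elastic_energy()].
#'
#' @param ref `n x d` reference positions.
#' @param disp `n x d` displacements.
#' @param params an [elastic_params()] object.
#' @param volumes per-particle volumes `v_i = m_i / rho_i` (recycled).
#' @param pairs optional precomputed reference-frame pairs.
#' @param reaction distribute momentum-balancing reactions (default TRUE).
#' @return An `n x d` matrix of elastic forces (N).
#' @export
elastic_forces <- function(ref, disp, params, volumes, pairs = NULL,
                           reaction = TRUE) {
  elastic_state(ref, disp, params, volumes, pairs, reaction)$force_elastic
}

#' Volume-conservation forces
#'
#' Gradient forces of the volume energy
#' `U_v = sum_i v_i kv (det J_i - 1)^2 / 2`:
#' `f_i = -v_i kv (det J_i - 1) cof(J_i) d_i`, where `cof(J)` is the
#' cofactor matrix of the deformation Jacobian (its rows are the
#' cross-products of the other rows of `J` in 3D), with the same
#' energy-gradient reaction distribution as [elastic_forces()].
#'
#' @inheritParams elastic_forces
#' @return An `n x d` matrix of volume-restoration forces (N).
#' @export
volume_forces <- function(ref, disp, params, volumes, pairs = NULL,
                          reaction = TRUE) {
  elastic_state(ref, disp, params, volumes, pairs, reaction)$force_volume
}

#' Strain energy of an elastic body
#'
#' `U = sum_i v_i (eps_i : sigma_i) / 2` (tensor double contraction).
#'
#' @inheritParams elastic_forces
#' @param include_volume also add the volume energy
#'   `sum_i v_i kv (det J_i - 1)^2 / 2`.
#' @return The scalar energy (J).
#' @export
elastic_energy <- function(ref, disp, params, volumes, pairs = NULL,
                           include_volume = FALSE) {
  st <- elastic_state(ref, disp, params, volumes, pairs, reaction = FALSE)
  st$energy_elastic + if (include_volume) st$energy_volume else 0
}

#' Rheological pair viscosity coefficient
#'
#' `mu = beta1 (1 - cos^2(theta) |v_i - v_j| / |r_i - r_j|)^beta2` with
#' `theta` the angle between the relative velocity and the separation; the
#' base is clamped to `[0, 1]` before exponentiation, and `beta1` is
#' returned when the relative speed is negligible (`< 1e-12`).
#'
#' @param v_i,v_j particle velocities.
#' @param r_i,r_j particle positions (must differ).
#' @param beta1,beta2 rheology constants.
#' @return The pair viscosity coefficient.
#' @export
rheological_viscosity_coefficient <- function(v_i, v_j, r_i, r_j,
                                              beta1 = 1, beta2 = 0.5) {
  dr <- r_i - r_j
  if (sqrt(sum(dr^2)) < 1e-15) abort("coincident particle positions")
  pos <- rbind(r_i, r_j)
  vel <- rbind(v_i, v_j)
  rheo_mu_cpp(pos, vel, matrix(c(1L, 2L), 1L), beta1, beta2)[1]
}
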