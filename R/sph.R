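# SPH kernel machinery, density estimation and fluid forces.

pos_cols <- function(d) c("x", "y", "z")[seq_len(d)]
vel_cols <- function(d) c("vx", "vy", "vz")[seq_len(d)]

particle_dim <- function(particles) {
  if ("z" %in% names(particles)) 3L else 2L
}

particle_pos <- function(particles) {
  as.matrix(particles[, pos_cols(particle_dim(particles)), drop = FALSE])
}
particle_vel <- function(particles) {
  as.matrix(particles[, vel_cols(particle_dim(particles)), drop = FALSE])
}

#' Fluid parameter set
#'
#' @param rest_density rest density `rho0` (kg/m^dim); `NA` requests
#'   calibration from the initial particle lattice at scene creation.
#' @param K equation-of-state stiffness in `p = K (rho - rho0)`.
#' @param mu_f dynamic viscosity coefficient of fluid-fluid pairs.
#' @param h smoothing length (m); kernel support is `2 h`.
#' @param gravity gravity vector (m/s^2), e.g. `c(0, -9.81)`.
#' @param clamp_negative_pressure clamp `p < 0` to 0 (default on; avoids
#'   particle clumping under tension).
#' @return A `fluid_params` list.
#' @export
fluid_params <- function(rest_density = NA_real_, K = 1, mu_f = 0.1,
                         h = 2e-5, gravity = c(0, 0),
                         clamp_negative_pressure = TRUE) {
  stopifnot_scalar_pos(K, "K")
  stopifnot_scalar_pos(h, "h")
  if (mu_f < 0) abort("`mu_f` must be >= 0")
  structure(list(rest_density = rest_density, K = K, mu_f = mu_f, h = h,
                 gravity = gravity,
                 clamp_negative_pressure = clamp_negative_pressure),
            class = "fluid_params")
}

#' Cubic B-spline smoothing kernel
#'
#' The standard cubic spline with support radius `2 h`:
#' `W(q) = sigma_d (1 - 1.5 q^2 + 0.75 q^3)` for `0 <= q < 1`,
#' `sigma_d 0.25 (2 - q)^3` for `1 <= q < 2`, 0 beyond, with `q = |r| / h`,
#' `sigma_2D = 10 / (7 pi h^2)`, `sigma_3D = 1 / (pi h^3)`. The gradient is
#' analytic and the Laplacian uses the radial form
#' `W'' + (d - 1) W' / r`.
#'
#' @param rvec displacement vector(s): a length-`dim` vector or an
#'   `n x dim` matrix.
#' @param h smoothing length.
#' @param dim 2 or 3.
#' @return A list with `W` (vector), `gradW` (matrix) and `lapW` (vector).
#' @export
cubic_spline_kernel <- function(rvec, h, dim = 2L) {
  stopifnot_scalar_pos(h, "h")
  if (is.null(dim(rvec))) rvec <- matrix(rvec, nrow = 1L)
  kernel_cubic_cpp(rvec, h, as.integer(dim))
}

#' All particle pairs within an interaction radius
#'
#' Exact pair enumeration (strictly closer than `radius`) via a uniform
#' grid with cell size equal to the radius.
#'
#' @param positions `n x dim` matrix of particle positions (or a particle
#'   tibble with `x`, `y`\[, `z`\] columns).
#' @param radius interaction radius (typically `2 h`).
#' @return An integer matrix with two columns of 1-based particle indices,
#'   each unordered pair once.
#' @export
neighbor_search <- function(positions, radius) {
  stopifnot_scalar_pos(radius, "radius")
  if (is.data.frame(positions)) positions <- particle_pos(positions)
  neighbor_pairs_cpp(positions, radius)
}

#' SPH interpolation of a scattered quantity
#'
#' `A(at) = sum_j A_j (m_j / rho_j) W(at - r_j, h)`.
#'
#' @param samples tibble/data frame with position columns `x`, `y`\[, `z`\]
#'   and columns `quantity`, `mass`, `density`.
#' @param at length-`dim` evaluation position.
#' @param h smoothing length.
#' @return The interpolated value (0 for an empty neighborhood).
#' @export
sph_interpolate <- function(samples, at, h) {
  if (nrow(samples) == 0L) return(0)
  P <- particle_pos(samples)
  d <- ncol(P)
  rv <- sweep(P, 2L, at, "-")
  W <- cubic_spline_kernel(-rv, h, d)$W
  sum(samples$quantity * samples$mass / samples$density * W)
}

#' SPH densities
#'
#' `rho_i = sum_j m_j W(r_i - r_j, h)` including the self term `j = i`.
#'
#' @param particles particle tibble with positions and `mass`.
#' @param h smoothing length.
#' @param pairs optional precomputed [neighbor_search()] pairs at radius
#'   `2 h`.
#' @return The tibble with its `density` column updated.
#' @export
compute_densities <- function(particles, h, pairs = NULL) {
  P <- particle_pos(particles)
  if (is.null(pairs)) pairs <- neighbor_search(P, 2 * h)
  particles$density <- densities_cpp(P, particles$mass, pairs, h, ncol(P))
  particles
}

#' Pressure from density via the linear equation of state
#'
#' `p_i = K (rho_i - rho0)`, optionally clamping negative pressures to 0.
#'
#' @param particles particle tibble with `density` computed.
#' @param params a [fluid_params()] object (uses `K`, `rest_density`,
#'   `clamp_negative_pressure`).
#' @return The tibble with its `pressure` column updated.
#' @export
pressure_from_density <- function(particles, params) {
  p <- params$K * (particles$density - params$rest_density)
  if (isTRUE(params$clamp_negative_pressure)) p <- pmax(p, 0)
  particles$pressure <- p
  particles
}

#' Pairwise pressure forces
#'
#' Mean-pressure SPH pressure force with the particle-volume factor
#' symmetrized per pair, applied equal-and-opposite so momentum is conserved
#' exactly and compressed regions repel:
#' `f_pair = -(p_i + p_j)/2 (m_i/rho_i + m_j/rho_j)/2 gradW(r_i - r_j)`.
#'
#' @param particles particle tibble with `density` and `pressure` computed.
#' @param pairs neighbor pairs ([neighbor_search()] at radius `2 h`).
#' @param h smoothing length.
#' @return An `n x dim` matrix of accumulated forces.
#' @export
pressure_forces <- function(particles, pairs, h) {
  P <- particle_pos(particles)
  pressure_forces_cpp(P, particles$mass, particles$density,
                      particles$pressure, pairs, h, ncol(P))
}

#' Pairwise viscosity forces
#'
#' `f_i += sum_j mu_ij (v_j - v_i) (m_j / rho_j) lapW(r_i - r_j, h)`;
#' the pair coefficient is the constant fluid viscosity for fluid pairs or
#' the rheological coefficient ([rheological_viscosity_coefficient()]) for
#' elastic pairs.
#'
#' @param particles particle tibble with velocities and `density`.
#' @param pairs neighbor pairs.
#' @param mu_pair per-pair viscosity coefficients (recycled if length 1).
#' @param h smoothing length.
#' @return An `n x dim` matrix of accumulated forces.
#' @export
viscosity_forces <- function(particles, pairs, mu_pair, h) {
  P <- particle_pos(particles)
  V <- particle_vel(particles)
  mu_pair <- rep_len(mu_pair, nrow(pairs))
  viscosity_forces_cpp(P, V, particles$mass, particles$density, pairs,
                       mu_pair, h, ncol(P))
}
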