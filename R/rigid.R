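# Rigid-body aggregation/advancement and cross-phase coupling.

#' Coupling parameter set
#'
#' @param Kc coupling coefficient scaling the cross-phase kernel-gradient
#'   force `f = -Kc m_a m_b gradW`.
#' @param coupling_h interaction smoothing length (m); support `2 coupling_h`.
#' @return A `coupling_params` list.
#' @export
coupling_params <- function(Kc = 1e-6, coupling_h = 2e-5) {
  if (Kc < 0) abort("`Kc` must be >= 0")
  stopifnot_scalar_pos(coupling_h, "coupling_h")
  structure(list(Kc = Kc, coupling_h = coupling_h), class = "coupling_params")
}

rotation_matrix_2d <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

#' Construct a rigid body from member particles
#'
#' Aggregates member particles into a rigid body: center of mass, total
#' mass, and the inertia (scalar about the out-of-plane axis in 2D, the
#' full tensor about the center of mass in 3D) computed from the member
#' masses and positions.
#'
#' @param positions `n x d` member positions.
#' @param masses member masses.
#' @param particle_ids indices of the members in the owning particle store.
#' @param mode `"dynamic"` (integrates forces) or `"scripted"` (prescribed
#'   velocity, forces ignored).
#' @param scripted_velocity for scripted mode: a matrix/data frame whose
#'   first column is time and remaining columns the velocity components,
#'   interpreted as a piecewise-constant profile.
#' @param external_force constant body force (N) added every step in
#'   dynamic mode (e.g. the pressing force of the instrument).
#' @return A `rigid_body` object.
#' @export
rigid_body <- function(positions, masses, particle_ids = seq_len(nrow(positions)),
                       mode = c("dynamic", "scripted"),
                       scripted_velocity = NULL, external_force = NULL) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  d <- ncol(positions)
  masses <- rep_len(masses, nrow(positions))
  M <- sum(masses)
  com <- colSums(positions * masses) / M
  rel <- sweep(positions, 2L, com, "-")
  if (d == 2L) {
    inertia <- sum(masses * (rel[, 1]^2 + rel[, 2]^2))
    orientation <- 0
    omega <- 0
  } else {
    inertia <- matrix(0, 3L, 3L)
    for (i in seq_len(nrow(rel))) {
      r <- rel[i, ]
      inertia <- inertia + masses[i] * (sum(r^2) * diag(3L) - tcrossprod(r))
    }
    orientation <- c(1, 0, 0, 0)
    omega <- c(0, 0, 0)
  }
  if (mode == "dynamic" && d == 2L && inertia <= 0 && nrow(positions) > 1L) {
    abort("dynamic rigid body needs positive inertia")
  }
  structure(list(particle_ids = particle_ids, mass = M, com = com,
                 local = rel, masses = masses, orientation = orientation,
                 velocity = rep(0, d), omega = omega, inertia = inertia,
                 mode = mode, scripted_velocity = scripted_velocity,
                 external_force = external_force %||% rep(0, d), dim = d),
            class = "rigid_body")
}

#' Aggregate member forces into a resultant force and torque
#'
#' `F_total = sum_i f_i`; `torque = sum_i (x_i - x_r) x f_i` about the
#' center of mass (scalar z-component in 2D).
#'
#' @param body a [rigid_body()].
#' @param positions current `n x d` member positions.
#' @param forces `n x d` per-member forces.
#' @return A list with `F_total` and `torque`.
#' @export
rigid_aggregate <- function(body, positions, forces) {
  positions <- as.matrix(positions); forces <- as.matrix(forces)
  F_total <- colSums(forces)
  rel <- sweep(positions, 2L, body$com, "-")
  torque <- if (body$dim == 2L) {
    sum(rel[, 1] * forces[, 2] - rel[, 2] * forces[, 1])
  } else {
    colSums(cbind(rel[, 2] * forces[, 3] - rel[, 3] * forces[, 2],
                  rel[, 3] * forces[, 1] - rel[, 1] * forces[, 3],
                  rel[, 1] * forces[, 2] - rel[, 2] * forces[, 1]))
  }
  list(F_total = F_total, torque = torque)
}

scripted_velocity_at <- function(profile, t) {
  profile <- as.matrix(profile)
  row <- max(which(profile[, 1] <= t + 1e-15), 1L)
  profile[row, -1L]
}

#' Advance a rigid body by one time step
#'
#' Dynamic mode: symplectic Euler on linear and angular state with the
#' world-frame inertia (quaternion renormalized each step in 3D). Scripted
#' mode: position advanced by the prescribed piecewise-constant velocity,
#' forces ignored. Member particles follow the rigid transform exactly.
#'
#' @param body a [rigid_body()].
#' @param F_total,torque aggregated force and torque ([rigid_aggregate()]).
#' @param dt time step (> 0).
#' @param t current time (used by scripted profiles).
#' @return The advanced body, with `member_positions` and
#'   `member_velocities` attached.
#' @export
advance_rigid <- function(body, F_total, torque, dt, t = 0) {
  stopifnot_scalar_pos(dt, "dt")
  d <- body$dim
  if (body$mode == "scripted") {
    u <- scripted_velocity_at(body$scripted_velocity, t)
    body$velocity <- as.numeric(u)
    body$com <- body$com + body$velocity * dt
  } else {
    body$velocity <- body$velocity + (F_total + body$external_force) / body$mass * dt
    if (d == 2L) {
      body$omega <- body$omega + torque / body$inertia * dt
      body$orientation <- body$orientation + body$omega * dt
    } else {
      R <- quat_to_matrix(body$orientation)
      Iw <- R %*% body$inertia %*% t(R)
      body$omega <- body$omega + solve(Iw, torque) * dt
      w <- body$omega
      q <- body$orientation
      dq <- 0.5 * c(-sum(w * q[2:4]),
                    q[1] * w + c(w[2] * q[4] - w[3] * q[3],
                                 w[3] * q[2] - w[1] * q[4],
                                 w[1] * q[3] - w[2] * q[2]))
      body$orientation <- quat_normalize(q + dq * dt)
    }
    body$com <- body$com + body$velocity * dt
  }
  R <- if (d == 2L) rotation_matrix_2d(body$orientation) else quat_to_matrix(body$orientation)
  pos <- sweep(body$local %*% t(R), 2L, body$com, "+")
  rel <- sweep(pos, 2L, body$com, "-")
  vel <- if (d == 2L) {
    cbind(body$velocity[1] - body$omega * rel[, 2],
          body$velocity[2] + body$omega * rel[, 1])
  } else {
    w <- body$omega
    sweep(cbind(w[2] * rel[, 3] - w[3] * rel[, 2],
                w[3] * rel[, 1] - w[1] * rel[, 3],
                w[1] * rel[, 2] - w[2] * rel[, 1]), 2L, body$velocity, "+")
  }
  body$member_positions <- pos
  body$member_velocities <- vel
  body
}

#' Cross-phase coupling forces
#'
#' For every cross-phase pair `(a, b)` within support:
#' `f = -Kc m_a m_b gradW(r_a - r_b, coupling_h)`, applied `+f` to `a` and
#' `-f` to `b` (equal and opposite).
#'
#' @param particles particle tibble (positions + `mass`).
#' @param pairs pairs of particle indices across phases.
#' @param params a [coupling_params()] object.
#' @return A list with `forces` (`n x d` accumulated) and `pair_force`
#'   (per-pair force on the first pair member).
#' @export
coupling_forces <- function(particles, pairs, params) {
  P <- particle_pos(particles)
  coupling_forces_cpp(P, particles$mass, pairs, params$Kc,
                      params$coupling_h, ncol(P))
}

#' Momentum-conserving collision response
#'
#' Applies the pairwise coupling impulses to the velocities:
#' `v_a += (f / m_a) dt`, `v_b -= (f / m_b) dt`, so
#' `m_a dv_a + m_b dv_b = 0` per pair and total momentum is unchanged.
#'
#' @param velocities `n x d` velocity matrix.
#' @param masses particle masses.
#' @param pairs two-column pair index matrix.
#' @param pair_force per-pair forces on the first member (`m x d`).
#' @param dt time step.
#' @return The updated velocity matrix.
#' @export
apply_collision_response <- function(velocities, masses, pairs, pair_force, dt) {
  stopifnot_scalar_pos(dt, "dt")
  velocities <- as.matrix(velocities)
  for (k in seq_len(ncol(velocities))) {
    imp <- pair_force[, k] * dt
    velocities[, k] <- velocities[, k] +
      as.vector(tapply_add(imp / masses[pairs[, 1]], pairs[, 1], nrow(velocities))) -
      as.vector(tapply_add(imp / masses[pairs[, 2]], pairs[, 2], nrow(velocities)))
  }
  velocities
}

tapply_add <- function(values, idx, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
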