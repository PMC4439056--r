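# Time stepping and cross-section contour extraction.

#' Advance the scene by one time step
#'
#' Pipeline per step: neighbor search, fluid densities and equation-of-state
#' pressures, force accumulation (fluid pressure + viscosity, elastic +
#' volume forces with rheological viscosity, gravity), cross-phase coupling
#' applied through the momentum-conserving collision response, symplectic
#' Euler integration of fluid/elastic particles, rigid-body aggregation and
#' advancement, and tank boundary response (position clamp, normal velocity
#' zeroed). Deterministic: no randomness anywhere in the forward model.
#'
#' @param scene an [sph_scene()].
#' @return The advanced scene (with a per-step `audit` of momentum sums).
#' @export
scene_step <- function(scene) {
  d <- scene$dim
  n <- length(scene$mass)
  pos <- scene$pos; vel <- scene$vel; mass <- scene$mass
  h <- scene$fluid$h
  ch <- scene$coupling$coupling_h
  eb <- scene$elastic
  h_e <- if (!is.null(eb)) eb$params$h_e else h
  beta1 <- if (!is.null(eb)) eb$params$beta1 else 0
  beta2 <- if (!is.null(eb)) eb$params$beta2 else 1
  sf <- scene_forces_cpp(pos, vel, mass, scene$phase_code, scene$density, h,
                         scene$fluid$rest_density, scene$fluid$K,
                         isTRUE(scene$fluid$clamp_negative_pressure),
                         scene$fluid$mu_f, beta1, beta2, h_e,
                         scene$coupling$Kc, ch, d)
  dens <- sf$dens
  free <- scene$phase_code != 3L

  # true-force accumulator (elastic + volume forces), a = f / m
  F <- matrix(0, n, d)
  audit <- list(pressure_force_sum = colSums(sf$F_press),
                coupling_force_sum = colSums(sf$F_coup),
                sph_force_sum = colSums(sf$F_sph))
  if (!is.null(eb)) {
    disp <- pos[eb$idx, , drop = FALSE] - eb$ref
    lc <- lame_constants(eb$params$young_E, eb$params$poisson_eta)
    es <- elastic_compute_cpp(eb$ref, disp, eb$pairs, h_e,
                              lc[["lambda"]], lc[["mu"]], eb$params$kv,
                              eb$volumes, d, TRUE)
    F[eb$idx, ] <- F[eb$idx, ] + es$force_elastic + es$force_volume
    audit$elastic_force_sum <- colSums(es$force_elastic + es$force_volume)
  }

  # coupling -> momentum-conserving response on fluid/elastic velocities;
  # rigid members collect theirs through body aggregation below
  vel[free, ] <- vel[free, ] +
    sf$F_coup[free, , drop = FALSE] / mass[free] * scene$dt

  # symplectic Euler: SPH force densities as a = f/rho, elastic as a = f/m,
  # gravity as a constant acceleration
  acc <- sf$F_sph[free, , drop = FALSE] / dens[free] +
    F[free, , drop = FALSE] / mass[free]
  if (isTRUE(scene$gravity_on)) {
    acc <- sweep(acc, 2L, scene$fluid$gravity, "+")
  }
  vel[free, ] <- vel[free, ] + acc * scene$dt
  pos[free, ] <- pos[free, ] + vel[free, , drop = FALSE] * scene$dt
  if (!all(is.finite(pos)) || !all(is.finite(vel))) {
    abort(sprintf("non-finite particle state at step %d (t = %g s)",
                  scene$step_count + 1L, scene$t))
  }

  # rigid bodies
  for (bi in seq_along(scene$bodies)) {
    body <- scene$bodies[[bi]]
    ids <- body$particle_ids
    fb <- sf$F_coup[ids, , drop = FALSE]
    if (isTRUE(scene$gravity_on) && body$mode == "dynamic") {
      fb <- fb + outer(mass[ids], scene$fluid$gravity)
    }
    agg <- rigid_aggregate(body, pos[ids, , drop = FALSE], fb)
    body <- advance_rigid(body, agg$F_total, agg$torque, scene$dt, scene$t)
    pos[ids, ] <- body$member_positions
    vel[ids, ] <- body$member_velocities
    body$member_positions <- NULL
    body$member_velocities <- NULL
    scene$bodies[[bi]] <- body
  }

  # tank boundary: clamp + zero the inward normal velocity (restitution 0)
  for (k in seq_len(d)) {
    lo <- scene$tank$min[k]; hi <- scene$tank$max[k]
    below <- free & pos[, k] < lo
    above <- free & pos[, k] > hi
    pos[below, k] <- lo
    vel[below, k] <- pmax(vel[below, k], 0)
    pos[above, k] <- hi
    vel[above, k] <- pmin(vel[above, k], 0)
  }

  if (!all(is.finite(pos)) || !all(is.finite(vel))) {
    abort(sprintf("non-finite particle state at step %d (t = %g s)",
                  scene$step_count + 1L, scene$t))
  }
  scene$pos <- pos
  scene$vel <- vel
  scene$density <- dens
  scene$pressure <- sf$pres
  scene$t <- scene$t + scene$dt
  scene$step_count <- scene$step_count + 1L
  scene$audit <- audit
  scene
}

#' Run a scene and emit cross-section contours
#'
#' Steps the scene `n_steps` times, extracting the elastic-phase
#' cross-section contour every `output_every` steps (after an optional
#' warm-up). Deterministic given the scene.
#'
#' @param scene an [sph_scene()].
#' @param n_steps number of steps after warm-up.
#' @param output_every emit a contour frame every this many steps.
#' @param warmup steps to run before the first frame window.
#' @param snapshots also collect particle tables at each frame.
#' @param phase phase whose cross-section is contoured.
#' @return A list with `scene` (final state), `contours` (tibble `frame`,
#'   `point_index`, `x`, `y` in raster pixels), and optionally `snapshots`.
#' @export
scene_run <- function(scene, n_steps, output_every = 10L, warmup = 0L,
                      snapshots = FALSE, phase = "elastic") {
  if (n_steps < 1) abort("`n_steps` must be >= 1")
  for (s in seq_len(warmup)) scene <- scene_step(scene)
  frames <- list()
  snaps <- list()
  frame_no <- 0L
  for (s in seq_len(n_steps)) {
    scene <- scene_step(scene)
    if (s %% output_every == 0L) {
      frame_no <- frame_no + 1L
      cs <- extract_cross_section(scene, phase = phase)
      frames[[frame_no]] <- dplyr::mutate(cs$contour, frame = frame_no,
                                          .before = 1L)
      if (snapshots) snaps[[frame_no]] <- scene_particles(scene)
    }
  }
  out <- list(scene = scene,
              contours = if (length(frames)) dplyr::bind_rows(frames) else
                tibble::tibble(frame = integer(), point_index = integer(),
                               x = numeric(), y = numeric()))
  if (snapshots) out$snapshots <- snaps
  out
}

#' Extract a cross-section mask and contour from a scene
#'
#' Kernel-splats the selected phase's particle volumes onto the calibrated
#' raster and takes the iso-line of the continuous splat field at
#' `threshold_frac` of the rest-state interior plateau (sub-pixel, via
#' [grDevices::contourLines()]; the largest closed loop is returned). The
#' binary mask is the thresholded field.
#'
#' @param scene an [sph_scene()].
#' @param phase particle phase to contour.
#' @param plane_z cross-section plane (3D scenes only; defaults to the
#'   phase's mean z).
#' @return A list with `mask` (logical `ny x nx` matrix), `contour`
#'   (tibble, raster pixel units) and `field` (the splat field).
#' @export
extract_cross_section <- function(scene, phase = "elastic", plane_z = NULL) {
  rs <- scene$raster
  f <- splat_phase(scene, phase, rs$x0, rs$y0, rs$spacing, rs$nx, rs$ny,
                   plane_z = plane_z)
  plateau <- rs$plateau
  if (is.na(plateau) || phase != "elastic") plateau <- median(f[f > 0.5 * max(f)])
  level <- rs$threshold_frac * plateau
  cl <- contourLines(x = seq_len(rs$nx) - 1, y = seq_len(rs$ny) - 1,
                     z = t(f), levels = level)
  if (!length(cl)) abort("cross-section produced no contour at the iso-level")
  areas <- vapply(cl, function(p) abs(polygon_area(p$x, p$y)), 1.0)
  best <- cl[[which.max(areas)]]
  ctr <- as_contour_tbl(best$x, best$y)
  if (polygon_area(ctr$x, ctr$y) < 0) {
    ctr <- as_contour_tbl(rev(best$x), rev(best$y))
  }
  list(mask = f >= level, contour = ctr, field = f)
}

#' Convert raster-pixel contour coordinates to physical units
#'
#' @param contour contour tibble in raster pixel units.
#' @param scene the owning scene (for raster origin/spacing).
#' @return The contour tibble with `x`, `y` in meters.
#' @export
contour_to_physical <- function(contour, scene) {
  rs <- scene$raster
  dplyr::mutate(contour, x = rs$x0 + .data$x * rs$spacing,
                y = rs$y0 + .data$y * rs$spacing)
}
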