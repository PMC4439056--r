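# Scene assembly: particle store, parameter sets, tank, rigid bodies,
# cross-section raster calibration.

#' Assemble a multiphase SPH scene
#'
#' Builds the simulation state from a particle table and the per-phase
#' parameter sets. Elastic bodies are bound to their initial (reference)
#' configuration: MLS neighborhoods, reference densities and per-particle
#' volumes are precomputed there. The fluid rest density, when not given,
#' is calibrated so the initial fluid lattice is stress-free. A raster for
#' cross-section extraction is calibrated once on the undeformed elastic
#' body.
#'
#' @param particles tibble with columns `id`, `phase`
#'   (`"fluid"`/`"elastic"`/`"rigid"`), `x`, `y`\[, `z`\],
#'   `vx`, `vy`\[, `vz`\], `mass`.
#' @param fluid a [fluid_params()] object.
#' @param elastic an [elastic_params()] object.
#' @param coupling a [coupling_params()] object.
#' @param bodies list of rigid-body specs: each a list with `ids` (particle
#'   ids), `mode`, and optionally `scripted_velocity` or `external_force`.
#' @param tank list with `min` and `max` corner vectors of the axis-aligned
#'   box.
#' @param dt time step (s).
#' @param gravity_on apply `fluid$gravity` to fluid/elastic particles and
#'   dynamic rigid bodies.
#' @param raster_spacing raster pixel spacing (m) for cross-section
#'   extraction; default `fluid$h / 2`.
#' @param threshold_frac iso-level as a fraction of the calibrated interior
#'   plateau of the kernel-splat field.
#' @return An `sph_scene` object.
#' @export
sph_scene <- function(particles, fluid = fluid_params(),
                      elastic = elastic_params(),
                      coupling = coupling_params(), bodies = list(),
                      tank = NULL, dt = 5e-6, gravity_on = FALSE,
                      raster_spacing = NULL, threshold_frac = 0.5) {
  stopifnot_scalar_pos(dt, "dt")
  d <- particle_dim(particles)
  pos <- particle_pos(particles)
  vel <- particle_vel(particles)
  dimnames(pos) <- dimnames(vel) <- NULL
  n <- nrow(pos)
  phase <- particles$phase
  mass <- particles$mass
  if (any(mass <= 0)) abort("particle masses must be positive")
  if (is.null(tank)) {
    pad <- 4 * fluid$h
    tank <- list(min = apply(pos, 2L, min) - pad,
                 max = apply(pos, 2L, max) + pad)
  }
  if (any(sweep(pos, 2L, tank$min, "<")) || any(sweep(pos, 2L, tank$max, ">"))) {
    abort("all particles must start inside the tank")
  }
  density <- rep(NA_real_, n)
  idxf <- which(phase == "fluid")
  idxe <- which(phase == "elastic")
  idxr <- which(phase == "rigid")
  elastic_block <- NULL
  if (length(idxe)) {
    ref <- pos[idxe, , drop = FALSE]
    pairs_e <- elastic_pairs(ref, elastic$h_e)
    rho_e <- densities_cpp(ref, mass[idxe], pairs_e, elastic$h_e, d)
    elastic_block <- list(idx = idxe, ref = ref, pairs = pairs_e,
                          params = elastic, ref_density = rho_e,
                          volumes = mass[idxe] / rho_e)
    density[idxe] <- rho_e
  }
  if (length(idxf)) {
    pairs_f <- neighbor_pairs_cpp(pos[idxf, , drop = FALSE], 2 * fluid$h)
    rho_f <- densities_cpp(pos[idxf, , drop = FALSE], mass[idxf], pairs_f,
                           fluid$h, d)
    # interior lattice density (edge particles are kernel-deficient), so the
    # undisturbed interior starts exactly stress-free
    if (is.na(fluid$rest_density)) fluid$rest_density <- max(rho_f)
    density[idxf] <- rho_f
  }
  if (length(idxr)) {
    # nominal lattice density so m / rho is the lattice cell volume
    density[idxr] <- mass[idxr] / fluid$h^d
  }
  body_objs <- purrr::map(bodies, function(b) {
    ids <- match(b$ids, particles$id)
    rigid_body(pos[ids, , drop = FALSE], mass[ids], particle_ids = ids,
               mode = b$mode %||% "dynamic",
               scripted_velocity = b$scripted_velocity,
               external_force = b$external_force)
  })
  scene <- structure(list(
    dim = d, id = particles$id, phase = phase,
    phase_code = match(phase, c("fluid", "elastic", "rigid")),
    pos = pos, vel = vel,
    mass = mass, density = density, pressure = rep(0, n),
    fluid = fluid, elastic = elastic_block, coupling = coupling,
    bodies = body_objs, tank = tank, dt = dt, gravity_on = gravity_on,
    t = 0, step_count = 0L, audit = NULL
  ), class = "sph_scene")
  scene$raster <- calibrate_raster(scene, raster_spacing %||% (fluid$h / 2),
                                   threshold_frac)
  scene
}

# Raster covering the tank; plateau calibrated on the undeformed elastic
# splat (median of values above half the maximum).
calibrate_raster <- function(scene, spacing, threshold_frac) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    abort("`threshold_frac` must lie in (0, 1)")
  }
  # pad beyond the tank so splat fields decay below any iso-level before the
  # raster boundary (open iso-lines would otherwise appear at the edges)
  pad <- 2.5 * max(scene$fluid$h,
                   if (!is.null(scene$elastic)) scene$elastic$params$h_e else 0)
  x0 <- scene$tank$min[1] - pad; y0 <- scene$tank$min[2] - pad
  nx <- max(32L, ceiling((scene$tank$max[1] + pad - x0) / spacing) + 1L)
  ny <- max(32L, ceiling((scene$tank$max[2] + pad - y0) / spacing) + 1L)
  plateau <- NA_real_
  if (!is.null(scene$elastic)) {
    f <- splat_phase(scene, "elastic", x0, y0, spacing, nx, ny)
    plateau <- median(f[f > 0.5 * max(f)])
  }
  list(x0 = x0, y0 = y0, spacing = spacing, nx = nx, ny = ny,
       threshold_frac = threshold_frac, plateau = plateau)
}

splat_phase <- function(scene, phase, x0, y0, spacing, nx, ny, plane_z = NULL) {
  idx <- which(scene$phase == phase)
  if (!length(idx)) abort(sprintf("no particles of phase '%s'", phase))
  pos <- scene$pos[idx, , drop = FALSE]
  vol <- scene$mass[idx] / scene$density[idx]
  h <- if (phase == "elastic") scene$elastic$params$h_e else scene$fluid$h
  if (scene$dim == 3L) {
    z0 <- plane_z %||% mean(pos[, 3])
    keep <- abs(pos[, 3] - z0) < 2 * h
    if (!any(keep)) abort("no particles within 2h of the cross-section plane")
    pos <- pos[keep, , drop = FALSE]
    vol <- vol[keep]
  }
  splat_field_cpp(pos[, 1:2, drop = FALSE], vol, h, x0, y0, spacing,
                  as.integer(nx), as.integer(ny), scene$dim)
}

#' Particle table view of a scene
#'
#' @param scene an [sph_scene()].
#' @return A tibble with `id`, `phase`, positions, velocities, `mass`,
#'   `density`, `pressure`.
#' @export
scene_particles <- function(scene) {
  d <- scene$dim
  out <- tibble::tibble(id = scene$id, phase = scene$phase)
  for (k in seq_len(d)) out[[pos_cols(d)[k]]] <- scene$pos[, k]
  for (k in seq_len(d)) out[[vel_cols(d)[k]]] <- scene$vel[, k]
  out$mass <- scene$mass
  out$density <- scene$density
  out$pressure <- scene$pressure
  out
}

#' @export
print.sph_scene <- function(x, ...) {
  cat(sprintf("SPH scene (%dD): %d particles (%d fluid, %d elastic, %d rigid), t = %g s\n",
              x$dim, length(x$mass), sum(x$phase == "fluid"),
              sum(x$phase == "elastic"), sum(x$phase == "rigid"), x$t))
  invisible(x)
}

# Write/read particle snapshots as CSV.

#' Write a particle snapshot CSV
#' @param scene an [sph_scene()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_snapshot_csv <- function(scene, path) {
  write.csv(scene_particles(scene), path, row.names = FALSE)
  invisible(path)
}
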