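# Seeded synthetic data: speckled phantom images with ground-truth masks,
# template particle scenes, and observation contour series from forward
# simulation with known parameters.

#' Specification of a synthetic ultrasound-like phantom
#'
#' Describes a low-SNR speckled two-region image with a weak-edge target:
#' a radially perturbed disc, multiplicative unit-mean gamma speckle, a
#' smooth multiplicative bias field and Gaussian blur.
#'
#' @param size `c(rows, cols)` image size.
#' @param center target center `(x, y)` in pixels; default image center.
#' @param radius mean target radius (px).
#' @param boundary_amp relative amplitude of the low-order harmonic
#'   boundary perturbation (0 = perfect circle).
#' @param interior,exterior mean intensities of target and background
#'   (0-255).
#' @param bias_amp amplitude of the smooth multiplicative intensity
#'   inhomogeneity (fraction of 1).
#' @param bias_scale length-scale of the bias field (px).
#' @param speckle_shape gamma shape parameter of the unit-mean
#'   multiplicative speckle; smaller = noisier; `Inf` = no speckle.
#' @param blur_sd Gaussian blur std (px); 0 = none.
#' @param seed mandatory RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(96, 96), center = NULL, radius = 28,
                         boundary_amp = 0.08, interior = 160, exterior = 60,
                         bias_amp = 0.15, bias_scale = 48,
                         speckle_shape = 8, blur_sd = 1, seed) {
  if (missing(seed)) abort("`seed` is mandatory for phantom generation")
  if (interior < 0 || interior > 255 || exterior < 0 || exterior > 255) {
    abort("intensities must lie in [0, 255]")
  }
  structure(list(size = size, center = center %||% (rev(size - 1) / 2),
                 radius = radius, boundary_amp = boundary_amp,
                 interior = interior, exterior = exterior,
                 bias_amp = bias_amp, bias_scale = bias_scale,
                 speckle_shape = speckle_shape, blur_sd = blur_sd,
                 seed = as.integer(seed)), class = "phantom_spec")
}

#' Generate a phantom image with its ground-truth mask
#'
#' Builds `clip( blur( bias_field x piecewise_means x speckle ) )` with the
#' mask taken from the analytic target shape. Fully reproducible from the
#' spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom` object: list with `image` (matrix, 0-255), `mask`
#'   (logical matrix) and `spec`.
#' @export
generate_phantom <- function(spec) {
  nr <- spec$size[1]; nc <- spec$size[2]
  with_seed(spec$seed, {
    px <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    py <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
    dx <- px - spec$center[1]; dy <- py - spec$center[2]
    rho <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    coef <- rnorm(3)
    coef <- coef / max(1, sqrt(sum(coef^2)))
    pert <- coef[1] * sin(2 * th) + coef[2] * cos(3 * th) + coef[3] * sin(4 * th)
    rad <- spec$radius * (1 + spec$boundary_amp * pert)
    mask <- rho < rad
    img <- ifelse(mask, spec$interior, spec$exterior)
    if (spec$bias_amp > 0) {
      dir <- runif(1, 0, 2 * pi)
      ph0 <- runif(1, 0, 2 * pi)
      bias <- 1 + spec$bias_amp *
        cos(2 * pi * (px * cos(dir) + py * sin(dir)) / spec$bias_scale + ph0)
      img <- img * bias
    }
    if (is.finite(spec$speckle_shape)) {
      img <- img * matrix(rgamma(nr * nc, shape = spec$speckle_shape,
                                 rate = spec$speckle_shape), nr, nc)
    }
    if (spec$blur_sd > 0) img <- gaussian_smooth(img, spec$blur_sd)
    img <- pmin(pmax(img, 0), 255)
    structure(list(image = img, mask = mask, spec = spec), class = "phantom")
  })
}

#' Write a phantom to disk (image PNG, mask PNG, spec JSON)
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(phantom$image / 255, file.path(dir, "image.png"))
  write_mask_png(phantom$mask, file.path(dir, "mask.png"))
  jsonlite::write_json(unclass(phantom$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Default parameter set of the particle framework
#'
#' The essential parameters of the multiphase model with their defaults,
#' free/fixed flags and bounds: external force F (N), Young's modulus E
#' (Pa), Poisson's ratio, smoothing length h (m), particle mass m (kg), the
#' rheology constants beta1/beta2, the volume-conservation stiffness kv
#' (Pa) and the coupling coefficient Kc.
#'
#' @param external_force,young_E,poisson_eta,h,particle_mass,beta1,beta2,kv,Kc
#'   parameter values.
#' @return A `parameter_set` tibble with columns `name`, `value`, `free`,
#'   `lower`, `upper`.
#' @export
default_parameters <- function(external_force = 0.25, young_E = 13e3,
                               poisson_eta = 0.47, h = 2e-5,
                               particle_mass = 3e-5, beta1 = 1, beta2 = 0.5,
                               kv = 1.3e3, Kc = 1e-6) {
  ps <- tibble::tibble(
    name = c("external_force", "young_E", "poisson_eta", "h",
             "particle_mass", "beta1", "beta2", "kv", "Kc"),
    value = c(external_force, young_E, poisson_eta, h, particle_mass,
              beta1, beta2, kv, Kc),
    free = FALSE,
    lower = c(0.05, 3e3, 0.3, 1e-5, 1e-5, 0.1, 0.1, 1e2, 1e-7),
    upper = c(1.0, 40e3, 0.49, 5e-5, 1e-4, 5, 2, 1e4, 1e-5)
  )
  class(ps) <- c("parameter_set", class(ps))
  ps
}

#' Mark parameters as free for estimation
#' @param params a [default_parameters()] tibble.
#' @param names parameter names to free.
#' @return The updated parameter set.
#' @export
set_free <- function(params, names) {
  bad <- setdiff(names, params$name)
  if (length(bad)) abort(sprintf("unknown parameters: %s", paste(bad, collapse = ", ")))
  params$free <- params$name %in% names
  params
}

#' Named vector of parameter values
#' @param params a [default_parameters()] tibble.
#' @return A named numeric vector.
#' @export
param_values <- function(params) setNames(params$value, params$name)

#' Set parameter values (clipped to bounds)
#' @param params a [default_parameters()] tibble.
#' @param values named numeric vector of new values.
#' @return The updated parameter set.
#' @export
set_param_values <- function(params, values) {
  idx <- match(names(values), params$name)
  params$value[idx] <- pmin(pmax(unname(values), params$lower[idx]),
                            params$upper[idx])
  params
}

#' Build a template scene
#'
#' Known templates: `"pressed_block_2d"` — a rectangular elastic tissue
#' block on the tank floor, flanked and capped by fluid, with a rigid bar
#' above the block that presses down under a constant external force
#' (`mode = "forced"`) or a prescribed velocity (`mode = "scripted"`).
#' Particle counts scale from the reference experiment's 4399/3344/120
#' (fluid/elastic/rigid) by `scale`.
#'
#' @param template template name.
#' @param scale particle-count scale factor relative to the reference
#'   experiment.
#' @param params a [default_parameters()] set supplying the physical
#'   parameter values.
#' @param bar_mode `"forced"` (constant downward force `external_force`) or
#'   `"scripted"` (constant downward velocity `bar_speed`).
#' @param bar_speed bar speed (m/s) for scripted mode.
#' @param dt time step (s).
#' @param seed recorded for provenance (the lattice construction itself is
#'   deterministic).
#' @return An [sph_scene()].
#' @export
generate_scene <- function(template = "pressed_block_2d", scale = 0.25,
                           params = default_parameters(),
                           bar_mode = c("forced", "scripted"),
                           bar_speed = 0.05, dt = 5e-6, seed = NULL) {
  if (!template %in% "pressed_block_2d") {
    abort(sprintf("unknown scene template '%s'", template))
  }
  bar_mode <- match.arg(bar_mode)
  pv <- param_values(params)
  h <- pv[["h"]]
  m <- pv[["particle_mass"]]
  n_e <- max(16L, round(3344 * scale))
  n_f <- max(16L, round(4399 * scale))
  n_r <- max(4L, round(120 * scale))
  blk_h <- max(4L, round(sqrt(n_e / 2.1)))
  blk_w <- max(4L, round(n_e / blk_h))
  margin <- 9L
  tank_w <- blk_w + 2L * margin
  tank_h <- blk_h + 26L
  at <- function(i) (i + 0.5) * h
  # elastic block on the floor
  eg <- expand.grid(i = margin + seq_len(blk_w) - 1L, j = seq_len(blk_h) - 1L)
  block_top <- at(blk_h - 1L)
  # rigid bar, two rows, narrower than the block, just inside coupling reach
  bar_w <- max(2L, ceiling(n_r / 2))
  bar_x0 <- margin + floor((blk_w - bar_w) / 2)
  bar_y <- block_top + 1.5 * h
  bg <- expand.grid(i = bar_x0 + seq_len(bar_w) - 1L, j = 0:1)
  bg <- bg[seq_len(n_r), ]
  rg <- data.frame(x = at(bg$i), y = bar_y + bg$j * h)
  # fluid fills the tank outside a protective corridor, bottom-up
  fx <- expand.grid(i = seq_len(tank_w) - 1L, j = seq_len(tank_h) - 1L)
  corridor <- fx$i >= margin - 2L & fx$i < margin + blk_w + 2L &
    at(fx$j) < bar_y + 6 * h
  fx <- fx[!corridor, , drop = FALSE]
  fx <- fx[order(fx$j, fx$i), , drop = FALSE]
  if (nrow(fx) < n_f) {
    abort("template cannot host the requested fluid count; reduce scale")
  }
  fx <- fx[seq_len(n_f), ]
  particles <- dplyr::bind_rows(
    tibble::tibble(phase = "fluid", x = at(fx$i), y = at(fx$j)),
    tibble::tibble(phase = "elastic", x = at(eg$i), y = at(eg$j)),
    tibble::tibble(phase = "rigid", x = rg$x, y = rg$y)
  )
  particles <- dplyr::mutate(particles, id = dplyr::row_number(),
                             vx = 0, vy = 0, mass = m, .before = 1L)
  bar_ids <- particles$id[particles$phase == "rigid"]
  body <- if (bar_mode == "forced") {
    list(ids = bar_ids, mode = "dynamic",
         external_force = c(0, -pv[["external_force"]]))
  } else {
    list(ids = bar_ids, mode = "scripted",
         scripted_velocity = cbind(t = 0, vx = 0, vy = -bar_speed))
  }
  tank <- list(min = c(0, 0), max = c(tank_w * h, tank_h * h))
  scene <- sph_scene(
    particles,
    fluid = fluid_params(h = h, gravity = c(0, -9.81)),
    elastic = elastic_params(young_E = pv[["young_E"]],
                             poisson_eta = pv[["poisson_eta"]],
                             kv = pv[["kv"]], beta1 = pv[["beta1"]],
                             beta2 = pv[["beta2"]], h_e = h),
    coupling = coupling_params(Kc = pv[["Kc"]], coupling_h = h),
    bodies = list(body), tank = tank, dt = dt, gravity_on = FALSE
  )
  attr(scene, "template") <- list(template = template, scale = scale,
                                  counts = c(fluid = n_f, elastic = n_e,
                                             rigid = n_r),
                                  bar_mode = bar_mode, seed = seed,
                                  bar_contact = c(x = mean(rg$x), y = block_top))
  scene
}

#' Specification of a synthetic observation series
#'
#' @param truth a [default_parameters()] set: the ground-truth parameter
#'   values `K*` used by the forward simulation.
#' @param template,scale scene template arguments ([generate_scene()]).
#' @param n_frames number of observed frames (>= 4).
#' @param frame_to_step simulator steps per observed frame.
#' @param warmup steps before the first frame.
#' @param jitter_sd observation noise std (raster px) applied along contour
#'   normals.
#' @param seed mandatory RNG seed.
#' @return An `observation_spec` list.
#' @export
observation_spec <- function(truth = default_parameters(),
                             template = "pressed_block_2d", scale = 0.25,
                             n_frames = 18L, frame_to_step = 25L,
                             warmup = 50L, jitter_sd = 0, seed) {
  if (missing(seed)) abort("`seed` is mandatory for observation generation")
  if (n_frames < 4) abort("`n_frames` must be >= 4")
  structure(list(truth = truth, template = template, scale = scale,
                 n_frames = as.integer(n_frames),
                 frame_to_step = as.integer(frame_to_step),
                 warmup = as.integer(warmup), jitter_sd = jitter_sd,
                 seed = as.integer(seed)), class = "observation_spec")
}

# Outward-ish normals of a closed contour (unit, perpendicular to the
# central-difference tangent).
contour_normals <- function(contour) {
  P <- contour_points(contour)
  n <- nrow(P)
  nxt <- P[c(2:n, 1L), ]; prv <- P[c(n, 1:(n - 1L)), ]
  tng <- nxt - prv
  len <- pmax(sqrt(rowSums(tng^2)), 1e-12)
  cbind(tng[, 2] / len, -tng[, 1] / len)
}

#' Generate an observation contour series by forward simulation
#'
#' Simulates the template scene with the truth parameters, extracts a
#' cross-section contour every `frame_to_step` steps, optionally adds
#' independent per-point normal jitter, and splits the frames half/half
#' into a training series and a validation series.
#'
#' @param spec an [observation_spec()].
#' @return A list with `train` (a `training_series`: `frames` tibble,
#'   `reference` contour, `region_a` indices, `frame_to_step`),
#'   `validation` (contour-series tibble), `truth`, `scene` (final state)
#'   and `spec`.
#' @export
generate_observation_series <- function(spec) {
  scene <- generate_scene(spec$template, spec$scale, spec$truth)
  for (s in seq_len(spec$warmup)) scene <- scene_step(scene)
  reference <- extract_cross_section(scene)$contour
  run <- scene_run(scene, n_steps = spec$n_frames * spec$frame_to_step,
                   output_every = spec$frame_to_step)
  contours <- run$contours
  if (spec$jitter_sd > 0) {
    contours <- with_seed(spec$seed, {
      dplyr::bind_rows(purrr::map(split(contours, contours$frame), function(cf) {
        nrm <- contour_normals(cf)
        jit <- rnorm(nrow(cf), sd = spec$jitter_sd)
        dplyr::mutate(cf, x = .data$x + jit * nrm[, 1],
                      y = .data$y + jit * nrm[, 2])
      }))
    })
  }
  n_train <- ceiling(spec$n_frames / 2)
  train_frames <- contours[contours$frame <= n_train, ]
  validation <- contours[contours$frame > n_train, ]
  contact <- attr(scene, "template")$bar_contact
  rs <- run$scene$raster
  contact_px <- c((contact[["x"]] - rs$x0) / rs$spacing,
                  (contact[["y"]] - rs$y0) / rs$spacing)
  region_a <- tracked_region(reference, contact_px, frac = 0.3)
  train <- structure(list(frames = train_frames, reference = reference,
                          region_a = region_a,
                          frame_to_step = spec$frame_to_step,
                          warmup = spec$warmup), class = "training_series")
  list(train = train, validation = validation, truth = spec$truth,
       scene = run$scene, spec = spec)
}

#' Tracked contour region nearest a contact point
#'
#' Selects the fraction of reference-contour points nearest the
#' force-bearing contact point; these are the points whose displacements
#' drive the estimation discrepancy.
#'
#' @param reference reference contour tibble.
#' @param contact `(x, y)` contact point in the contour's coordinates.
#' @param frac fraction of points to keep.
#' @return Integer indices into the reference contour rows.
#' @export
tracked_region <- function(reference, contact, frac = 0.3) {
  P <- contour_points(reference)
  d <- sqrt((P[, 1] - contact[1])^2 + (P[, 2] - contact[2])^2)
  k <- max(3L, ceiling(frac * nrow(P)))
  sort(order(d)[seq_len(k)])
}
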