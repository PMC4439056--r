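# Iterative contour-matching parameter estimation: fit the particle
# framework's free parameters to a training series of contours, then
# predict subsequent frames.

#' Signed displacement set of tracked contour points
#'
#' For each tracked point `a` of the reference contour, the displacement of
#' the frame contour: the signed distance from `a` to the nearest point of
#' `contour_t` (resampled to 1 px), with the sign taken along the reference
#' contour normal at `a`. One value per tracked point.
#'
#' @param contour_t frame contour tibble.
#' @param contour_ref reference contour tibble.
#' @param region_a integer indices of tracked points into `contour_ref`.
#' @return Numeric vector of signed displacement magnitudes (px), length
#'   `length(region_a)`.
#' @export
displacement_set <- function(contour_t, contour_ref, region_a) {
  if (nrow(contour_t) == 0L || nrow(contour_ref) == 0L) abort("empty contour")
  P <- contour_points(contour_ref)[region_a, , drop = FALSE]
  nrm <- contour_normals(contour_ref)[region_a, , drop = FALSE]
  Q <- resample_polyline(contour_t, 1)
  out <- numeric(nrow(P))
  for (k in seq_len(nrow(P))) {
    d2 <- (Q[, 1] - P[k, 1])^2 + (Q[, 2] - P[k, 2])^2
    j <- which.min(d2)
    dv <- Q[j, ] - P[k, ]
    out[k] <- sign(sum(dv * nrm[k, ])) * sqrt(d2[j])
  }
  out
}

#' Discrepancy between predicted and observed displacement sets
#'
#' `S_t = sum_k |Dhat_t[k] - D_t[k]|`.
#'
#' @param d_hat,d displacement vectors of equal length.
#' @return The non-negative discrepancy (px).
#' @export
discrepancy <- function(d_hat, d) {
  if (length(d_hat) != length(d)) abort("displacement sets differ in length")
  sum(abs(d_hat - d))
}

# Observed displacement sets D_t for frames 1..n of a training series.
observed_displacements <- function(series) {
  frames <- sort(unique(series$frames$frame))
  purrr::map(setNames(frames, frames), function(f) {
    displacement_set(series$frames[series$frames$frame == f, ],
                     series$reference, series$region_a)
  })
}

# Simulate frames 1..t_max under `values` and return the S_i vector.
# Memoized per estimation call on the parameter values.
make_discrepancy_evaluator <- function(series, scene_builder) {
  D_obs <- observed_displacements(series)
  cache <- new.env(parent = emptyenv())
  n_sims <- 0L
  evaluate <- function(values, t_max) {
    key <- paste(format(values, digits = 15), t_max, sep = "|", collapse = "|")
    if (!is.null(got <- cache[[key]])) return(got)
    scene <- scene_builder(values)
    for (s in seq_len(series$warmup)) scene <- scene_step(scene)
    run <- scene_run(scene, n_steps = t_max * series$frame_to_step,
                     output_every = series$frame_to_step)
    S <- vapply(seq_len(t_max), function(t) {
      ct <- run$contours[run$contours$frame == t, ]
      discrepancy(displacement_set(ct, series$reference, series$region_a),
                  D_obs[[as.character(t)]])
    }, 1.0)
    n_sims <<- n_sims + 1L
    cache[[key]] <- S
    S
  }
  list(evaluate = evaluate, sims = function() n_sims)
}

#' Initialize the parameter set on a coarse grid
#'
#' Deterministic log-spaced grid (5 points per free parameter within its
#' bounds), scanned in order; returns the first grid point whose first-frame
#' discrepancy satisfies `S_1 <= T/2`.
#'
#' @param series a `training_series` (see [generate_observation_series()]).
#' @param scene_builder function mapping a named parameter-value vector to
#'   an [sph_scene()].
#' @param params a [default_parameters()] set with free flags and bounds.
#' @param T_threshold acceptance threshold `T` (px).
#' @param evaluator internal: a shared discrepancy evaluator.
#' @return The parameter set at the accepted grid point, with the achieved
#'   `S_1` attached as attribute `S1`.
#' @export
initialize_parameters <- function(series, scene_builder, params, T_threshold,
                                  evaluator = NULL) {
  stopifnot_scalar_pos(T_threshold, "T_threshold")
  free <- which(params$free)
  if (!length(free)) abort("at least one parameter must be free")
  ev <- evaluator %||% make_discrepancy_evaluator(series, scene_builder)
  grids <- purrr::map(free, function(i) {
    exp(seq(log(params$lower[i]), log(params$upper[i]), length.out = 5L))
  })
  combos <- as.matrix(expand.grid(grids))
  colnames(combos) <- params$name[free]
  for (g in seq_len(nrow(combos))) {
    values <- param_values(set_param_values(params, combos[g, ]))
    S1 <- ev$evaluate(values, 1L)[1]
    if (S1 <= T_threshold / 2) {
      out <- set_param_values(params, combos[g, ])
      attr(out, "S1") <- S1
      return(out)
    }
  }
  abort("no grid point achieves S_1 <= T/2; widen the bounds or increase T")
}

#' Adjust parameters until all frame discrepancies pass
#'
#' Deterministic coordinate descent over the free parameters in their
#' declared order: multiplicative perturbations (starting at +/-20%, halved
#' on non-improvement of `max_i S_i`), clipped to bounds, until all
#' `S_i <= T` for frames `1..t_max` or the evaluation budget is exhausted
#' (then an error carrying the best parameters and residuals).
#'
#' @inheritParams initialize_parameters
#' @param t_max number of frames to fit.
#' @param budget maximum number of forward simulations for this call.
#' @return The adjusted parameter set (attribute `S` holds the final
#'   discrepancies).
#' @export
adjust <- function(series, scene_builder, params, T_threshold, t_max,
                   budget = 60L, evaluator = NULL) {
  ev <- evaluator %||% make_discrepancy_evaluator(series, scene_builder)
  free <- which(params$free)
  cur <- params
  used <- 0L
  S <- ev$evaluate(param_values(cur), t_max); used <- used + 1L
  obj <- max(S)
  step <- setNames(rep(0.2, length(free)), params$name[free])
  while (any(S > T_threshold) && used < budget) {
    improved_any <- FALSE
    for (i in free) {
      nm <- cur$name[i]
      for (dir in c(1, -1)) {
        if (used >= budget || all(S <= T_threshold)) break
        cand <- set_param_values(cur, setNames(cur$value[i] * (1 + dir * step[nm]), nm))
        if (identical(cand$value[i], cur$value[i])) next  # clipped to bound
        S_c <- ev$evaluate(param_values(cand), t_max); used <- used + 1L
        if (max(S_c) < obj) {
          cur <- cand; S <- S_c; obj <- max(S_c)
          improved_any <- TRUE
        }
      }
    }
    if (!improved_any) {
      step <- step / 2
      if (all(step < 1e-4)) break
    }
  }
  if (any(S > T_threshold)) {
    abort(message = sprintf(
      "adjustment budget exhausted with max S_i = %.3g > T = %.3g", max(S),
      T_threshold), class = "hifumotion_adjust_failure", best = cur,
      residuals = S)
  }
  attr(cur, "S") <- S
  cur
}

#' Iterative parameter estimation from a training contour series
#'
#' The stepwise algorithm: initialize the free parameters so the
#' first-frame discrepancy satisfies `S_1 <= T/2`; then for each later
#' frame `t`, keep the current estimate if all `S_i <= T` for `i <= t`,
#' otherwise adjust over the frames seen so far. On exit every training
#' frame satisfies `S_t <= T`.
#'
#' @inheritParams initialize_parameters
#' @return A `motion_fit` object: `parameters` (estimated set), `records`
#'   (tibble `t`, `S_t`, `accepted`), `T_threshold`, `n_sims`, plus the
#'   series and builder for downstream prediction.
#' @export
estimate_parameters <- function(series, scene_builder, params, T_threshold) {
  frames <- sort(unique(series$frames$frame))
  n <- length(frames)
  if (n < 2) abort("need at least 2 training frames")
  ev <- make_discrepancy_evaluator(series, scene_builder)
  cur <- initialize_parameters(series, scene_builder, params, T_threshold,
                               evaluator = ev)
  records <- list()
  for (t in 2:n) {
    S <- ev$evaluate(param_values(cur), t)
    accepted <- all(S <= T_threshold)
    if (!accepted) {
      cur <- adjust(series, scene_builder, cur, T_threshold, t, evaluator = ev)
      S <- attr(cur, "S")
    }
    records[[t - 1L]] <- tibble::tibble(t = t, S_t = S[t], accepted = accepted)
  }
  S_final <- ev$evaluate(param_values(cur), n)
  structure(list(parameters = cur, records = dplyr::bind_rows(records),
                 S_final = S_final, T_threshold = T_threshold,
                 n_sims = ev$sims(), series = series,
                 scene_builder = scene_builder), class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  est <- x$parameters[x$parameters$free, ]
  cat(sprintf("Motion-model fit: %d free parameter(s), %d forward simulations\n",
              nrow(est), x$n_sims))
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-15s %.6g\n", est$name[i], est$value[i]))
  }
  cat(sprintf("  max S_t = %.3g (T = %.3g)\n", max(x$S_final), x$T_threshold))
  invisible(x)
}

#' Predict a contour series with a parameter set
#'
#' Forward-simulates the scene built from the parameter values and emits
#' `n_frames` cross-section contour frames (an empty series for
#' `n_frames = 0`).
#'
#' @param params parameter set (or a `motion_fit`, whose estimate is used).
#' @param scene_builder function mapping named values to a scene (taken
#'   from the fit when `params` is a `motion_fit`).
#' @param n_frames number of frames to emit.
#' @param frame_to_step steps per frame.
#' @param warmup steps before the first frame.
#' @return A contour-series tibble (`frame`, `point_index`, `x`, `y`).
#' @export
predict_motion <- function(params, scene_builder = NULL, n_frames,
                           frame_to_step = 10L, warmup = 20L) {
  if (inherits(params, "motion_fit")) {
    scene_builder <- scene_builder %||% params$scene_builder
    frame_to_step <- params$series$frame_to_step
    warmup <- params$series$warmup
    params <- params$parameters
  }
  if (n_frames == 0L) {
    return(tibble::tibble(frame = integer(), point_index = integer(),
                          x = numeric(), y = numeric()))
  }
  scene <- scene_builder(param_values(params))
  for (s in seq_len(warmup)) scene <- scene_step(scene)
  scene_run(scene, n_steps = n_frames * frame_to_step,
            output_every = frame_to_step)$contours
}
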