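# Displacement sets, discrepancies and the iterative estimation algorithm.

circle_contour <- function(R = 10, n = 72, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  hifumotion:::as_contour_tbl(cx + R * cos(th), cy + R * sin(th))
}

test_that("displacement sets are zero for identical contours and track shifts", {
  ref <- circle_contour()
  expect_equal(displacement_set(ref, ref, 1:10), rep(0, 10), tolerance = 1e-9)
  moved <- dplyr::mutate(ref, x = x + 3)
  # leading-edge points (near theta = 0) move outward by ~3
  lead <- which(ref$x > 9.5)
  D <- displacement_set(moved, ref, lead)
  expect_equal(length(D), length(lead))
  expect_equal(abs(D), rep(3, length(lead)), tolerance = 0.5)
})

test_that("discrepancy is the summed absolute difference", {
  expect_equal(discrepancy(c(1, 2), c(0.5, 2.5)), 1.0)
  expect_equal(discrepancy(1:5, 1:5), 0)
  a <- runif(6); b <- runif(6); p <- sample(6)
  expect_equal(discrepancy(a[p], b[p]), discrepancy(a, b))
  expect_error(discrepancy(1:3, 1:4), "length")
})

# A reduced-scale estimation setting shared by the algorithm tests.
make_setting <- function(seed = 7, n_frames = 6) {
  obs <- generate_observation_series(
    observation_spec(scale = 0.1, n_frames = n_frames, frame_to_step = 15L,
                     warmup = 30L, seed = seed))
  builder <- function(values) {
    generate_scene("pressed_block_2d", 0.1,
                   set_param_values(default_parameters(), values))
  }
  list(obs = obs, builder = builder)
}

test_that("initialization scans the grid and respects the S1 <= T/2 rule", {
  st <- make_setting()
  params <- set_free(default_parameters(), "external_force")
  # huge T: the very first grid point (the lower bound) passes vacuously
  init <- initialize_parameters(st$obs$train, st$builder, params,
                                T_threshold = 1e6)
  expect_equal(init$value[init$name == "external_force"],
               params$lower[params$name == "external_force"])
  expect_lte(attr(init, "S1"), 1e6 / 2)
  # bounds excluding the truth with a tiny T: no grid point can pass
  bad <- params
  bad$lower[bad$name == "external_force"] <- 0.9
  bad$upper[bad$name == "external_force"] <- 1.0
  bad$value[bad$name == "external_force"] <- 0.95
  expect_error(initialize_parameters(st$obs$train, st$builder, bad,
                                     T_threshold = 1e-4), "grid")
  expect_error(initialize_parameters(st$obs$train, st$builder,
                                     default_parameters(), 1),
               "free")
})

test_that("adjust returns promptly when all frames already pass", {
  st <- make_setting()
  truth <- set_free(default_parameters(), "external_force")
  out <- adjust(st$obs$train, st$builder, truth, T_threshold = 1,
                t_max = 3)
  expect_equal(param_values(out), param_values(truth))
  expect_true(all(attr(out, "S") <= 1))
})

test_that("estimation is deterministic and satisfies its own acceptance rule", {
  st <- make_setting()
  params <- set_free(default_parameters(), "external_force")
  Tthr <- 0.05 * length(st$obs$train$region_a)
  f1 <- estimate_parameters(st$obs$train, st$builder, params, Tthr)
  f2 <- estimate_parameters(st$obs$train, st$builder, params, Tthr)
  expect_identical(param_values(f1$parameters), param_values(f2$parameters))
  expect_true(all(f1$S_final <= Tthr))
  # independent re-audit: fresh evaluator, same parameters
  ev <- hifumotion:::make_discrepancy_evaluator(st$obs$train, st$builder)
  S <- ev$evaluate(param_values(f1$parameters),
                   max(st$obs$train$frames$frame))
  expect_true(all(S <= Tthr))
  # broom-style surfaces
  expect_true(all(c("name", "estimate", "free") %in% names(tidy(f1))))
  expect_true(glance(f1)$all_accepted)
})

test_that("a noisy series still terminates within the scaled threshold", {
  obs <- generate_observation_series(
    observation_spec(scale = 0.1, n_frames = 4, frame_to_step = 15L,
                     warmup = 30L, jitter_sd = 0.5, seed = 11))
  builder <- function(values) {
    generate_scene("pressed_block_2d", 0.1,
                   set_param_values(default_parameters(), values))
  }
  params <- set_free(default_parameters(), "external_force")
  Tthr <- length(obs$train$region_a) * 3 * 0.5  # |A| * 3 sigma
  fit <- estimate_parameters(obs$train, builder, params, Tthr)
  expect_true(all(fit$S_final <= Tthr))
})

test_that("prediction with zero frames yields an empty series", {
  st <- make_setting()
  params <- default_parameters()
  out <- predict_motion(params, st$builder, n_frames = 0)
  expect_equal(nrow(out), 0L)
})

test_that("truth-parameter prediction reproduces the truth-generated frames", {
  st <- make_setting(seed = 13, n_frames = 4)
  pred <- predict_motion(default_parameters(), st$builder, n_frames = 4,
                         frame_to_step = 15L, warmup = 30L)
  shape <- c(st$obs$scene$raster$ny, st$obs$scene$raster$nx)
  truth_all <- dplyr::bind_rows(st$obs$train$frames, st$obs$validation)
  rep <- evaluate_contour_series(pred, truth_all, shape)
  expect_gte(min(rep$dsc[rep$frame %in% as.character(1:4)]), 0.99)
})
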