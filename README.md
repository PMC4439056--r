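# hifumotion

Modeling and predicting soft-tissue motion and deformation during
ultrasound-guided high intensity focused ultrasound (HIFU) therapy.

During HIFU ablation the target tissue (a tumor, or an experimental tissue
sample in a water tank) moves and deforms under external force, so the
treatment focus must be re-aimed continuously. hifumotion implements the
computational chain that makes that prediction possible:

1. **Segmentation** — a geodesic localized Chan–Vese (GLCV) level-set model
   for speckled, low-contrast, intensity-inhomogeneous ultrasound-like
   images. The localized fitting flow
   `∂φ/∂t = δ(φ)[∫ B(x,y) δ(φ(y)) ((I−c_x2)² − (I−c_x1)²) dy + μ κ]`
   is gated with a geodesic flow `t(x) δ(φ)[g|∇φ|κ + ∇g·∇φ + α g|∇φ|]`
   wherever the local means are uniform (`|c_x1 − c_x2| < κ₁`), so the
   balloon force crosses flat regions and the localized fit locks onto
   edges.
2. **Simulation** — a multiphase smoothed particle hydrodynamics (SPH)
   framework coupling fluid (cubic-spline kernel, `p = K(ρ − ρ₀)` equation
   of state, viscosity), elastic tissue (moving-least-squares displacement
   gradients, unhalved Green–Saint-Venant strain `ε = JᵀJ − I`, Hooke
   stress, volume-conservation forces, rheological pair viscosity
   `β₁(1 − cos²θ |Δv|/|Δr|)^β₂`) and rigid bodies (the pressing
   instrument), with momentum-conserving kernel-gradient coupling
   `f = −K_c m_a m_b ∇W`.
3. **Estimation** — the iterative contour-matching algorithm: initialize the
   free parameters so the first-frame discrepancy satisfies `S₁ ≤ T/2`,
   then accept or adjust frame by frame until every training frame satisfies
   `S_t ≤ T`, where `S_t` sums absolute displacement differences over the
   tracked contour region near the contact point.
4. **Metrics** — Dice similarity coefficient, symmetric mean squared
   nearest-point distance (MSSD) and Hausdorff distance between contours.
5. **Synthetic data** — seeded generators for speckle phantoms with ground
   truth masks, template particle scenes, and observation contour series
   from forward simulation with known parameters.

## A worked example

Segment a speckled phantom, then recover the pressing force from a
forward-simulated observation series:

```r
library(hifumotion)

# --- segmentation ----------------------------------------------------------
phantom <- generate_phantom(phantom_spec(seed = 101))
fit <- glcv_segment(phantom$image,
                    contour_init("ellipse", center = c(47.5, 47.5),
                                 semi_axes = c(14, 14)),
                    glcv_params(alpha = 0.15, kappa1 = 25))
dice(fit$mask, phantom$mask)
#> [1] 0.9875383
glance(fit)
#> # A tibble: 1 x 5
#>   iterations converged area_px perimeter_px energy
#>        <int> <lgl>       <int>        <dbl>  <dbl>
#> 1        800 FALSE        2421          244   739.

# --- estimation ------------------------------------------------------------
obs <- generate_observation_series(
  observation_spec(scale = 0.25, n_frames = 18, seed = 7))
builder <- function(values) {
  generate_scene("pressed_block_2d", 0.25,
                 set_param_values(default_parameters(), values))
}
fit <- estimate_parameters(obs$train, builder,
                           set_free(default_parameters(), "external_force"),
                           T_threshold = 0.03 * length(obs$train$region_a))
fit
#> Motion-model fit: 1 free parameter(s), 21 forward simulations
#>   external_force  0.25357
#>   max S_t = 1.03 (T = 2.28)
```

The recovered force (0.254 N against a ground truth of 0.25 N) then predicts
the held-out validation frames:

```r
pred <- predict_motion(fit, n_frames = 18)
shape <- c(obs$scene$raster$ny, obs$scene$raster$nx)
evaluate_contour_series(pred[pred$frame > 9, ], obs$validation, shape)
#>    frame       dsc         mssd hausdorff
#> 1     10 0.9997094 1.031743e-03 0.4387041
#> 2     11 0.9998547 2.575033e-04 0.4856537
#> ...
#> 10   min 0.9995630 2.511930e-05 0.0120019
#> 11   max 1.0000000 1.332916e-03 0.4856537
#> 12  mean 0.9998380 4.668241e-04 0.3070140
```

A mean validation Dice of ≈1.0 says the one-parameter fit reproduces the
truth-generated contours essentially exactly at this scale. `autoplot()`
methods exist for segmentations, phantoms and motion fits, and
`tidy()`/`glance()` return tabular summaries.

The full workflow (segment → observe → estimate → predict → evaluate) is
wrapped in `pipeline_run(pipeline_config(seed = 5))`, and a thin
command-line wrapper lives at `inst/cli/hifu-motion.R`.

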