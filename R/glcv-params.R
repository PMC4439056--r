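#' Parameters of the GLCV level-set segmenter
#'
#' Bundles the tunable constants of the geodesic localized Chan-Vese flow.
#' All lengths are in pixels and intensities on the 0-255 scale.
#'
#' @param r local-window radius of the characteristic function B(x, y)
#'   (pixels); the localized means are computed over the disc `||x - y|| < r`.
#' @param kappa1 uniformity threshold on the local mean contrast
#'   `|c_x1 - c_x2|`; below it the point is treated as low-contrast and the
#'   geodesic (edge-driven) term is switched on.
#' @param mu weight of the contour-length penalty (curvature term). The
#'   default scales with the squared intensity range so the two energy terms
#'   are commensurate.
#' @param alpha balloon-force constant of the geodesic term; positive grows
#'   the contour (phi >= 0 inside), negative shrinks it.
#' @param sigma standard deviation (pixels) of the Gaussian smoothing used by
#'   the edge-stopping function g.
#' @param eps regularization width of the smoothed Heaviside/Dirac pair.
#' @param dt evolution step size (CFL fraction when the update is
#'   max-normalized, see [glcv_step()]).
#' @param max_iter iteration cap of the segmentation loop.
#' @param reinit_every period (iterations) of signed-distance
#'   reinitialization.
#' @param band_width half-width (pixels) of the narrow band around the zero
#'   level set on which updates are applied; must exceed `r`.
#' @param patience number of consecutive iterations with an unchanged
#'   interface sign pattern required to declare convergence.
#'
#' @return An object of class `glcv_params` (a named list).
#' @export
glcv_params <- function(r = 9, kappa1 = 10, mu = 255^2, alpha = -0.5,
                        sigma = 1.5, eps = 1.0, dt = 0.2, max_iter = 800L,
                        reinit_every = 20L, band_width = r + 3, patience = 30L) {
  stopifnot_scalar_pos(kappa1, "kappa1")
  stopifnot_scalar_pos(sigma, "sigma")
  stopifnot_scalar_pos(eps, "eps")
  stopifnot_scalar_pos(dt, "dt")
  if (r < 1) abort("`r` must be >= 1")
  if (band_width <= r) abort("`band_width` must exceed `r`")
  structure(list(r = r, kappa1 = kappa1, mu = mu, alpha = alpha,
                 sigma = sigma, eps = eps, dt = dt,
                 max_iter = as.integer(max_iter),
                 reinit_every = as.integer(reinit_every),
                 band_width = band_width, patience = as.integer(patience)),
            class = "glcv_params")
}

#' @export
print.glcv_params <- function(x, ...) {
  cat("GLCV parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

validate_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix of intensities")
  }
  if (nrow(image) < 16 || ncol(image) < 16) abort("image must be at least 16x16")
  if (!all(is.finite(image))) abort("image intensities must be finite")
  image
}
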