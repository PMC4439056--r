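#' Regularized Heaviside and Dirac pair
#'
#' Smooth arctan-based surrogates for the step and impulse used by the
#' level-set region integrals: `H_eps(z) = 1/2 (1 + 2/pi atan(z/eps))` and
#' its derivative `delta_eps(z) = eps / (pi (eps^2 + z^2))`.
#'
#' @param z numeric vector/matrix of level-set values.
#' @param eps regularization width (> 0).
#' @return A list with elements `H` and `delta`, each the shape of `z`.
#' @export
heaviside_dirac <- function(z, eps = 1.0) {
  stopifnot_scalar_pos(eps, "eps")
  list(H = 0.5 * (1 + (2 / pi) * atan(z / eps)),
       delta = eps / (pi * (eps^2 + z^2)))
}

# Sum of m over the strict disc ||offset|| < r with edge replication.
# Row-decomposed: for each vertical offset dy the admissible horizontal
# offsets form a run [-kx, kx], summed with a cumulative box filter.
conv_disc <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- ceiling(r) - 1L
  ri <- pmin(pmax(seq_len(nr + 2L * rr) - rr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * rr) - rr, 1L), nc)
  P <- m[ri, ci, drop = FALSE]
  CS <- cbind(0, t(apply(P, 1L, cumsum)))  # row-wise prefix sums, once
  out <- matrix(0, nr, nc)
  for (dy in -rr:rr) {
    k2 <- r^2 - dy^2
    if (k2 <= 0) next
    kx <- floor(sqrt(k2 - 1e-9))
    rows <- (rr + 1L + dy):(rr + nr + dy)
    out <- out + CS[rows, (rr + kx + 2L):(rr + nc + kx + 1L), drop = FALSE] -
      CS[rows, (rr - kx + 1L):(rr + nc - kx), drop = FALSE]
  }
  out
}

disc_size <- function(r) {
  rr <- ceiling(r) - 1L
  n <- 0L
  for (dy in -rr:rr) {
    k2 <- r^2 - dy^2
    if (k2 <= 0) next
    n <- n + 2L * floor(sqrt(k2 - 1e-9)) + 1L
  }
  n
}

# Separable Gaussian smoothing with replicated edges; kernel radius 3 sigma.
gaussian_smooth <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(m, 0L, i - rad - 1L)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_replicate(out, i - rad - 1L, 0L)
  out2
}

#' Localized interior/exterior mean fields
#'
#' For every pixel x, the Heaviside-weighted mean intensities of the local
#' disc `||x - y|| < r`: `c_x1` over the interior (`H(phi)` weight) and
#' `c_x2` over the exterior (`1 - H(phi)`). Sides whose weight sum is
#' (numerically) empty fall back to the plain disc mean and are flagged.
#'
#' @param image intensity matrix.
#' @param phi level-set matrix, same shape, `phi >= 0` inside.
#' @param r local-window radius (pixels).
#' @param eps Heaviside regularization width.
#' @return A list with matrices `c1`, `c2` and logical matrices
#'   `degenerate1`, `degenerate2` marking fallback pixels.
#' @export
local_means_field <- function(image, phi, r, eps = 1.0) {
  if (!all(dim(image) == dim(phi))) abort("`image` and `phi` shapes differ")
  H <- heaviside_dirac(phi, eps)$H
  convH <- conv_disc(H, r)
  convHI <- conv_disc(H * image, r)
  convI <- conv_disc(image, r)
  n_disc <- disc_size(r)
  conv1mH <- n_disc - convH
  conv1mHI <- convI - convHI
  tiny <- 1e-8 * n_disc
  deg1 <- convH < tiny
  deg2 <- conv1mH < tiny
  full_mean <- convI / n_disc
  c1 <- ifelse(deg1, full_mean, convHI / pmax(convH, tiny))
  c2 <- ifelse(deg2, full_mean, conv1mHI / pmax(conv1mH, tiny))
  list(c1 = c1, c2 = c2, degenerate1 = deg1, degenerate2 = deg2)
}

#' Localized means at a single pixel
#'
#' Convenience accessor for [local_means_field()] at one location.
#'
#' @inheritParams local_means_field
#' @param x length-2 vector `(x, y)` in 0-based pixel coordinates
#'   (x = column, y = row).
#' @return Named numeric vector `c(c1 = ..., c2 = ...)`.
#' @export
local_means <- function(image, phi, x, r, eps = 1.0) {
  lm <- local_means_field(image, phi, r, eps)
  i <- x[2] + 1L; j <- x[1] + 1L
  if (i < 1 || i > nrow(image) || j < 1 || j > ncol(image)) {
    abort("`x` outside the image")
  }
  c(c1 = lm$c1[i, j], c2 = lm$c2[i, j])
}

#' Local-uniformity indicator t(x)
#'
#' Returns 1 where the local contrast `|c1 - c2|` is strictly below
#' `kappa1` (low-contrast / nearly uniform neighborhood, where the geodesic
#' term is switched on), 0 otherwise.
#'
#' @param c1,c2 localized interior/exterior means (vectors or matrices).
#' @param kappa1 positive contrast threshold.
#' @return 0/1 numeric of the same shape.
#' @export
uniformity_indicator <- function(c1, c2, kappa1) {
  stopifnot_scalar_pos(kappa1, "kappa1")
  (abs(c1 - c2) < kappa1) + 0
}

#' Edge-stopping function g
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)`: close to 1 in flat regions, small
#' on strong edges of the Gaussian-smoothed image (central-difference
#' gradient, replicated borders).
#'
#' @param image intensity matrix.
#' @param sigma Gaussian smoothing standard deviation (pixels).
#' @return Matrix of `g` values in `(0, 1]`.
#' @export
edge_stopping <- function(image, sigma) {
  stopifnot_scalar_pos(sigma, "sigma")
  g <- grad_central(gaussian_smooth(image, sigma))
  1 / (1 + g$gx^2 + g$gy^2)
}

# Curvature div(grad phi / |grad phi|) by central differences, |grad phi|
# floored at 1e-8, replicated edges.
curvature_div <- function(phi) {
  g <- grad_central(phi)
  nrm <- pmax(sqrt(g$gx^2 + g$gy^2), 1e-8)
  nx <- g$gx / nrm
  ny <- g$gy / nrm
  (shift_replicate(nx, 0L, 1L) - shift_replicate(nx, 0L, -1L)) / 2 +
    (shift_replicate(ny, 1L, 0L) - shift_replicate(ny, -1L, 0L)) / 2
}

#' Localized Chan-Vese energy
#'
#' Discretized localized region energy plus the length penalty:
#' `E = sum_x delta(phi(x)) sum_y B(x,y) F_region(y; x) + mu sum_x
#' delta(phi(x)) |grad phi(x)|` with
#' `F_region = H(phi(y)) (I(y) - c_x1)^2 + (1 - H(phi(y))) (I(y) - c_x2)^2`.
#' A monitoring quantity: the evolution should drive it down.
#'
#' @param image intensity matrix.
#' @param phi level-set matrix.
#' @param params a [glcv_params()] object.
#' @return A single number.
#' @export
lcv_energy <- function(image, phi, params) {
  r <- params$r; eps <- params$eps
  hd <- heaviside_dirac(phi, eps)
  H <- hd$H
  lm <- local_means_field(image, phi, r, eps)
  convH <- conv_disc(H, r)
  convHI <- conv_disc(H * image, r)
  convHI2 <- conv_disc(H * image^2, r)
  convI <- conv_disc(image, r)
  convI2 <- conv_disc(image^2, r)
  n_disc <- disc_size(r)
  fit <- (convHI2 - 2 * lm$c1 * convHI + lm$c1^2 * convH) +
    ((convI2 - convHI2) - 2 * lm$c2 * (convI - convHI) +
       lm$c2^2 * (n_disc - convH))
  g <- grad_central(phi)
  sum(hd$delta * fit) + params$mu * sum(hd$delta * sqrt(g$gx^2 + g$gy^2))
}

#' Localized Chan-Vese velocity field
#'
#' The descent velocity of [lcv_energy()]:
#' `v(x) = delta(phi(x)) [ sum_y B(x,y) delta(phi(y)) ((I(y) - c_x2)^2 -
#' (I(y) - c_x1)^2) + mu div(grad phi / |grad phi|) ]`,
#' evaluated at every pixel (the segmentation loop applies it on the narrow
#' band only).
#'
#' @inheritParams lcv_energy
#' @return Matrix of per-pixel velocities.
#' @export
lcv_velocity <- function(image, phi, params) {
  r <- params$r; eps <- params$eps
  hd <- heaviside_dirac(phi, eps)
  lm <- local_means_field(image, phi, r, eps)
  convD <- conv_disc(hd$delta, r)
  convDI <- conv_disc(hd$delta * image, r)
  # (I - c2)^2 - (I - c1)^2 = (c1 - c2) (2 I - c1 - c2), c's frozen at x
  fit <- (lm$c1 - lm$c2) * (2 * convDI - (lm$c1 + lm$c2) * convD)
  hd$delta * (fit + params$mu * curvature_div(phi))
}

#' One GLCV evolution step
#'
#' Advances the level set by the localized Chan-Vese velocity plus, where
#' the neighborhood is locally uniform (`t(x) = 1`), the geodesic flow
#' `g |grad phi| div(grad phi / |grad phi|) + grad g . grad phi +
#' alpha g |grad phi|`, all gated by `delta(phi)`. Updates are restricted to
#' the narrow band `|phi| <= band_width`. When `normalize = TRUE` the
#' combined velocity is scaled by its maximum absolute band value so `dt`
#' acts as a CFL fraction.
#'
#' @param phi level-set matrix.
#' @param image intensity matrix.
#' @param params a [glcv_params()] object.
#' @param g optional precomputed edge-stopping field ([edge_stopping()]).
#' @param normalize scale the update by `max |v|` over the band.
#' @param v_scale optional fixed velocity scale overriding the per-step
#'   maximum (used by [glcv_segment()] so updates decay as the flow
#'   settles instead of being renormalized to constant speed).
#' @return The advanced level-set matrix, with the pre-normalization band
#'   maximum attached as attribute `vmax`.
#' @export
glcv_step <- function(phi, image, params, g = NULL, normalize = TRUE,
                      v_scale = NULL) {
  if (!all(dim(image) == dim(phi))) abort("`image` and `phi` shapes differ")
  eps <- params$eps
  hd <- heaviside_dirac(phi, eps)
  lm <- local_means_field(image, phi, params$r, eps)
  convD <- conv_disc(hd$delta, params$r)
  convDI <- conv_disc(hd$delta * image, params$r)
  fit <- (lm$c1 - lm$c2) * (2 * convDI - (lm$c1 + lm$c2) * convD)
  kappa <- curvature_div(phi)
  v <- hd$delta * (fit + params$mu * kappa)
  tx <- uniformity_indicator(lm$c1, lm$c2, params$kappa1)
  if (any(tx > 0)) {
    if (is.null(g)) g <- edge_stopping(image, params$sigma)
    gp <- grad_central(phi)
    gg <- grad_central(g)
    ngrad <- sqrt(gp$gx^2 + gp$gy^2)
    geo <- tx * hd$delta *
      (g * ngrad * kappa + gg$gx * gp$gx + gg$gy * gp$gy +
         params$alpha * g * ngrad)
    v <- v + geo
  }
  band <- abs(phi) <= params$band_width
  vmax <- max(abs(v[band]), 0)
  if (!is.null(v_scale)) {
    if (v_scale > 0) v <- v / v_scale
  } else if (normalize && vmax > 0) {
    v <- v / vmax
  }
  upd <- phi
  upd[band] <- phi[band] + params$dt * v[band]
  if (!all(is.finite(upd))) {
    abort("non-finite values in the GLCV update (diverging evolution)")
  }
  attr(upd, "vmax") <- vmax
  upd
}

#' Initial contour specification
#'
#' @param kind `"ellipse"` or `"polygon"`.
#' @param center length-2 `(x, y)` center in pixels (ellipse).
#' @param semi_axes length-2 semi-axes `(a, b)` in pixels (ellipse).
#' @param polygon two-column matrix or data frame of `(x, y)` vertices
#'   (polygon, at least 3).
#' @return A `contour_init` object.
#' @export
contour_init <- function(kind = c("ellipse", "polygon"), center = NULL,
                         semi_axes = NULL, polygon = NULL) {
  kind <- match.arg(kind)
  if (kind == "ellipse") {
    if (is.null(center) || is.null(semi_axes)) {
      abort("ellipse init needs `center` and `semi_axes`")
    }
    if (any(semi_axes <= 0)) abort("degenerate ellipse (zero area)")
  } else {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3) abort("polygon init needs >= 3 vertices")
    if (abs(polygon_area(polygon[, 1], polygon[, 2])) < 1e-9) {
      abort("degenerate polygon (zero area)")
    }
  }
  structure(list(kind = kind, center = center, semi_axes = semi_axes,
                 polygon = polygon), class = "contour_init")
}

# Shoelace signed area.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Dense boundary sampling of an init (<= 0.25 px spacing).
init_boundary_points <- function(init) {
  if (init$kind == "ellipse") {
    a <- init$semi_axes[1]; b <- init$semi_axes[2]
    n <- max(64L, ceiling(2 * pi * max(a, b) / 0.25))
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(init$center[1] + a * cos(th), init$center[2] + b * sin(th))
  } else {
    resample_polyline(init$polygon, spacing = 0.25, closed = TRUE)
  }
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum distance from query points (qx, qy) to a point cloud, chunked.
min_dist_to_points <- function(qx, qy, bx, by, chunk = 4096L) {
  out <- numeric(length(qx))
  for (s in seq(1L, length(qx), by = chunk)) {
    e <- min(s + chunk - 1L, length(qx))
    d2 <- outer(qx[s:e], bx, "-")^2 + outer(qy[s:e], by, "-")^2
    idx <- max.col(-d2, ties.method = "first")
    out[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), idx)])
  }
  out
}

#' Initialize a level set as a signed distance to an initial contour
#'
#' @param shape `c(rows, cols)` of the image grid.
#' @param init a [contour_init()] object lying within the grid.
#' @return A level-set matrix, positive inside the contour.
#' @export
initialize_level_set <- function(shape, init) {
  nr <- shape[1]; nc <- shape[2]
  bp <- init_boundary_points(init)
  if (any(bp[, 1] < 0) || any(bp[, 1] > nc - 1) ||
      any(bp[, 2] < 0) || any(bp[, 2] > nr - 1)) {
    abort("initial contour lies outside the image bounds")
  }
  px <- rep(seq_len(nc) - 1, each = nr)
  py <- rep(seq_len(nr) - 1, times = nc)
  d <- min_dist_to_points(px, py, bp[, 1], bp[, 2])
  inside <- if (init$kind == "ellipse") {
    ((px - init$center[1]) / init$semi_axes[1])^2 +
      ((py - init$center[2]) / init$semi_axes[2])^2 <= 1
  } else {
    points_in_polygon(px, py, init$polygon[, 1], init$polygon[, 2])
  }
  matrix(ifelse(inside, d, -d), nr, nc)
}

# Sub-pixel zero crossings of phi along grid edges -> (x, y) points.
interface_points <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  pts <- list()
  a <- phi[, -nc, drop = FALSE]; b <- phi[, -1L, drop = FALSE]
  ih <- which(a * b < 0, arr.ind = TRUE)
  if (nrow(ih)) {
    t0 <- a[ih] / (a[ih] - b[ih])
    pts[[1]] <- cbind((ih[, 2] - 1) + t0, ih[, 1] - 1)
  }
  a <- phi[-nr, , drop = FALSE]; b <- phi[-1L, , drop = FALSE]
  iv <- which(a * b < 0, arr.ind = TRUE)
  if (nrow(iv)) {
    t0 <- a[iv] / (a[iv] - b[iv])
    pts[[2]] <- cbind(iv[, 2] - 1, (iv[, 1] - 1) + t0)
  }
  iz <- which(phi == 0, arr.ind = TRUE)
  if (nrow(iz)) pts[[3]] <- cbind(iz[, 2] - 1, iz[, 1] - 1)
  do.call(rbind, pts)
}

#' Reinitialize a level set to a signed distance function
#'
#' Rebuilds `phi` as the exact distance to the sub-pixel zero level set
#' (linearly interpolated along grid edges), keeping the sign pattern.
#'
#' @param phi level-set matrix with a non-empty zero level set.
#' @return A signed distance matrix with the same interface.
#' @export
reinitialize <- function(phi) {
  ip <- interface_points(phi)
  if (is.null(ip) || nrow(ip) == 0L) {
    abort("contour vanished: empty zero level set")
  }
  nr <- nrow(phi); nc <- ncol(phi)
  px <- rep(seq_len(nc) - 1, each = nr)
  py <- rep(seq_len(nr) - 1, times = nc)
  d <- min_dist_to_points(px, py, ip[, 1], ip[, 2])
  matrix(d, nr, nc) * ifelse(phi >= 0, 1, -1)
}

#' Segment an image with the GLCV flow
#'
#' Runs [glcv_step()] with periodic reinitialization until the interface
#' sign pattern is unchanged for `params$patience` consecutive iterations or
#' `params$max_iter` is reached.
#'
#' The evolution operates on intensities normalized to `[0, 1]` (with
#' `kappa1` and `mu` rescaled by 1/255 and 1/255^2 from their 0-255-scale
#' values) so that the localized fitting term, the length penalty and the
#' O(1) geodesic terms are commensurate; without this the geodesic flow
#' that drives uniform regions is numerically invisible next to the
#' intensity-scale terms.
#'
#' @param image intensity matrix (0-255).
#' @param init a [contour_init()] object.
#' @param params a [glcv_params()] object (0-255 intensity conventions).
#' @return A `glcv_fit` object: list with `mask` (logical matrix), `contour`
#'   (tibble `point_index`, `x`, `y`), `phi`, `iterations`, `energy`
#'   (monitoring trace), `converged`.
#' @export
glcv_segment <- function(image, init, params = glcv_params()) {
  image <- validate_image(image) / 255
  params$kappa1 <- params$kappa1 / 255
  params$mu <- params$mu / 255^2
  phi <- initialize_level_set(dim(image), init)
  g <- edge_stopping(image, params$sigma)
  stable <- 0L
  energy <- c()
  sign_prev <- phi >= 0
  it <- 0L
  v_scale <- NULL
  while (it < params$max_iter) {
    it <- it + 1L
    phi <- glcv_step(phi, image, params, g = g, v_scale = v_scale)
    if (is.null(v_scale)) v_scale <- max(attr(phi, "vmax"), 1e-12)
    if (it %% params$reinit_every == 0L) {
      phi <- reinitialize(phi)
    }
    if (it %% 10L == 0L || it == 1L) {
      energy <- c(energy, lcv_energy(image, phi, params))
    }
    sign_now <- phi >= 0
    if (all(sign_now == sign_prev)) {
      stable <- stable + 1L
      if (stable >= params$patience) break
    } else {
      stable <- 0L
    }
    sign_prev <- sign_now
  }
  converged <- stable >= params$patience
  if (!converged) warn("GLCV reached max_iter without a stable interface")
  mask <- phi >= 0
  if (!any(mask)) abort("contour vanished during evolution")
  structure(list(mask = mask, contour = mask_to_contour(mask), phi = phi,
                 iterations = it, energy = energy, converged = converged,
                 params = params, init = init),
            class = "glcv_fit")
}

#' @export
print.glcv_fit <- function(x, ...) {
  cat(sprintf("GLCV segmentation: %d iterations (%s), %d foreground px, %d contour points\n",
              x$iterations, if (x$converged) "converged" else "max_iter",
              sum(x$mask), nrow(x$contour)))
  invisible(x)
}
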