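# Independent brute-force oracles used across the suite. These are written
# directly from the mathematical definitions (plain loops, no shared code
# with the implementation).

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

# Disc sum of m over ||offset|| < r with replicated edges, quadruple loop.
oracle_disc_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  rr <- ceiling(r)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -rr:rr) for (dj in -rr:rr) {
      if (di^2 + dj^2 < r^2) {
        s <- s + m[clamp_idx(i + di, nr), clamp_idx(j + dj, nc)]
      }
    }
    out[i, j] <- s
  }
  out
}

oracle_H <- function(z, eps) 0.5 * (1 + (2 / pi) * atan(z / eps))
oracle_delta <- function(z, eps) eps / (pi * (eps^2 + z^2))

# Local means at every pixel by direct disc summation.
oracle_local_means <- function(image, phi, r, eps) {
  H <- oracle_H(phi, eps)
  num1 <- oracle_disc_sum(H * image, r); den1 <- oracle_disc_sum(H, r)
  numI <- oracle_disc_sum(image, r); denA <- oracle_disc_sum(matrix(1, nrow(image), ncol(image)), r)
  c1 <- num1 / den1
  c2 <- (numI - num1) / (denA - den1)
  list(c1 = c1, c2 = c2)
}

# Central-difference curvature with clamped borders, |grad| floored.
oracle_curvature <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  gx <- gy <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx[i, j] <- (phi[i, clamp_idx(j + 1, nc)] - phi[i, clamp_idx(j - 1, nc)]) / 2
    gy[i, j] <- (phi[clamp_idx(i + 1, nr), j] - phi[clamp_idx(i - 1, nr), j]) / 2
  }
  nrm <- pmax(sqrt(gx^2 + gy^2), 1e-8)
  nx <- gx / nrm; ny <- gy / nrm
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- (nx[i, clamp_idx(j + 1, nc)] - nx[i, clamp_idx(j - 1, nc)]) / 2 +
      (ny[clamp_idx(i + 1, nr), j] - ny[clamp_idx(i - 1, nr), j]) / 2
  }
  out
}

# Localized CV descent velocity, quadruple loop.
oracle_lcv_velocity <- function(image, phi, r, eps, mu) {
  nr <- nrow(image); nc <- ncol(image)
  lm <- oracle_local_means(image, phi, r, eps)
  kap <- oracle_curvature(phi)
  del <- oracle_delta(phi, eps)
  rr <- ceiling(r)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -rr:rr) for (dj in -rr:rr) {
      if (di^2 + dj^2 < r^2) {
        ii <- clamp_idx(i + di, nr); jj <- clamp_idx(j + dj, nc)
        Iy <- image[ii, jj]
        s <- s + del[ii, jj] *
          ((Iy - lm$c2[i, j])^2 - (Iy - lm$c1[i, j])^2)
      }
    }
    out[i, j] <- del[i, j] * (s + mu * kap[i, j])
  }
  out
}

# Localized CV energy, quadruple loop.
oracle_lcv_energy <- function(image, phi, r, eps, mu) {
  nr <- nrow(image); nc <- ncol(image)
  lm <- oracle_local_means(image, phi, r, eps)
  H <- oracle_H(phi, eps)
  del <- oracle_delta(phi, eps)
  rr <- ceiling(r)
  E <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -rr:rr) for (dj in -rr:rr) {
      if (di^2 + dj^2 < r^2) {
        ii <- clamp_idx(i + di, nr); jj <- clamp_idx(j + dj, nc)
        Iy <- image[ii, jj]
        s <- s + H[ii, jj] * (Iy - lm$c1[i, j])^2 +
          (1 - H[ii, jj]) * (Iy - lm$c2[i, j])^2
      }
    }
    gx <- (phi[i, clamp_idx(j + 1, nc)] - phi[i, clamp_idx(j - 1, nc)]) / 2
    gy <- (phi[clamp_idx(i + 1, nr), j] - phi[clamp_idx(i - 1, nr), j]) / 2
    E <- E + del[i, j] * s + mu * del[i, j] * sqrt(gx^2 + gy^2)
  }
  E
}

# Cubic spline kernel, independent formulas.
oracle_W <- function(r, h, dim) {
  sig <- if (dim == 2) 10 / (7 * pi * h^2) else 1 / (pi * h^3)
  q <- r / h
  if (q < 1) sig * (1 - 1.5 * q^2 + 0.75 * q^3)
  else if (q < 2) sig * 0.25 * (2 - q)^3
  else 0
}
oracle_gradW <- function(rvec, h, dim) {
  sig <- if (dim == 2) 10 / (7 * pi * h^2) else 1 / (pi * h^3)
  r <- sqrt(sum(rvec^2)); q <- r / h
  if (r < 1e-14) return(rep(0, length(rvec)))
  dw <- if (q < 1) sig * (-3 * q + 2.25 * q^2)
  else if (q < 2) -0.75 * sig * (2 - q)^2
  else 0
  (dw / h) * rvec / r
}
oracle_lapW <- function(r, h, dim) {
  sig <- if (dim == 2) 10 / (7 * pi * h^2) else 1 / (pi * h^3)
  q <- r / h
  d2 <- if (q < 1) sig * (-3 + 4.5 * q) else if (q < 2) 1.5 * sig * (2 - q) else 0
  d1 <- if (q < 1) sig * (-3 * q + 2.25 * q^2) else if (q < 2) -0.75 * sig * (2 - q)^2 else 0
  if (r < 1e-14) -3 * dim * sig / h^2 else d2 / h^2 + (dim - 1) * (d1 / h) / r
}

# O(n^2) SPH oracles on particle tables.
oracle_densities <- function(pos, mass, h, dim) {
  n <- nrow(pos)
  rho <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      s <- s + mass[j] * oracle_W(sqrt(sum((pos[i, ] - pos[j, ])^2)), h, dim)
    }
    rho[i] <- s
  }
  rho
}

oracle_pressure_forces <- function(pos, mass, rho, pres, h, dim) {
  n <- nrow(pos)
  f <- matrix(0, n, ncol(pos))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    rv <- pos[i, ] - pos[j, ]
    r <- sqrt(sum(rv^2))
    if (r >= 2 * h || r < 1e-14) next
    gw <- oracle_gradW(rv, h, dim)
    vbar <- 0.5 * (mass[i] / rho[i] + mass[j] / rho[j])
    fp <- -0.5 * (pres[i] + pres[j]) * vbar * gw
    f[i, ] <- f[i, ] + fp
    f[j, ] <- f[j, ] - fp
  }
  f
}

oracle_viscosity_forces <- function(pos, vel, mass, rho, mu, h, dim) {
  n <- nrow(pos)
  f <- matrix(0, n, ncol(pos))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (r >= 2 * h) next
    f[i, ] <- f[i, ] + mu * (vel[j, ] - vel[i, ]) * (mass[j] / rho[j]) *
      oracle_lapW(r, h, dim)
  }
  f
}

# Central finite differences of a scalar function of the displacement field.
oracle_fd_gradient <- function(fun, disp, step = 1e-6) {
  g <- matrix(0, nrow(disp), ncol(disp))
  for (i in seq_len(nrow(disp))) for (k in seq_len(ncol(disp))) {
    dp <- disp; dp[i, k] <- dp[i, k] + step
    dm <- disp; dm[i, k] <- dm[i, k] - step
    g[i, k] <- (fun(dp) - fun(dm)) / (2 * step)
  }
  g
}

# Shoelace area of a closed polygon given as a contour tibble or matrix.
oracle_polygon_area <- function(pts) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2]) / 2)
}

# A small random-blob phantom for segmentation-free level-set tests.
make_test_image <- function(n = 10, seed = 1, lo = 0, hi = 200) {
  set.seed(seed)
  matrix(runif(n * n, lo, hi), n, n)
}

make_test_phi <- function(n = 10, cx = NULL, cy = NULL, R = n / 3) {
  cx <- cx %||% ((n - 1) / 2); cy <- cy %||% ((n - 1) / 2)
  outer(seq_len(n) - 1, seq_len(n) - 1,
        function(y, x) R - sqrt((x - cx)^2 + (y - cy)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
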