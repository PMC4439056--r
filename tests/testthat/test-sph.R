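# SPH kernel, neighbor search, density estimation and fluid forces.

test_that("cubic spline kernel has compact support, symmetry and unit mass", {
  h <- 1.3
  expect_equal(cubic_spline_kernel(c(2 * h, 0), h, 2)$W, 0)
  expect_equal(cubic_spline_kernel(c(0.7, 0.4), h, 2)$W,
               cubic_spline_kernel(c(-0.7, -0.4), h, 2)$W)
  # quadrature of W over its support integrates to 1 in 2D and 3D
  xs <- seq(-2 * h, 2 * h, length.out = 141)
  g2 <- as.matrix(expand.grid(x = xs, y = xs))
  expect_equal(sum(cubic_spline_kernel(g2, h, 2)$W) * diff(xs)[1]^2, 1,
               tolerance = 1e-3)
  xs3 <- seq(-2 * h, 2 * h, length.out = 41)
  g3 <- as.matrix(expand.grid(x = xs3, y = xs3, z = xs3))
  expect_equal(sum(cubic_spline_kernel(g3, h, 3)$W) * diff(xs3)[1]^3, 1,
               tolerance = 1e-3)
})

test_that("kernel gradient matches finite differences of W", {
  h <- 0.9
  set.seed(5)
  for (k in 1:10) {
    rv <- runif(2, -1.6, 1.6)
    if (sqrt(sum(rv^2)) < 1e-3) next
    gw <- cubic_spline_kernel(rv, h, 2)$gradW
    for (ax in 1:2) {
      e <- c(0, 0); e[ax] <- 1e-6
      num <- (cubic_spline_kernel(rv + e, h, 2)$W -
                cubic_spline_kernel(rv - e, h, 2)$W) / 2e-6
      expect_equal(gw[1, ax], num, tolerance = max(1e-6 * abs(num), 1e-8))
    }
  }
  # analytic forms agree with the independent oracle
  expect_equal(as.vector(cubic_spline_kernel(c(0.5, 0.3), h, 2)$gradW),
               oracle_gradW(c(0.5, 0.3), h, 2), tolerance = 1e-12)
  expect_equal(cubic_spline_kernel(c(1.1, 0.2), h, 2)$lapW,
               oracle_lapW(sqrt(1.1^2 + 0.2^2), h, 2), tolerance = 1e-12)
})

test_that("neighbor search is exact against the all-pairs brute force", {
  expect_equal(nrow(neighbor_search(rbind(c(0, 0), c(1.9, 0)), 2)), 1L)
  expect_equal(nrow(neighbor_search(rbind(c(0, 0), c(2.1, 0)), 2)), 0L)
  set.seed(8)
  P <- matrix(runif(200, 0, 3), 100, 2)
  pr <- neighbor_search(P, 0.5)
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  D <- as.matrix(dist(P))
  bf <- which(D < 0.5 & upper.tri(D), arr.ind = TRUE)
  expect_identical(key(pr), key(bf))
  # 3D
  P3 <- matrix(runif(150, 0, 2), 50, 3)
  pr3 <- neighbor_search(P3, 0.6)
  D3 <- as.matrix(dist(P3))
  bf3 <- which(D3 < 0.6 & upper.tri(D3), arr.ind = TRUE)
  expect_identical(key(pr3), key(bf3))
})

test_that("sph_interpolate reproduces point values and constants", {
  h <- 1
  one <- tibble::tibble(x = 2, y = 3, quantity = 5, mass = 2, density = 4)
  expect_equal(sph_interpolate(one, c(2, 3), h),
               5 * (2 / 4) * oracle_W(0, h, 2))
  # constant field on a lattice: interior value within 2%
  g <- expand.grid(x = seq(0, 10, by = 1), y = seq(0, 10, by = 1))
  lat <- tibble::tibble(x = g$x, y = g$y, vx = 0, vy = 0, mass = 1)
  lat <- compute_densities(lat, h)
  lat$quantity <- 7
  expect_equal(sph_interpolate(lat, c(5, 5), h), 7, tolerance = 0.02)
  # empty neighborhood
  expect_equal(sph_interpolate(one[0, ], c(0, 0), h), 0)
})

test_that("densities match lattice theory and the O(n^2) oracle", {
  h <- 1
  # isolated particle: self term only
  iso <- tibble::tibble(x = 0, y = 0, mass = 3)
  expect_equal(compute_densities(iso, h)$density, 3 * oracle_W(0, h, 2))
  # 3D lattice at spacing h: interior density within 2% of m/h^3
  g <- expand.grid(x = 0:8, y = 0:8, z = 0:8)
  lat <- tibble::tibble(x = g$x, y = g$y, z = g$z, mass = 2)
  lat <- compute_densities(lat, h)
  mid <- which(g$x == 4 & g$y == 4 & g$z == 4)
  expect_equal(lat$density[mid], 2 / h^3, tolerance = 0.02)
  # linearity in mass
  lat2 <- lat; lat2$mass <- 2 * lat$mass
  lat2 <- compute_densities(lat2, h)
  expect_equal(lat2$density, 2 * lat$density, tolerance = 1e-12)
  # random cloud equals the brute-force oracle
  set.seed(3)
  P <- matrix(runif(120, 0, 4), 60, 2)
  cl <- tibble::tibble(x = P[, 1], y = P[, 2], mass = runif(60, 0.5, 2))
  cl <- compute_densities(cl, h)
  expect_equal(cl$density, oracle_densities(P, cl$mass, h, 2),
               tolerance = 1e-10)
})

test_that("partition of unity holds on interior lattice points", {
  h <- 1
  g <- expand.grid(x = 0:12, y = 0:12)
  lat <- tibble::tibble(x = g$x, y = g$y, mass = 1)
  lat <- compute_densities(lat, h)
  interior <- which(g$x %in% 4:8 & g$y %in% 4:8)
  for (i in interior[c(1, 7, 13)]) {
    rv <- cbind(lat$x[i] - lat$x, lat$y[i] - lat$y)
    W <- cubic_spline_kernel(rv, h, 2)$W
    expect_equal(sum(lat$mass / lat$density * W), 1, tolerance = 0.03)
  }
})

test_that("equation of state and the clamp flag behave as specified", {
  p <- tibble::tibble(x = 1:3, y = 0, mass = 1, density = c(1000, 1010, 990))
  pr <- fluid_params(rest_density = 1000, K = 1000)
  out <- pressure_from_density(p, pr)
  expect_equal(out$pressure, c(0, 10000, 0))
  pr2 <- fluid_params(rest_density = 1000, K = 1000,
                      clamp_negative_pressure = FALSE)
  expect_equal(pressure_from_density(p, pr2)$pressure, c(0, 10000, -10000))
})

test_that("pressure forces repel, balance pairwise and match the oracle", {
  h <- 1
  two <- tibble::tibble(x = c(0, 1.2), y = 0, vx = 0, vy = 0, mass = 1,
                        density = 1, pressure = 10)
  pairs <- neighbor_search(two, 2 * h)
  f <- pressure_forces(two, pairs, h)
  expect_equal(f[1, ], -f[2, ], tolerance = 1e-14)
  expect_lt(f[1, 1], 0)  # particle 1 pushed away from particle 2
  expect_equal(f[1, 2], 0)
  # zero pressures give zero forces
  two0 <- two; two0$pressure <- 0
  expect_equal(max(abs(pressure_forces(two0, pairs, h))), 0)
  # 3-particle configuration matches the brute-force double loop
  tri <- tibble::tibble(x = c(0, 1.1, 0.4), y = c(0, 0.2, 0.9),
                        mass = c(1, 2, 1.5), density = c(1, 1.2, 0.9),
                        pressure = c(5, 2, 7))
  prs <- neighbor_search(tri, 2 * h)
  f3 <- pressure_forces(tri, prs, h)
  o3 <- oracle_pressure_forces(cbind(tri$x, tri$y), tri$mass, tri$density,
                               tri$pressure, h, 2)
  expect_equal(f3, o3, tolerance = 1e-10)
  expect_equal(colSums(f3), c(0, 0), tolerance = 1e-15)
})

test_that("viscosity forces dissipate relative motion and match the oracle", {
  h <- 1
  two <- tibble::tibble(x = c(0, 1.2), y = 0, vx = c(1, -1), vy = 0,
                        mass = 1, density = 1)
  pairs <- neighbor_search(two, 2 * h)
  f <- viscosity_forces(two, pairs, mu_pair = 0.5, h = h)
  expect_lt(f[1, 1], 0)  # decelerates the approaching pair
  expect_gt(f[2, 1], 0)
  # equal velocities give zero forces
  same <- two; same$vx <- 2
  expect_equal(max(abs(viscosity_forces(same, pairs, 0.5, h))), 0)
  # 3-particle oracle
  tri <- tibble::tibble(x = c(0, 1.3, 0.5), y = c(0, 0, 1.1),
                        vx = c(0.3, -0.2, 0), vy = c(0, 0.5, -0.4),
                        mass = c(1, 1.4, 0.8), density = c(1, 1.1, 0.95))
  prs <- neighbor_search(tri, 2 * h)
  f3 <- viscosity_forces(tri, prs, mu_pair = 0.7, h = h)
  o3 <- oracle_viscosity_forces(cbind(tri$x, tri$y),
                                cbind(tri$vx, tri$vy), tri$mass,
                                tri$density, 0.7, h, 2)
  expect_equal(f3, o3, tolerance = 1e-10)
})

test_that("density positivity lower bound holds on random clouds", {
  set.seed(14)
  h <- 0.8
  P <- matrix(runif(100, 0, 2), 50, 2)
  cl <- tibble::tibble(x = P[, 1], y = P[, 2], mass = runif(50, 0.1, 3))
  cl <- compute_densities(cl, h)
  expect_true(all(cl$density >= cl$mass * oracle_W(0, h, 2) - 1e-12))
})
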