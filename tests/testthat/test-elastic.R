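# Particle elasticity: MLS gradients, Green-Saint-Venant strain, Hooke
# stress, force/energy consistency, rheological viscosity coefficient.
# Module tests run in scale-free units (h_e = 1).

make_cloud <- function(n = 12, seed = 1, spread = 1.5) {
  set.seed(seed)
  matrix(runif(2 * n, 0, spread), n, 2)
}

epar <- function(..., h_e = 1) elastic_params(h_e = h_e, ...)

test_that("MLS gradient reproduces linear displacement fields exactly", {
  ref <- make_cloud(15, seed = 2)
  M <- matrix(c(0.3, -0.1, 0.2, 0.05), 2, 2)  # du/dx
  disp <- ref %*% t(M)
  for (i in c(1, 7, 15)) {
    g <- mls_displacement_gradient(ref, disp, i, epar())
    expect_false(g$degenerate)
    expect_equal(g$grad_u, M, tolerance = 1e-8)
  }
  # constant displacement: zero gradient
  g0 <- mls_displacement_gradient(ref, matrix(0.4, 15, 2), 3, epar())
  expect_equal(g0$grad_u, matrix(0, 2, 2), tolerance = 1e-12)
})

test_that("rank-deficient neighborhoods are flagged degenerate", {
  ref <- cbind(c(0, 0.5, 1.0), 0)  # collinear
  g <- mls_displacement_gradient(ref, ref * 0, 1, epar())
  expect_true(g$degenerate)
  expect_equal(g$grad_u, matrix(0, 2, 2))
})

test_that("Green-Saint-Venant strain vanishes for rigid motions and expands uniaxially", {
  expect_equal(green_strain(matrix(0, 3, 3)), matrix(0, 3, 3))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(max(abs(green_strain(R - diag(3)))), 0, tolerance = 1e-12)
  lam <- 0.17
  eps <- green_strain(diag(c(lam, 0, 0)))
  expect_equal(eps[1, 1], 2 * lam + lam^2, tolerance = 1e-14)
  expect_equal(sum(abs(eps)) - abs(eps[1, 1]), 0, tolerance = 1e-14)
  # both printed forms coincide: grad_u + grad_u^T + grad_u^T grad_u
  G <- matrix(c(0.1, 0.02, -0.03, 0.05), 2, 2)
  expect_equal(green_strain(G), G + t(G) + t(G) %*% G, tolerance = 1e-14)
})

test_that("Hooke stress follows the Lame constants, including the reference values", {
  expect_equal(stress(matrix(0, 3, 3), epar()), matrix(0, 3, 3))
  # zero Poisson coupling: uniaxial stress E*e
  s <- stress(diag(c(0.01, 0, 0)), epar(young_E = 200, poisson_eta = 0))
  expect_equal(s, diag(c(2, 0, 0)), tolerance = 1e-12)
  # reference soft-tissue values: E = 13 kPa, eta = 0.47
  lc <- lame_constants(13e3, 0.47)
  expect_equal(unname(lc["lambda"]), 13e3 * 0.47 / (1.47 * 0.06))
  expect_equal(unname(lc["mu"]), 13e3 / (2 * 1.47))
  s2 <- stress(diag(c(0.01, 0, 0)), epar(young_E = 13e3, poisson_eta = 0.47))
  expect_equal(diag(s2),
               c(lc[["lambda"]] * 0.01 + 2 * lc[["mu"]] * 0.01,
                 lc[["lambda"]] * 0.01, lc[["lambda"]] * 0.01),
               tolerance = 1e-10)
  expect_error(stress(diag(3) * 0.01, elastic_params(poisson_eta = 0.5)),
               "poisson_eta")
  expect_error(lame_constants(1e3, 0.5), "singular")
})

test_that("rigid motions produce vanishing elastic and volume forces", {
  ref <- make_cloud(50, seed = 6, spread = 3)
  pr <- epar(young_E = 10, poisson_eta = 0.3, kv = 5)
  set.seed(30)
  for (k in 1:5) {
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    tr <- runif(2, -2, 2)
    disp <- sweep(ref %*% t(R), 2, tr, "+") - ref
    fe <- elastic_forces(ref, disp, pr, volumes = 0.01)
    fv <- volume_forces(ref, disp, pr, volumes = 0.01)
    expect_lt(max(abs(fe)), 1e-9)
    expect_lt(max(abs(fv)), 1e-9)
  }
})

test_that("reaction-distributed forces sum to zero over the body", {
  ref <- make_cloud(20, seed = 9)
  set.seed(9)
  disp <- matrix(rnorm(40, sd = 0.03), 20, 2)
  pr <- epar(young_E = 10, poisson_eta = 0.3, kv = 4)
  fe <- elastic_forces(ref, disp, pr, volumes = 0.01)
  fv <- volume_forces(ref, disp, pr, volumes = 0.01)
  expect_lt(max(abs(colSums(fe + fv))), 1e-9)
})

test_that("forces are the gradient of the strain and volume energies", {
  ref <- make_cloud(9, seed = 12, spread = 1.2)
  set.seed(12)
  disp <- matrix(rnorm(18, sd = 0.02), 9, 2)
  pr <- epar(young_E = 10, poisson_eta = 0.3, kv = 6)
  vols <- 0.01
  f_el <- elastic_forces(ref, disp, pr, vols)
  g_el <- -oracle_fd_gradient(function(d) elastic_energy(ref, d, pr, vols),
                              disp, step = 1e-6)
  scale <- max(abs(f_el))
  expect_lt(max(abs(f_el - g_el)) / scale, 0.1)
  pr_v <- epar(young_E = 10, poisson_eta = 0.3, kv = 6)
  f_vol <- volume_forces(ref, disp, pr_v, vols)
  U_v <- function(d) {
    st <- hifumotion:::elastic_state(ref, d, pr_v, vols, reaction = FALSE)
    st$energy_volume
  }
  g_vol <- -oracle_fd_gradient(U_v, disp, step = 1e-6)
  expect_lt(max(abs(f_vol - g_vol)) / max(abs(f_vol)), 0.1)
})

test_that("strain energy is non-negative, zero when undeformed, and quadratic", {
  ref <- make_cloud(15, seed = 3)
  pr <- epar(young_E = 10, poisson_eta = 0.25)
  expect_equal(elastic_energy(ref, ref * 0, pr, 0.01), 0)
  set.seed(3)
  disp <- matrix(rnorm(30, sd = 0.005), 15, 2)
  e1 <- elastic_energy(ref, disp, pr, 0.01)
  expect_gt(e1, 0)
  e2 <- elastic_energy(ref, 2 * disp, pr, 0.01)
  expect_equal(e2 / e1, 4, tolerance = 0.05)
})

test_that("small-strain limit agrees with the linear strain tensor", {
  G <- matrix(c(4e-4, -2e-4, 3e-4, 5e-4), 2, 2)
  eps <- green_strain(G)
  lin <- G + t(G)
  expect_lt(max(abs(eps - lin)) / max(abs(lin)), 0.002)
})

test_that("isotropic compression produces outward volume-restoring forces", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ref <- rbind(c(0, 0), cbind(cos(th), sin(th)), 0.5 * cbind(cos(th), sin(th)))
  s <- 0.95
  disp <- (s - 1) * ref
  pr <- epar(young_E = 10, poisson_eta = 0.3, kv = 10, h_e = 1.2)
  fv <- volume_forces(ref, disp, pr, 0.01, reaction = FALSE)
  rim <- 2:13
  radial <- rowSums(fv[rim, ] * ref[rim, ])
  expect_true(all(radial > 0))
  # det J = 1 (undeformed): zero volume force
  f0 <- volume_forces(ref, 0 * ref, pr, 0.01)
  expect_equal(max(abs(f0)), 0, tolerance = 1e-12)
})

test_that("rheological viscosity coefficient follows the angular formula", {
  expect_equal(rheological_viscosity_coefficient(c(1, 0), c(1, 0), c(0, 0),
                                                 c(1, 0), 2, 0.5), 2)
  # perpendicular relative velocity: cos(theta) = 0 -> beta1
  expect_equal(rheological_viscosity_coefficient(c(0, 1), c(0, -1), c(0, 0),
                                                 c(1, 0), 1.5, 0.7), 1.5)
  # aligned motion, |dv|/|dr| = 0.36 -> beta1 (1 - 0.36)^beta2
  expect_equal(rheological_viscosity_coefficient(c(0.36, 0), c(0, 0),
                                                 c(1, 0), c(0, 0), 1, 0.5),
               sqrt(0.64))
  # base clamped at 0 for fast approach
  expect_equal(rheological_viscosity_coefficient(c(5, 0), c(0, 0),
                                                 c(1, 0), c(0, 0), 1, 0.5), 0)
  expect_error(rheological_viscosity_coefficient(c(1, 0), c(0, 0),
                                                 c(1, 1), c(1, 1), 1, 0.5),
               "coincident")
})
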