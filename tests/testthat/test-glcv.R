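# Level-set machinery: regularized step/impulse, localized means, the GLCV
# evolution and its LCV limit, initialization and reinitialization.

test_that("regularized Heaviside/Dirac pair has the right values and limits", {
  hd <- heaviside_dirac(0, eps = 0.37)
  expect_equal(hd$H, 0.5)
  expect_equal(heaviside_dirac(0, eps = 1)$delta, 1 / pi)
  expect_lt(abs(heaviside_dirac(1e6, eps = 1)$H - 1), 1e-5)
  expect_lt(heaviside_dirac(-1e6, eps = 1)$H, 1e-5)
  # delta is the derivative of H
  z <- seq(-3, 3, by = 0.25)
  num <- (heaviside_dirac(z + 1e-6, 0.8)$H - heaviside_dirac(z - 1e-6, 0.8)$H) / 2e-6
  expect_equal(num, heaviside_dirac(z, 0.8)$delta, tolerance = 1e-6)
})

test_that("localized means match the brute-force disc summation", {
  n <- 12
  img <- matrix(0, n, n); img[, (n / 2 + 1):n] <- 200
  phi <- outer(seq_len(n) - 1, seq_len(n) - 1, function(y, x) (n - 1) / 2 - x)
  lm <- local_means_field(img, phi, r = 5, eps = 1)
  o <- oracle_local_means(img, phi, r = 5, eps = 1)
  expect_equal(lm$c1, o$c1, tolerance = 1e-12)
  expect_equal(lm$c2, o$c2, tolerance = 1e-12)
  # pointwise accessor agrees at the boundary pixel
  cm <- local_means(img, phi, x = c(n / 2 - 1, 5), r = 5, eps = 1)
  expect_equal(unname(cm["c1"]), o$c1[6, n / 2], tolerance = 1e-12)
})

test_that("localized means are exact for a constant image and plain disc means", {
  img <- matrix(42, 16, 16)
  phi <- make_test_phi(16)
  lm <- local_means_field(img, phi, r = 4, eps = 1)
  expect_equal(lm$c1, matrix(42, 16, 16), tolerance = 1e-12)
  expect_equal(lm$c2, matrix(42, 16, 16), tolerance = 1e-12)
  # disc entirely on the interior side: c1 equals the plain disc mean
  img2 <- make_test_image(16, seed = 4)
  phi2 <- matrix(50, 16, 16)  # everything deep inside
  lm2 <- local_means_field(img2, phi2, r = 3, eps = 1)
  plain <- oracle_disc_sum(img2, 3) / hifumotion:::disc_size(3)
  # H(50) is not exactly 1, but interior weighting is uniform so the
  # weighted mean equals the plain mean
  expect_equal(lm2$c1[8, 8], plain[8, 8], tolerance = 1e-9)
})

test_that("uniformity indicator uses a strict threshold", {
  expect_equal(uniformity_indicator(5, 5, 10), 1)
  expect_equal(uniformity_indicator(0, 10, 10), 0)  # |diff| == kappa1 -> 0
  expect_equal(uniformity_indicator(0, 200, 10), 0)
  m <- uniformity_indicator(matrix(0, 2, 2), matrix(c(1, 9.99, 10, 11), 2, 2), 10)
  expect_equal(as.vector(m), c(1, 1, 0, 0))
})

test_that("edge stopping is 1 on flat images and follows 1/(1+m^2) on ramps", {
  expect_equal(edge_stopping(matrix(7, 20, 20), 1.5), matrix(1, 20, 20))
  # linear ramp of slope m survives Gaussian smoothing in the interior
  m_slope <- 3
  img <- outer(rep(1, 24), seq_len(24) - 1) * m_slope
  g <- edge_stopping(img, sigma = 1.2)
  expect_equal(g[12, 12], 1 / (1 + m_slope^2), tolerance = 1e-8)
  # step edge: g at the edge strictly below flat-region g
  img2 <- matrix(0, 20, 20); img2[, 11:20] <- 100
  g2 <- edge_stopping(img2, sigma = 1.5)
  expect_lt(g2[10, 10], g2[10, 2])
})

test_that("lcv_energy matches the quadruple-loop oracle and is mu-monotone", {
  img <- make_test_image(8, seed = 2)
  phi <- make_test_phi(8)
  pr <- glcv_params(r = 2, mu = 3, eps = 1, band_width = 3)
  expect_equal(lcv_energy(img, phi, pr),
               oracle_lcv_energy(img, phi, 2, 1, 3), tolerance = 1e-10)
  # constant image with mu = 0: residuals vanish
  pr0 <- glcv_params(r = 2, mu = 0, band_width = 3)
  expect_equal(lcv_energy(matrix(9, 8, 8), phi, pr0), 0, tolerance = 1e-8)
  # energy non-decreasing in mu at fixed phi
  e1 <- lcv_energy(img, phi, glcv_params(r = 2, mu = 1, band_width = 3))
  e2 <- lcv_energy(img, phi, glcv_params(r = 2, mu = 5, band_width = 3))
  expect_gte(e2, e1)
})

test_that("lcv_velocity matches the quadruple-loop oracle on small images", {
  for (seed in 1:3) {
    img <- make_test_image(10, seed = seed)
    phi <- make_test_phi(10)
    pr <- glcv_params(r = 3, mu = if (seed == 1) 0 else 2, eps = 1, band_width = 4)
    v <- lcv_velocity(img, phi, pr)
    o <- oracle_lcv_velocity(img, phi, 3, 1, pr$mu)
    expect_equal(v, o, tolerance = 1e-10)
  }
  # constant image, mu = 0: velocity identically zero
  v0 <- lcv_velocity(matrix(5, 10, 10), make_test_phi(10),
                     glcv_params(r = 3, mu = 0, band_width = 4))
  expect_equal(max(abs(v0)), 0, tolerance = 1e-10)
})

test_that("lcv_velocity is invariant to a constant intensity shift", {
  img <- make_test_image(12, seed = 9)
  phi <- make_test_phi(12)
  pr <- glcv_params(r = 3, mu = 2, band_width = 4)
  v1 <- lcv_velocity(img, phi, pr)
  v2 <- lcv_velocity(img + 77, phi, pr)
  expect_lt(max(abs(v1 - v2)) / max(abs(v1)), 1e-10)
})

test_that("evolving a two-region image with the LCV flow decreases the energy", {
  n <- 24
  img <- matrix(60, n, n)
  img[8:17, 8:17] <- 160
  phi <- make_test_phi(n, cx = 11.5, cy = 11.5, R = 7)
  pr <- glcv_params(r = 4, mu = 0.5, kappa1 = 1e-12, dt = 0.2, band_width = 6)
  e0 <- lcv_energy(img, phi, pr)
  for (it in 1:40) phi <- glcv_step(phi, img, pr)
  expect_lt(lcv_energy(img, phi, pr), e0)
})

test_that("GLCV reduces to the LCV update bitwise when t(x) is 0 everywhere", {
  img <- make_test_image(20, seed = 3, lo = 0, hi = 255)
  phi <- make_test_phi(20)
  pr <- glcv_params(r = 3, kappa1 = 1e-300, mu = 2, band_width = 5, dt = 0.2)
  stepped <- glcv_step(phi, img, pr)
  # reference LCV-only update built from lcv_velocity with the same
  # normalization and band restriction
  v <- lcv_velocity(img, phi, pr)
  band <- abs(phi) <= pr$band_width
  vmax <- max(abs(v[band]))
  ref <- phi
  ref[band] <- phi[band] + pr$dt * (v[band] / vmax)
  expect_identical(as.vector(stepped), as.vector(ref))
})

test_that("geodesic-only step moves a circle at the mean-curvature + balloon rate", {
  n <- 48; R <- 12
  phi <- make_test_phi(n, R = R)
  img <- matrix(100, n, n)  # constant: t(x) = 1, g = 1, LCV fit = 0
  alpha <- -0.4
  pr <- glcv_params(r = 3, kappa1 = 10, mu = 0, alpha = alpha, dt = 1,
                    band_width = 5)
  out <- glcv_step(phi, img, pr, normalize = FALSE)
  # on the contour (phi ~ 0, |grad phi| = 1): dphi = dt delta(0) (kappa + alpha),
  # kappa = -1/R for a shrinking-positive-inside circle
  expected <- heaviside_dirac(0, pr$eps)$delta * (-1 / R + alpha)
  on_contour <- which(abs(phi) < 0.2, arr.ind = TRUE)
  dphi <- (out - phi)[on_contour]
  expect_equal(mean(dphi), expected, tolerance = 0.15 * abs(expected))
})

test_that("level-set initialization gives a signed distance to the init contour", {
  init <- contour_init("ellipse", center = c(24, 24), semi_axes = c(10, 10))
  phi <- initialize_level_set(c(48, 48), init)
  expect_equal(phi[25, 25], 10, tolerance = 0.5)
  expect_lt(phi[1, 1], 0)                      # far corner outside
  expect_lt(abs(phi[25, 35]), 0.71)            # point on the contour
  # polygon init and zero-area rejection
  sq <- contour_init("polygon", polygon = cbind(c(10, 30, 30, 10), c(10, 10, 30, 30)))
  phis <- initialize_level_set(c(48, 48), sq)
  expect_gt(phis[21, 21], 0)
  expect_error(contour_init("polygon", polygon = cbind(c(1, 2, 3), c(1, 2, 3))),
               "degenerate")
})

test_that("reinitialize restores the signed-distance property and keeps the interface", {
  phi <- make_test_phi(40, R = 11)
  # idempotence on an exact signed distance
  expect_lt(max(abs(reinitialize(phi) - phi)), 0.5)
  # gradient renormalization of a scaled field
  out <- reinitialize(3 * phi)
  expect_lt(max(abs(out - phi)), 0.5)
  g <- hifumotion:::grad_central(out)
  nrm <- sqrt(g$gx^2 + g$gy^2)
  away <- abs(out) > 2 & abs(out) < 8
  expect_true(all(nrm[away] > 0.8 & nrm[away] < 1.2))
  # sign pattern preserved away from the interface
  far <- abs(phi) > 1
  expect_true(all((out[far] >= 0) == (phi[far] >= 0)))
  # interface preservation as mask overlap
  expect_gte(dice(reinitialize(phi) >= 0, phi >= 0), 0.99)
  expect_error(reinitialize(matrix(1, 10, 10)), "vanished")
})

test_that("segmentation recovers a noise-free phantom and is stable at the truth", {
  p <- generate_phantom(phantom_spec(size = c(64, 64), radius = 22,
                                     boundary_amp = 0, speckle_shape = Inf,
                                     bias_amp = 0, blur_sd = 1, seed = 21))
  init <- contour_init("ellipse", center = c(31.5, 31.5), semi_axes = c(14, 14))
  fit <- suppressWarnings(
    glcv_segment(p$image, init, glcv_params(alpha = 0.15, kappa1 = 25,
                                            max_iter = 450)))
  expect_gte(dice(fit$mask, p$mask), 0.98)
  expect_s3_class(fit$contour, "tbl_df")
  # initializing at the true contour stays there
  truth_init <- contour_init("ellipse", center = c(31.5, 31.5),
                             semi_axes = c(22, 22))
  fit2 <- suppressWarnings(
    glcv_segment(p$image, truth_init, glcv_params(alpha = 0.15, kappa1 = 25,
                                                  max_iter = 250)))
  expect_gte(dice(fit2$mask, p$mask), 0.98)
})

test_that("segmentation is equivariant under integer image translation", {
  p <- generate_phantom(phantom_spec(size = c(64, 64), center = c(29, 29),
                                     radius = 20, boundary_amp = 0,
                                     speckle_shape = Inf, bias_amp = 0,
                                     blur_sd = 1, seed = 33))
  shift <- 4L
  img_s <- matrix(p$image[1, 1], 64, 64)
  img_s[(1 + shift):64, (1 + shift):64] <- p$image[1:(64 - shift), 1:(64 - shift)]
  pr <- glcv_params(alpha = 0.15, kappa1 = 25, max_iter = 350)
  f1 <- suppressWarnings(glcv_segment(p$image,
    contour_init("ellipse", center = c(29, 29), semi_axes = c(14, 14)), pr))
  f2 <- suppressWarnings(glcv_segment(img_s,
    contour_init("ellipse", center = c(29 + shift, 29 + shift),
                 semi_axes = c(14, 14)), pr))
  m2_back <- f2$mask[(1 + shift):64, (1 + shift):64]
  m1_crop <- f1$mask[1:(64 - shift), 1:(64 - shift)]
  expect_gte(dice(m1_crop, m2_back), 0.98)
})
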