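# Fourier-domain orientation analysis

test_that("alignment coefficient hits its calibration extremes", {
  expect_equal(alignment_coefficient(point_mass_spectrum(45)), 1)
  uniform <- orientation_spectrum(theta_centers(180), rep(1, 180))
  expect_equal(alignment_coefficient(uniform), 0, tolerance = 1e-12)
})

test_that("alignment coefficient matches closed forms on two-bin spectra", {
  spec <- orientation_spectrum(c(0, pi / 4), c(1, 1))
  expect_equal(alignment_coefficient(spec), sqrt(2) / 2)
  spec <- orientation_spectrum(c(0, pi / 2), c(1, 1))
  expect_equal(alignment_coefficient(spec), 0, tolerance = 1e-12)
})

test_that("spectrum constructor validates its inputs", {
  expect_error(orientation_spectrum(c(0, pi), c(1, 1)), "\\[0, pi\\)")
  expect_error(orientation_spectrum(c(0, 1), c(1, -1)), "non-negative")
  expect_error(orientation_spectrum(c(0, 1), c(1, 1, 1)), "equal length")
})

test_that("dominant orientation is the halved doubled-angle circular mean", {
  spec <- point_mass_spectrum(which.min(abs(theta_centers(180) - pi / 3)))
  expect_equal(dominant_orientation(spec), pi / 3, tolerance = pi / 180)
  # perfectly balanced axes: undefined
  balanced <- orientation_spectrum(c(0, pi / 2), c(1, 1))
  expect_error(dominant_orientation(balanced), "undefined")
  # 2:1 energy at 0 vs pi/2 resolves to 0
  spec <- orientation_spectrum(c(0, pi / 2), c(2, 1))
  expect_equal(dominant_orientation(spec), 0)
})

test_that("sinusoidal stripes concentrate band energy at the stripe axis", {
  n <- 128
  img <- 0.5 + 0.5 * matrix(sin(2 * pi * 0.15 * seq_len(n)), n, n)
  # intensity varies with row only: stripe/fiber axis horizontal, theta = 0
  spec <- angular_spectrum(img)
  near0 <- spec$theta_bins < 5 * pi / 180 | spec$theta_bins > pi - 5 * pi / 180
  expect_gte(sum(spec$energy[near0]) / spec$total_energy, 0.9)
  expect_lt(min(abs(c(dominant_orientation(spec) - 0,
                      dominant_orientation(spec) - pi))), 5 * pi / 180)
  # the same pattern rotated 90 degrees (transpose) -> vertical axis
  spec_t <- angular_spectrum(t(img))
  expect_equal(dominant_orientation(spec_t), pi / 2, tolerance = 5 * pi / 180)
})

test_that("white noise is near-isotropic", {
  coefs <- vapply(1:10, function(s) {
    set.seed(s)
    alignment_coefficient(angular_spectrum(matrix(runif(128^2), 128, 128)))
  }, numeric(1))
  expect_lt(mean(coefs), 0.1)
})

test_that("constant images and invalid bands are rejected", {
  expect_error(angular_spectrum(matrix(1, 32, 32)), "degenerate")
  m <- matrix(runif(64), 8, 8)
  expect_error(angular_spectrum(m, r_min = 0.3, r_max = 0.2), "r_min < r_max")
  expect_error(angular_spectrum(m, r_min = 0, r_max = 0.7), "<= 0.5")
})

test_that("density counts the non-zero pixel fraction", {
  expect_equal(fiber_density(matrix(0, 10, 10)), 0)
  m <- matrix(0, 10, 10)
  m[1:25] <- 0.5
  expect_equal(fiber_density(m), 0.25)
  expect_error(fiber_density(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("density is monotone under union of fibrous signal", {
  s1 <- generate_fiber_image(small_field(seed = 4L))
  s2 <- generate_fiber_image(small_field(seed = 5L))
  e1 <- enhance(isolate_collagen(rgb_to_lab(s1$image)))$values
  e2 <- enhance(isolate_collagen(rgb_to_lab(s2$image)))$values
  expect_gte(fiber_density(pmax(e1, e2)), fiber_density(e1))
  expect_gte(fiber_density(pmax(e1, e2)), fiber_density(e2))
})

test_that("full chain tracks the ground-truth alignment at both extremes", {
  sim_hi <- generate_fiber_image(medium_field(kappa = 100,
                                              mean_orientation = pi / 4,
                                              seed = 2L))
  res_hi <- analyze_image(sim_hi$image)
  expect_gte(res_hi$coefficient, 0.8)
  expect_lt(abs(res_hi$coefficient - true_alignment(sim_hi$truth$orientations)),
            0.15)
  expect_equal(res_hi$dominant_orientation, pi / 4, tolerance = 5 * pi / 180)

  lo <- vapply(1:10, function(s) {
    sim <- generate_fiber_image(medium_field(kappa = 0, seed = s))
    analyze_image(sim$image)$coefficient
  }, numeric(1))
  expect_lte(mean(lo), 0.15)
  expect_true(all(lo >= 0 & lo <= 1))
})

test_that("blank input fails with the degenerate stage named", {
  sim <- generate_fiber_image(small_field(n_fibers = 0L, noise_sd = 0))
  expect_error(analyze_image(sim$image), "angular_spectrum")
})

test_that("the coefficient is robust to 2x downsampling", {
  sim <- generate_fiber_image(medium_field(kappa = 8, seed = 9L))
  full <- analyze_image(sim$image)$coefficient
  half <- analyze_image(downsample_rgb(sim$image, 2L))$coefficient
  expect_lt(abs(full - half), 0.1)
})
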