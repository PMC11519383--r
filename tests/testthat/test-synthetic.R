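# simulator: fiber fields, ground-truth alignment, wound series

test_that("ground-truth alignment matches closed forms", {
  expect_equal(true_alignment(rep(0.3, 7)), 1)
  expect_equal(true_alignment(c(0, pi / 2)), 0, tolerance = 1e-12)
  expect_equal(true_alignment(c(0, pi / 4)), sqrt(2) / 2)
  expect_error(true_alignment(numeric(0)), "non-empty")
})

test_that("an empty field is pure background and has zero density", {
  p <- small_field(n_fibers = 0L, noise_sd = 0)
  sim <- generate_fiber_image(p)
  for (ch in 1:3) {
    expect_true(all(sim$image[, , ch] == p$background_color[ch]))
  }
  expect_equal(sum(sim$truth$fiber_mask), 0)
  enh <- enhance(isolate_collagen(rgb_to_lab(sim$image)))
  expect_equal(fiber_density(enh), 0)
})

test_that("generation is byte-identical for identical params and seed", {
  p <- small_field(n_red_blobs = 3L, seed = 7L)
  s1 <- generate_fiber_image(p)
  s2 <- generate_fiber_image(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_fiber_image(small_field(n_red_blobs = 3L, seed = 8L))
  expect_false(identical(s1$image, s3$image))
})

test_that("highly concentrated fields are near-perfectly aligned", {
  p <- fiber_field_params(n_fibers = 200L, kappa = 100,
                          mean_orientation = pi / 4, image_size = 64L,
                          fiber_length = 20, seed = 1L)
  sim <- generate_fiber_image(p)
  expect_length(sim$truth$orientations, 200L)
  expect_gte(true_alignment(sim$truth$orientations), 0.98)
})

test_that("isotropic fields have near-zero alignment on average", {
  r <- vapply(1:30, function(s) {
    th <- (rvonmises(500, 0, 0) / 2) %% pi
    true_alignment(th)
  }, numeric(1))
  expect_lt(mean(r), 0.1)
})

test_that("expected alignment is non-decreasing in concentration", {
  kappas <- c(0, 0.5, 1, 2, 4, 8, 16, 100)
  means <- vapply(kappas, function(k) {
    mean(vapply(1:20, function(s) {
      set.seed(1000 + s)
      true_alignment((rvonmises(300, pi / 2, k) / 2) %% pi)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("generated stain colours honour the CIELAB isolation contract", {
  p <- small_field(noise_sd = 0, seed = 12L)
  sim <- generate_fiber_image(p)
  lab <- rgb_to_lab(sim$image)
  # fiber pixels (majority fiber coverage) are blue-dominant
  expect_true(all(lab$b[sim$truth$fiber_mask] < 0))
  # untouched background pixels are near-neutral
  bg <- sim$image[, , 1] == p$background_color[1] &
    sim$image[, , 2] == p$background_color[2] &
    sim$image[, , 3] == p$background_color[3]
  expect_gt(sum(bg), 0)
  expect_true(all(abs(lab$b[bg]) < 5) && all(abs(lab$a[bg]) < 5))
})

test_that("invalid fiber-field parameters are rejected at construction", {
  expect_error(fiber_field_params(image_size = 100.5), "integer")
  expect_error(fiber_field_params(n_fibers = -1), "non-negative")
  expect_error(fiber_field_params(kappa = -2), "non-negative")
  expect_error(fiber_field_params(mean_orientation = pi), "\\[0, pi\\)")
  expect_error(fiber_field_params(collagen_color = c(200, 60, 80)),
               "blue-dominant") # a red stain cannot stand in for collagen
  expect_error(fiber_field_params(background_color = c(0, 0, 255)),
               "near-neutral")
  expect_error(fiber_field_params(collagen_color = c(-5, 0, 300)),
               "\\[0, 255\\]")
})

test_that("wound series follow the decay model and its limits", {
  # zero-rate limit: constant at Y0
  ws <- generate_wound_series(wound_series_params(Y0 = 6, plateau = 0, k = 0,
                                                  noise_sd = 0))
  expect_true(all(ws$area == 6))
  # half-life identity: Y0=4, k=ln 2, plateau 0 -> area 2 at day 1
  ws <- generate_wound_series(wound_series_params(Y0 = 4, plateau = 0,
                                                  k = log(2), times = 0:3,
                                                  noise_sd = 0))
  expect_equal(ws$area[ws$time == 1], 2)
  # seeded reproducibility
  p <- wound_series_params(noise_sd = 0.5, seed = 99L)
  expect_identical(generate_wound_series(p), generate_wound_series(p))
  expect_false(identical(
    generate_wound_series(p),
    generate_wound_series(wound_series_params(noise_sd = 0.5, seed = 100L))
  ))
})

test_that("invalid wound-series parameters are rejected", {
  expect_error(wound_series_params(Y0 = 1, plateau = 2), "Y0 >= plateau")
  expect_error(wound_series_params(times = c(0, 2, 1)),
               "strictly increasing")
  expect_error(wound_series_params(times = 1:5), "start at 0")
  expect_error(wound_series_params(k = -1), "non-negative")
})
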