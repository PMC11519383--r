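# shared fixture builders: small, fast fields for unit tests; the acceptance
# suite uses full-size fields

small_field <- function(...) {
  args <- utils::modifyList(
    list(image_size = 160L, n_fibers = 80L, fiber_length = 50,
         fiber_width = 3),
    list(...)
  )
  do.call(fiber_field_params, args)
}

medium_field <- function(...) {
  args <- utils::modifyList(
    list(image_size = 256L, n_fibers = 150L, fiber_length = 80,
         fiber_width = 3),
    list(...)
  )
  do.call(fiber_field_params, args)
}

# evenly spaced bin centres over [0, pi)
theta_centers <- function(n) (seq_len(n) - 0.5) * pi / n

point_mass_spectrum <- function(at_bin, n_bins = 180L, energy = 1) {
  e <- numeric(n_bins)
  e[at_bin] <- energy
  orientation_spectrum(theta_centers(n_bins), e)
}
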