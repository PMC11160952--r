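# Shared helpers: small, fast synthetic inputs built in code.

# Quick angiogram parameters: 150 px at 0.04 mm/px still covers 6 mm but
# generates in well under a second.
quick_gen_params <- function(...) {
  args <- list(image_size = 150L, pixel_pitch = 0.04, noise_sd = 0,
               n_big_vessels = 2L, big_vessel_width = 4, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(image_gen_params, args)
}

# Random star-shaped polygon (simple by construction): sorted angles with
# positive radii about the origin.
random_star_polygon <- function(n = 20L, rmin = 0.2, rmax = 1) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(x = r * cos(theta), y = r * sin(theta))
}

# Regular polygon approximating a circle.
regular_polygon <- function(n, radius, center = c(0, 0)) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + radius * cos(theta),
        y = center[2] + radius * sin(theta))
}

fit_quietly <- function(...) {
  suppressWarnings(suppressMessages(fit_intereye_model(...)))
}
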