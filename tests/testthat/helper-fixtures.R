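## Shared fixtures, built once per test run and memoized. Sheets and
## receptive-field weight matrices are deterministic; weight construction
## is the only moderately expensive step.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

## reference patch for a sheet's raster geometry (annulus layout irrelevant)
ref_patch_for <- function(sheet, deg_per_pixel = 0.05) {
  with_stream(1, generate_model_patch(list(zeta = 1, rho = 1),
                                      center = sheet$region_center,
                                      side = sheet$region_side,
                                      deg_per_pixel = deg_per_pixel))
}

sheet6 <- function() memo("sheet6", build_sheet(n = 6))
weights6 <- function() memo("weights6", rf_weights(sheet6(), ref_patch_for(sheet6())))
sheet10 <- function() memo("sheet10", build_sheet(n = 10))
weights10 <- function() memo("weights10", rf_weights(sheet10(), ref_patch_for(sheet10())))
sheet20 <- function() memo("sheet20", build_sheet(n = 20))
weights20 <- function() memo("weights20", rf_weights(sheet20(), ref_patch_for(sheet20())))

## hand-built single-oscillator sheet for weight/contrast unit tests
toy_sheet <- function(center = c(0, 0), sigma = 0.25) {
  structure(list(n = 1L, N = 1L,
                 rf_centers = matrix(center, 1, 2,
                                     dimnames = list(NULL, c("x", "y"))),
                 rf_sigma = sigma,
                 cortical_coords = matrix(0, 1, 2),
                 distances = matrix(0, 1, 1),
                 region_center = center, region_side = 1,
                 params = retinotopy_params()),
            class = "oscillator_sheet")
}

## hand-built texture patch from a luminance matrix
toy_patch <- function(L, deg_per_pixel = 0.1, center = c(0, 0)) {
  npx <- nrow(L); npy <- ncol(L)
  xs <- center[1] - npx * deg_per_pixel / 2 + (seq_len(npx) - 0.5) * deg_per_pixel
  ys <- center[2] - npy * deg_per_pixel / 2 + (seq_len(npy) - 0.5) * deg_per_pixel
  structure(list(luminance = L, xs = xs, ys = ys,
                 deg_per_pixel = deg_per_pixel, origin = c(xs[1], ys[1]),
                 background_luminance = 60.76,
                 annuli = data.frame(x = numeric(0), y = numeric(0),
                                     contrast = numeric(0))),
            class = "texture_patch")
}

## hand-built phase trajectory from a (timepoints x N) phase matrix
toy_trajectory <- function(theta, duration = 1) {
  structure(list(times = seq(0, duration, length.out = nrow(theta)),
                 theta = theta,
                 omega = rep(0, ncol(theta))),
            class = "phase_trajectory")
}
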