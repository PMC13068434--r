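## Texture stimulus synthesis: grids of non-overlapping Gabor annuli whose
## per-element contrasts are drawn at a given contrast heterogeneity (zeta)
## and whose spacing is scaled by a grid-coarseness factor (rho).

#' Gabor annulus parameters
#'
#' Geometry and luminance of a single texture element: a ring-shaped
#' grating patch that is equiluminant on average with the background.
#'
#' @param diameter annulus diameter in degrees of visual angle.
#' @param spatial_frequency carrier spatial frequency in cycles/degree.
#' @param mean_luminance mean luminance of the annulus in cd/m^2.
#' @param background_luminance luminance of the uniform background in cd/m^2.
#' @return an object of class `annulus_params`.
#' @export
annulus_params <- function(diameter = 0.7, spatial_frequency = 5.7,
                           mean_luminance = 60.76,
                           background_luminance = 60.76) {
  if (diameter <= 0 || spatial_frequency <= 0 ||
      mean_luminance <= 0 || background_luminance <= 0)
    stop_invalid("annulus parameters must be positive")
  structure(list(diameter = diameter,
                 spatial_frequency = spatial_frequency,
                 mean_luminance = mean_luminance,
                 background_luminance = background_luminance),
            class = "annulus_params")
}

#' Build the Cartesian grid of stimulus conditions
#'
#' The two manipulated factors are contrast heterogeneity `zeta` (the width
#' of the uniform distribution, centred at 0.5, from which annulus contrasts
#' are drawn) and grid coarseness `rho` (a multiplicative scale on the
#' centre-to-centre spacing of the annuli). The canonical 5 x 5 design uses
#' zeta in {0.01, 0.2575, 0.505, 0.7525, 1} and rho in
#' {1, 1.125, 1.25, 1.375, 1.5}; other sizes space levels evenly over
#' [0.01, 1] and [1, 1.5] (the 5 x 5 levels are themselves evenly spaced,
#' so the canonical design is the `n = 5` special case).
#'
#' @param n_zeta,n_rho number of levels per factor (>= 2).
#' @return a data.frame with one row per condition and columns
#'   `zeta_level`, `rho_level`, `zeta`, `rho`.
#' @examples
#' nrow(build_condition_grid(5, 5))   # 25 conditions
#' nrow(build_condition_grid(30, 30)) # 900 conditions
#' @export
build_condition_grid <- function(n_zeta = 5, n_rho = 5) {
  if (n_zeta < 2 || n_rho < 2)
    stop_invalid("need at least 2 levels per factor")
  zl <- seq(0.01, 1, length.out = n_zeta)
  rl <- seq(1, 1.5, length.out = n_rho)
  g <- expand.grid(zeta_level = seq_len(n_zeta), rho_level = seq_len(n_rho))
  g$zeta <- zl[g$zeta_level]
  g$rho <- rl[g$rho_level]
  g
}

#' Sample annulus contrasts at a given contrast heterogeneity
#'
#' Contrasts are i.i.d. uniform on `[0.5 - zeta/2, 0.5 + zeta/2]`; the mean
#' contrast is 0.5 regardless of `zeta`. Background texture uses `zeta = 1`
#' (the full range `[0, 1]`).
#'
#' @param n number of draws.
#' @param zeta contrast heterogeneity in (0, 1].
#' @return numeric vector of contrasts in `[0, 1]`.
#' @export
sample_contrasts <- function(n, zeta) {
  if (zeta <= 0 || zeta > 1) stop_invalid("zeta must be in (0, 1]")
  if (n < 1) stop_invalid("n must be >= 1")
  runif(n, 0.5 - zeta / 2, 0.5 + zeta / 2)
}

#' Place annulus centres on a jittered regular grid
#'
#' Centres start on a regular square grid with spacing `base_spacing * rho`
#' (anchored at the region centre) and are then displaced in a random
#' direction by a uniform radial distance between zero and half the
#' edge-to-edge gap of neighbouring annuli, `(spacing - diameter) / 2`.
#' That jitter bound guarantees non-overlap by construction: two centres
#' can approach each other by at most `spacing - diameter`.
#'
#' @param region_width,region_height extent of the region, degrees.
#' @param rho grid coarseness scale (>= 1).
#' @param annulus an [annulus_params()] object.
#' @param base_spacing centre-to-centre spacing at `rho = 1`, degrees.
#' @return a two-column matrix of centre coordinates relative to the region
#'   centre at the origin.
#' @export
place_annulus_centers <- function(region_width, region_height, rho,
                                  annulus = annulus_params(),
                                  base_spacing = 0.9) {
  s <- base_spacing * rho
  d <- annulus$diameter
  if (s < d) stop_invalid("grid spacing smaller than annulus diameter")
  mx <- floor((region_width - d) / s) + 1
  my <- floor((region_height - d) / s) + 1
  if (mx * my < 4) stop_invalid("region too small for at least 4 annuli")
  px <- (seq_len(mx) - (mx + 1) / 2) * s
  py <- (seq_len(my) - (my + 1) / 2) * s
  cx <- rep(px, each = my)
  cy <- rep(py, times = mx)
  jr <- runif(length(cx), 0, (s - d) / 2)
  ja <- runif(length(cx), 0, 2 * pi)
  cbind(x = cx + jr * cos(ja), y = cy + jr * sin(ja))
}

## radially symmetric luminance-modulation profile of one annulus, defined
## on a pixel grid of radial distances rr; zero mean over its support and
## normalised to max |g| = 1 so L = Lbar * (1 + c * g) stays within
## Lbar * (1 +/- c)
annulus_profile <- function(rr, annulus) {
  d <- annulus$diameter
  mask <- rr <= d / 2
  raw <- exp(-(rr - d / 4)^2 / (2 * (d / 8)^2)) *
    cos(2 * pi * annulus$spatial_frequency * rr)
  g <- raw - mean(raw[mask])
  g / max(abs(g[mask]))
}

#' Render a texture patch from annulus centres and contrasts
#'
#' Each annulus is drawn as `L = Lbar * (1 + c * g(r))` where `g` is a
#' radially symmetric carrier windowed by an annular Gaussian envelope
#' (ring radius `diameter / 4`, envelope SD `diameter / 8`, hard cutoff at
#' `diameter / 2`), shifted to zero mean over its support so that every
#' annulus is exactly equiluminant with the background. Pixels outside all
#' annuli equal the background luminance.
#'
#' @param centers two-column matrix of annulus centres, degrees (absolute
#'   visual-field coordinates).
#' @param contrasts per-annulus Michelson-type contrasts in `[0, 1]`.
#' @param annulus an [annulus_params()] object.
#' @param deg_per_pixel raster resolution, degrees per pixel.
#' @param center visual-field coordinates of the raster centre, degrees.
#' @param width,height raster extent, degrees.
#' @return an object of class `texture_patch`: a list with the luminance
#'   raster (rows index x, columns index y), pixel-centre coordinate axes
#'   `xs`/`ys`, resolution, and an `annuli` data.frame.
#' @export
render_patch <- function(centers, contrasts, annulus = annulus_params(),
                         deg_per_pixel = 0.05, center = c(0, 0),
                         width = 6.7, height = width) {
  if (nrow(centers) != length(contrasts))
    stop_invalid("centers and contrasts lengths differ")
  if (length(contrasts) && (min(contrasts) < 0 || max(contrasts) > 1))
    stop_invalid("contrasts must lie in [0, 1]")
  if (deg_per_pixel <= 0) stop_invalid("deg_per_pixel must be positive")
  npx <- max(1L, round(width / deg_per_pixel))
  npy <- max(1L, round(height / deg_per_pixel))
  xs <- center[1] - width / 2 + (seq_len(npx) - 0.5) * deg_per_pixel
  ys <- center[2] - height / 2 + (seq_len(npy) - 0.5) * deg_per_pixel
  Lbar <- annulus$mean_luminance
  L <- matrix(annulus$background_luminance, npx, npy)
  d <- annulus$diameter
  for (k in seq_along(contrasts)) {
    ix <- which(abs(xs - centers[k, 1]) <= d / 2)
    iy <- which(abs(ys - centers[k, 2]) <= d / 2)
    if (!length(ix) || !length(iy)) next
    rr <- sqrt(outer((xs[ix] - centers[k, 1])^2,
                     (ys[iy] - centers[k, 2])^2, "+"))
    mask <- rr <= d / 2
    if (!any(mask)) next
    g <- annulus_profile(rr, annulus)
    sub <- L[ix, iy, drop = FALSE]
    sub[mask] <- Lbar * (1 + contrasts[k] * g[mask])
    L[ix, iy] <- sub
  }
  structure(list(luminance = L, xs = xs, ys = ys,
                 deg_per_pixel = deg_per_pixel,
                 origin = c(xs[1], ys[1]),
                 background_luminance = annulus$background_luminance,
                 annuli = data.frame(x = centers[, 1], y = centers[, 2],
                                     contrast = contrasts)),
            class = "texture_patch")
}

#' @exportS3Method base::print
print.texture_patch <- function(x, ...) {
  cat(sprintf(
    "texture_patch: %d x %d px (%.3f deg/px), %d annuli, background %.2f cd/m2\n",
    nrow(x$luminance), ncol(x$luminance), x$deg_per_pixel,
    nrow(x$annuli), x$background_luminance))
  invisible(x)
}

#' Generate the model's input patch for one stimulus condition
#'
#' Renders the square region of the visual field feeding the oscillator
#' sheet: side `sqrt(45)` degrees (the area of the 9 x 5 degree figure),
#' centred at 7 degrees eccentricity on the horizontal meridian by default.
#' Annuli are placed at coarseness `rho` and contrasts sampled at
#' heterogeneity `zeta`.
#'
#' @param condition a list or one-row data.frame with elements `zeta`, `rho`.
#' @param annulus an [annulus_params()] object.
#' @param center region centre in visual-field degrees.
#' @param side region side length, degrees.
#' @param deg_per_pixel raster resolution.
#' @param base_spacing annulus grid spacing at `rho = 1`, degrees.
#' @return a `texture_patch`.
#' @export
generate_model_patch <- function(condition, annulus = annulus_params(),
                                 center = c(7, 0), side = sqrt(45),
                                 deg_per_pixel = 0.05, base_spacing = 0.9) {
  centers <- place_annulus_centers(side, side, condition$rho, annulus,
                                   base_spacing)
  centers <- sweep(centers, 2, center, "+")
  contrasts <- sample_contrasts(nrow(centers), condition$zeta)
  render_patch(centers, contrasts, annulus, deg_per_pixel,
               center = center, width = side, height = side)
}

#' Figure geometry for full behavioural displays
#'
#' The figure is a rectangle of nominally 9 x 5 degrees (long axis horizontal
#' or vertical), centred at nominally 7 degrees eccentricity, lying wholly
#' within one visual-field quadrant. Width, height and eccentricity are
#' jittered uniformly within the stated tolerances when sampled.
#'
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param quadrant visual-field quadrant 1-4 (counter-clockwise from
#'   upper-right).
#' @param width,height nominal long/short side, degrees.
#' @param width_jitter,height_jitter,ecc_jitter half-ranges of the uniform
#'   jitter on width, height and eccentricity.
#' @param eccentricity nominal eccentricity of the figure centre, degrees.
#' @return an object of class `figure_geometry`.
#' @export
figure_geometry <- function(orientation = c("vertical", "horizontal"),
                            quadrant = 4, width = 9, height = 5,
                            eccentricity = 7, width_jitter = 0.7,
                            height_jitter = 0.4, ecc_jitter = 1) {
  orientation <- match.arg(orientation)
  if (!quadrant %in% 1:4) stop_invalid("quadrant must be 1, 2, 3 or 4")
  structure(list(orientation = orientation, quadrant = quadrant,
                 width = width, height = height,
                 eccentricity = eccentricity, width_jitter = width_jitter,
                 height_jitter = height_jitter, ecc_jitter = ecc_jitter),
            class = "figure_geometry")
}

## realize a figure rectangle: jitter sizes and eccentricity, then pick a
## polar angle (uniform over the feasible range) keeping the rectangle
## wholly inside its quadrant; returns centre and half-sizes
sample_figure_rect <- function(figure) {
  w <- figure$width + runif(1, -figure$width_jitter, figure$width_jitter)
  h <- figure$height + runif(1, -figure$height_jitter, figure$height_jitter)
  ecc <- figure$eccentricity + runif(1, -figure$ecc_jitter, figure$ecc_jitter)
  if (figure$orientation == "vertical") { tmp <- w; w <- h; h <- tmp }
  ## quadrant interior: angle in (0, 90) degrees for quadrant 1 etc.; the
  ## rectangle (axis-aligned) must keep |x| >= w/2 and |y| >= h/2 margins
  lo <- asin(min(1, (h / 2) / ecc))
  hi <- acos(min(1, (w / 2) / ecc))
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop_invalid("figure cannot fit inside a single quadrant")
  ang <- runif(1, lo, hi)
  sx <- c(1, -1, -1, 1)[figure$quadrant]
  sy <- c(1, 1, -1, -1)[figure$quadrant]
  list(cx = sx * ecc * cos(ang), cy = sy * ecc * sin(ang),
       half_w = w / 2, half_h = h / 2, eccentricity = ecc)
}

#' Generate a full behavioural display
#'
#' Renders a full-field texture with background annuli at maximum contrast
#' heterogeneity (`zeta = 1`) and annuli whose centres fall inside the
#' figure rectangle drawn at the condition's heterogeneity. The figure's
#' polar angle is randomised within its quadrant.
#'
#' @inheritParams generate_model_patch
#' @param figure a [figure_geometry()] object.
#' @param display_width,display_height display extent, degrees.
#' @return a `texture_patch`; the realised figure rectangle is attached as
#'   attribute `"figure_rect"`.
#' @export
generate_full_display <- function(condition, figure = figure_geometry(),
                                  annulus = annulus_params(),
                                  display_width = 30, display_height = 24,
                                  deg_per_pixel = 0.1, base_spacing = 0.9) {
  rect <- sample_figure_rect(figure)
  if (abs(rect$cx) < rect$half_w || abs(rect$cy) < rect$half_h)
    stop_invalid("figure crosses a quadrant boundary")
  centers <- place_annulus_centers(display_width, display_height,
                                   condition$rho, annulus, base_spacing)
  inside <- abs(centers[, 1] - rect$cx) <= rect$half_w &
    abs(centers[, 2] - rect$cy) <= rect$half_h
  contrasts <- sample_contrasts(nrow(centers), 1)
  if (any(inside))
    contrasts[inside] <- sample_contrasts(sum(inside), condition$zeta)
  patch <- render_patch(centers, contrasts, annulus, deg_per_pixel,
                        center = c(0, 0), width = display_width,
                        height = display_height)
  patch$annuli$in_figure <- inside
  attr(patch, "figure_rect") <- rect
  patch
}
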