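## Retinotopically mapped oscillator sheet: receptive-field centres on a
## regular grid in visual space, cortical positions through a
## complex-logarithmic (monopole) map, eccentricity-scaled RF sizes, and
## the distance-dependent initial coupling matrix.

#' Retinotopic map parameters
#'
#' The monopole complex-logarithmic approximation of the V1 retinotopic map,
#' `w = alpha * log(z + a)`, with `z` the complex visual-field position in
#' degrees. With the generic human values `a = 0.7`, `alpha = 0.9` the map
#' returns cortical position in centimetres; `mm_per_unit` converts map
#' units to millimetres, the unit in which the coupling decay constant
#' (estimated from macaque recordings as decay per millimetre of cortex)
#' is expressed.
#'
#' @param a foveal shift of the map, degrees.
#' @param alpha map scale.
#' @param mm_per_unit millimetres of cortex per map unit.
#' @return an object of class `retinotopy_params`.
#' @export
retinotopy_params <- function(a = 0.7, alpha = 0.9, mm_per_unit = 10) {
  if (a <= 0 || alpha <= 0 || mm_per_unit <= 0)
    stop_invalid("retinotopy parameters must be positive")
  structure(list(a = a, alpha = alpha, mm_per_unit = mm_per_unit),
            class = "retinotopy_params")
}

#' Lateral coupling parameters
#'
#' Maximum coupling strength and exponential decay per millimetre of
#' cortical distance, both taken as constants from independent macaque
#' electrophysiology.
#'
#' @param gamma maximum coupling strength (rad/s).
#' @param lambda coupling decay factor per millimetre of cortical distance.
#' @return an object of class `coupling_config`.
#' @export
coupling_config <- function(gamma = 24.63, lambda = 0.22) {
  if (gamma <= 0 || lambda < 0)
    stop_invalid("gamma must be > 0 and lambda >= 0")
  structure(list(gamma = gamma, lambda = lambda), class = "coupling_config")
}

#' Map visual-field coordinates to cortical coordinates
#'
#' Applies the monopole map `w = alpha * log(z + a)` to each point and
#' scales to millimetres. Real (horizontal-meridian) inputs map to real
#' outputs; local magnification `|dw/dz| = alpha / |z + a|` decreases with
#' eccentricity.
#'
#' @param points two-column matrix (or length-2 vector) of visual
#'   coordinates, degrees.
#' @param params a [retinotopy_params()] object.
#' @return two-column matrix of cortical coordinates, millimetres.
#' @examples
#' visual_to_cortical(c(0, 0))  # fixation: 10 * 0.9 * log(0.7) mm
#' @export
visual_to_cortical <- function(points, params = retinotopy_params()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  z <- complex(real = points[, 1], imaginary = points[, 2])
  if (any(Mod(z + params$a) < .Machine$double.eps * 10))
    stop_invalid("point at the map singularity z = -a")
  w <- params$alpha * log(z + params$a) * params$mm_per_unit
  cbind(Re(w), Im(w))
}

#' Receptive-field diameter from eccentricity
#'
#' Threshold-linear V1 scaling: `max(0.172 * e - 0.25, 1)` degrees.
#'
#' @param eccentricity eccentricity in degrees (vectorised, >= 0).
#' @return receptive-field diameter, degrees.
#' @examples
#' rf_diameter(7)   # 1 (below the 1-degree floor)
#' rf_diameter(10)  # 1.47
#' @export
rf_diameter <- function(eccentricity) {
  if (any(eccentricity < 0)) stop_invalid("eccentricity must be >= 0")
  pmax(0.172 * eccentricity - 0.25, 1)
}

#' Gaussian SD from receptive-field diameter
#'
#' Composes the Gaussian-beam relation `FWHM = sqrt(ln 2)/sqrt(2) * diameter`
#' with `sigma = FWHM / (2 sqrt(2 ln 2))`, which collapses to exactly one
#' quarter of the diameter.
#'
#' @param diameter receptive-field diameter, degrees (> 0).
#' @return Gaussian standard deviation, degrees.
#' @export
diameter_to_sigma <- function(diameter) {
  if (any(diameter <= 0)) stop_invalid("diameter must be positive")
  diameter / 4
}

#' Build the oscillator sheet
#'
#' Lays an `n x n` regular grid of receptive-field centres over the square
#' model region, maps them to cortex with [visual_to_cortical()], assigns
#' each oscillator a Gaussian RF whose SD follows the threshold-linear
#' eccentricity scaling at its own centre, and computes the full matrix of
#' pairwise Euclidean cortical distances. Receptive fields are equally
#' spaced in the visual field but, through cortical magnification, not on
#' the cortical surface.
#'
#' @param region_center centre of the region, visual degrees.
#' @param region_side side length of the square region, degrees.
#' @param n grid side; the sheet holds `N = n^2` oscillators.
#' @param params a [retinotopy_params()] object.
#' @return an object of class `oscillator_sheet` with fields `n`, `N`,
#'   `rf_centers` (N x 2, degrees), `rf_sigma` (degrees),
#'   `cortical_coords` (N x 2, mm), `distances` (N x N, mm).
#' @export
build_sheet <- function(region_center = c(7, 0), region_side = sqrt(45),
                        n = 20, params = retinotopy_params()) {
  if (n < 2) stop_invalid("n must be >= 2")
  pos <- (seq_len(n) - (n + 1) / 2) * region_side / n
  X <- rep(pos, each = n) + region_center[1]
  Y <- rep(pos, times = n) + region_center[2]
  cc <- visual_to_cortical(cbind(X, Y), params)
  ecc <- sqrt(X^2 + Y^2)
  sig <- diameter_to_sigma(rf_diameter(ecc))
  structure(list(n = n, N = n^2, rf_centers = cbind(x = X, y = Y),
                 rf_sigma = sig, cortical_coords = cc,
                 distances = as.matrix(dist(cc)),
                 region_center = region_center, region_side = region_side,
                 params = params),
            class = "oscillator_sheet")
}

#' @exportS3Method base::print
print.oscillator_sheet <- function(x, ...) {
  cat(sprintf(
    "oscillator_sheet: %d x %d = %d oscillators over %.2f deg at (%g, %g); cortical extent %.2f mm\n",
    x$n, x$n, x$N, x$region_side, x$region_center[1], x$region_center[2],
    max(x$distances)))
  invisible(x)
}

#' Session-1 coupling matrix from cortical distance
#'
#' `K_ij = gamma * exp(-lambda * d_ij)`: maximal at zero distance, decaying
#' exponentially along the cortical surface. The diagonal is stored as zero
#' (self-coupling contributes `sin(0) = 0` to the dynamics regardless).
#'
#' @param sheet an [build_sheet()] result.
#' @param config a [coupling_config()] object.
#' @return an object of class `coupling_matrix`: list with the `N x N`
#'   matrix `K`, `session = 1` and `gamma`.
#' @export
initial_coupling <- function(sheet, config = coupling_config()) {
  K <- config$gamma * exp(-config$lambda * sheet$distances)
  diag(K) <- 0
  structure(list(K = K, session = 1L, gamma = config$gamma),
            class = "coupling_matrix")
}

#' @exportS3Method base::print
print.coupling_matrix <- function(x, ...) {
  off <- x$K[upper.tri(x$K)]
  cat(sprintf(
    "coupling_matrix (session %d): %d x %d, off-diagonal range [%.3f, %.3f], gamma = %.2f\n",
    x$session, nrow(x$K), ncol(x$K), min(off), max(off), x$gamma))
  invisible(x)
}

## accept either a coupling_matrix or a plain numeric matrix
as_K <- function(K) {
  if (inherits(K, "coupling_matrix")) K$K
  else if (is.matrix(K)) K
  else stop_invalid("K must be a matrix or coupling_matrix")
}
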