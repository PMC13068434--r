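## Arnold tongue container and comparison metrics: min-max normalization,
## Pearson correlation, weighted Jaccard similarity, Simpson tongue
## volume, 2D psychometric surface with 75% contour, and fold-based noise
## ceilings.

#' Arnold tongue container
#'
#' A gridded map over contrast heterogeneity (rows) and grid coarseness
#' (columns) holding synchrony, accuracy or response probability.
#'
#' @param values numeric matrix, `length(zeta_axis)` x `length(rho_axis)`.
#' @param zeta_axis,rho_axis strictly increasing level values.
#' @param kind one of `"synchrony"`, `"accuracy"`, `"probability"`.
#' @param normalized has min-max normalization been applied?
#' @return an object of class `arnold_tongue`.
#' @export
arnold_tongue <- function(values, zeta_axis, rho_axis,
                          kind = c("synchrony", "accuracy", "probability"),
                          normalized = FALSE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != length(zeta_axis) || ncol(values) != length(rho_axis))
    stop_invalid("values must be length(zeta_axis) x length(rho_axis)")
  if (any(diff(zeta_axis) <= 0) || any(diff(rho_axis) <= 0))
    stop_invalid("axes must be strictly increasing")
  structure(list(values = values, zeta_axis = zeta_axis,
                 rho_axis = rho_axis, kind = kind, normalized = normalized),
            class = "arnold_tongue")
}

#' @exportS3Method base::print
print.arnold_tongue <- function(x, digits = 3, ...) {
  cat(sprintf("arnold_tongue (%s%s): %d zeta x %d rho levels\n", x$kind,
              if (x$normalized) ", normalized" else "",
              length(x$zeta_axis), length(x$rho_axis)))
  m <- round(x$values, digits)
  dimnames(m) <- list(zeta = signif(x$zeta_axis, 4),
                      rho = signif(x$rho_axis, 4))
  print(m)
  invisible(x)
}

#' Display an Arnold tongue as an image
#'
#' @param x an `arnold_tongue`.
#' @param ... passed to [graphics::image()].
#' @export
plot.arnold_tongue <- function(x, ...) {
  graphics::image(x$zeta_axis, x$rho_axis, x$values,
                  xlab = "contrast heterogeneity (zeta)",
                  ylab = "grid coarseness (rho)",
                  main = paste("Arnold tongue:", x$kind), ...)
  invisible(x)
}

as_tongue_values <- function(x) {
  if (inherits(x, "arnold_tongue")) x$values else as.matrix(x)
}

#' Min-max normalize a tongue to the unit interval
#'
#' Maps the minimum cell to 0 and the maximum to 1, the rescaling applied
#' to behavioural accuracy before comparing it with the synchronization
#' index on the same `[0, 1]` range.
#'
#' @param tongue an `arnold_tongue`.
#' @return the normalized `arnold_tongue`.
#' @export
minmax_normalize <- function(tongue) {
  v <- tongue$values
  rng <- range(v)
  if (diff(rng) == 0)
    stop_invalid("normalization failure: constant map")
  tongue$values <- (v - rng[1]) / diff(rng)
  tongue$normalized <- TRUE
  tongue
}

#' Pearson similarity of two tongues
#'
#' Product-moment correlation over flattened cells.
#'
#' @param A,B `arnold_tongue` objects (or matrices) of the same shape.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(A, B) {
  a <- as_tongue_values(A)
  b <- as_tongue_values(B)
  if (!all(dim(a) == dim(b))) stop_invalid("tongue shapes differ")
  if (sd(a) == 0 || sd(b) == 0)
    stop_invalid("undefined correlation: constant map")
  cor(as.vector(a), as.vector(b))
}

#' Weighted Jaccard similarity of two tongues
#'
#' `sum(min(a, b)) / sum(max(a, b))` over cells; requires both maps in the
#' same nonnegative range (min-max normalize accuracy first). More
#' conservative than correlation: a constant offset between otherwise
#' identical maps lowers it below 1.
#'
#' @param A,B `arnold_tongue` objects (or matrices) of the same shape with
#'   nonnegative entries.
#' @return similarity in `[0, 1]`; two all-zero maps compare as 1.
#' @export
weighted_jaccard <- function(A, B) {
  a <- as_tongue_values(A)
  b <- as_tongue_values(B)
  if (!all(dim(a) == dim(b))) stop_invalid("tongue shapes differ")
  if (min(a) < 0 || min(b) < 0) stop_invalid("entries must be nonnegative")
  den <- sum(pmax(a, b))
  if (den == 0) return(1)
  sum(pmin(a, b)) / den
}

## composite-Simpson quadrature weights for possibly even point counts:
## Simpson panels over the largest odd prefix, trapezoid for a final
## leftover panel; assumes (and checks) a uniform grid
simpson_weights <- function(x) {
  n <- length(x)
  if (n < 3) stop_invalid("Simpson integration needs >= 3 points per axis")
  h <- diff(x)
  if (max(abs(h - h[1])) > 1e-9 * max(abs(x)))
    stop_invalid("Simpson integration requires a uniform grid")
  h <- h[1]
  w <- numeric(n)
  m <- if (n %% 2 == 1) n else n - 1
  ws <- rep(c(2, 4), length.out = m)
  ws[1] <- 1
  ws[m] <- 1
  w[1:m] <- ws * h / 3
  if (m < n) {  # close the last panel with a trapezoid
    w[n - 1] <- w[n - 1] + h / 2
    w[n] <- w[n] + h / 2
  }
  w
}

#' Tongue size by two-dimensional Simpson integration
#'
#' The volume under the tongue surface over the native
#' `(zeta, rho)` rectangle, by tensor-product composite Simpson
#' quadrature (with a trapezoid closing panel on axes with an even number
#' of points).
#'
#' @param tongue an `arnold_tongue` with at least 3 points per axis.
#' @return the scalar volume.
#' @examples
#' # constant 1 over [0.01, 1] x [1, 1.5]: 0.99 * 0.5
#' tongue_size(arnold_tongue(matrix(1, 5, 5),
#'                           seq(0.01, 1, length.out = 5),
#'                           seq(1, 1.5, length.out = 5)))
#' @export
tongue_size <- function(tongue) {
  wz <- simpson_weights(tongue$zeta_axis)
  wr <- simpson_weights(tongue$rho_axis)
  as.numeric(t(wz) %*% tongue$values %*% wr)
}

#' Fit a 2D psychometric surface to an accuracy tongue
#'
#' Maximum-binomial-likelihood fit of the chance-floored logistic surface
#' `acc = 0.5 + 0.5 / (1 + exp(-(b0 + b1 zeta + b2 rho + b3 zeta rho)))`
#' to per-condition correct counts, and the level set at 75% accuracy
#' (where the inner linear predictor crosses zero).
#'
#' @param accuracy_tongue an `arnold_tongue` of accuracies.
#' @param trial_counts matrix of per-condition trial counts (same shape),
#'   or a single count applying to every cell.
#' @return list with `beta` (named length-4), `se` (delta-method standard
#'   errors from the numeric Hessian), `contour75` (data.frame of the 75%
#'   level set sampled along zeta; rows where the contour leaves the rho
#'   range are dropped), `logLik` and `converged`.
#' @export
fit_tongue_surface <- function(accuracy_tongue, trial_counts) {
  acc <- accuracy_tongue$values
  if (length(trial_counts) == 1)
    trial_counts <- matrix(trial_counts, nrow(acc), ncol(acc))
  zz <- matrix(accuracy_tongue$zeta_axis, nrow(acc), ncol(acc))
  rr <- matrix(accuracy_tongue$rho_axis, nrow(acc), ncol(acc), byrow = TRUE)
  k <- round(acc * trial_counts)
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * zz + beta[3] * rr + beta[4] * zz * rr
    p <- 0.5 + 0.5 * plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (trial_counts - k) * log(1 - p))
  }
  fit <- optim(c(0, -1, 0, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  se <- rep(NA_real_, 4)
  hs <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(hs, "try-error") && all(diag(hs) > 0)) se <- sqrt(diag(hs))
  beta <- setNames(fit$par, c("b0", "b_zeta", "b_rho", "b_interact"))
  zg <- seq(min(accuracy_tongue$zeta_axis), max(accuracy_tongue$zeta_axis),
            length.out = 101)
  den <- beta[3] + beta[4] * zg
  rg <- ifelse(abs(den) > 1e-12, -(beta[1] + beta[2] * zg) / den, NA)
  keep <- is.finite(rg) & rg >= min(accuracy_tongue$rho_axis) &
    rg <= max(accuracy_tongue$rho_axis)
  list(beta = beta, se = setNames(se, names(beta)),
       contour75 = data.frame(zeta = zg[keep], rho = rg[keep]),
       logLik = -fit$value, converged = fit$convergence == 0)
}

#' Fold-based noise ceiling
#'
#' For each cross-validation fold, compares the mean behavioural tongue of
#' the held-in participants with the left-out participant's tongue, and
#' summarizes the distribution of similarity values by its 25th and 75th
#' percentiles — the band bounding the model-to-behaviour fit attainable
#' given between-participant variability.
#'
#' @param fold_mean_tongues list of held-in mean tongues, one per fold.
#' @param leftout_tongues list of left-out tongues, parallel to the folds.
#' @param metric similarity function of two tongues, e.g.
#'   [weighted_jaccard()] or [pearson_similarity()].
#' @return named numeric `c(lower, upper)` (25th/75th percentiles) with
#'   the per-fold values as attribute `"values"`.
#' @export
noise_ceiling <- function(fold_mean_tongues, leftout_tongues,
                          metric = weighted_jaccard) {
  if (length(fold_mean_tongues) < 2) stop_invalid("need at least 2 folds")
  if (length(fold_mean_tongues) != length(leftout_tongues))
    stop_invalid("fold and left-out lists must be parallel")
  vals <- mapply(function(a, b) metric(a, b),
                 fold_mean_tongues, leftout_tongues)
  out <- quantile(vals, c(0.25, 0.75), names = FALSE)
  names(out) <- c("lower", "upper")
  attr(out, "values") <- vals
  out
}

#' Cellwise mean of a list of tongues
#'
#' @param tongues non-empty list of `arnold_tongue`s on a common grid.
#' @return an `arnold_tongue` of the cellwise mean.
#' @export
mean_tongue <- function(tongues) {
  stopifnot(length(tongues) >= 1)
  v <- Reduce(`+`, lapply(tongues, function(t) t$values)) / length(tongues)
  t1 <- tongues[[1]]
  arnold_tongue(v, t1$zeta_axis, t1$rho_axis, kind = t1$kind)
}
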