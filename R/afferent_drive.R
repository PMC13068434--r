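## Afferent drive: Gaussian receptive-field weighting of the stimulus
## raster, weighted RMS local contrast, and the linear contrast-to-
## frequency mapping that sets each oscillator's intrinsic gamma frequency.

#' Receptive-field pixel weights for a sheet over a patch raster
#'
#' For oscillator `i` and pixel `h`, the weight is the isotropic Gaussian
#' `exp(-((x_h - X_i)^2 + (y_h - Y_i)^2) / (2 sigma_i^2))` (value 1 at the
#' RF centre). Weights are truncated beyond `truncation * sigma` and stored
#' sparsely; because local contrast normalises by the summed weights, the
#' truncation error is negligible. The weight structure depends only on
#' the sheet and the raster geometry, so it is computed once and reused
#' across all trials that share the raster.
#'
#' @param sheet an [build_sheet()] result.
#' @param patch a `texture_patch` defining the raster geometry.
#' @param truncation truncation radius in units of sigma.
#' @return an object of class `rf_weights`: sparse weight matrix `W`
#'   (N x pixels, column-major pixel order matching the raster), per-row
#'   sums, and the raster axes.
#' @export
rf_weights <- function(sheet, patch, truncation = 4) {
  xs <- patch$xs
  ys <- patch$ys
  half <- patch$deg_per_pixel / 2
  ## border RFs inevitably overhang the raster a little (their centres sit
  ## inside the modelled region); diagnose only when an RF overhangs by
  ## more than 3 sigma, i.e. its centre lies outside the raster
  overhang <- pmax(
    (min(xs) - half) - (sheet$rf_centers[, 1] - 3 * sheet$rf_sigma),
    (sheet$rf_centers[, 1] + 3 * sheet$rf_sigma) - (max(xs) + half),
    (min(ys) - half) - (sheet$rf_centers[, 2] - 3 * sheet$rf_sigma),
    (sheet$rf_centers[, 2] + 3 * sheet$rf_sigma) - (max(ys) + half))
  if (any(overhang > 3 * sheet$rf_sigma))
    warning("some receptive fields extend beyond the raster by > 3 sigma; ",
            "their local contrast is estimated from partial support")
  np <- length(xs) * length(ys)
  pix_x <- rep(xs, times = length(ys))  # column-major: x fastest
  pix_y <- rep(ys, each = length(xs))
  ii <- vector("list", sheet$N)
  jj <- vector("list", sheet$N)
  vv <- vector("list", sheet$N)
  for (i in seq_len(sheet$N)) {
    s <- sheet$rf_sigma[i]
    cx <- sheet$rf_centers[i, 1]
    cy <- sheet$rf_centers[i, 2]
    sel <- which(abs(pix_x - cx) <= truncation * s &
                 abs(pix_y - cy) <= truncation * s)
    w <- exp(-((pix_x[sel] - cx)^2 + (pix_y[sel] - cy)^2) / (2 * s^2))
    keep <- w > 1e-8
    ii[[i]] <- rep.int(i, sum(keep))
    jj[[i]] <- sel[keep]
    vv[[i]] <- w[keep]
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(sheet$N, np))
  structure(list(W = W, row_sums = Matrix::rowSums(W), xs = xs, ys = ys,
                 deg_per_pixel = patch$deg_per_pixel,
                 truncation = truncation),
            class = "rf_weights")
}

#' Weighted RMS local contrast per oscillator
#'
#' `C_i = 100 * sqrt( sum_h w_ih (L_h - Lbar)^2 / Lbar^2 / sum_h w_ih )`,
#' with `Lbar` the mean luminance over all pixels of the patch. The factor
#' 100 expresses contrast in percent, the unit in which the
#' contrast-to-frequency mapping spans the physiological 25-50 Hz range.
#'
#' @param patch a `texture_patch`.
#' @param weights an [rf_weights()] result built on the same raster.
#' @param scale contrast scale factor (100 = percent).
#' @return an object of class `contrast_field`: list with per-oscillator
#'   contrast `C` (percent) and the scale used.
#' @export
weighted_rms_contrast <- function(patch, weights, scale = 100) {
  if (!isTRUE(all.equal(weights$xs, patch$xs)) ||
      !isTRUE(all.equal(weights$ys, patch$ys)))
    stop_invalid("weights were built for a different raster geometry")
  Lbar <- mean(patch$luminance)
  if (Lbar <= 0) stop_invalid("patch mean luminance must be positive")
  dev2 <- as.vector((patch$luminance - Lbar)^2) / Lbar^2
  C <- scale * sqrt(as.vector(weights$W %*% dev2) / weights$row_sums)
  structure(list(C = C, scale = scale), class = "contrast_field")
}

#' Intrinsic frequency from local contrast
#'
#' The linear gamma frequency-contrast relation `nu = 25 + 0.25 * C` Hz
#' (`C` in percent), with angular frequency `omega = 2 pi nu`.
#'
#' @param C local contrast in percent (vector or `contrast_field`).
#' @param intercept frequency at zero contrast, Hz.
#' @param slope Hz per percent contrast.
#' @return an object of class `frequency_vector`: list with `nu` (Hz) and
#'   `omega` (rad/s).
#' @examples
#' contrast_to_frequency(0)$nu    # 25
#' contrast_to_frequency(100)$nu  # 50
#' @export
contrast_to_frequency <- function(C, intercept = 25, slope = 0.25) {
  if (inherits(C, "contrast_field")) C <- C$C
  if (any(C < 0)) stop_invalid("contrast must be >= 0")
  nu <- intercept + slope * C
  structure(list(nu = nu, omega = 2 * pi * nu), class = "frequency_vector")
}

#' Afferent drive of a sheet by a patch
#'
#' Convenience composition of [weighted_rms_contrast()] and
#' [contrast_to_frequency()].
#'
#' @inheritParams weighted_rms_contrast
#' @return a `frequency_vector`.
#' @export
afferent_drive <- function(patch, weights) {
  contrast_to_frequency(weighted_rms_contrast(patch, weights))
}
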