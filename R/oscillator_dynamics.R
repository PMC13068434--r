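## Kuramoto dynamics of the sheet: per-trial integration, the order
## parameter and pairwise phase-locking values, rate-proxy readouts, and
## full sessions over the condition grid producing simulated Arnold
## tongues.

#' Trial simulation settings
#'
#' @param duration stimulus monitoring interval, seconds.
#' @param dt output time step, seconds.
#' @param subsample_points number of timepoints (from the second half of
#'   the trial) used for phase-locking values.
#' @param substeps internal RK4 substeps per output step.
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(duration = 1, dt = 0.001, subsample_points = 50,
                         substeps = 2) {
  if (duration <= 0 || dt <= 0 || dt >= duration)
    stop_invalid("need 0 < dt < duration")
  if (subsample_points < 2) stop_invalid("subsample_points must be >= 2")
  structure(list(duration = duration, dt = dt,
                 subsample_points = subsample_points,
                 substeps = as.integer(substeps)),
            class = "trial_config")
}

#' Integrate one trial of the Kuramoto sheet
#'
#' Integrates `dtheta_i/dt = omega_i + (1/N) sum_j K_ij sin(theta_j -
#' theta_i)` with a fixed-step classical Runge-Kutta scheme (compiled;
#' phases are stored unwrapped on the output grid). Initial phases are
#' drawn i.i.d. uniform on `[0, 2 pi)` from the current RNG state unless
#' supplied.
#'
#' @param omega intrinsic angular frequencies (rad/s); a numeric vector or
#'   a `frequency_vector`.
#' @param K coupling matrix (`coupling_matrix` or plain N x N matrix).
#' @param config a [trial_config()] object.
#' @param theta0 optional initial phases, radians.
#' @return an object of class `phase_trajectory`: list with `times`,
#'   `theta` (timepoints x N, unwrapped radians) and `omega`.
#' @export
simulate_trial <- function(omega, K, config = trial_config(),
                           theta0 = NULL) {
  if (inherits(omega, "frequency_vector")) omega <- omega$omega
  Km <- as_K(K)
  N <- length(omega)
  if (!all(dim(Km) == N)) stop_invalid("K must be N x N matching omega")
  if (!all(is.finite(omega)) || !all(is.finite(Km)))
    stop_invalid("non-finite omega or K")
  if (is.null(theta0)) theta0 <- runif(N, 0, 2 * pi)
  nsteps <- round(config$duration / config$dt)
  theta <- .kuramoto_rk4(theta0, omega, Km, config$dt, nsteps,
                         config$substeps)
  if (!all(is.finite(theta))) stop("integration failure: non-finite phases")
  structure(list(times = seq(0, by = config$dt, length.out = nsteps + 1),
                 theta = theta, omega = omega),
            class = "phase_trajectory")
}

#' Kuramoto order parameter of one phase configuration
#'
#' The complex mean `(1/N) sum_j exp(i theta_j)`: its magnitude `r` in
#' `[0, 1]` measures zero-lag synchrony, its argument `psi` is the mean
#' phase.
#'
#' @param phases numeric vector of phases, radians.
#' @return list with `r` and `psi` (in (-pi, pi]).
#' @examples
#' order_parameter(c(0, pi))$r        # 0
#' order_parameter(c(0, pi / 2))$r    # sqrt(2)/2
#' @export
order_parameter <- function(phases) {
  if (!length(phases)) stop_invalid("empty phase vector")
  z <- mean(exp(1i * phases))
  list(r = Mod(z), psi = Arg(z))
}

## r(t) for every output timepoint of a trajectory
order_parameter_series <- function(traj) {
  z <- rowMeans(exp(1i * traj$theta))
  list(r = Mod(z), psi = Arg(z))
}

## indices of output timepoints strictly inside the second half of the trial
second_half_index <- function(traj, config) {
  which(traj$times > config$duration / 2)
}

#' Trial-level synchrony summary
#'
#' The order-parameter magnitude averaged over the second half of the
#' trial, the readout used for every per-trial synchrony value.
#'
#' @param traj a [simulate_trial()] result.
#' @param config the [trial_config()] used.
#' @return scalar `r_mean` in `[0, 1]`.
#' @export
trial_synchrony <- function(traj, config = trial_config()) {
  idx <- second_half_index(traj, config)
  mean(order_parameter_series(traj)$r[idx])
}

#' Pairwise phase-locking values of one trial
#'
#' `PLV_ij = | mean_t exp(i (theta_i(t) - theta_j(t))) |` over the second
#' half of the trial subsampled to `config$subsample_points` timepoints.
#' Symmetric with unit diagonal.
#'
#' @inheritParams trial_synchrony
#' @return an N x N matrix with entries in `[0, 1]`.
#' @export
pairwise_plv <- function(traj, config = trial_config()) {
  idx <- second_half_index(traj, config)
  sub <- idx[round(seq(1, length(idx),
                       length.out = config$subsample_points))]
  th <- traj$theta[sub, , drop = FALSE]
  Cm <- cos(th)
  Sm <- sin(th)
  re <- crossprod(Cm) + crossprod(Sm)          # sum_t cos(theta_i - theta_j)
  im <- crossprod(Sm, Cm) - crossprod(Cm, Sm)  # sum_t sin(theta_i - theta_j)
  P <- sqrt(re^2 + im^2) / length(sub)
  pmin(P, 1)
}

## instantaneous frequency (Hz) by finite differences of unwrapped phases
instantaneous_frequency <- function(traj) {
  dt <- diff(traj$times[1:2])
  diff(traj$theta) / (2 * pi * dt)
}

#' Firing-rate proxy readouts of one trial
#'
#' Treats each oscillator's instantaneous frequency as a proxy for the
#' instantaneous population firing rate. The figure rate is the
#' time-and-population mean instantaneous frequency; the background proxy
#' is the mean feedforward frequency of a maximum-heterogeneity patch
#' (the background is not simulated: its synchrony regime is equated with
#' the figure at `zeta = 1`).
#'
#' @param traj a [simulate_trial()] result (figure region).
#' @param background_frequencies a `frequency_vector` computed from a
#'   `zeta = 1` patch.
#' @return list with `figure_rate`, `background_rate_proxy` and
#'   `rate_difference`, Hz.
#' @export
rate_readouts <- function(traj, background_frequencies) {
  if (inherits(background_frequencies, "frequency_vector"))
    bg <- background_frequencies$nu
  else bg <- background_frequencies
  fig <- mean(instantaneous_frequency(traj))
  bgm <- mean(bg)
  list(figure_rate = fig, background_rate_proxy = bgm,
       rate_difference = fig - bgm)
}

#' Precompute the afferent drive of a whole session
#'
#' Generates every trial's stimulus patch and feedforward frequencies for
#' a session schedule (each condition once per block, fresh stimulus per
#' trial) without integrating the dynamics. Precomputing the drive lets
#' the learning-rate grid search re-simulate a session under many
#' candidate coupling matrices at the cost of integration only.
#'
#' @param sheet an [build_sheet()] result.
#' @param weights an [rf_weights()] result for the session's raster.
#' @param conditions a condition grid from [build_condition_grid()].
#' @param blocks number of blocks (each condition once per block).
#' @param annulus an [annulus_params()] object.
#' @param seed master seed; per-trial streams are derived from it.
#' @param session session index used in stream derivation.
#' @return an object of class `session_drive`: a list of trial records
#'   (`omega`, `zeta_level`, `rho_level`, `block`, `theta_seed`) plus the
#'   condition grid.
#' @export
session_drive <- function(sheet, weights, conditions = build_condition_grid(),
                          blocks = 30, annulus = annulus_params(),
                          seed = 1709026616, session = 1) {
  trials <- vector("list", blocks * nrow(conditions))
  k <- 0
  for (b in seq_len(blocks)) {
    for (ci in seq_len(nrow(conditions))) {
      k <- k + 1
      cond <- conditions[ci, ]
      patch <- with_stream(
        derive_seed(seed, "stim", session, b, ci),
        generate_model_patch(cond, annulus,
                             center = sheet$region_center,
                             side = sheet$region_side,
                             deg_per_pixel = weights$deg_per_pixel))
      drv <- afferent_drive(patch, weights)
      trials[[k]] <- list(omega = drv$omega, nu = drv$nu,
                          zeta_level = cond$zeta_level,
                          rho_level = cond$rho_level,
                          zeta = cond$zeta, rho = cond$rho, block = b,
                          theta_seed = derive_seed(seed, "theta", session,
                                                   b, ci))
    }
  }
  structure(list(trials = trials, conditions = conditions, blocks = blocks,
                 session = session),
            class = "session_drive")
}

#' Simulate a session from a precomputed drive
#'
#' Integrates every trial of the drive under one coupling matrix and
#' aggregates per-condition synchrony (mean over blocks) into an Arnold
#' tongue. Optionally retains per-trial phase-locking matrices for the
#' Hebbian learning step and computes rate-proxy readouts.
#'
#' @param drive a [session_drive()] result.
#' @param K coupling matrix for this session.
#' @param config a [trial_config()] object.
#' @param retain_plv keep each trial's PLV matrix?
#' @param rates compute instantaneous-frequency readouts per trial?
#' @return an object of class `session_result`: `tongue` (synchrony
#'   [arnold_tongue()]), `trials` data.frame (block, condition, `r_mean`,
#'   optional `figure_rate`), `plv` (list or NULL), `session`.
#' @export
simulate_session <- function(drive, K, config = trial_config(),
                             retain_plv = FALSE, rates = FALSE) {
  Km <- as_K(K)
  conds <- drive$conditions
  nz <- max(conds$zeta_level)
  nr <- max(conds$rho_level)
  acc <- matrix(0, nz, nr)
  cnt <- matrix(0L, nz, nr)
  ntr <- length(drive$trials)
  rec <- data.frame(block = integer(ntr), zeta_level = integer(ntr),
                    rho_level = integer(ntr), zeta = numeric(ntr),
                    rho = numeric(ntr), r_mean = numeric(ntr),
                    figure_rate = NA_real_)
  plv <- if (retain_plv) vector("list", ntr) else NULL
  for (k in seq_len(ntr)) {
    tr <- drive$trials[[k]]
    theta0 <- with_stream(tr$theta_seed, runif(length(tr$omega), 0, 2 * pi))
    traj <- simulate_trial(tr$omega, Km, config, theta0 = theta0)
    r <- trial_synchrony(traj, config)
    rec$block[k] <- tr$block
    rec$zeta_level[k] <- tr$zeta_level
    rec$rho_level[k] <- tr$rho_level
    rec$zeta[k] <- tr$zeta
    rec$rho[k] <- tr$rho
    rec$r_mean[k] <- r
    if (rates) rec$figure_rate[k] <- mean(instantaneous_frequency(traj))
    if (retain_plv) plv[[k]] <- pairwise_plv(traj, config)
    acc[tr$zeta_level, tr$rho_level] <- acc[tr$zeta_level, tr$rho_level] + r
    cnt[tr$zeta_level, tr$rho_level] <- cnt[tr$zeta_level, tr$rho_level] + 1L
  }
  zl <- sort(unique(conds$zeta))
  rl <- sort(unique(conds$rho))
  tongue <- arnold_tongue(acc / cnt, zl, rl, kind = "synchrony")
  structure(list(tongue = tongue, trials = rec, plv = plv,
                 session = drive$session),
            class = "session_result")
}

#' Run one full session of the model
#'
#' Thin composition of [session_drive()] and [simulate_session()]: fresh
#' stimuli per trial, each condition once per block, synchrony averaged
#' over the second half of each trial and over blocks.
#'
#' @inheritParams session_drive
#' @inheritParams simulate_session
#' @param K coupling matrix for this session.
#' @return a `session_result`.
#' @examples
#' \donttest{
#' sheet <- build_sheet(n = 6)
#' patch <- generate_model_patch(list(zeta = 1, rho = 1))
#' w <- rf_weights(sheet, patch)
#' res <- run_session(sheet, w, initial_coupling(sheet),
#'                    conditions = build_condition_grid(2, 2), blocks = 1)
#' res$tongue
#' }
#' @export
run_session <- function(sheet, weights, K,
                        conditions = build_condition_grid(), blocks = 30,
                        config = trial_config(), annulus = annulus_params(),
                        seed = 1709026616, session = 1,
                        retain_plv = FALSE, rates = FALSE) {
  drive <- session_drive(sheet, weights, conditions, blocks, annulus,
                         seed, session)
  simulate_session(drive, K, config, retain_plv = retain_plv, rates = rates)
}

#' Locate the session-1 synchronization cutoff in contrast heterogeneity
#'
#' Sweeps contrast heterogeneity at fixed grid coarseness, simulating
#' fresh stimuli and random initial phases per trial, and classifies a
#' level as synchronized when the mean (over trials) of the time-averaged
#' order parameter reaches `threshold`. Reports the largest synchronized
#' level — the heterogeneity beyond which the untrained model never
#' reaches a synchronized state.
#'
#' @param sheet an [build_sheet()] result.
#' @param weights an [rf_weights()] result for the model raster.
#' @param K coupling matrix.
#' @param zetas heterogeneity levels to sweep.
#' @param rho grid coarseness (densest grid, 1, by default).
#' @param trials_per_level trials per level.
#' @param config a [trial_config()] object.
#' @param seed master seed.
#' @param threshold synchronized-state criterion on the time-averaged
#'   order parameter.
#' @return list with `cutoff` (largest synchronized zeta, 0 if none),
#'   `levels` data.frame (zeta, mean r, per-level SEM, synchronized),
#'   and `n_trials`.
#' @export
synchronization_cutoff <- function(sheet, weights, K,
                                   zetas = c(seq(0.01, 0.96, by = 0.05), 1),
                                   rho = 1, trials_per_level = 10,
                                   config = trial_config(),
                                   seed = 1709026616, threshold = 0.5) {
  Km <- as_K(K)
  lev <- lapply(seq_along(zetas), function(zi) {
    r <- vapply(seq_len(trials_per_level), function(t) {
      patch <- with_stream(
        derive_seed(seed, "cutoff-stim", zi, t),
        generate_model_patch(list(zeta = zetas[zi], rho = rho),
                             center = sheet$region_center,
                             side = sheet$region_side,
                             deg_per_pixel = weights$deg_per_pixel))
      omega <- afferent_drive(patch, weights)$omega
      theta0 <- with_stream(derive_seed(seed, "cutoff-theta", zi, t),
                            runif(length(omega), 0, 2 * pi))
      traj <- simulate_trial(omega, Km, config, theta0 = theta0)
      trial_synchrony(traj, config)
    }, numeric(1))
    data.frame(zeta = zetas[zi], r_mean = mean(r),
               sem = sd(r) / sqrt(length(r)),
               synchronized = mean(r) >= threshold)
  })
  lev <- do.call(rbind, lev)
  sync <- lev$zeta[lev$synchronized]
  list(cutoff = if (length(sync)) max(sync) else 0, levels = lev,
       n_trials = nrow(lev) * trials_per_level)
}
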