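## Session-wise Hebbian plasticity: psychometric linking of synchrony to
## response probability, correctness-weighted accumulation of pairwise
## phase-locking into an experience matrix Q, the convex coupling update
## between sessions, the coarse-to-fine search for the effective learning
## rate E, and the leave-one-out cross-validation harness.

#' Psychometric parameters linking synchrony to performance
#'
#' @param mu0 intercept, log-odds.
#' @param mu1 slope, log-odds per unit synchrony.
#' @param se optional standard errors (named length-2).
#' @return an object of class `psychometric_params`.
#' @export
psychometric_params <- function(mu0, mu1, se = c(mu0 = NA_real_,
                                                 mu1 = NA_real_)) {
  if (!is.finite(mu0) || !is.finite(mu1))
    stop_invalid("psychometric parameters must be finite")
  structure(list(mu0 = mu0, mu1 = mu1, se = se),
            class = "psychometric_params")
}

#' Probability of a correct response given synchrony
#'
#' The logistic psychometric function
#' `P_c = 1 / (1 + exp(-mu0 - mu1 r))`.
#'
#' @param r synchrony in `[0, 1]` (vectorised).
#' @param params a [psychometric_params()] object.
#' @return probabilities in (0, 1).
#' @export
prob_correct <- function(r, params) {
  plogis(params$mu0 + params$mu1 * r)
}

#' Fit the psychometric function from matched tongues
#'
#' Binomial maximum-likelihood fit of per-condition correct counts against
#' model synchrony, across the matched cells of a simulated synchrony
#' tongue and a behavioural accuracy tongue (both from session 1).
#'
#' @param synchrony_tongue simulated `arnold_tongue` (kind synchrony).
#' @param accuracy_tongue behavioural `arnold_tongue` (kind accuracy).
#' @param trial_counts per-condition trial counts: matrix of the tongue
#'   shape or a single scalar.
#' @return a [psychometric_params()] object; attribute `"separation"` is
#'   TRUE if the fit was flagged as numerically divergent (perfectly
#'   separated data).
#' @export
fit_psychometric <- function(synchrony_tongue, accuracy_tongue,
                             trial_counts) {
  r <- as.vector(as_tongue_values(synchrony_tongue))
  acc <- as.vector(as_tongue_values(accuracy_tongue))
  n <- if (length(trial_counts) == 1)
    rep(trial_counts, length(acc)) else as.vector(trial_counts)
  k <- round(acc * n)
  if (all(k == 0) || all(k == n))
    stop_invalid("fit failure: degenerate accuracy (all 0 or all 1)")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(cbind(k, n - k) ~ r, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- psychometric_params(unname(cf[1]), unname(cf[2]),
                             se = c(mu0 = unname(se[1]),
                                    mu1 = unname(se[2])))
  attr(out, "separation") <- separated
  out
}

#' Accumulate correctness-weighted phase-locking over a session
#'
#' Sums each trial's PLV matrix weighted by the probability that the model
#' answered that trial correctly, normalised by the summed weights, giving
#' the experience matrix `Q = sum_t P_c(r_t) PLV_t / sum_t P_c(r_t)` with
#' entries in `[0, 1]`. The weight normalization preserves the bound
#' `K <= gamma` under the coupling update and the `gamma * Q` fixed point.
#'
#' @param plv_per_trial list of per-trial PLV matrices.
#' @param r_per_trial per-trial synchrony values, parallel to the list.
#' @param params a [psychometric_params()] object.
#' @return an object of class `experience_matrix` with field `Q`.
#' @export
accumulate_experience <- function(plv_per_trial, r_per_trial, params) {
  if (!length(plv_per_trial) || length(plv_per_trial) != length(r_per_trial))
    stop_invalid("plv list and synchrony values must be parallel, non-empty")
  w <- prob_correct(r_per_trial, params)
  if (sum(w) <= 0) stop_invalid("invalid state: all-zero trial weights")
  Q <- matrix(0, nrow(plv_per_trial[[1]]), ncol(plv_per_trial[[1]]))
  for (t in seq_along(plv_per_trial)) Q <- Q + w[t] * plv_per_trial[[t]]
  structure(list(Q = Q / sum(w), weights = w), class = "experience_matrix")
}

as_Q <- function(Q) {
  if (inherits(Q, "experience_matrix")) Q$Q
  else if (is.matrix(Q)) Q
  else stop_invalid("Q must be a matrix or experience_matrix")
}

#' Update the coupling matrix between sessions
#'
#' The Hebbian relaxation of structural coupling toward experience-scaled
#' functional coupling, integrated over the inter-session interval:
#' `K^{s+1} = exp(-E) K^s + (1 - exp(-E)) gamma Q^s` with effective
#' learning rate `E`. A convex combination, so coupling stays within
#' `[0, gamma]` for all sessions.
#'
#' @param K current coupling (`coupling_matrix` or matrix).
#' @param Q experience matrix for the session.
#' @param gamma maximum coupling strength.
#' @param E effective learning rate (>= 0).
#' @return a `coupling_matrix` for the next session (zero diagonal).
#' @export
update_coupling <- function(K, Q, gamma = 24.63, E) {
  if (E < 0) stop_invalid("E must be >= 0")
  Km <- as_K(K)
  Qm <- as_Q(Q)
  if (!all(dim(Km) == dim(Qm))) stop_invalid("K and Q shapes differ")
  a <- exp(-E)
  Kn <- a * Km + (1 - a) * gamma * Qm
  diag(Kn) <- 0
  session <- if (inherits(K, "coupling_matrix")) K$session + 1L else NA_integer_
  structure(list(K = Kn, session = session, gamma = gamma),
            class = "coupling_matrix")
}

#' Learning-rate search settings
#'
#' @param grid_levels number of nested grids in the coarse-to-fine search.
#' @param candidates_per_grid candidate learning rates per grid.
#' @param E_range range of the initial (log-spaced) grid.
#' @return an object of class `learning_config`.
#' @export
learning_config <- function(grid_levels = 5, candidates_per_grid = 25,
                            E_range = c(1e-3, 10)) {
  if (grid_levels < 1 || candidates_per_grid < 3)
    stop_invalid("need >= 1 grid level and >= 3 candidates per grid")
  structure(list(grid_levels = grid_levels,
                 candidates_per_grid = candidates_per_grid,
                 E_range = E_range),
            class = "learning_config")
}

#' Estimate the effective learning rate by coarse-to-fine grid search
#'
#' For each candidate `E`, applies one coupling update from the session-1
#' state, re-simulates session 2 on its precomputed drive, and scores the
#' weighted Jaccard similarity between the simulated synchrony tongue and
#' the (min-max normalised) session-2 behavioural tongue. The first grid
#' is log-spaced over `config$E_range`; each refinement grid spans the
#' interval between the neighbours of the current optimum. Ties resolve
#' to the smallest candidate.
#'
#' @param session2_behavior `arnold_tongue` of session-2 accuracy.
#' @param K1 session-1 coupling.
#' @param Q1 session-1 experience matrix.
#' @param drive2 a [session_drive()] for session 2.
#' @param gamma maximum coupling strength.
#' @param config a [learning_config()] object.
#' @param sim_config a [trial_config()] for the re-simulations.
#' @return list with the selected `E`, its `objective`, and a `trace`
#'   data.frame of every evaluated candidate (level, E, objective).
#' @export
estimate_learning_rate <- function(session2_behavior, K1, Q1, drive2,
                                   gamma = 24.63,
                                   config = learning_config(),
                                   sim_config = trial_config()) {
  target <- minmax_normalize(session2_behavior)
  evaluate <- function(E) {
    K2 <- update_coupling(K1, Q1, gamma, E)
    res <- simulate_session(drive2, K2, sim_config)
    weighted_jaccard(target, res$tongue)
  }
  grid <- exp(seq(log(config$E_range[1]), log(config$E_range[2]),
                  length.out = config$candidates_per_grid))
  trace <- list()
  best_E <- NA_real_
  best_obj <- -Inf
  for (level in seq_len(config$grid_levels)) {
    obj <- vapply(grid, evaluate, numeric(1))
    if (any(!is.finite(obj))) stop("search failure: non-finite objective")
    trace[[level]] <- data.frame(level = level, E = grid, objective = obj)
    top <- which(obj == max(obj))[1]  # ties -> smallest E (grid is sorted)
    if (obj[top] > best_obj ||
        (obj[top] == best_obj && grid[top] < best_E)) {
      best_obj <- obj[top]
      best_E <- grid[top]
    }
    if (level < config$grid_levels) {
      lo <- grid[max(1, top - 1)]
      hi <- grid[min(length(grid), top + 1)]
      grid <- seq(lo, hi, length.out = config$candidates_per_grid)
    }
  }
  list(E = best_E, objective = best_obj, trace = do.call(rbind, trace))
}

#' Simulate learning across sessions
#'
#' Runs the model forward from a session-1 coupling matrix: simulate a
#' session, accumulate its correctness-weighted phase-locking, update the
#' coupling, repeat. Session drives (stimuli and feedforward frequencies)
#' are precomputed and shared, so repeated forward runs under different
#' parameters reuse them.
#'
#' @param drives list of [session_drive()] objects, one per session, in
#'   order starting at session 1.
#' @param K1 session-1 coupling.
#' @param psych a [psychometric_params()] object (trial weighting).
#' @param E effective learning rate.
#' @param gamma maximum coupling strength.
#' @param sim_config a [trial_config()] object.
#' @param keep_Q retain the per-session experience matrices?
#' @return list with `tongues` (per-session synchrony tongues), `K_final`,
#'   and optionally `Q` (list).
#' @export
learn_sessions <- function(drives, K1, psych, E, gamma = 24.63,
                           sim_config = trial_config(), keep_Q = FALSE) {
  S <- length(drives)
  tongues <- vector("list", S)
  Qs <- if (keep_Q) vector("list", S) else NULL
  K <- K1
  for (s in seq_len(S)) {
    need_Q <- s < S || keep_Q
    res <- simulate_session(drives[[s]], K, sim_config,
                            retain_plv = need_Q)
    tongues[[s]] <- res$tongue
    if (need_Q) {
      Q <- accumulate_experience(res$plv, res$trials$r_mean, psych)
      if (keep_Q) Qs[[s]] <- Q
      if (s < S) K <- update_coupling(K, Q, gamma, E)
    }
  }
  out <- list(tongues = tongues, K_final = K)
  if (keep_Q) out$Q <- Qs
  out
}

#' Leave-one-out cross-validation of the learning model
#'
#' For each participant: fit the psychometric function on the held-in
#' participants' mean session-1 accuracy tongue (against the shared
#' simulated session-1 synchrony tongue), accumulate session-1
#' experience, estimate the effective learning rate against the held-in
#' mean session-2 tongue, then run the model forward through the
#' remaining sessions. Predictions are evaluated only on sessions 3
#' onward of the left-out participant (sessions 1-2 are consumed by
#' fitting). No left-out data enters any fitting step.
#'
#' @param behavior_tongues nested list: `behavior_tongues[[p]][[s]]` is
#'   participant `p`'s accuracy `arnold_tongue` for session `s`
#'   (sessions `1..sessions` required); see [behavior_tongues()].
#' @param drives list of [session_drive()]s for sessions `1..sessions`.
#' @param K1 session-1 coupling.
#' @param trial_counts behavioural trials per condition cell (scalar or
#'   matrix), used in the psychometric fit.
#' @param gamma maximum coupling strength.
#' @param sessions number of training sessions simulated.
#' @param learn_config a [learning_config()] object.
#' @param sim_config a [trial_config()] object.
#' @return list of folds; each fold holds `participant` (the left-out
#'   index), `psych`, `E`, and `tongues` (simulated synchrony tongues for
#'   sessions `1..sessions`).
#' @export
loo_cross_validate <- function(behavior_tongues, drives, K1, trial_counts,
                               gamma = 24.63, sessions = 8,
                               learn_config = learning_config(),
                               sim_config = trial_config()) {
  P <- length(behavior_tongues)
  if (P < 2) stop_invalid("need at least 2 participants")
  if (length(drives) < sessions)
    stop_invalid("need a session drive for every simulated session")
  ok <- vapply(behavior_tongues, function(b) length(b) >= 2, logical(1))
  if (!all(ok)) stop_invalid("every participant needs sessions 1 and 2")
  ## shared across folds: the model's session 1 involves no learning
  res1 <- simulate_session(drives[[1]], K1, sim_config, retain_plv = TRUE)
  folds <- vector("list", P)
  for (p in seq_len(P)) {
    held_in <- setdiff(seq_len(P), p)
    acc1 <- mean_tongue(lapply(held_in, function(q) behavior_tongues[[q]][[1]]))
    acc2 <- mean_tongue(lapply(held_in, function(q) behavior_tongues[[q]][[2]]))
    psych <- fit_psychometric(res1$tongue, acc1, trial_counts)
    Q1 <- accumulate_experience(res1$plv, res1$trials$r_mean, psych)
    est <- estimate_learning_rate(acc2, K1, Q1, drives[[2]], gamma,
                                  learn_config, sim_config)
    tongues <- vector("list", sessions)
    tongues[[1]] <- res1$tongue
    K <- update_coupling(K1, Q1, gamma, est$E)
    for (s in 2:sessions) {
      res <- simulate_session(drives[[s]], K, sim_config,
                              retain_plv = s < sessions)
      tongues[[s]] <- res$tongue
      if (s < sessions) {
        Qs <- accumulate_experience(res$plv, res$trials$r_mean, psych)
        K <- update_coupling(K, Qs, gamma, est$E)
      }
    }
    folds[[p]] <- list(participant = p, psych = psych, E = est$E,
                       tongues = tongues)
  }
  folds
}
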