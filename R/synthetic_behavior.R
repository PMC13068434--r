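## Synthetic 2AFC behavioural datasets with the statistical structure the
## analysis pipeline assumes: per-condition accuracy driven by model
## synchrony through the logistic psychometric link, subject-level
## heterogeneity, session-over-session improvement, and a transfer-session
## reset at the untrained retinal location.

#' Subject-level observer profile
#'
#' Deviations of one synthetic observer from the population psychometric
#' parameters, plus an individual effective learning rate and lapse rate.
#'
#' @param mu0_offset additive deviation of the psychometric intercept.
#' @param mu1_scale multiplicative deviation of the slope.
#' @param E_subject the observer's effective learning rate.
#' @param lapse_rate probability of a stimulus-independent lapse, in
#'   `[0, 0.1]`.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(mu0_offset = 0, mu1_scale = 1,
                            E_subject = 0.15, lapse_rate = 0.02) {
  if (lapse_rate < 0 || lapse_rate > 0.1)
    stop_invalid("lapse_rate must be in [0, 0.1]")
  if (E_subject < 0 || mu1_scale <= 0)
    stop_invalid("E_subject must be >= 0 and mu1_scale > 0")
  structure(list(mu0_offset = mu0_offset, mu1_scale = mu1_scale,
                 E_subject = E_subject, lapse_rate = lapse_rate),
            class = "subject_profile")
}

#' Population distribution of observer profiles
#'
#' Intercept offsets are normal, slope scales and learning rates
#' log-normal, lapse rates uniform on `[0, lapse_max]`.
#'
#' @param mu0_sd SD of the normal intercept offsets.
#' @param mu1_sdlog log-SD of the slope scales (median 1).
#' @param E_median,E_sdlog median and log-SD of the learning rates.
#' @param lapse_max upper bound of the uniform lapse distribution.
#' @return an object of class `population_params`.
#' @export
population_params <- function(mu0_sd = 0.3, mu1_sdlog = 0.2,
                              E_median = 0.15, E_sdlog = 0.3,
                              lapse_max = 0.05) {
  structure(list(mu0_sd = mu0_sd, mu1_sdlog = mu1_sdlog,
                 E_median = E_median, E_sdlog = E_sdlog,
                 lapse_max = lapse_max),
            class = "population_params")
}

#' Draw observer profiles from the population
#'
#' @param n number of observers.
#' @param population a [population_params()] object.
#' @return list of [subject_profile()]s.
#' @export
sample_profiles <- function(n, population = population_params()) {
  lapply(seq_len(n), function(i)
    subject_profile(
      mu0_offset = rnorm(1, 0, population$mu0_sd),
      mu1_scale = rlnorm(1, 0, population$mu1_sdlog),
      E_subject = rlnorm(1, log(population$E_median), population$E_sdlog),
      lapse_rate = runif(1, 0, population$lapse_max)))
}

#' Generate one participant's trial records
#'
#' Per trial, the probability of a correct response is
#' `max(0.5, (1 - lapse) * P_c(r; mu0 + offset, mu1 * scale))` with `r`
#' the model synchrony for that condition and session; correctness is a
#' Bernoulli draw. Sessions 1-8 use the corresponding model tongues;
#' session 9 (the transfer session, figure moved to an untrained
#' quadrant) reuses the session-1 tongue — learning in the model is
#' retinotopically local, so performance resets at the new location.
#'
#' @param profile a [subject_profile()].
#' @param model_tongues list of synchrony `arnold_tongue`s for sessions
#'   1 to 8 (at least 1; missing late sessions fall back to the last
#'   provided, but the canonical call supplies all 8).
#' @param psych population-level [psychometric_params()].
#' @param blocks blocks per session; every condition appears once per
#'   block.
#' @param participant participant identifier.
#' @param sessions_total total sessions including the transfer session.
#' @return data.frame of trial records: `participant`, `session`,
#'   `block`, `zeta_level`, `rho_level`, `figure_orientation`, `correct`.
#' @export
generate_participant <- function(profile, model_tongues, psych,
                                 blocks = 30, participant = 1L,
                                 sessions_total = 9) {
  if (!length(model_tongues)) stop_invalid("missing model tongues")
  n_train <- sessions_total - 1
  obs <- psychometric_params(psych$mu0 + profile$mu0_offset,
                             psych$mu1 * profile$mu1_scale)
  out <- vector("list", sessions_total)
  for (s in seq_len(sessions_total)) {
    s_model <- if (s == sessions_total) 1L else min(s, length(model_tongues))
    tongue <- model_tongues[[s_model]]
    nz <- length(tongue$zeta_axis)
    nr <- length(tongue$rho_axis)
    grid <- expand.grid(zeta_level = seq_len(nz), rho_level = seq_len(nr))
    r <- tongue$values[cbind(grid$zeta_level, grid$rho_level)]
    p <- pmax(0.5, (1 - profile$lapse_rate) * prob_correct(r, obs))
    n_cond <- nrow(grid)
    df <- data.frame(
      participant = participant,
      session = s,
      block = rep(seq_len(blocks), each = n_cond),
      zeta_level = rep(grid$zeta_level, times = blocks),
      rho_level = rep(grid$rho_level, times = blocks),
      figure_orientation = sample(c("H", "V"), blocks * n_cond,
                                  replace = TRUE),
      correct = rbinom(blocks * n_cond, 1, rep(p, times = blocks)))
    out[[s]] <- df
  }
  do.call(rbind, out)
}

#' Generate a synthetic behavioural cohort
#'
#' Draws observer profiles from the population, simulates session-wise
#' model learning per observer (each with its own effective learning
#' rate), and emits the full trial table for all sessions including the
#' transfer session.
#'
#' @param n_participants cohort size (>= 2).
#' @param drives list of [session_drive()]s for the training sessions
#'   (their length sets the number of training sessions).
#' @param K1 session-1 coupling.
#' @param psych population-level [psychometric_params()].
#' @param population a [population_params()] object.
#' @param blocks behavioural blocks per session.
#' @param gamma maximum coupling strength.
#' @param sim_config a [trial_config()] object.
#' @param seed master seed.
#' @return list with `trials` (the full data.frame), `profiles`, and
#'   `model_tongues` (per-participant lists of per-session synchrony
#'   tongues).
#' @export
generate_cohort <- function(n_participants = 8, drives, K1, psych,
                            population = population_params(), blocks = 30,
                            gamma = 24.63, sim_config = trial_config(),
                            seed = 1709026616) {
  if (n_participants < 2) stop_invalid("need at least 2 participants")
  profiles <- with_stream(derive_seed(seed, "profiles"),
                          sample_profiles(n_participants, population))
  trials <- vector("list", n_participants)
  tongue_sets <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    lrn <- learn_sessions(drives, K1, psych, profiles[[p]]$E_subject,
                          gamma, sim_config)
    tongue_sets[[p]] <- lrn$tongues
    trials[[p]] <- with_stream(
      derive_seed(seed, "behavior", p),
      generate_participant(profiles[[p]], lrn$tongues, psych,
                           blocks = blocks, participant = p,
                           sessions_total = length(drives) + 1))
  }
  list(trials = do.call(rbind, trials), profiles = profiles,
       model_tongues = tongue_sets)
}

behavior_columns <- c("participant", "session", "block", "zeta_level",
                      "rho_level", "figure_orientation", "correct")

#' Write a behavioural trial table to CSV
#'
#' @param trials a trial data.frame (see [generate_participant()]).
#' @param path output file.
#' @export
write_behavior <- function(trials, path) {
  write.csv(trials[, behavior_columns], path, row.names = FALSE)
}

#' Load and validate a behavioural trial table
#'
#' Accepts the canonical CSV schema (participant, session, block,
#' zeta_level, rho_level, figure_orientation, correct); rejects missing
#' columns and out-of-range values with the offending row indices.
#'
#' @param path CSV file.
#' @param n_levels number of levels per stimulus factor.
#' @return validated data.frame of trial records.
#' @export
load_behavior <- function(path, n_levels = 5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(behavior_columns, names(df))
  if (length(missing))
    stop_invalid("schema error: missing columns ",
                 paste(missing, collapse = ", "))
  bad <- which(!(df$correct %in% c(0, 1)) |
               df$zeta_level < 1 | df$zeta_level > n_levels |
               df$rho_level < 1 | df$rho_level > n_levels |
               df$session < 1 | df$block < 1)
  if (length(bad))
    stop_invalid("schema error: invalid values in rows ",
                 paste(utils::head(bad, 10), collapse = ", "))
  df
}

#' Aggregate trials into per-session accuracy tongues
#'
#' @param trials a validated trial data.frame.
#' @param zeta_axis,rho_axis level values of the condition grid.
#' @param participant optional participant id to subset to.
#' @return nested list: `[[participant]][[session]]` accuracy
#'   `arnold_tongue`s (participants in sorted order of their ids), each
#'   with per-cell trial counts attached as attribute `"counts"`.
#' @export
behavior_tongues <- function(trials, zeta_axis = c(0.01, 0.2575, 0.505,
                                                   0.7525, 1),
                             rho_axis = c(1, 1.125, 1.25, 1.375, 1.5),
                             participant = NULL) {
  if (!is.null(participant))
    trials <- trials[trials$participant %in% participant, ]
  parts <- sort(unique(trials$participant))
  lapply(parts, function(p) {
    tp <- trials[trials$participant == p, ]
    lapply(sort(unique(tp$session)), function(s) {
      ts <- tp[tp$session == s, ]
      acc <- matrix(NA_real_, length(zeta_axis), length(rho_axis))
      cnt <- matrix(0L, length(zeta_axis), length(rho_axis))
      agg <- stats::aggregate(correct ~ zeta_level + rho_level, ts,
                              function(x) c(mean(x), length(x)))
      acc[cbind(agg$zeta_level, agg$rho_level)] <- agg$correct[, 1]
      cnt[cbind(agg$zeta_level, agg$rho_level)] <- agg$correct[, 2]
      t <- arnold_tongue(acc, zeta_axis, rho_axis, kind = "accuracy")
      attr(t, "counts") <- cnt
      t
    })
  })
}
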