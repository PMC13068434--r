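## End-to-end orchestration: one configuration object, a reproducible
## pipeline that simulates tongues, generates (or loads) behaviour, fits
## the psychometric link and learning rate, runs learning forward, and an
## evaluation step producing per-session similarity tables, tongue sizes
## and noise ceilings.

#' Experiment configuration
#'
#' Bundles every module's settings with a single master seed. The
#' defaults reproduce the full study design (20 x 20 oscillator sheet,
#' 5 x 5 condition grid, 30 blocks, 8 training sessions); smaller values
#' give desk-scale runs.
#'
#' @param n oscillator grid side.
#' @param n_zeta,n_rho condition-grid sizes.
#' @param blocks simulated blocks per session.
#' @param behavior_blocks behavioural blocks per session for the
#'   synthetic cohort.
#' @param sessions number of training sessions.
#' @param n_participants synthetic cohort size.
#' @param seed master seed.
#' @param annulus,retinotopy,coupling,trial,learning,population module
#'   configuration objects.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n = 20, n_zeta = 5, n_rho = 5, blocks = 30,
                              behavior_blocks = 30, sessions = 8,
                              n_participants = 8, seed = 1709026616,
                              annulus = annulus_params(),
                              retinotopy = retinotopy_params(),
                              coupling = coupling_config(),
                              trial = trial_config(),
                              learning = learning_config(),
                              population = population_params()) {
  structure(list(n = n, n_zeta = n_zeta, n_rho = n_rho, blocks = blocks,
                 behavior_blocks = behavior_blocks, sessions = sessions,
                 n_participants = n_participants, seed = seed,
                 annulus = annulus, retinotopy = retinotopy,
                 coupling = coupling, trial = trial, learning = learning,
                 population = population),
            class = "experiment_config")
}

## deterministic fingerprint of a configuration (and of outputs) for the
## run manifest: FNV-style fold over the serialized object
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes[seq(1, length(bytes), by = 7)]))
    h <- (h * 16777619 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full modelling pipeline
#'
#' Builds the sheet and receptive-field weights, precomputes the session
#' drives, simulates session 1, obtains behaviour (a synthetic cohort
#' unless a trial table is supplied), fits the psychometric link on
#' session 1, estimates the effective learning rate on session 2, runs
#' learning forward through all sessions, and evaluates the simulated
#' tongues against behaviour. Deterministic given the configuration.
#'
#' @param config an [experiment_config()] object.
#' @param behavior optional trial data.frame (see [load_behavior()]); if
#'   NULL a synthetic cohort is generated from the configured population.
#' @return a list with `tongues` (simulated, per session), `psych`, `E`,
#'   `evaluation` (see [evaluate_tongues()]), `behavior`, and a
#'   `manifest` recording the configuration, its hash and a hash of the
#'   simulated tongues.
#' @export
run_pipeline <- function(config = experiment_config(), behavior = NULL) {
  conditions <- build_condition_grid(config$n_zeta, config$n_rho)
  sheet <- build_sheet(n = config$n, params = config$retinotopy)
  ref_patch <- with_stream(
    derive_seed(config$seed, "ref"),
    generate_model_patch(conditions[1, ], config$annulus,
                         center = sheet$region_center,
                         side = sheet$region_side))
  weights <- rf_weights(sheet, ref_patch)
  K1 <- initial_coupling(sheet, config$coupling)
  drives <- lapply(seq_len(config$sessions), function(s)
    session_drive(sheet, weights, conditions, config$blocks,
                  config$annulus, config$seed, session = s))
  if (is.null(behavior)) {
    truth <- psychometric_params(0, 4)
    cohort <- generate_cohort(config$n_participants, drives, K1, truth,
                              config$population, config$behavior_blocks,
                              config$coupling$gamma, config$trial,
                              config$seed)
    behavior <- cohort$trials
  }
  zl <- sort(unique(conditions$zeta))
  rl <- sort(unique(conditions$rho))
  bt <- behavior_tongues(behavior, zl, rl)
  acc1 <- mean_tongue(lapply(bt, `[[`, 1))
  acc2 <- mean_tongue(lapply(bt, `[[`, 2))
  res1 <- simulate_session(drives[[1]], K1, config$trial, retain_plv = TRUE)
  psych <- fit_psychometric(res1$tongue, acc1, config$behavior_blocks)
  Q1 <- accumulate_experience(res1$plv, res1$trials$r_mean, psych)
  est <- estimate_learning_rate(acc2, K1, Q1, drives[[2]],
                                config$coupling$gamma, config$learning,
                                config$trial)
  lrn <- learn_sessions(drives, K1, psych, est$E, config$coupling$gamma,
                        config$trial)
  evaluation <- evaluate_tongues(lrn$tongues, bt)
  list(tongues = lrn$tongues, psych = psych, E = est$E,
       evaluation = evaluation, behavior = behavior,
       manifest = list(config = config, config_hash = config_hash(config),
                       tongue_hash = config_hash(lapply(lrn$tongues,
                                                        `[[`, "values")),
                       package_version =
                         as.character(utils::packageVersion("gammatongue"))))
}

#' Evaluate simulated tongues against behaviour
#'
#' Per-session Pearson correlation and weighted Jaccard similarity
#' between the simulated synchrony tongues and the cohort-mean accuracy
#' tongues (min-max normalised), Simpson tongue sizes for both (min-max
#' normalised across sessions for display), and fold-based noise-ceiling
#' bands when more than one participant is available.
#'
#' @param sim_tongues list of simulated synchrony tongues per session.
#' @param behavior_tongues nested per-participant, per-session accuracy
#'   tongues (see [behavior_tongues()]).
#' @param held_out_only if TRUE, restrict the similarity table to
#'   sessions 3 onward (the sessions untouched by parameter fitting).
#' @return list with `similarity` (data.frame: session, pearson,
#'   jaccard, noise-ceiling bounds), `sizes` (data.frame: session,
#'   simulated and behavioural Simpson volumes plus their across-session
#'   min-max normalisations).
#' @export
evaluate_tongues <- function(sim_tongues, behavior_tongues,
                             held_out_only = FALSE) {
  S <- length(sim_tongues)
  P <- length(behavior_tongues)
  sessions <- seq_len(S)
  if (held_out_only) sessions <- sessions[sessions >= 3]
  rows <- lapply(sessions, function(s) {
    beh <- lapply(seq_len(P), function(p) behavior_tongues[[p]][[s]])
    mt <- minmax_normalize(mean_tongue(beh))
    pear <- pearson_similarity(sim_tongues[[s]], mt)
    jac <- weighted_jaccard(sim_tongues[[s]], mt)
    nc <- c(lower = NA_real_, upper = NA_real_)
    if (P >= 3) {
      folds <- lapply(seq_len(P), function(p)
        minmax_normalize(mean_tongue(beh[-p])))
      outs <- lapply(seq_len(P), function(p) minmax_normalize(beh[[p]]))
      nc <- noise_ceiling(folds, outs, weighted_jaccard)
    }
    data.frame(session = s, pearson = pear, jaccard = jac,
               ceiling_lower = nc[["lower"]], ceiling_upper = nc[["upper"]])
  })
  sim_sizes <- vapply(sim_tongues, tongue_size, numeric(1))
  beh_sizes <- vapply(seq_len(S), function(s) {
    beh <- lapply(seq_len(P), function(p) behavior_tongues[[p]][[s]])
    tongue_size(mean_tongue(beh))
  }, numeric(1))
  mm <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    (x - min(x)) / diff(range(x))
  list(similarity = do.call(rbind, rows),
       sizes = data.frame(session = seq_len(S), simulated = sim_sizes,
                          behavioral = beh_sizes,
                          simulated_norm = mm(sim_sizes),
                          behavioral_norm = mm(beh_sizes)))
}
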