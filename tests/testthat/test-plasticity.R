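test_that("the psychometric link evaluates the logistic exactly", {
  expect_equal(prob_correct(0.5, psychometric_params(-2, 4)), 0.5)
  expect_equal(prob_correct(0.5, psychometric_params(0, 2)),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  flat <- psychometric_params(1, 0)
  expect_equal(prob_correct(c(0, 0.5, 1), flat),
               rep(1 / (1 + exp(-1)), 3))
})

test_that("psychometric fitting recovers known parameters", {
  set.seed(41)
  r <- matrix(runif(25, 0, 1), 5, 5)
  truth <- psychometric_params(-0.5, 3)
  n <- 400
  acc <- matrix(rbinom(25, n, prob_correct(r, truth)) / n, 5, 5)
  ax <- seq(0.01, 1, length.out = 5)
  rx <- seq(1, 1.5, length.out = 5)
  fit <- fit_psychometric(arnold_tongue(r, ax, rx),
                          arnold_tongue(acc, ax, rx, kind = "accuracy"), n)
  expect_lt(abs(fit$mu0 - truth$mu0), 2 * fit$se["mu0"])
  expect_lt(abs(fit$mu1 - truth$mu1), 2 * fit$se["mu1"])
  ## accuracy unrelated to synchrony: slope indistinguishable from zero
  acc0 <- matrix(rbinom(25, n, 0.7) / n, 5, 5)
  fit0 <- fit_psychometric(arnold_tongue(r, ax, rx),
                           arnold_tongue(acc0, ax, rx, kind = "accuracy"), n)
  expect_lt(abs(fit0$mu1), 2.5 * fit0$se["mu1"])
  ## degenerate accuracy is rejected
  acc1 <- matrix(1, 5, 5)
  expect_error(fit_psychometric(arnold_tongue(r, ax, rx),
                                arnold_tongue(acc1, ax, rx,
                                              kind = "accuracy"), n),
               "degenerate")
  ## perfect separation is flagged
  accs <- matrix(as.numeric(r > 0.5), 5, 5)
  fits <- fit_psychometric(arnold_tongue(r, ax, rx),
                           arnold_tongue(accs, ax, rx, kind = "accuracy"),
                           n)
  expect_true(attr(fits, "separation"))
})

test_that("experience accumulation is a correctness-weighted mean", {
  P1 <- matrix(0.2, 3, 3)
  P2 <- matrix(0.6, 3, 3)
  ## P_c of 0.25 and 0.75 for the two trials
  params <- psychometric_params(qlogis(0.25), qlogis(0.75) - qlogis(0.25))
  Q <- accumulate_experience(list(P1, P2), c(0, 1), params)
  expect_equal(Q$Q, matrix(0.5, 3, 3), tolerance = 1e-12)
  ## single trial: Q equals that trial's PLV
  expect_equal(accumulate_experience(list(P2), 0.3, params)$Q, P2)
  ## equal weights cancel: plain mean
  Qeq <- accumulate_experience(list(P1, P2), c(0.4, 0.4),
                               psychometric_params(0, 1))
  expect_equal(Qeq$Q, (P1 + P2) / 2, tolerance = 1e-12)
  expect_error(accumulate_experience(list(), numeric(0), params), "parallel")
})

test_that("the coupling update has exact limits and stays bounded", {
  set.seed(42)
  N <- 8
  K0 <- matrix(runif(N * N, 0, 24), N, N)
  K0 <- (K0 + t(K0)) / 2
  diag(K0) <- 0
  Q <- matrix(runif(N * N), N, N)
  Q <- (Q + t(Q)) / 2
  gamma <- 24.63
  expect_equal(update_coupling(K0, Q, gamma, 0)$K, K0)          # no learning
  big <- update_coupling(K0, Q, gamma, 50)$K
  QT <- Q
  diag(QT) <- 0
  expect_equal(big, gamma * QT, tolerance = 1e-12)              # fixed point
  half <- update_coupling(K0, Q, gamma, log(2))$K
  expect_equal(half, {
    m <- (K0 + gamma * Q) / 2
    diag(m) <- 0
    m
  }, tolerance = 1e-12)
  expect_error(update_coupling(K0, Q, gamma, -1), "E must be")
  ## boundedness across many sessions with arbitrary experience
  K <- K0
  for (s in 1:50) {
    Qs <- matrix(runif(N * N), N, N)
    Qs <- (Qs + t(Qs)) / 2
    K <- update_coupling(K, Qs, gamma, runif(1, 0, 2))$K
    expect_true(all(K >= 0 & K <= gamma))
    expect_equal(K, t(K), tolerance = 1e-12)
  }
})

test_that("the nested grid search matches exhaustive evaluation", {
  sh <- sheet6()
  w <- weights6()
  K1 <- initial_coupling(sh)
  conds <- build_condition_grid(2, 2)
  cfg <- trial_config(substeps = 1)
  drive2 <- session_drive(sh, w, conds, blocks = 1, seed = 55, session = 2)
  res1 <- run_session(sh, w, K1, conds, blocks = 1, config = cfg,
                      seed = 55, session = 1, retain_plv = TRUE)
  psych <- psychometric_params(0, 4)
  Q1 <- accumulate_experience(res1$plv, res1$trials$r_mean, psych)
  ## a behaviour tongue with some structure
  target <- arnold_tongue(matrix(c(0.9, 0.7, 0.75, 0.55), 2, 2),
                          c(0.01, 1), c(1, 1.5), kind = "accuracy")
  lc <- learning_config(grid_levels = 2, candidates_per_grid = 5)
  est <- estimate_learning_rate(target, K1, Q1, drive2,
                                config = lc, sim_config = cfg)
  ## oracle: re-evaluate every visited candidate directly
  norm_target <- minmax_normalize(target)
  redo <- vapply(est$trace$E, function(E) {
    K2 <- update_coupling(K1, Q1, 24.63, E)
    weighted_jaccard(norm_target, simulate_session(drive2, K2, cfg)$tongue)
  }, numeric(1))
  expect_equal(est$trace$objective, redo, tolerance = 1e-12)
  expect_equal(est$objective, max(redo))
  expect_equal(est$E, est$trace$E[which.max(est$trace$objective)])
  ## refinement grids nest inside the coarse grid's neighbour interval
  g1 <- est$trace[est$trace$level == 1, ]
  g2 <- est$trace[est$trace$level == 2, ]
  expect_gte(min(g2$E), min(g1$E))
  expect_lte(max(g2$E), max(g1$E))
})

test_that("leave-one-out folds are exchangeable and leak-free", {
  sh <- sheet6()
  w <- weights6()
  K1 <- initial_coupling(sh)
  conds <- build_condition_grid(2, 2)
  cfg <- trial_config(substeps = 1)
  drives <- lapply(1:3, function(s)
    session_drive(sh, w, conds, blocks = 1, seed = 60, session = s))
  ## three participants with literally identical behaviour
  one <- with_stream(61, {
    tongue <- arnold_tongue(matrix(c(0.92, 0.8, 0.85, 0.7), 2, 2),
                            c(0.01, 1), c(1, 1.5), kind = "accuracy")
    lapply(1:3, function(s) tongue)
  })
  behavior <- list(one, one, one)
  folds <- loo_cross_validate(behavior, drives, K1, trial_counts = 30,
                              sessions = 3,
                              learn_config = learning_config(
                                grid_levels = 2, candidates_per_grid = 5),
                              sim_config = cfg)
  expect_length(folds, 3)
  Es <- vapply(folds, `[[`, numeric(1), "E")
  expect_true(all(Es == Es[1]))  # exchangeable cohort, identical fits
  mus <- vapply(folds, function(f) f$psych$mu1, numeric(1))
  expect_true(all(mus == mus[1]))
  expect_length(folds[[1]]$tongues, 3)
  ## altering only the left-out participant's data must not change the fold
  behavior2 <- behavior
  behavior2[[2]] <- lapply(behavior[[2]], function(t) {
    t$values <- pmin(1, t$values + 0.05)
    t
  })
  folds2 <- loo_cross_validate(behavior2, drives, K1, trial_counts = 30,
                               sessions = 3,
                               learn_config = learning_config(
                                 grid_levels = 2, candidates_per_grid = 5),
                               sim_config = cfg)
  expect_equal(folds2[[2]]$E, folds[[2]]$E)
  expect_equal(folds2[[2]]$psych$mu1, folds[[2]]$psych$mu1)
  expect_error(loo_cross_validate(behavior[1], drives, K1, 30),
               "at least 2")
})
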