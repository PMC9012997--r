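test_that("SMOTE balances classes by convex minority interpolation", {
  set.seed(1)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(1, 10), rep(0, 50))
  out <- smote(X, y, k_neighbors = 5, seed = 2)
  expect_equal(as.vector(table(out$y)), c(50L, 50L))
  expect_equal(out$X[1:60, ], X)           # originals preserved, first
  expect_equal(out$synthetic, c(rep(FALSE, 60), rep(TRUE, 40)))

  # synthetic points lie inside the minority convex hull (here: a segment)
  Xs <- rbind(c(0, 0), c(1, 1), matrix(rnorm(20, 5), 10, 2))
  colnames(Xs) <- c("a", "b")
  ys <- c(1, 1, rep(0, 10))
  o2 <- smote(Xs, ys, k_neighbors = 1, seed = 3)
  syn <- o2$X[o2$synthetic, , drop = FALSE]
  expect_equal(syn[, "a"], syn[, "b"], tolerance = 1e-12)
  expect_true(all(syn >= 0 & syn <= 1))

  # balanced input unchanged
  o3 <- smote(X[1:20, ], rep(c(0, 1), 10), seed = 1)
  expect_equal(nrow(o3$X), 20)
  expect_error(smote(X, c(rep(1, 3), rep(0, 57))), class = "otevents_error")
})

test_that("logit fit matches the gradient-free likelihood oracle and is invariant to row duplication", {
  set.seed(5)
  X <- matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("u", "v")))
  y <- rbinom(400, 1, plogis(-0.5 + 1.2 * X[, 1] - 0.8 * X[, 2]))
  m <- fit_event_model(X, y)
  orc <- oracle_logit(X, y)
  expect_equal(unname(c(m$intercept, m$coefficients)), orc, tolerance = 1e-4)

  m2 <- fit_event_model(rbind(X, X), c(y, y))
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-8)

  expect_error(fit_event_model(X, rep(1, 400)), class = "otevents_error")
})

test_that("null predictors stay insignificant and informative ones are retained", {
  set.seed(6)
  reps <- 30
  null_ok <- 0; noise_dropped <- 0; informative_kept <- 0
  for (r in seq_len(reps)) {
    sim <- synth_logistic(2000, coefs = c(MT = 1.5, SH = -0.8), seed = 100 + r)
    Xn <- cbind(sim$X, NOISE = rnorm(2000))
    m <- backward_eliminate(Xn, sim$y)
    if (!"NOISE" %in% m$predictors) noise_dropped <- noise_dropped + 1
    if (all(c("MT", "SH") %in% m$predictors))
      informative_kept <- informative_kept + 1
    # independent outcome: all p-values should typically stay above 0.05
    y0 <- sample(sim$y)
    m0 <- fit_event_model(sim$X, y0)
    if (all(m0$p_values > 0.05)) null_ok <- null_ok + 1
  }
  expect_gte(noise_dropped / reps, 0.9)
  expect_equal(informative_kept, reps)
  expect_gte(null_ok / reps, 0.8)

  # everything eliminated -> intercept-only degenerate model
  set.seed(9)
  Xjunk <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("p", "q")))
  yjunk <- rbinom(200, 1, 0.3)
  md <- backward_eliminate(Xjunk, yjunk)
  expect_true(md$degenerate || all(md$p_values <= 0.05))
  if (md$degenerate) expect_length(md$predictors, 0)
})

test_that("driver ranking orders a realistic coefficient profile", {
  # a typical central-European station profile:
  # GH -0.44, MT 4.29, SH -1.66, SSRD 0.76, WT 0.61
  m <- structure(list(coefficients = c(GH = -0.44, MT = 4.29, SH = -1.66,
                                       SSRD = 0.76, WT = 0.61)),
                 class = "logistic_model")
  r <- rank_drivers(m)
  expect_equal(r$predictor, c("MT", "SH", "SSRD"))
  expect_equal(r$role, c("MID", "SMID", "TMID"))
  expect_equal(r$coefficient, c(4.29, -1.66, 0.76))  # signs preserved

  single <- structure(list(coefficients = c(MT = 2.0)),
                      class = "logistic_model")
  rs <- rank_drivers(single)
  expect_equal(rs$role, "MID")
  expect_equal(nrow(rs), 1)

  # ties broken by fixed column order GH, MT, SH, SSRD, WT
  tie <- structure(list(coefficients = c(WT = 1.0, MT = -1.0)),
                   class = "logistic_model")
  expect_equal(rank_drivers(tie)$predictor[1], "MT")
})

test_that("McFadden R2 follows the log-likelihood arithmetic", {
  # hand-computed: y = 1,0,1,0 with p = .8,.2,.8,.2 vs null p = .5
  m <- structure(list(intercept = 0, coefficients = c(x = log(16)),
                      predictors = "x"), class = "logistic_model")
  X <- matrix(c(0.5, -0.5, 0.5, -0.5), 4, 1, dimnames = list(NULL, "x"))
  y <- c(1, 0, 1, 0)
  expect_equal(unname(predict_prob(m, X)), c(0.8, 0.2, 0.8, 0.2))
  expect_equal(mcfadden_r2(m, X, y), 1 - log(0.8) / log(0.5),
               tolerance = 1e-12)

  # model equal to null -> 0
  m0 <- structure(list(intercept = qlogis(0.5), coefficients = numeric(0),
                       predictors = character(0),
                       log_likelihood = 4 * log(0.5),
                       null_log_likelihood = 4 * log(0.5)),
                  class = "logistic_model")
  expect_equal(mcfadden_r2(m0), 0)
})

test_that("classification metrics handle exact counts and edge thresholds", {
  y <- c(rep(1, 10), rep(0, 10))
  prob <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  cm <- classification_metrics(y, prob, 0.5)   # TP=8 FP=2 FN=2
  expect_equal(c(cm$precision, cm$recall, cm$f1), c(0.8, 0.8, 0.8))

  cm2 <- classification_metrics(y, prob, 0.95)
  expect_equal(cm2$recall, 0)
  cm3 <- classification_metrics(y, c(rep(0.9, 10), rep(0.1, 10)), 0.5)
  expect_equal(c(cm3$precision, cm3$recall, cm3$f1), c(1, 1, 1))
  expect_error(classification_metrics(y, prob[1:5], 0.5),
               class = "otevents_error")
})

test_that("threshold calibration attains the grid minimum of mean |P - R|", {
  sim <- synth_logistic(800, seed = 21)
  cal <- calibrate_threshold(sim$X, sim$y, folds = 5, seed = 2)
  expect_equal(unname(cal$objective[format(cal$threshold)]),
               min(cal$objective, na.rm = TRUE))
  # ties resolve toward 0.5 then smaller (constructed argmin check)
  obj <- cal$objective[!is.na(cal$objective)]
  best <- as.numeric(names(obj)[obj == min(obj)])
  expect_equal(cal$threshold, best[order(abs(best - 0.5), best)][1])
})

test_that("nested evaluation is leakage-free, deterministic, and honest on nulls", {
  sim <- synth_logistic(900, seed = 31)
  r1 <- evaluate_model(sim$X, sim$y, folds = 5, inner_folds = 5, seed = 3)
  r2 <- evaluate_model(sim$X, sim$y, folds = 5, inner_folds = 5, seed = 3)
  expect_equal(r1$per_fold, r2$per_fold)
  # validation folds partition the original rows: no synthetic samples leak
  expect_equal(sum(r1$per_fold$n_val), length(sim$y))
  expect_true(all(r1$per_fold[c("precision", "recall", "f1", "mcfadden")] >= 0 &
                    r1$per_fold[c("precision", "recall", "f1", "mcfadden")] <= 1))
  expect_gt(r1$f1, 0.5)

  # permuted labels collapse F1 to the event-rate baseline
  set.seed(4)
  yperm <- sample(sim$y)
  r0 <- evaluate_model(sim$X, yperm, folds = 5, inner_folds = 5, seed = 3)
  # a permuted-label model has no skill: F1 sits at the event-rate level,
  # far below the informative model's
  expect_lt(abs(r0$f1 - mean(sim$y)), 0.15)
  expect_lt(r0$f1, r1$f1 - 0.25)
})
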