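test_that("logistic fit equals the closed-form log odds ratio on a 2x2 table", {
  # none: 40 yes / 10 no; lower: 25 yes / 25 no -> b = ln((25*10)/(25*40))
  tr <- data.frame(
    participant_id = "p1",
    mask = rep(c("none", "lower"), times = c(50, 50)),
    correct = c(rep(c(TRUE, FALSE), c(40, 10)), rep(c(TRUE, FALSE), c(25, 25)))
  )
  res <- fit_logistic_mixed(tr, random = NULL)
  b <- res$b[res$term == "lower > none"]
  expect_equal(b, log(0.25), tolerance = 1e-4)
  expect_lt(res$ci_low[res$term == "lower > none"], b)
  expect_error(fit_logistic_mixed(tr[tr$mask == "none", ], random = NULL),
               "2 mask levels")
  sep <- data.frame(participant_id = "p", mask = rep(c("none", "lower"), each = 10),
                    correct = rep(c(TRUE, FALSE), each = 10))
  expect_error(fit_logistic_mixed(sep, random = NULL), "separation")
})

test_that("null simulations give small coefficients and calibrated intervals", {
  hits <- 0
  for (seed in 1:30) {
    tr <- make_logit_dataset(n_p = 15, n_per_mask = 20,
                             b_mask = c(lower = 0, upper = 0, none = 0),
                             u_sd = 0.6, seed = seed)
    res <- fit_logistic_mixed(tr)
    row <- res[res$term == "lower > none", ]
    hits <- hits + (row$ci_low <= 0 && 0 <= row$ci_high)
  }
  expect_gte(hits / 30, 0.80)   # ~95% nominal, 30 replicates
})

test_that("a constructed accuracy drop yields a negative mask coefficient", {
  tr <- make_logit_dataset(n_p = 30, n_per_mask = 30,
                           b_mask = c(lower = -1.2, upper = -0.3, none = 0),
                           seed = 5)
  res <- fit_logistic_mixed(tr)
  expect_lt(res$b[res$term == "lower > none"], 0)
  expect_lt(res$p[res$term == "lower > none"], 0.05)
})

test_that("linear RT model matches an independent least-squares solve", {
  set.seed(6)
  n <- 120
  tr <- data.frame(
    participant_id = "p1",
    mask = sample(c("lower", "none"), n, replace = TRUE),
    correct = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
  tr$log_rt <- rnorm(n, 6.7, 0.3) - 0.1 * (tr$mask == "lower" & tr$correct)
  res <- fit_linear_mixed(tr, random = NULL)
  # normal-equations oracle with the same cell-coding
  X <- cbind(1, tr$mask == "lower", !tr$correct,
             (tr$mask == "lower") & !tr$correct)
  beta <- solve(t(X) %*% X, t(X) %*% tr$log_rt)
  expect_equal(res$b[res$term == "Correct: lower > none"], beta[2],
               tolerance = 1e-8)
  expect_equal(res$b[res$term == "Face mask * rating"], beta[4],
               tolerance = 1e-8)
  expect_equal(res$b[res$term == "Incorrect: lower > none"], beta[2] + beta[4],
               tolerance = 1e-8)
})

test_that("identical RT distributions across cells give near-zero coefficients", {
  set.seed(7)
  tr <- expand.grid(participant_id = sprintf("P%02d", 1:20),
                    mask = c("lower", "none"), rep = 1:20,
                    stringsAsFactors = FALSE)
  tr$correct <- runif(nrow(tr)) < 0.8
  tr$log_rt <- rnorm(nrow(tr), 6.7, 0.25)
  res <- fit_linear_mixed(tr)
  expect_true(all(abs(res$statistic) < 3))
  # constructed slowdown for correct lower-mask trials
  tr2 <- tr
  tr2$log_rt <- tr2$log_rt + 0.15 * (tr2$mask == "lower" & tr2$correct)
  res2 <- fit_linear_mixed(tr2)
  expect_gt(res2$b[res2$term == "Correct: lower > none"], 0.05)
})

test_that("cluster bootstrap is deterministic, consistent, and failure-aware", {
  tr <- make_logit_dataset(n_p = 20, n_per_mask = 20, seed = 11)
  fn <- logistic_contrast_fn()
  ci1 <- bootstrap_ci(fn, tr, n_boot = 80, seed = 2)
  ci2 <- bootstrap_ci(fn, tr, n_boot = 80, seed = 2)
  expect_identical(ci1, ci2)
  row <- ci1[ci1$term == "lower > none", ]
  expect_lte(row$ci_low, row$b)
  expect_gte(row$ci_high, row$b)

  # toy 2x2 CI contains the closed-form estimate
  tr22 <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:50), each = 2),
    mask = rep(c("none", "lower"), times = 50),
    correct = c(rbind(rep(c(TRUE, FALSE), c(40, 10)),
                      rep(c(TRUE, FALSE), c(25, 25))))
  )
  ci <- bootstrap_ci(logistic_contrast_fn(), tr22, n_boot = 120, seed = 3)
  r <- ci[ci$term == "lower > none", ]
  expect_lte(r$ci_low, log(0.25))
  expect_gte(r$ci_high, log(0.25))

  # constant estimator -> zero-width interval
  const_fn <- function(d) c(k = 1.5)
  cc <- bootstrap_ci(const_fn, tr, n_boot = 40, seed = 1)
  expect_equal(cc$ci_low, cc$ci_high)

  # > 5% refit failures abort with a log
  flaky <- local({
    i <- 0
    function(d) {
      i <<- i + 1
      if (i %% 3 == 0) stop("synthetic failure")
      c(k = mean(d$correct))
    }
  })
  expect_error(bootstrap_ci(flaky, tr, n_boot = 30, seed = 1), "5%")
})

test_that("two-tailed mask test keeps its size under participant heterogeneity", {
  n_rep <- 120
  rejections <- 0
  for (seed in seq_len(n_rep)) {
    tr <- make_logit_dataset(n_p = 20, n_per_mask = 12,
                             b_mask = c(lower = 0, none = 0), u_sd = 0.8,
                             seed = 1000 + seed)
    res <- fit_logistic_mixed(tr)
    rejections <- rejections + (res$p[res$term == "lower > none"] < 0.05)
  }
  # nominal 5%; allow 7.5% plus binomial simulation error at 120 replicates
  expect_lte(rejections / n_rep, 0.075 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("chance tests flag above-chance accuracy and respect the null", {
  tr_hi <- make_logit_dataset(n_p = 25, n_per_mask = 25, b0 = 0.62,
                              b_mask = c(lower = 0, upper = 0, none = 0),
                              u_sd = 0.3, seed = 21)  # ~65% accuracy
  res <- chance_test(tr_hi)
  expect_true(all(res$above_chance))

  all_correct <- data.frame(participant_id = rep(c("a", "b"), 20),
                            mask = "none", correct = TRUE)
  res2 <- chance_test(all_correct)
  expect_true(res2$above_chance)
  expect_error(chance_test(data.frame(participant_id = "a", mask = "none",
                                      correct = TRUE)), "fewer than 2")
})

test_that("the false-positive cascade gates stages per pairing", {
  set.seed(31)
  # small synthetic incongruent set: null everywhere except one loaded pairing
  grid <- expand.grid(participant_id = sprintf("P%02d", 1:16),
                      expression = EMOTIONS, rated_emotion = EMOTIONS,
                      mask = MASKS, rep = 1:2, stringsAsFactors = FALSE)
  grid <- grid[grid$expression != grid$rated_emotion, ]
  grid$pairing <- paste(grid$expression, grid$rated_emotion, sep = ":")
  n <- nrow(grid)
  p_yes <- rep(0.25, n)
  loaded <- grid$pairing == "surprise:anger" & grid$mask == "lower"
  p_yes[loaded] <- 0.75
  grid$response <- ifelse(runif(n) < p_yes, "yes", "no")
  grid$correct <- grid$response == "no"
  grid$rt_ms <- exp(rnorm(n, 6.6, 0.3)) + 250
  grid$rt_ms[loaded] <- exp(rnorm(sum(loaded), 7.1, 0.3)) + 250

  out <- fp_cascade(grid, ddm_args = list(n_samples = 150, burn_in = 50, seed = 1))
  expect_equal(nrow(out$trail), 30)
  expect_setequal(out$trail$stage_reached, unique(out$trail$stage_reached))
  expect_gte(out$trail$stage_reached[out$trail$pairing == "surprise:anger"], 2)
  # most pairings stay at stage 1 under the null
  expect_gte(mean(out$trail$stage_reached == 1), 0.7)
})
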