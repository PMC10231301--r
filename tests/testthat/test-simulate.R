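test_that("driftless diffusion splits evenly and matches the closed-form mean passage time", {
  p <- ddm_params(v = 0, a = 2, z = 0.5, t = 0)
  sim <- simulate_trial(p, n = 1e5, seed = 11)
  # symmetry: upper fraction 0.5 within 3 Monte-Carlo SEs
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(mean(sim$upper) - 0.5), 3 * se)
  # E[T] = x (a - x) with unit diffusion, x = a z -> 1.0 s
  expect_lt(abs(mean(sim$rt) - 1.0), 0.02)
})

test_that("absorption fractions match the closed form across drift settings", {
  p <- ddm_params(v = 1, a = 2, z = 0.5, t = 0)
  sim <- simulate_trial(p, n = 1e5, seed = 12)
  target <- (1 - exp(-2)) / (1 - exp(-4))   # 0.88080
  expect_lt(abs(mean(sim$upper) - target), 3 * sqrt(target * (1 - target) / 1e5) + 0.003)

  # grid check with inter-trial variabilities off
  grid <- expand.grid(v = c(-0.5, 0.8), a = c(1, 1.6), z = c(0.35, 0.6))
  for (i in seq_len(nrow(grid))) {
    pi <- ddm_params(v = grid$v[i], a = grid$a[i], z = grid$z[i], t = 0)
    sim <- simulate_trial(pi, n = 2e4, seed = 100 + i)
    pexp <- choice_probability(pi)
    expect_lt(abs(mean(sim$upper) - pexp),
              3 * sqrt(pexp * (1 - pexp) / 2e4) + 0.004)
  }
})

test_that("simulated studies show the constructed mask deficit and exact bookkeeping", {
  design <- generate_blocks(6, seed = 21)
  schedule <- schedule_rounds(sprintf("P%02d", 1:60), seed = 21)
  drift <- matrix(1.8, 6, 3, dimnames = list(EMOTIONS, MASKS))
  drift["disgust", "lower"] <- 0.6   # strong lower-mask deficit for disgust
  truth <- ground_truth(drift = drift, contamination_rate = 0,
                        attention_fail_rate = 0, intercept_sd = 0.2)
  tr <- simulate_study(design, schedule, truth, seed = 31)
  expect_equal(nrow(tr), 60 * nrow(design))

  cong <- tr[tr$congruent & tr$rated_emotion == "disgust", ]
  acc <- tapply(cong$correct, cong$mask, mean)
  expect_lt(acc[["lower"]], acc[["none"]])
  mrt <- tapply(cong$rt_ms[cong$correct], cong$mask[cong$correct], mean)
  expect_gt(mrt[["lower"]], mrt[["none"]])
})

test_that("contamination and attention flags behave as configured", {
  design <- generate_blocks(6, seed = 5)
  schedule <- schedule_rounds(c("a", "b", "c"), seed = 5)
  clean <- simulate_study(design, schedule,
                          ground_truth(contamination_rate = 0,
                                       attention_fail_rate = 0),
                          seed = 6)
  expect_equal(sum(clean$rt_ms < 100), 0)
  expect_false(any(clean$attention_failed))

  dirty <- simulate_study(design, schedule,
                          ground_truth(contamination_rate = 0.3,
                                       attention_fail_rate = 0),
                          seed = 6)
  expect_true(all(dirty$rt_ms[dirty$contaminant] < 100))
  expect_gt(sum(dirty$contaminant), 0)
})

test_that("identical seeds reproduce identical datasets", {
  design <- generate_blocks(6, seed = 7)
  schedule <- schedule_rounds(c("a", "b"), seed = 7)
  truth <- ground_truth()
  expect_identical(simulate_study(design, schedule, truth, seed = 9),
                   simulate_study(design, schedule, truth, seed = 9))
  expect_false(identical(simulate_study(design, schedule, truth, seed = 9),
                         simulate_study(design, schedule, truth, seed = 10)))
})

test_that("correctness, congruency and response are mutually consistent", {
  design <- generate_blocks(6, seed = 8)
  schedule <- schedule_rounds(c("a", "b"), seed = 8)
  tr <- simulate_study(design, schedule,
                       ground_truth(contamination_rate = 0.1,
                                    attention_fail_rate = 0), seed = 12)
  expect_true(all(tr$rt_ms > 0))
  yes <- tr$response == "yes"
  expect_identical(tr$correct, tr$congruent == yes)
})
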