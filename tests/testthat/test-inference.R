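small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- make_hier_dataset(n_p = 12, n_per = 10, seed = 3)
      mod <- build_model(tr, ddm_model_spec())
      cache <<- list(trials = tr, model = mod,
                     fit = sample_posterior(mod, n_samples = 500,
                                            burn_in = 100, seed = 21))
    }
    cache
  }
})

test_that("model building maps trials to drift cells with shared parameters", {
  tr <- make_hier_dataset(n_p = 5, n_per = 4, seed = 1)
  mod <- build_model(tr, ddm_model_spec())
  expect_setequal(mod$cells, c("lower", "upper", "none"))
  expect_equal(length(mod$pids), 5)
  expect_equal(mod$data$n, nrow(tr))
  # parameter vector: 3 drift cells + shared a, z, t0, sv + u_sd + intercepts
  fit <- sample_posterior(mod, n_samples = 60, burn_in = 10, seed = 1)
  expect_setequal(grep("^u\\[", colnames(fit$draws), invert = TRUE, value = TRUE),
                  c("v_lower", "v_upper", "v_none", "a", "z", "t0", "sv", "u_sd"))
  expect_equal(sum(grepl("^u\\[", colnames(fit$draws))), 5)

  # boundary-variant: a indexed by mask, drift-by-mask retained
  modb <- build_model(tr, ddm_model_spec(boundary_by_mask = TRUE))
  fitb <- sample_posterior(modb, n_samples = 60, burn_in = 10, seed = 1)
  expect_true(all(c("a_lower", "a_upper", "a_none", "v_lower") %in%
                    colnames(fitb$draws)))

  # flat data reduces to a single-condition fit
  flat <- tr[tr$mask == "none", ]
  modf <- build_model(flat, ddm_model_spec())
  expect_equal(modf$cells, "none")

  expect_error(build_model(flat, ddm_model_spec(cells = c("lower", "none"))),
               "lower")
  expect_error(build_model(tr[0, ], ddm_model_spec()), "prior_only")
})

test_that("the log-posterior callable is finite and prior-sensitive", {
  x <- small_fit()
  state <- maskddm:::init_state(x$model)
  lp <- x$model$log_posterior(state)
  expect_true(is.finite(lp))
  state$a <- -1
  expect_identical(x$model$log_posterior(state), -Inf)
})

test_that("sampling is deterministic in the seed and retains n - burn_in draws", {
  x <- small_fit()
  expect_equal(nrow(x$fit$draws), 400)
  f2 <- sample_posterior(x$model, n_samples = 500, burn_in = 100, seed = 21)
  expect_identical(x$fit$draws, f2$draws)
  f3 <- sample_posterior(x$model, n_samples = 500, burn_in = 100, seed = 22)
  expect_false(identical(x$fit$draws, f3$draws))
  expect_true(all(is.finite(x$fit$draws)))
  expect_false(anyDuplicated(colnames(x$fit$draws)) > 0)
  # diagnostics attached for structural parameters
  expect_true(all(c("rhat", "ess") %in% names(x$fit$diagnostics)))
})

test_that("prior-only sampling reproduces the prior moments", {
  spec <- ddm_model_spec(prior_only = TRUE)
  mod <- build_model(data.frame(), spec)
  fit <- sample_posterior(mod, n_samples = 4000, burn_in = 500, seed = 8)
  v <- fit$draws[, "v_none"]
  # prior: normal(0, 2); MH autocorrelation widens the Monte-Carlo error
  expect_lt(abs(mean(v)), 0.25)
  expect_lt(abs(sd(v) - 2), 0.3)
  u_sd <- fit$draws[, "u_sd"]
  # half-normal(0, 1): mean sqrt(2/pi) = 0.798
  expect_lt(abs(mean(u_sd) - sqrt(2 / pi)), 0.12)
})

test_that("posterior contrast probabilities follow their definition", {
  A <- c(1, 2, 3, 4)
  draws <- cbind(A = A, B = A, C = A + 10, Z = c(-1, -2, 1, 2))
  expect_equal(posterior_prob(draws, "A > B")$probability, 0.5)
  expect_equal(posterior_prob(draws, "C > A")$probability, 1.0)
  expect_equal(posterior_prob(draws, "Z > 0")$probability, 0.5)
  expect_equal(posterior_prob(draws, "Z < 0")$probability, 0.5)
  expect_equal(posterior_prob(draws, "A > 2")$probability, 0.625)  # tie at 2 counts 1/2
  expect_error(posterior_prob(draws, "missing > 0"), "unknown parameter")
  expect_error(posterior_prob(draws, "A >= B"), "contrast")

  set.seed(9)
  d2 <- cbind(A = rnorm(4800, 1, 1), B = rnorm(4800, 0, 1))
  expect_equal(posterior_prob(d2, "A > B")$probability, pnorm(1 / sqrt(2)),
               tolerance = 0.025)
})

test_that("cross-study comparison is antisymmetric and detects larger effects", {
  set.seed(10)
  mk <- function(eff, n = 2000) cbind(v_lower = rnorm(n, eff, 0.05),
                                      v_none = rnorm(n, 1.5, 0.05))
  s1 <- mk(1.1); s2 <- mk(0.7)   # study 2 effect twice study 1's
  expect_equal(compare_fits(s1, s1)$probability, 0.5, tolerance = 0.03)
  p12 <- compare_fits(s1, s2)$probability
  p21 <- compare_fits(s2, s1)$probability
  expect_equal(p12 + p21, 1, tolerance = 1e-12)
  expect_lt(p12, 0.001)  # study 2 effect more negative -> P(e2 > e1) tiny
  # mismatched draw counts resampled deterministically
  s3 <- mk(0.7, 1500)
  expect_equal(compare_fits(s1, s3, seed = 4)$probability,
               compare_fits(s1, s3, seed = 4)$probability)
})

test_that("posterior means are stable when the chain is lengthened", {
  x <- small_fit()
  long <- sample_posterior(x$model, n_samples = 1000, burn_in = 100, seed = 21)
  key <- c("v_lower", "v_none", "a")
  mc_se <- apply(x$fit$draws[, key], 2, sd) /
    sqrt(pmax(x$fit$diagnostics$ess[match(key, x$fit$diagnostics$parameter)], 1))
  delta <- abs(colMeans(x$fit$draws[, key]) - colMeans(long$draws[, key]))
  expect_true(all(delta < 6 * mc_se + 0.05))
})
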