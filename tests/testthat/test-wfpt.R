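dens_mass <- function(p, boundary, rel.tol = 1e-9) {
  integrate(function(t) wfpt_density(t, boundary, p), p$t, Inf,
            rel.tol = rel.tol, subdivisions = 500L)$value
}

test_that("density is zero at and below the non-decision time", {
  p <- ddm_params(v = 1, a = 2, z = 0.5, t = 0.3)
  expect_equal(wfpt_density(c(0.05, 0.3), "upper", p), c(0, 0))
  expect_gt(wfpt_density(0.31, "upper", p), 0)
})

test_that("reflection symmetry: upper(v, z) equals lower(-v, 1-z)", {
  grid <- expand.grid(v = c(-1, 0, 1.5), a = c(1, 2), z = c(0.3, 0.5, 0.7),
                      t = c(0.45, 1.1))
  for (i in seq_len(nrow(grid))) {
    p1 <- ddm_params(v = grid$v[i], a = grid$a[i], z = grid$z[i], t = 0.2)
    p2 <- ddm_params(v = -grid$v[i], a = grid$a[i], z = 1 - grid$z[i], t = 0.2)
    expect_equal(wfpt_density(grid$t[i], "upper", p1),
                 wfpt_density(grid$t[i], "lower", p2), tolerance = 1e-10)
  }
})

test_that("density mass at each boundary equals the absorption probability", {
  set.seed(14)
  for (i in 1:12) {
    p <- ddm_params(v = runif(1, -2, 2), a = runif(1, 0.8, 2.5),
                    z = runif(1, 0.3, 0.7), t = 0.25)
    up <- dens_mass(p, "upper")
    lo <- dens_mass(p, "lower")
    expect_lt(abs(up + lo - 1), 1e-4)
    expect_lt(abs(up - choice_probability(p)), 1e-4)
  }
})

test_that("closed-form absorption probability covers edge regimes", {
  expect_equal(choice_probability(ddm_params(v = 0, a = 2, z = 0.5, t = 0)), 0.5)
  expect_equal(choice_probability(ddm_params(v = 1, a = 2, z = 0.5, t = 0)),
               (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  expect_equal(choice_probability(ddm_params(v = 50, a = 2, z = 0.5, t = 0)), 1,
               tolerance = 1e-12)
  expect_equal(choice_probability(ddm_params(v = -50, a = 2, z = 0.5, t = 0)), 0,
               tolerance = 1e-12)
})

test_that("variability marginals reduce to the plain density and track simulation", {
  p0 <- ddm_params(v = 1.2, a = 1.6, z = 0.5, t = 0.3)
  tt <- seq(0.35, 2.5, by = 0.05)
  expect_identical(integrate_variabilities(tt, "upper", p0),
                   wfpt_density(tt, "upper", p0))

  # sz/st quadrature against a Monte-Carlo histogram oracle
  p1 <- ddm_params(v = 1.2, a = 1.6, z = 0.5, t = 0.3, sv = 0.4, sz = 0.2,
                   st = 0.15)
  sim <- simulate_trial(p1, n = 4e4, seed = 33)
  br <- seq(0, 4, by = 0.1)
  up <- sim$upper & sim$rt < 4
  h <- hist(sim$rt[up], breaks = br, plot = FALSE)
  mids <- h$mids
  dens <- integrate_variabilities(mids, "upper", p1, rel_tol = 1e-6)
  phat <- h$counts / nrow(sim)
  pmod <- dens * 0.1
  expect_lt(sum(abs(phat - pmod)), 0.03)
})

test_that("increasing drift variability spreads the first-passage density", {
  p_lo <- ddm_params(v = 1.5, a = 1.6, z = 0.5, t = 0.3, sv = 0.1)
  p_hi <- ddm_params(v = 1.5, a = 1.6, z = 0.5, t = 0.3, sv = 1.2)
  tt <- seq(0.31, 5, by = 0.01)
  spread <- function(p) {
    d <- wfpt_density(tt, "upper", p)
    w <- d / sum(d)
    m <- sum(w * tt)
    sum(w * (tt - m)^2)
  }
  expect_gt(spread(p_hi), spread(p_lo))
})

test_that("log-likelihood is an order-independent sum of per-trial log densities", {
  p <- ddm_params(v = 1, a = 1.8, z = 0.5, t = 0.3, sv = 0.3)
  set.seed(4)
  rt <- 0.3 + rexp(100, 2)
  up <- runif(100) < 0.8
  ll <- ddm_loglik(rt, up, p)
  # loop oracle
  ll_loop <- 0
  for (i in 1:100) {
    ll_loop <- ll_loop + log(wfpt_density(rt[i], if (up[i]) "upper" else "lower", p))
  }
  expect_equal(ll, ll_loop, tolerance = 1e-10)
  perm <- sample(100)
  expect_equal(ddm_loglik(rt[perm], up[perm], p), ll, tolerance = 1e-10)
  expect_equal(ddm_loglik(rt[1], up[1], p),
               log(wfpt_density(rt[1], if (up[1]) "upper" else "lower", p)))
  expect_error(ddm_loglik(c(0.2, 0.8), c(TRUE, TRUE), p), "trial 1")
})

test_that("log-likelihood peaks near the generating drift on a large sample", {
  p_true <- ddm_params(v = 1.2, a = 1.6, z = 0.5, t = 0.3)
  sim <- simulate_trial(p_true, n = 4000, seed = 55)
  grid <- seq(0.4, 2.0, by = 0.1)
  ll <- vapply(grid, function(v) {
    ddm_loglik(sim$rt, sim$upper, ddm_params(v = v, a = 1.6, z = 0.5, t = 0.3))
  }, numeric(1))
  expect_lt(abs(grid[which.max(ll)] - 1.2), 0.15)
})

test_that("density agrees with long Euler-Maruyama runs in both fast and slow regimes", {
  sets <- list(ddm_params(v = 2, a = 1, z = 0.5, t = 0),
               ddm_params(v = 0.6, a = 1.8, z = 0.45, t = 0))
  for (p in sets) {
    sim <- simulate_trial(p, n = 1e5, seed = 77)
    expect_lt(binned_l1(sim, p, tmax = 8, width = 0.1), 0.02)
  }
})
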