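# Fixture builders shared across test files. Everything is generated in code
# at test time; no stored data.

# Single-emotion hierarchical dataset: n_p participants x (3 masks x n_per
# trials), drift = v_true[mask] + participant intercept, diffusion choices/RTs.
make_hier_dataset <- function(v_true = c(lower = 0.8, upper = 1.3, none = 1.5),
                              n_p = 40, n_per = 18, u_sd = 0.3, a = 1.77,
                              z = 0.5, t = 0.35, sv = 0.2, seed = 1) {
  u <- with_test_seed(seed, rnorm(n_p, 0, u_sd))
  masks <- names(v_true)
  grid <- expand.grid(p = seq_len(n_p), mask = masks, rep = seq_len(n_per),
                      stringsAsFactors = FALSE)
  params <- maskddm::ddm_params(v = 0, a = a, z = z, t = t, sv = sv)
  params$v <- v_true[grid$mask] + u[grid$p]
  sim <- maskddm::simulate_trial(params, seed = seed + 7)
  data.frame(participant_id = sprintf("P%03d", grid$p),
             mask = grid$mask, correct = sim$upper, rt_ms = sim$rt * 1000,
             stringsAsFactors = FALSE)
}

# Clustered binary-outcome dataset for logistic/bootstrap checks:
# logit P(correct) = b0 + b_mask + participant intercept.
make_logit_dataset <- function(n_p = 24, n_per_mask = 15,
                               b0 = 1.2, b_mask = c(lower = -0.8, upper = -0.4,
                                                    none = 0),
                               u_sd = 0.8, seed = 1) {
  with_test_seed(seed, {
    u <- rnorm(n_p, 0, u_sd)
    grid <- expand.grid(p = seq_len(n_p), mask = names(b_mask),
                        rep = seq_len(n_per_mask), stringsAsFactors = FALSE)
    eta <- b0 + b_mask[grid$mask] + u[grid$p]
    data.frame(participant_id = sprintf("P%03d", grid$p), mask = grid$mask,
               correct = runif(nrow(grid)) < plogis(eta),
               stringsAsFactors = FALSE)
  })
}

# marginal (population-averaged) log-odds contrast implied by a
# random-intercept logistic model, by Gauss-Hermite integration
marginal_logodds <- function(b0, b_eff, b_ref = 0, u_sd = 0.8, n_nodes = 60) {
  gh <- pracma_gh(n_nodes)
  pmarg <- function(b) sum(gh$w * plogis(b0 + b + sqrt(2) * u_sd * gh$x)) / sqrt(pi)
  qlogis(pmarg(b_eff)) - qlogis(pmarg(b_ref))
}

# Gauss-Hermite nodes via eigen-decomposition of the Jacobi matrix
pracma_gh <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# joint binned L1 distance between simulated (boundary, rt) frequencies and
# the WFPT density, with model bin masses computed by trapezoid integration
# on a fine grid (coarse midpoint evaluation misstates fast-regime bins)
binned_l1 <- function(sim, params, tmax = 8, width = 0.1, grid_step = 0.002) {
  br <- seq(0, tmax, by = width)
  tt <- seq(0, tmax, by = grid_step)
  l1 <- 0
  for (b in c(TRUE, FALSE)) {
    d <- maskddm::wfpt_density(tt, ifelse(b, "upper", "lower"), params)
    cum <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * grid_step))
    pmod <- diff(cum[match(round(br, 10), round(tt, 10))])
    sel <- sim$upper == b & sim$rt < tmax
    h <- hist(sim$rt[sel], breaks = br, plot = FALSE)
    l1 <- l1 + sum(abs(h$counts / nrow(sim) - pmod))
  }
  l1
}

# deterministic tiny trial table covering the full 6 x 6 crossing
full_crossing_trials <- function() {
  g <- expand.grid(expression = maskddm::EMOTIONS,
                   rated_emotion = maskddm::EMOTIONS,
                   stringsAsFactors = FALSE)
  g
}
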