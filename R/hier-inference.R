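#' Specify a hierarchical drift-diffusion model
#'
#' Cell-means drift design: one drift-rate coefficient per mask condition
#' (pairwise contrasts are computed on posterior draws), a participant random
#' intercept on drift with a group SD, and shared boundary separation,
#' starting point, non-decision time and drift variability estimated once
#' across mask conditions. The boundary variant indexes boundary separation by
#' mask while retaining drift-by-mask as a covariate — the follow-up used to
#' check that drift effects are not boundary effects in disguise.
#'
#' Priors are weakly informative and fully exposed: normal(0, 2^2) on drift
#' coefficients; half-normal(0, 1) on the intercept SD; truncated normals on
#' `a`, `z`, `t`; half-normal on `sv`.
#'
#' @param cells mask cells the drift design expects; `NULL` uses the masks
#'   present in the data. A listed cell with no trials is an error.
#' @param boundary_by_mask estimate one boundary separation per mask
#'   (follow-up model) instead of a shared one.
#' @param estimate_sv estimate inter-trial drift variability (analytic
#'   marginal); if `FALSE`, `sv` is fixed at `sv_fixed`.
#' @param sv_fixed,sz,st fixed values for variabilities not estimated
#'   (seconds for `st`).
#' @param priors named list overriding any of: `v_mean`, `v_sd`,
#'   `u_sd_scale`, `a_mean`, `a_sd`, `z_mean`, `z_sd`, `t_mean`, `t_sd`,
#'   `sv_scale`.
#' @param rel_tol WFPT series truncation tolerance.
#' @param prior_only build a model with zero trials that samples the prior
#'   (test mode).
#' @return an object of class `ddm_model_spec`.
#' @export
ddm_model_spec <- function(cells = NULL, boundary_by_mask = FALSE,
                           estimate_sv = TRUE, sv_fixed = 0, sz = 0, st = 0,
                           priors = list(), rel_tol = 1e-6,
                           prior_only = FALSE) {
  default_priors <- list(v_mean = 0, v_sd = 2, u_sd_scale = 1,
                         a_mean = 1.5, a_sd = 1, z_mean = 0.5, z_sd = 0.25,
                         t_mean = 0.3, t_sd = 0.25, sv_scale = 2)
  unknown <- setdiff(names(priors), names(default_priors))
  if (length(unknown) > 0) stop("unknown prior setting(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  default_priors[names(priors)] <- priors
  structure(list(cells = cells, boundary_by_mask = boundary_by_mask,
                 estimate_sv = estimate_sv, sv_fixed = sv_fixed,
                 sz = sz, st = st, priors = default_priors,
                 rel_tol = rel_tol, prior_only = prior_only),
            class = "ddm_model_spec")
}

#' Build a hierarchical DDM from a preprocessed trial table
#'
#' Maps every trial to exactly one drift cell and one participant, converts
#' response times to seconds, and assembles the log-posterior (WFPT
#' log-likelihood plus prior log-density). Accuracy coding throughout: the
#' upper boundary is the correct response, so `correct` determines the
#' absorbing boundary.
#'
#' @param trials preprocessed trial table with columns `participant_id`,
#'   `mask`, `correct`, `rt_ms` (empty table allowed only for prior-only
#'   specs).
#' @param spec a [ddm_model_spec()].
#' @return an object of class `ddm_model` with a `log_posterior(state)`
#'   callable and the documented parameter vector.
#' @export
build_model <- function(trials, spec = ddm_model_spec()) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  if (nrow(trials) == 0 && !spec$prior_only) {
    stop("no trials supplied; use a prior_only spec for prior sampling", call. = FALSE)
  }
  if (nrow(trials) > 0) {
    assert_columns(trials, c("participant_id", "mask", "correct", "rt_ms"))
    cells <- spec$cells %||% intersect(MASKS, unique(as.character(trials$mask)))
    empty <- setdiff(cells, unique(as.character(trials$mask)))
    if (length(empty) > 0) {
      stop("drift cell(s) with no trials: ", paste(empty, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(unique(as.character(trials$mask)), cells)
    if (length(extra) > 0) {
      stop("trials present for unlisted cell(s): ", paste(extra, collapse = ", "), call. = FALSE)
    }
    pids <- sort(unique(as.character(trials$participant_id)))
    data <- list(
      rt = trials$rt_ms / 1000,
      upper = as.integer(as.logical(trials$correct)),
      mask_idx = match(as.character(trials$mask), cells),
      part_idx = match(as.character(trials$participant_id), pids),
      n = nrow(trials)
    )
    idx_mask <- lapply(seq_along(cells), function(m) which(data$mask_idx == m))
    idx_part <- lapply(seq_along(pids), function(i) which(data$part_idx == i))
  } else {
    cells <- spec$cells %||% MASKS
    pids <- character(0)
    data <- list(rt = numeric(0), upper = integer(0), mask_idx = integer(0),
                 part_idx = integer(0), n = 0L)
    idx_mask <- rep(list(integer(0)), length(cells))
    idx_part <- list()
  }
  model <- structure(list(
    data = data, cells = cells, pids = pids,
    idx_mask = idx_mask, idx_part = idx_part, spec = spec
  ), class = "ddm_model")
  model$log_posterior <- function(state) {
    ld <- model_trial_logdens(model, state)
    sum(ld) + model_log_prior(model, state)
  }
  model
}

#' @export
print.ddm_model <- function(x, ...) {
  cat("Hierarchical drift-diffusion model\n")
  cat(sprintf("  %d trials, %d participants, drift cells: %s\n",
              x$data$n, length(x$pids), paste(x$cells, collapse = ", ")))
  cat(sprintf("  boundary %s; sv %s; sz = %g, st = %g\n",
              if (x$spec$boundary_by_mask) "by mask" else "shared",
              if (x$spec$estimate_sv) "estimated" else sprintf("fixed at %g", x$spec$sv_fixed),
              x$spec$sz, x$spec$st))
  invisible(x)
}

# per-trial log densities under a parameter state (subset via idx)
model_trial_logdens <- function(model, state, idx = NULL) {
  d <- model$data
  if (d$n == 0) return(numeric(0))
  idx <- idx %||% seq_len(d$n)
  v_tr <- state$v[d$mask_idx[idx]] + state$u[d$part_idx[idx]]
  a_tr <- if (length(state$a) > 1) state$a[d$mask_idx[idx]] else state$a
  dens <- .wfpt_pdf_cpp(d$rt[idx], d$upper[idx], v_tr, a_tr, state$z,
                        state$t0, state$sv, model$spec$sz, model$spec$st,
                        model$spec$rel_tol, 10L)
  log(dens)
}

model_log_prior <- function(model, state) {
  pr <- model$spec$priors
  lp <- sum(dnorm(state$v, pr$v_mean, pr$v_sd, log = TRUE)) +
    dnorm(state$u_sd, 0, pr$u_sd_scale, log = TRUE) +
    sum(dnorm(state$a, pr$a_mean, pr$a_sd, log = TRUE)) +
    dnorm(state$z, pr$z_mean, pr$z_sd, log = TRUE) +
    dnorm(state$t0, pr$t_mean, pr$t_sd, log = TRUE)
  if (model$spec$estimate_sv) lp <- lp + dnorm(state$sv, 0, pr$sv_scale, log = TRUE)
  if (length(state$u) > 0) lp <- lp + sum(dnorm(state$u, 0, state$u_sd, log = TRUE))
  if (state$u_sd <= 0 || any(state$a <= 0) || state$z <= 0 || state$z >= 1 ||
      state$t0 < 0 || state$sv < 0) lp <- -Inf
  lp
}

# EZ-style moment initialisation: accuracy + RT mean/variance give starting
# values for v, a, t that put the chain near the posterior mode.
ez_init <- function(rt, upper) {
  pc <- min(max(mean(upper), 0.02), 0.98)
  if (abs(pc - 0.5) < 1e-3) pc <- 0.51
  ok <- upper == 1
  vrt <- if (sum(ok) >= 3) var(rt[ok]) else var(rt)
  if (!is.finite(vrt) || vrt <= 1e-4) vrt <- 1e-2
  mrt <- if (any(ok)) mean(rt[ok]) else mean(rt)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * abs(x)^0.25
  v <- min(max(v, -4), 4)
  a <- min(max(L / v, 0.5), 3.5)
  y <- -v * a
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  t0 <- mrt - mdt
  list(v = v, a = a, t0 = t0)
}

init_state <- function(model, init = NULL) {
  d <- model$data
  K <- length(model$cells)
  spec <- model$spec
  if (d$n > 0) {
    base <- ez_init(d$rt, d$upper)
    v <- vapply(seq_len(K), function(m) {
      idx <- model$idx_mask[[m]]
      ez_init(d$rt[idx], d$upper[idx])$v
    }, numeric(1))
    t0 <- min(max(base$t0, 0.05), 0.9 * min(d$rt))
    a <- base$a
  } else {
    v <- rep(spec$priors$v_mean, K)
    a <- spec$priors$a_mean
    t0 <- spec$priors$t_mean
  }
  state <- list(
    v = v,
    u = rep(0, length(model$pids)),
    u_sd = 0.3,
    a = if (spec$boundary_by_mask) rep(a, K) else a,
    z = 0.5,
    t0 = t0,
    sv = if (spec$estimate_sv) 0.2 else spec$sv_fixed
  )
  if (!is.null(init)) state[names(init)] <- init
  state
}

#' Draw posterior samples by adaptive Metropolis-within-Gibbs
#'
#' Single-chain random-walk sampling over parameter blocks (drift
#' coefficients, participant intercepts, intercept SD, shared parameters),
#' with proposal scales tuned during burn-in toward 20-50% acceptance and
#' frozen afterwards. The default protocol draws 5000 samples and discards
#' the initial 200 as burn-in, retaining 4800. Positive parameters are
#' proposed on the log scale and the starting point on the logit scale, with
#' the matching Jacobian terms in the acceptance ratio.
#'
#' @param model a [build_model()] object.
#' @param n_samples total MCMC draws (including burn-in).
#' @param burn_in initial draws discarded.
#' @param seed integer seed; identical seeds give identical draws.
#' @param init optional named list of starting values overriding the
#'   moment-based initialisation.
#' @param n_chains number of chains (diagnostic mode; draws from all chains
#'   are pooled after per-chain burn-in, protocol runs use 1).
#' @return an object of class `ddm_fit`: retained `draws` (matrix with named
#'   columns `v_<mask>`, `a` or `a_<mask>`, `z`, `t0`, `sv`, `u_sd`,
#'   `u[<pid>]`), acceptance rates, and split-chain convergence diagnostics
#'   (split R-hat, effective sample size) for the structural parameters.
#' @export
sample_posterior <- function(model, n_samples = 5000, burn_in = 200,
                             seed = 1L, init = NULL, n_chains = 1L) {
  stopifnot(inherits(model, "ddm_model"), burn_in < n_samples)
  chains <- lapply(seq_len(n_chains), function(ch) {
    run_chain(model, n_samples, burn_in, seed + (ch - 1L) * 1000L, init)
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  key <- grep("^u\\[", colnames(draws), invert = TRUE, value = TRUE)
  diag <- data.frame(
    parameter = key,
    rhat = vapply(key, function(p) split_rhat(draws[, p]), numeric(1)),
    ess = vapply(key, function(p) ess_draws(draws[, p]), numeric(1)),
    row.names = NULL
  )
  structure(list(draws = draws, n_samples = n_samples, burn_in = burn_in,
                 seed = seed, cells = model$cells, pids = model$pids,
                 acceptance = chains[[1]]$acceptance, diagnostics = diag,
                 spec = model$spec),
            class = "ddm_fit")
}

run_chain <- function(model, n_samples, burn_in, seed, init) {
  set.seed(seed)
  d <- model$data
  spec <- model$spec
  pr <- spec$priors
  K <- length(model$cells)
  n_p <- length(model$pids)
  state <- init_state(model, init)

  # ensure a finite starting log-likelihood (shrink t0 / temper drift if not)
  if (d$n > 0) {
    for (try in 1:10) {
      ld <- model_trial_logdens(model, state)
      if (all(is.finite(ld))) break
      state$t0 <- state$t0 * 0.6
      state$v <- state$v * 0.8
      state$a <- pmin(pmax(state$a, 0.8), 2.5)
      if (try == 10) stop("could not find a finite log-posterior at initialization", call. = FALSE)
    }
  } else ld <- numeric(0)

  n_a <- length(state$a)
  par_names <- c(paste0("v_", model$cells),
                 if (n_a > 1) paste0("a_", model$cells) else "a",
                 "z", "t0", "sv", "u_sd",
                 if (n_p > 0) paste0("u[", model$pids, "]"))
  draws <- matrix(NA_real_, n_samples, length(par_names),
                  dimnames = list(NULL, par_names))

  # proposal scales, roughly 1/sqrt(information) to start
  n_m <- vapply(model$idx_mask, length, integer(1))
  n_i <- vapply(model$idx_part, length, integer(1))
  ps <- list(v = 2.5 / sqrt(n_m + 10), u = 2.5 / sqrt(n_i + 10),
             a = rep(1.5 / sqrt(d$n + 10), n_a), z = 2 / sqrt(d$n + 10),
             t0 = 1 / sqrt(d$n + 10), sv = 6 / sqrt(d$n + 10),
             u_sd = 0.6 / sqrt(n_p + 2))
  acc <- rapply(ps, function(x) x * 0, how = "replace")
  att <- acc
  batch <- 0L

  lp_prior_v <- function(x) dnorm(x, pr$v_mean, pr$v_sd, log = TRUE)

  mh_subset <- function(idx, dens_fun, la_prior) {
    # generic accept step for a parameter touching trials `idx`
    if (d$n > 0 && length(idx) > 0) {
      dn <- dens_fun(idx)
      la <- sum(dn) - sum(ld[idx]) + la_prior
    } else {
      dn <- NULL
      la <- la_prior
    }
    ok <- is.finite(la) && log(runif(1)) < la
    list(ok = ok, dn = dn)
  }

  for (it in seq_len(n_samples)) {
    # --- drift coefficients, one per mask cell
    for (m in seq_len(K)) {
      idx <- model$idx_mask[[m]]
      prop <- state$v[m] + rnorm(1, 0, ps$v[m])
      res <- mh_subset(idx, function(ix) {
        st2 <- state; st2$v[m] <- prop
        model_trial_logdens(model, st2, ix)
      }, lp_prior_v(prop) - lp_prior_v(state$v[m]))
      att$v[m] <- att$v[m] + 1
      if (res$ok) {
        state$v[m] <- prop
        if (!is.null(res$dn)) ld[idx] <- res$dn
        acc$v[m] <- acc$v[m] + 1
      }
    }
    # --- participant intercepts on drift
    for (i in seq_len(n_p)) {
      idx <- model$idx_part[[i]]
      prop <- state$u[i] + rnorm(1, 0, ps$u[i])
      res <- mh_subset(idx, function(ix) {
        st2 <- state; st2$u[i] <- prop
        model_trial_logdens(model, st2, ix)
      }, dnorm(prop, 0, state$u_sd, log = TRUE) -
         dnorm(state$u[i], 0, state$u_sd, log = TRUE))
      att$u[i] <- att$u[i] + 1
      if (res$ok) {
        state$u[i] <- prop
        if (!is.null(res$dn)) ld[idx] <- res$dn
        acc$u[i] <- acc$u[i] + 1
      }
    }
    # --- intercept SD (conjugate-free MH on the log scale; no data term)
    {
      prop <- state$u_sd * exp(rnorm(1, 0, ps$u_sd))
      la <- sum(dnorm(state$u, 0, prop, log = TRUE)) -
        sum(dnorm(state$u, 0, state$u_sd, log = TRUE)) +
        dnorm(prop, 0, pr$u_sd_scale, log = TRUE) -
        dnorm(state$u_sd, 0, pr$u_sd_scale, log = TRUE) +
        log(prop) - log(state$u_sd)
      att$u_sd <- att$u_sd + 1
      if (is.finite(la) && log(runif(1)) < la) {
        state$u_sd <- prop; acc$u_sd <- acc$u_sd + 1
      }
    }
    # --- boundary separation (shared or per mask)
    for (j in seq_len(n_a)) {
      idx <- if (n_a > 1) model$idx_mask[[j]] else seq_len(d$n)
      prop <- state$a[j] * exp(rnorm(1, 0, ps$a[j]))
      res <- mh_subset(idx, function(ix) {
        st2 <- state; st2$a[j] <- prop
        model_trial_logdens(model, st2, ix)
      }, dnorm(prop, pr$a_mean, pr$a_sd, log = TRUE) -
         dnorm(state$a[j], pr$a_mean, pr$a_sd, log = TRUE) +
         log(prop) - log(state$a[j]))
      att$a[j] <- att$a[j] + 1
      if (res$ok) {
        state$a[j] <- prop
        if (!is.null(res$dn)) ld[idx] <- res$dn
        acc$a[j] <- acc$a[j] + 1
      }
    }
    # --- starting point (logit scale)
    {
      lg <- qlogis(state$z) + rnorm(1, 0, ps$z)
      prop <- plogis(lg)
      res <- mh_subset(seq_len(d$n), function(ix) {
        st2 <- state; st2$z <- prop
        model_trial_logdens(model, st2, ix)
      }, dnorm(prop, pr$z_mean, pr$z_sd, log = TRUE) -
         dnorm(state$z, pr$z_mean, pr$z_sd, log = TRUE) +
         log(prop * (1 - prop)) - log(state$z * (1 - state$z)))
      att$z <- att$z + 1
      if (res$ok) {
        state$z <- prop
        if (!is.null(res$dn)) ld[seq_len(d$n)] <- res$dn
        acc$z <- acc$z + 1
      }
    }
    # --- non-decision time (log scale; zero density above min rt rejects)
    {
      prop <- state$t0 * exp(rnorm(1, 0, ps$t0))
      res <- mh_subset(seq_len(d$n), function(ix) {
        st2 <- state; st2$t0 <- prop
        model_trial_logdens(model, st2, ix)
      }, dnorm(prop, pr$t_mean, pr$t_sd, log = TRUE) -
         dnorm(state$t0, pr$t_mean, pr$t_sd, log = TRUE) +
         log(prop) - log(state$t0))
      att$t0 <- att$t0 + 1
      if (res$ok) {
        state$t0 <- prop
        if (!is.null(res$dn)) ld[seq_len(d$n)] <- res$dn
        acc$t0 <- acc$t0 + 1
      }
    }
    # --- drift variability (log scale, analytic marginal in the kernel)
    if (spec$estimate_sv) {
      prop <- state$sv * exp(rnorm(1, 0, ps$sv))
      res <- mh_subset(seq_len(d$n), function(ix) {
        st2 <- state; st2$sv <- prop
        model_trial_logdens(model, st2, ix)
      }, dnorm(prop, 0, pr$sv_scale, log = TRUE) -
         dnorm(state$sv, 0, pr$sv_scale, log = TRUE) +
         log(prop) - log(state$sv))
      att$sv <- att$sv + 1
      if (res$ok) {
        state$sv <- prop
        if (!is.null(res$dn)) ld[seq_len(d$n)] <- res$dn
        acc$sv <- acc$sv + 1
      }
    }

    draws[it, ] <- c(state$v, state$a, state$z, state$t0, state$sv,
                     state$u_sd, state$u)

    # --- proposal adaptation, burn-in only
    if (it %% 20 == 0 && it <= burn_in) {
      batch <- batch + 1L
      delta <- min(0.3, 1 / sqrt(batch))
      for (nm in names(ps)) {
        rate <- ifelse(att[[nm]] > 0, acc[[nm]] / att[[nm]], 0.4)
        ps[[nm]] <- ps[[nm]] * exp(ifelse(rate > 0.4, delta, -delta))
        acc[[nm]] <- acc[[nm]] * 0
        att[[nm]] <- att[[nm]] * 0
      }
    }
  }

  rate_of <- function(nm) if (all(att[[nm]] == 0)) NA_real_ else sum(acc[[nm]]) / sum(att[[nm]])
  list(draws = draws[(burn_in + 1):n_samples, , drop = FALSE],
       acceptance = vapply(names(ps), rate_of, numeric(1)))
}

# split-chain potential scale reduction on a single chain (first vs second half)
split_rhat <- function(x) {
  n <- length(x) %/% 2
  h <- list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  m <- vapply(h, mean, numeric(1))
  w <- mean(vapply(h, var, numeric(1)))
  b <- n * var(m)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# effective sample size from the autocorrelation function (initial positive
# sums truncated at the first non-positive lag)
ess_draws <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- as.numeric(acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf)[-1]
  s <- 0
  for (r in rho) { if (r <= 0) break; s <- s + r }
  max(1, n / (1 + 2 * s))
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical DDM fit: %d retained draws (of %d, burn-in %d), seed %d\n",
              nrow(x$draws), x$n_samples, x$burn_in, x$seed))
  print(summary(x))
  invisible(x)
}

#' @export
summary.ddm_fit <- function(object, ...) {
  key <- grep("^u\\[", colnames(object$draws), invert = TRUE, value = TRUE)
  d <- object$draws[, key, drop = FALSE]
  out <- data.frame(
    parameter = key,
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    ci_low = apply(d, 2, quantile, 0.025),
    ci_high = apply(d, 2, quantile, 0.975),
    row.names = NULL
  )
  merge(out, object$diagnostics, by = "parameter", sort = FALSE)
}

#' Posterior probability of a parameter contrast
#'
#' Evaluates the fraction of retained posterior draws satisfying a contrast
#' such as `"v_lower > v_none"`, `"v_lower > 0"` or `"v_lower < 0"` — the
#' Bayesian hypothesis tests used to compare drift (or boundary) coefficients
#' across mask conditions and against zero. Strict inequality; exact ties
#' contribute 1/2 so that `P(A > B) + P(A < B) = 1`.
#'
#' @param fit a `ddm_fit`, or a draws matrix with named columns.
#' @param contrast a string `"A > B"`, `"A < B"`, `"A > c"` or `"A < c"`
#'   where `A`, `B` are parameter names and `c` a number.
#' @return a list of class `hypothesis_test`: `label`, `probability`,
#'   `contrast` (parsed sides).
#' @examples
#' draws <- cbind(v_lower = rnorm(1000, 1), v_none = rnorm(1000, 1.5))
#' posterior_prob(draws, "v_lower > v_none")
#' @export
posterior_prob <- function(fit, contrast) {
  draws <- if (inherits(fit, "ddm_fit")) fit$draws else as.matrix(fit)
  m <- regmatches(contrast, regexec("^\\s*(\\S+)\\s*([<>])\\s*(\\S+)\\s*$", contrast))[[1]]
  if (length(m) != 4) stop("contrast must look like 'A > B', 'A > 0' or 'A < 0'", call. = FALSE)
  lhs_name <- m[2]; op <- m[3]; rhs_name <- m[4]
  get_side <- function(nm) {
    if (suppressWarnings(!is.na(as.numeric(nm)))) return(rep(as.numeric(nm), nrow(draws)))
    if (!nm %in% colnames(draws)) {
      stop(sprintf("unknown parameter '%s'; available: %s", nm,
                   paste(head(colnames(draws), 12), collapse = ", ")), call. = FALSE)
    }
    draws[, nm]
  }
  a <- get_side(lhs_name); b <- get_side(rhs_name)
  pgt <- mean((a > b) + 0.5 * (a == b))
  p <- if (op == ">") pgt else 1 - pgt
  structure(list(label = sprintf("P(%s %s %s)", lhs_name, op, rhs_name),
                 probability = p,
                 contrast = list(lhs = lhs_name, op = op, rhs = rhs_name)),
            class = "hypothesis_test")
}

#' @export
print.hypothesis_test <- function(x, ...) {
  cat(sprintf("%s = %.4f\n", x$label, x$probability))
  invisible(x)
}

#' Compare a contrast of coefficient differences across two fits
#'
#' Probability that the mask effect in one study exceeds the same effect in
#' another, e.g. P(lower2 - none2 > lower1 - none1), treating the two
#' posteriors as independent and pairing draws. Mismatched draw counts are
#' handled by resampling both chains with replacement to the larger count
#' (seeded, documented); exact ties contribute 1/2.
#'
#' @param fit1,fit2 `ddm_fit` objects (or draws matrices); `fit2` is the
#'   later study.
#' @param coef length-2 character vector `c(effect, reference)`; the contrast
#'   compared is `effect - reference` in each fit.
#' @param seed seed for the pairing resample.
#' @return a `hypothesis_test` with the cross-study probability.
#' @export
compare_fits <- function(fit1, fit2, coef = c("v_lower", "v_none"), seed = 1L) {
  stopifnot(length(coef) == 2)
  d1 <- if (inherits(fit1, "ddm_fit")) fit1$draws else as.matrix(fit1)
  d2 <- if (inherits(fit2, "ddm_fit")) fit2$draws else as.matrix(fit2)
  for (nm in coef) {
    if (!nm %in% colnames(d1) || !nm %in% colnames(d2)) {
      stop("both fits must expose coefficient '", nm, "'", call. = FALSE)
    }
  }
  e1 <- d1[, coef[1]] - d1[, coef[2]]
  e2 <- d2[, coef[1]] - d2[, coef[2]]
  if (length(e1) != length(e2)) {
    n <- max(length(e1), length(e2))
    with_seed(seed, {
      e1 <- e1[sample.int(length(e1), n, replace = TRUE)]
      e2 <- e2[sample.int(length(e2), n, replace = TRUE)]
    })
  }
  p <- mean((e2 > e1) + 0.5 * (e2 == e1))
  structure(list(
    label = sprintf("P(%s2 - %s2 > %s1 - %s1)", coef[1], coef[2], coef[1], coef[2]),
    probability = p,
    contrast = list(effect = coef[1], reference = coef[2])
  ), class = "hypothesis_test")
}
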