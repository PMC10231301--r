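#' Mixed binomial logistic regression of emotion ratings on mask condition
#'
#' Two-tailed binomial logistic model of a binary trial outcome on mask
#' condition with a participant random intercept (Laplace-approximate
#' likelihood via lme4). With `random = NULL` (or a single participant) the
#' model reduces to an ordinary logistic regression, in which case the
#' coefficient on a 2x2 table equals the closed-form log odds ratio. Reference
#' level is "none"; reported rows follow the standard contrast set
#' lower > none, upper > none, lower > upper (whichever levels are present).
#'
#' @param trials trial table.
#' @param outcome name of the logical/0-1 outcome column (e.g. `correct`, or
#'   a "rated yes" indicator).
#' @param predictor name of the mask-condition column.
#' @param random name of the clustering column for the random intercept, or
#'   `NULL` for a plain logistic fit.
#' @param ref reference mask level.
#' @return a `regression_result` data frame: one row per contrast with `term`,
#'   `b`, `ci_low`, `ci_high` (Wald), `statistic` (z), `p`.
#' @export
fit_logistic_mixed <- function(trials, outcome = "correct", predictor = "mask",
                               random = "participant_id", ref = "none") {
  assert_columns(trials, c(outcome, predictor))
  y <- as.integer(as.logical(trials[[outcome]]))
  if (any(is.na(y))) stop("outcome must be binary with no missing values", call. = FALSE)
  lev <- intersect(MASKS, unique(as.character(trials[[predictor]])))
  if (length(lev) == 0) lev <- unique(as.character(trials[[predictor]]))
  if (length(lev) < 2) stop("need at least 2 mask levels, got: ", paste(lev, collapse = ", "), call. = FALSE)
  if (ref %in% lev) lev <- c(ref, setdiff(lev, ref))
  dat <- data.frame(.y = y, .x = factor(as.character(trials[[predictor]]), levels = lev))
  empty <- lev[!lev %in% as.character(dat$.x)]
  if (length(empty) > 0) stop("empty mask level(s): ", paste(empty, collapse = ", "), call. = FALSE)

  use_mixed <- !is.null(random) && length(unique(trials[[random]])) > 1
  if (use_mixed) {
    dat$.g <- factor(as.character(trials[[random]]))
    fit <- lme4::glmer(.y ~ .x + (1 | .g), data = dat, family = binomial,
                       control = lme4::glmerControl(calc.derivs = FALSE,
                                                    check.conv.singular = "ignore"))
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  } else {
    fit <- glm(.y ~ .x, data = dat, family = binomial)
    if (any(abs(coef(fit)) > 15)) {
      stop("complete (or quasi-complete) separation: a mask level has all-0 or all-1 outcomes",
           call. = FALSE)
    }
    beta <- coef(fit)
    V <- vcov(fit)
  }
  contrast_table(beta, V, lev, stat_name = "z")
}

# assemble the pairwise mask contrasts from a fitted coefficient vector
contrast_table <- function(beta, V, lev, stat_name = "z") {
  ref <- lev[1]
  others <- lev[-1]
  rows <- list()
  cvec <- function(term) {
    v <- setNames(numeric(length(beta)), names(beta))
    v[term] <- 1
    v
  }
  for (o in others) {
    rows[[paste0(o, " > ", ref)]] <- cvec(paste0(".x", o))
  }
  if (length(others) == 2) {
    v <- cvec(paste0(".x", others[1]))
    v[paste0(".x", others[2])] <- -1
    rows[[paste0(others[1], " > ", others[2])]] <- v
  }
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    cv <- rows[[nm]]
    b <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    stat <- b / se
    data.frame(term = nm, b = b, ci_low = b - 1.96 * se, ci_high = b + 1.96 * se,
               statistic = stat, p = 2 * pnorm(-abs(stat)),
               stringsAsFactors = FALSE)
  }))
  names(out)[names(out) == "statistic"] <- "statistic"
  attr(out, "stat_name") <- stat_name
  class(out) <- c("regression_result", class(out))
  rownames(out) <- NULL
  out
}

#' Mixed linear regression of log response times on mask x accuracy
#'
#' Linear mixed model of log-transformed RTs on the mask-by-rating-accuracy
#' interaction with a participant random intercept, reported in the row
#' structure of the study's RT tables: the interaction term, the simple
#' effect among correct ratings ("Correct: lower > none") and among incorrect
#' ratings ("Incorrect: lower > none"). Test statistics are coefficient /
#' standard error (t), with normal-approximation p-values.
#'
#' @param trials trial table; only two mask levels should be present (filter
#'   to e.g. lower + none before calling).
#' @param log_rt name of the log-RT column (see [transform_rt()]).
#' @param accuracy name of the logical correctness column.
#' @inheritParams fit_logistic_mixed
#' @return a `regression_result` data frame with the three rows above.
#' @export
fit_linear_mixed <- function(trials, log_rt = "log_rt", predictor = "mask",
                             accuracy = "correct", random = "participant_id",
                             ref = "none") {
  assert_columns(trials, c(log_rt, predictor, accuracy))
  lev <- intersect(MASKS, unique(as.character(trials[[predictor]])))
  lev <- c(ref, setdiff(lev, ref))
  if (length(lev) != 2) {
    stop("fit_linear_mixed expects exactly 2 mask levels (got ",
         paste(lev, collapse = ", "), "); filter the trials first", call. = FALSE)
  }
  eff <- lev[2]
  acc <- as.logical(trials[[accuracy]])
  if (length(unique(acc)) < 2) {
    stop("both accuracy levels must be present to estimate the interaction", call. = FALSE)
  }
  dat <- data.frame(
    .y = trials[[log_rt]],
    .x = factor(as.character(trials[[predictor]]), levels = lev),
    # reference level "correct" so the .x coefficient is the correct-trials
    # simple effect
    .acc = factor(ifelse(acc, "correct", "incorrect"),
                  levels = c("correct", "incorrect"))
  )
  use_mixed <- !is.null(random) && length(unique(trials[[random]])) > 1
  if (use_mixed) {
    dat$.g <- factor(as.character(trials[[random]]))
    fit <- lme4::lmer(.y ~ .x * .acc + (1 | .g), data = dat,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  } else {
    fit <- stats::lm(.y ~ .x * .acc, data = dat)
    beta <- coef(fit)
    if (any(is.na(beta))) {
      stop("rank-deficient design; collinear term(s): ",
           paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
    }
    V <- vcov(fit)
  }
  xterm <- paste0(".x", eff)
  iterm <- paste0(xterm, ":.accincorrect")
  combo <- function(label, w) {
    if (!all(names(w) %in% names(beta))) {
      stop("rank-deficient design; missing term(s): ",
           paste(setdiff(names(w), names(beta)), collapse = ", "),
           call. = FALSE)
    }
    cv <- setNames(numeric(length(beta)), names(beta))
    cv[names(w)] <- w
    b <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    data.frame(term = label, b = b, ci_low = b - 1.96 * se,
               ci_high = b + 1.96 * se, statistic = b / se,
               p = 2 * pnorm(-abs(b / se)), stringsAsFactors = FALSE)
  }
  out <- rbind(
    combo("Face mask * rating", setNames(1, iterm)),
    combo(sprintf("Correct: %s > %s", eff, ref), setNames(1, xterm)),
    combo(sprintf("Incorrect: %s > %s", eff, ref), setNames(c(1, 1), c(xterm, iterm)))
  )
  attr(out, "stat_name") <- "t"
  class(out) <- c("regression_result", class(out))
  rownames(out) <- NULL
  out
}

#' Cluster-bootstrap confidence intervals for regression coefficients
#'
#' Percentile 95% CIs from refits on datasets resampled by participant (the
#' random-effect unit), 1000 iterations by default. `fit_fn` must be
#' deterministic given data and return a named numeric coefficient vector.
#'
#' @param fit_fn function(data) -> named numeric vector.
#' @param trials data to resample.
#' @param cluster name of the participant (cluster) column.
#' @param n_boot number of bootstrap iterations.
#' @param seed integer seed; identical seeds give identical CIs.
#' @param conf confidence level.
#' @return data frame with `term`, `b` (full-data estimate), `ci_low`,
#'   `ci_high`, plus attributes `n_boot`, `seed`, `n_failed` and the bootstrap
#'   draw matrix.
#' @export
bootstrap_ci <- function(fit_fn, trials, cluster = "participant_id",
                         n_boot = 1000, seed = 1L, conf = 0.95) {
  assert_columns(trials, cluster)
  point <- fit_fn(trials)
  ids <- unique(as.character(trials[[cluster]]))
  by_id <- split(seq_len(nrow(trials)), as.character(trials[[cluster]]))
  draws <- matrix(NA_real_, n_boot, length(point),
                  dimnames = list(NULL, names(point)))
  failures <- character(0)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- sample(ids, length(ids), replace = TRUE)
      idx <- unlist(by_id[take], use.names = FALSE)
      boot <- trials[idx, , drop = FALSE]
      # resampled clusters get fresh ids so duplicates stay distinct clusters
      boot[[cluster]] <- rep(seq_along(take),
                             times = vapply(by_id[take], length, integer(1)))
      est <- tryCatch(fit_fn(boot), error = function(e) {
        failures <<- c(failures, conditionMessage(e))
        NULL
      })
      if (!is.null(est)) draws[b, ] <- est[names(point)]
    }
  })
  n_failed <- sum(!stats::complete.cases(draws))
  if (n_failed > 0.05 * n_boot) {
    stop(sprintf("bootstrap failed in %d/%d refits (> 5%%); first errors: %s",
                 n_failed, n_boot,
                 paste(head(unique(failures), 3), collapse = " | ")),
         call. = FALSE)
  }
  alpha <- (1 - conf) / 2
  ok <- stats::complete.cases(draws)
  out <- data.frame(
    term = names(point),
    b = as.numeric(point),
    ci_low = apply(draws[ok, , drop = FALSE], 2, quantile, alpha, names = FALSE),
    ci_high = apply(draws[ok, , drop = FALSE], 2, quantile, 1 - alpha, names = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "n_failed") <- n_failed
  attr(out, "draws") <- draws
  out
}

#' Marginal (population-averaged) logistic mask contrasts
#'
#' Coefficient function for use with [bootstrap_ci()]: ordinary logistic
#' regression of the outcome on mask condition, returning the mask contrasts.
#' Clustering by participant is accounted for by the cluster bootstrap itself,
#' making this the population-averaged companion to [fit_logistic_mixed()].
#'
#' @inheritParams fit_logistic_mixed
#' @return named numeric vector of contrast estimates.
#' @export
logistic_contrast_fn <- function(outcome = "correct", predictor = "mask",
                                 ref = "none") {
  function(trials) {
    res <- fit_logistic_mixed(trials, outcome = outcome, predictor = predictor,
                              random = NULL, ref = ref)
    setNames(res$b, res$term)
  }
}

#' Test accuracy against chance per mask condition
#'
#' Two-tailed test of whether the probability of a correct rating differs
#' from 0.5, via the intercept of a participant-random-intercept logistic
#' model fitted within each mask condition.
#'
#' @param trials trial table with `correct`, `mask` and participant columns.
#' @inheritParams fit_logistic_mixed
#' @return data frame per condition: intercept `b` (log-odds vs chance), `z`,
#'   `p`, `above_chance` (significantly above 0.5), `accuracy` (raw mean).
#' @export
chance_test <- function(trials, predictor = "mask", outcome = "correct",
                        random = "participant_id") {
  assert_columns(trials, c(predictor, outcome))
  conds <- intersect(MASKS, unique(as.character(trials[[predictor]])))
  out <- lapply(conds, function(cond) {
    sub <- trials[trials[[predictor]] == cond, , drop = FALSE]
    if (nrow(sub) < 2) stop("condition '", cond, "' has fewer than 2 trials", call. = FALSE)
    y <- as.integer(as.logical(sub[[outcome]]))
    # all-0/all-1 outcomes degenerate to the Agresti-style adjusted estimate
    use_mixed <- !is.null(random) && length(unique(sub[[random]])) > 1 &&
      var(y) > 0
    if (use_mixed) {
      dat <- data.frame(.y = y, .g = factor(as.character(sub[[random]])))
      fit <- lme4::glmer(.y ~ 1 + (1 | .g), data = dat, family = binomial,
                         control = lme4::glmerControl(calc.derivs = FALSE,
                                                      check.conv.singular = "ignore"))
      b <- lme4::fixef(fit)[1]
      se <- sqrt(as.matrix(vcov(fit))[1, 1])
    } else {
      ybar <- min(max(mean(y), 1e-6), 1 - 1e-6)
      b <- qlogis(ybar)
      se <- sqrt(1 / (sum(y) + 0.5) + 1 / (sum(1 - y) + 0.5))
    }
    z <- b / se
    data.frame(mask = cond, b = as.numeric(b), z = as.numeric(z),
               p = 2 * pnorm(-abs(z)),
               above_chance = (2 * pnorm(-abs(z)) < 0.05) & b > 0,
               accuracy = mean(y), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Conditional analysis cascade over incongruent pairings (false positives)
#'
#' For each of the 30 incongruent expression-by-rating pairings: always test
#' whether masks influenced the (misidentification) ratings; where that effect
#' is significant, test whether masks influenced response times; where the RT
#' effect is significant too, estimate mask effects on drift rates for that
#' pairing. The per-pairing decision trail is returned. Significance gate:
#' two-tailed p < `alpha` on any vs-none mask contrast, uncorrected by
#' default; set `p_adjust = "BH"` for a Benjamini-Hochberg-corrected gate at
#' stage 1.
#'
#' @param trials trial table including incongruent trials (with `pairing`,
#'   `response`, `mask`, `rt_ms`, `correct`, `participant_id` columns; see
#'   [classify_congruency()]).
#' @param alpha gate level.
#' @param p_adjust `"none"` (default, matching uncorrected reporting) or a
#'   method accepted by [stats::p.adjust()].
#' @param ddm_args list of arguments for the stage-3 drift fit
#'   (`n_samples`, `burn_in`, `seed`); kept small by default since 30
#'   pairings may reach it.
#' @return list with `trail` (data frame: pairing, stage reached, gate
#'   p-values) and `results` (per-pairing list of stage outputs).
#' @export
fp_cascade <- function(trials, alpha = 0.05, p_adjust = "none",
                       ddm_args = list(n_samples = 800, burn_in = 200, seed = 1L)) {
  assert_columns(trials, c("pairing", "expression", "rated_emotion", "mask",
                           "response", "correct", "rt_ms", "participant_id"))
  inc <- trials[trials$expression != trials$rated_emotion, , drop = FALSE]
  pairings <- as.vector(outer(EMOTIONS, EMOTIONS, paste, sep = ":"))
  pairings <- pairings[vapply(strsplit(pairings, ":"), function(x) x[1] != x[2], logical(1))]
  missing <- setdiff(pairings, unique(inc$pairing))
  if (length(missing) > 0) {
    stop("incongruent trials missing for pairing(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  results <- list()
  trail <- vector("list", length(pairings))
  stage1_p <- rep(NA_real_, length(pairings))
  stage1 <- vector("list", length(pairings))
  for (k in seq_along(pairings)) {
    sub <- inc[inc$pairing == pairings[k], , drop = FALSE]
    sub$rated_yes <- sub$response == "yes"
    r <- fit_logistic_mixed(sub, outcome = "rated_yes")
    stage1[[k]] <- r
    vs_none <- grepl("> none$", r$term)
    stage1_p[k] <- min(r$p[vs_none])
  }
  gate1 <- stats::p.adjust(stage1_p, method = p_adjust) < alpha
  for (k in seq_along(pairings)) {
    pairing <- pairings[k]
    sub <- inc[inc$pairing == pairing, , drop = FALSE]
    res <- list(ratings = stage1[[k]])
    stage <- 1L
    rt_p <- NA_real_
    if (gate1[k]) {
      stage <- 2L
      sub$log_rt <- transform_rt(sub$rt_ms)
      # which mask showed the rating effect drives the RT comparison
      vs_none <- stage1[[k]][grepl("> none$", stage1[[k]]$term), ]
      eff_mask <- sub("^(\\w+) > none$", "\\1", vs_none$term[which.min(vs_none$p)])
      sub2 <- sub[sub$mask %in% c(eff_mask, "none"), , drop = FALSE]
      rt_res <- tryCatch(fit_linear_mixed(sub2), error = function(e) NULL)
      res$rts <- rt_res
      if (!is.null(rt_res)) {
        rt_p <- min(rt_res$p[grepl("^Correct|^Incorrect", rt_res$term)])
        if (rt_p < alpha) {
          stage <- 3L
          mod <- build_model(sub, ddm_model_spec())
          fit <- do.call(sample_posterior,
                         c(list(model = mod), ddm_args))
          res$drift <- summary(fit)
          res$drift_tests <- lapply(
            sprintf("v_%s > v_none", setdiff(mod$cells, "none")),
            function(ct) posterior_prob(fit, ct))
        }
      }
    }
    results[[pairing]] <- res
    trail[[k]] <- data.frame(pairing = pairing, stage_reached = stage,
                             rating_p = stage1_p[k], rt_p = rt_p,
                             stringsAsFactors = FALSE)
  }
  list(trail = do.call(rbind, trail), results = results)
}

#' @export
print.regression_result <- function(x, ...) {
  stat <- attr(x, "stat_name") %||% "z"
  cat(sprintf("Regression contrasts (b [95%% CI], %s, p)\n", stat))
  df <- as.data.frame(x)
  df$b <- sprintf("% .3f", df$b)
  df$CI <- sprintf("[% .3f, % .3f]", x$ci_low, x$ci_high)
  df[[stat]] <- sprintf("% .2f", x$statistic)
  df$p <- format.pval(x$p, digits = 3)
  print(df[, c("term", "b", "CI", stat, "p")], row.names = FALSE)
  invisible(x)
}
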