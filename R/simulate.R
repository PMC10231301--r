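#' Ground truth for a synthetic masked-expression study
#'
#' Encodes the generative structure the inference machinery must recover:
#' a drift-rate coefficient for every (emotion x mask) cell of congruent
#' trials, a participant random-intercept SD on drift, shared diffusion
#' parameters, and the contamination processes (fast guesses, attention-check
#' failures).
#'
#' Default drift cells follow the study conditions the task emulates: evidence
#' accumulates fastest for unmasked faces; lower masks slow accumulation for
#' mouth-diagnostic emotions (disgust, happiness, sadness, surprise) and upper
#' masks for eye-diagnostic emotions (anger, fear), with deficits on the order
#' of 0.4-0.7 evidence-units/s against an unmasked drift near 1.8 and a
#' boundary separation near 1.77 — the scale of published hierarchical DDM
#' fits of this task family.
#'
#' @param drift 6 x 3 numeric matrix (rows = emotions, columns = masks) of
#'   congruent-trial drift rates toward the correct "yes"; dimnames are
#'   enforced. A single number is recycled to all cells.
#' @param incongruent_drift drift toward the correct "no" on incongruent
#'   trials (scalar).
#' @param intercept_sd SD of the participant random intercept on drift.
#' @param a,z,t,sv,sz,st shared diffusion parameters (seconds for `t`, `st`).
#' @param contamination_rate probability a trial is replaced by a fast guess
#'   (uniform RT below 100 ms, random response), in `[0, 1)`.
#' @param attention_fail_rate probability a participant fails the attention
#'   checks, in `[0, 1)`.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(drift = NULL, incongruent_drift = 1.5,
                         intercept_sd = 0.3, a = 1.77, z = 0.5, t = 0.35,
                         sv = 0.2, sz = 0, st = 0,
                         contamination_rate = 0.02,
                         attention_fail_rate = 0.1) {
  if (is.null(drift)) {
    none <- c(anger = 1.8, disgust = 1.8, fear = 1.7, happiness = 2.2,
              sadness = 1.7, surprise = 2.0)
    lower_def <- c(anger = 0.05, disgust = 0.7, fear = 0.25, happiness = 0.45,
                   sadness = 0.55, surprise = 0.5)
    upper_def <- c(anger = 0.65, disgust = 0.1, fear = 0.6, happiness = 0.15,
                   sadness = 0.25, surprise = 0.4)
    drift <- cbind(lower = none - lower_def, upper = none - upper_def,
                   none = none)
  }
  if (length(drift) == 1) {
    drift <- matrix(drift, 6, 3, dimnames = list(EMOTIONS, MASKS))
  }
  drift <- as.matrix(drift)
  if (!all(dim(drift) == c(6, 3))) stop("drift must be a 6 x 3 matrix (emotions x masks)", call. = FALSE)
  if (is.null(dimnames(drift))) dimnames(drift) <- list(EMOTIONS, MASKS)
  drift <- drift[EMOTIONS, MASKS]
  if (!all(is.finite(drift))) stop("all drift cells must be finite", call. = FALSE)
  if (contamination_rate < 0 || contamination_rate >= 1)
    stop("contamination_rate must lie in [0, 1)", call. = FALSE)
  if (attention_fail_rate < 0 || attention_fail_rate >= 1)
    stop("attention_fail_rate must lie in [0, 1)", call. = FALSE)
  # shared parameters must form a valid bundle
  validate_ddm_params(ddm_params(0, a, z, t, sv, sz, st))
  structure(list(drift = drift, incongruent_drift = incongruent_drift,
                 intercept_sd = intercept_sd, a = a, z = z, t = t, sv = sv,
                 sz = sz, st = st, contamination_rate = contamination_rate,
                 attention_fail_rate = attention_fail_rate),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic-study ground truth\n")
  cat(sprintf("  shared: a = %.3g, z = %.3g, t = %.3g s, sv = %.3g, sz = %.3g, st = %.3g\n",
              x$a, x$z, x$t, x$sv, x$sz, x$st))
  cat(sprintf("  participant intercept SD on drift: %.3g\n", x$intercept_sd))
  cat(sprintf("  contamination %.3g, attention-fail %.3g\n",
              x$contamination_rate, x$attention_fail_rate))
  cat("  congruent drift cells (emotion x mask):\n")
  print(round(x$drift, 3))
  invisible(x)
}

#' Simulate first-passage trials from the diffusion process
#'
#' Small-step Euler-Maruyama simulation (default dt = 1e-4 s) of the Wiener
#' process between absorbing boundaries, with inter-trial variability draws
#' (drift normal, start point and non-decision time uniform). Paths that
#' exceed `max_t` without absorption are resampled and counted.
#'
#' @param params a [ddm_params()] object; `params$v` may be a per-trial
#'   vector.
#' @param n number of trials (ignored when `params$v` is a vector).
#' @param seed integer seed for the simulator's own RNG stream.
#' @param dt Euler-Maruyama step in seconds.
#' @param max_t path-time cap in seconds before resampling.
#' @return data frame with `upper` (logical: upper/correct boundary),
#'   `rt` (seconds, including non-decision time) and `decision_time`
#'   (seconds); attribute `n_resampled` counts capped paths.
#' @examples
#' p <- ddm_params(v = 1, a = 2, z = 0.5, t = 0)
#' sim <- simulate_trial(p, n = 500, seed = 7)
#' mean(sim$upper)   # near (1 - exp(-2)) / (1 - exp(-4))
#' @export
simulate_trial <- function(params, n = 1L, seed = 1L, dt = 1e-4, max_t = 30) {
  validate_ddm_params(params)
  v <- if (length(params$v) > 1) as.numeric(params$v) else rep(params$v, n)
  res <- .ddm_sim_cpp(v, params$a, params$z, params$t, params$sv, params$sz,
                      params$st, dt, max_t, as.double(seed))
  out <- data.frame(upper = res$upper == 1L, rt = res$rt)
  out$decision_time <- out$rt - params$t  # mean shift only; per-trial t draws absorbed in rt
  attr(out, "n_resampled") <- res$n_resampled
  if (res$n_resampled > 0) {
    message(sprintf("simulate_trial: %d path(s) exceeded max_t = %g s and were resampled",
                    as.integer(res$n_resampled), max_t))
  }
  out
}

#' Simulate a complete study dataset
#'
#' Walks the round schedule: on each round a participant views every stimulus
#' of the scheduled block in random order and judges whether it shows the
#' scheduled emotion. Choices and response times come from the diffusion
#' process under accuracy coding (upper boundary = correct), with trial drift
#' = ground-truth cell + participant intercept. Congruent trials drift toward
#' the correct "yes", incongruent trials toward the correct "no". Contaminant
#' trials are injected as uniform fast guesses below 100 ms at the stated
#' rate, and attention-check failures are flagged per participant.
#'
#' @param design output of [generate_blocks()].
#' @param schedule output of [schedule_rounds()].
#' @param truth a [ground_truth()] object.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param dt Euler-Maruyama step (seconds).
#' @return trial table: one row per scheduled stimulus with columns
#'   `participant_id`, `round_index`, `rated_emotion`, `actor_id`,
#'   `expression`, `mask`, `block_index`, `congruent`, `pairing`, `response`
#'   ("yes"/"no"), `correct`, `rt_ms`, `contaminant`, `attention_failed`.
#' @export
simulate_study <- function(design, schedule, truth, seed = 1L, dt = 1e-4) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_columns(design, c("actor_id", "expression", "mask", "block_index"),
                 "design")
  assert_columns(schedule,
                 c("participant_id", "round_index", "rated_emotion", "block_index"),
                 "schedule")
  with_seed(derive_seed(seed, "simulate"), {
    pids <- unique(schedule$participant_id)
    u <- setNames(rnorm(length(pids), 0, truth$intercept_sd), pids)
    attention_failed <- setNames(runif(length(pids)) < truth$attention_fail_rate, pids)

    blocks <- split(design, design$block_index)
    rows <- vector("list", nrow(schedule))
    for (k in seq_len(nrow(schedule))) {
      sch <- schedule[k, ]
      blk <- blocks[[as.character(sch$block_index)]]
      blk <- blk[sample.int(nrow(blk)), ]  # random within-block presentation
      congruent <- blk$expression == sch$rated_emotion
      v_correct <- ifelse(congruent,
                          truth$drift[cbind(sch$rated_emotion, blk$mask)],
                          truth$incongruent_drift)
      rows[[k]] <- data.frame(
        participant_id = sch$participant_id,
        round_index = sch$round_index,
        rated_emotion = sch$rated_emotion,
        actor_id = blk$actor_id,
        expression = blk$expression,
        mask = blk$mask,
        block_index = sch$block_index,
        congruent = congruent,
        v = v_correct + u[[as.character(sch$participant_id)]],
        stringsAsFactors = FALSE
      )
    }
    trials <- do.call(rbind, rows)
    rownames(trials) <- NULL

    p <- ddm_params(v = 0, a = truth$a, z = truth$z, t = truth$t,
                    sv = truth$sv, sz = truth$sz, st = truth$st)
    p$v <- trials$v
    sim <- simulate_trial(p, seed = derive_seed(seed, "mcmc") + 11L, dt = dt)
    trials$v <- NULL
    trials$correct <- sim$upper
    trials$rt_ms <- sim$rt * 1000

    # fast-guess contaminants: uniform below 100 ms, coin-flip response
    contaminant <- runif(nrow(trials)) < truth$contamination_rate
    if (any(contaminant)) {
      n_c <- sum(contaminant)
      trials$rt_ms[contaminant] <- runif(n_c, 0, 100)
      trials$correct[contaminant] <- runif(n_c) < 0.5
    }
    trials$contaminant <- contaminant

    # response follows from correctness and congruency (accuracy coding)
    trials$response <- ifelse(trials$congruent == trials$correct, "yes", "no")
    trials$attention_failed <- attention_failed[trials$participant_id]
    trials$pairing <- paste(trials$expression, trials$rated_emotion, sep = ":")
    trials[, c("participant_id", "round_index", "rated_emotion", "actor_id",
               "expression", "mask", "block_index", "congruent", "pairing",
               "response", "correct", "rt_ms", "contaminant",
               "attention_failed")]
  })
}

#' Serialize a ground truth to JSON
#' @param truth a [ground_truth()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$drift <- as.data.frame(x$drift)
  write_json_file(x, path)
}
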