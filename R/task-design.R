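#' Generate counterbalanced blocks of masked-expression stimuli
#'
#' Builds the six-block stimulus design of the masked-expression rating task:
#' every (actor, expression, mask) triple occurs exactly once across blocks;
#' within a block each actor contributes exactly one expression shown with all
#' three masks, and each expression is contributed by exactly
#' `n_actors / 6` actors. The expression-to-block assignment is a balanced
#' Latin square over actor groups of size `n_actors / 6`, with actor-to-group
#' assignment stratified by gender (and ethnicity when provided) so strata are
#' spread evenly over groups; indivisible strata degrade gracefully to
#' approximate balance with a warning.
#'
#' @param n_actors number of actors; must be divisible by the number of
#'   emotions.
#' @param emotions character vector of expressions (default the 6 basic
#'   emotions).
#' @param masks character vector of mask conditions (default lower/upper/none).
#' @param n_blocks number of blocks; must equal `length(emotions)`.
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @param actor_gender optional character vector (length `n_actors`); defaults
#'   to an even female/male split.
#' @param actor_ethnicity optional character vector (length `n_actors`).
#' @return a data frame with one row per stimulus slot: `actor_id`,
#'   `actor_gender`, `actor_ethnicity`, `expression`, `mask`, `block_index`.
#'   Total rows = `n_actors * length(emotions) * length(masks)`.
#' @examples
#' d <- generate_blocks(36, seed = 1)   # 648 stimuli, 108 per block
#' table(d$block_index)
#' @export
generate_blocks <- function(n_actors, emotions = EMOTIONS, masks = MASKS,
                            n_blocks = length(emotions), seed = 1L,
                            actor_gender = NULL, actor_ethnicity = NULL) {
  n_emo <- length(emotions)
  if (n_actors %% n_emo != 0) {
    stop(sprintf(paste0("design infeasible: n_actors (%d) must be divisible ",
                        "by the number of emotions (%d) so each expression is ",
                        "contributed by equally many actors per block"),
                 n_actors, n_emo), call. = FALSE)
  }
  if (n_blocks != n_emo) {
    stop(sprintf(paste0("design infeasible: n_blocks (%d) must equal the ",
                        "number of emotions (%d) for full counterbalancing"),
                 n_blocks, n_emo), call. = FALSE)
  }
  if (anyDuplicated(emotions) || anyDuplicated(masks)) {
    stop("emotions and masks must be distinct labels", call. = FALSE)
  }
  gender <- actor_gender %||% rep(c("female", "male"), length.out = n_actors)
  if (length(gender) != n_actors) stop("actor_gender must have length n_actors", call. = FALSE)
  ethnicity <- actor_ethnicity %||% rep(NA_character_, n_actors)
  if (length(ethnicity) != n_actors) stop("actor_ethnicity must have length n_actors", call. = FALSE)

  group_size <- n_actors %/% n_emo
  actor_id <- sprintf("A%03d", seq_len(n_actors))

  with_seed(seed, {
    # Deal actors into n_emo groups round-robin within shuffled strata so each
    # group mirrors the gender (x ethnicity) composition of the full set.
    stratum <- if (all(is.na(ethnicity))) gender else paste(gender, ethnicity)
    by_stratum <- split(seq_len(n_actors), stratum)
    by_stratum <- lapply(by_stratum, function(ix) ix[sample.int(length(ix))])
    dealt <- unlist(by_stratum[sample.int(length(by_stratum))], use.names = FALSE)
    group_of <- integer(n_actors)
    group_of[dealt] <- rep_len(seq_len(n_emo), n_actors)

    # group sizes are exact by round-robin dealing; stratum balance is exact
    # only when every stratum divides evenly over the groups
    if (any(vapply(by_stratum, length, integer(1)) %% n_emo != 0)) {
      message("generate_blocks: gender/ethnicity strata do not divide evenly ",
              "over actor groups; using approximate (within-one) balance")
    }

    # Balanced Latin square over groups: block b, group g shows expression
    # row[(g + b - 2) mod n + 1] where row is a random base permutation.
    base_perm <- sample.int(n_emo)
    rows <- lapply(seq_len(n_blocks), function(b) {
      expr_of_group <- emotions[base_perm[((seq_len(n_emo) + b - 2L) %% n_emo) + 1L]]
      data.frame(
        actor_id = rep(actor_id, each = length(masks)),
        actor_gender = rep(gender, each = length(masks)),
        actor_ethnicity = rep(ethnicity, each = length(masks)),
        expression = rep(expr_of_group[group_of], each = length(masks)),
        mask = rep(masks, times = n_actors),
        block_index = b,
        stringsAsFactors = FALSE
      )
    })
    design <- do.call(rbind, rows)
    rownames(design) <- NULL
    design
  })
}

#' Schedule rating rounds for each participant
#'
#' Each participant completes six rounds; on each round they rate one emotion
#' while viewing one stimulus block. Emotion order and block order are
#' randomized jointly and independently per participant, so each participant
#' rates every emotion exactly once and sees every block exactly once. The
#' yes-response hand is randomized once per participant and held constant.
#'
#' @param participant_ids vector of unique participant identifiers.
#' @param n_rounds number of rounds; must equal the number of emotions (6).
#' @param emotions character vector of emotions rated (default the 6 basic
#'   emotions).
#' @param seed integer seed.
#' @return data frame with columns `participant_id`, `round_index`,
#'   `rated_emotion`, `block_index`, `key_mapping` (hand assigned to "yes").
#' @export
schedule_rounds <- function(participant_ids, n_rounds = 6L,
                            emotions = EMOTIONS, seed = 1L) {
  if (anyDuplicated(participant_ids)) {
    stop("duplicate participant ids: ",
         paste(unique(participant_ids[duplicated(participant_ids)]),
               collapse = ", "), call. = FALSE)
  }
  if (n_rounds != length(emotions)) {
    stop(sprintf("n_rounds (%d) must equal the number of emotions (%d)",
                 n_rounds, length(emotions)), call. = FALSE)
  }
  with_seed(seed, {
    per_p <- lapply(as.character(participant_ids), function(pid) {
      data.frame(
        participant_id = pid,
        round_index = seq_len(n_rounds),
        rated_emotion = emotions[sample.int(n_rounds)],
        block_index = sample.int(n_rounds),
        key_mapping = sample(c("left", "right"), 1L),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, per_p)
    rownames(out) <- NULL
    out
  })
}

#' Classify trials as congruent or incongruent
#'
#' A trial is congruent when the viewed expression matches the emotion rated
#' that round (an incorrect "no" there is a false-negative error) and
#' incongruent otherwise (an incorrect "yes" is a false-positive
#' misidentification). With 6 emotions the full expression-by-rating crossing
#' yields 6 congruent and 30 incongruent pairings.
#'
#' @param trials data frame with columns `expression` and `rated_emotion`,
#'   both drawn from the same 6-level emotion vocabulary.
#' @return `trials` with added columns `congruent` (logical) and `pairing`
#'   (label `"expression:rated_emotion"`).
#' @export
classify_congruency <- function(trials) {
  assert_columns(trials, c("expression", "rated_emotion"))
  assert_emotions(trials$expression, "expression")
  assert_emotions(trials$rated_emotion, "rated_emotion")
  trials$congruent <- trials$expression == trials$rated_emotion
  trials$pairing <- paste(trials$expression, trials$rated_emotion, sep = ":")
  trials
}

#' Write a stimulus design to CSV plus a JSON manifest
#'
#' @param design output of [generate_blocks()].
#' @param csv_path,manifest_path output file paths (manifest optional).
#' @param seed the seed the design was generated with (recorded in the
#'   manifest).
#' @return `csv_path`, invisibly.
#' @export
write_design <- function(design, csv_path, manifest_path = NULL, seed = NA) {
  write.csv(design, csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    write_json_file(list(
      n_stimuli = nrow(design),
      n_blocks = length(unique(design$block_index)),
      stimuli_per_block = as.list(table(design$block_index)),
      n_actors = length(unique(design$actor_id)),
      emotions = sort(unique(design$expression)),
      masks = sort(unique(design$mask)),
      seed = seed
    ), manifest_path)
  }
  invisible(csv_path)
}
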