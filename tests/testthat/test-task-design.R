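test_that("block generation reproduces the published design counts", {
  d1 <- generate_blocks(36, seed = 1)
  expect_equal(nrow(d1), 648)
  expect_true(all(table(d1$block_index) == 108))

  d2 <- generate_blocks(18, seed = 2)
  expect_equal(nrow(d2), 324)
  expect_true(all(table(d2$block_index) == 54))

  d3 <- generate_blocks(6, seed = 3)
  expect_equal(nrow(d3), 108)
  expect_true(all(table(d3$block_index) == 18))
  # minimal design: one actor per expression per block
  per <- table(d3$block_index, d3$expression) / 3
  expect_true(all(per == 1))
})

test_that("counterbalancing invariants hold across many seeds", {
  for (seed in 1:20) {
    d <- generate_blocks(12, seed = seed)
    # each (actor, expression, mask) triple exactly once
    expect_equal(anyDuplicated(d[, c("actor_id", "expression", "mask")]), 0L)
    # within a block: one expression per actor, all three masks
    per_actor <- aggregate(expression ~ actor_id + block_index, d,
                           function(x) length(unique(x)))
    expect_true(all(per_actor$expression == 1))
    expect_true(all(table(d$block_index, d$actor_id) == 3))
    # each expression contributed by n_actors/6 actors per block
    expect_true(all(table(d$block_index, d$expression) == 12 / 6 * 3))
    # block sizes sum to n_actors * 18
    expect_equal(nrow(d), 12 * 18)
  }
})

test_that("design generation is deterministic in the seed and validates input", {
  expect_identical(generate_blocks(12, seed = 9), generate_blocks(12, seed = 9))
  expect_false(identical(generate_blocks(12, seed = 9),
                         generate_blocks(12, seed = 10)))
  expect_error(generate_blocks(10), "divisible")
  expect_error(generate_blocks(12, n_blocks = 5), "n_blocks")
})

test_that("gender stratification balances groups and warns when indivisible", {
  d <- generate_blocks(12, seed = 4)
  # each expression slot within a block is gender balanced (group size 2)
  comp <- table(d$block_index, d$expression, d$actor_gender)
  expect_true(all(comp == 3))
  expect_message(
    generate_blocks(18, seed = 1,
                    actor_ethnicity = rep(c("a", "b", "c", "d"), length.out = 18)),
    "strata"
  )
})

test_that("round schedules cover every emotion and block once per participant", {
  s <- schedule_rounds(c("p1", "p2"), seed = 1)
  expect_equal(nrow(s), 12)
  for (pid in c("p1", "p2")) {
    sub <- s[s$participant_id == pid, ]
    expect_setequal(sub$rated_emotion, EMOTIONS)
    expect_setequal(sub$block_index, 1:6)
    expect_equal(length(unique(sub$key_mapping)), 1L)
  }
  big <- schedule_rounds(sprintf("P%03d", 1:228), seed = 5)
  expect_equal(nrow(big), 228 * 6)
  expect_identical(schedule_rounds(letters[1:4], seed = 3),
                   schedule_rounds(letters[1:4], seed = 3))
  expect_error(schedule_rounds(c("a", "a", "b")), "duplicate")
})

test_that("congruency classification yields 6 congruent and 30 incongruent pairings", {
  g <- full_crossing_trials()
  out <- classify_congruency(g)
  expect_equal(sum(out$congruent), 6)
  expect_equal(sum(!out$congruent), 30)
  expect_equal(length(unique(out$pairing[out$congruent])), 6)
  expect_equal(length(unique(out$pairing[!out$congruent])), 30)
  expect_true(out$congruent[out$expression == "disgust" &
                            out$rated_emotion == "disgust"])
  expect_error(classify_congruency(data.frame(expression = "joy",
                                              rated_emotion = "anger")),
               "unknown")
})

test_that("a full session yields one-sixth congruent trials per participant", {
  design <- generate_blocks(6, seed = 2)
  schedule <- schedule_rounds(c("x", "y"), seed = 2)
  # cross schedule with blocks (no simulation needed for the count property)
  rows <- merge(schedule, design, by = "block_index")
  rows <- classify_congruency(rows)
  per <- tapply(rows$congruent, rows$participant_id, mean)
  expect_true(all(abs(per - 1 / 6) < 1e-12))
})
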