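# Artificial-grammar design: inventory, timing arithmetic, stream and
# test-trial construction, and the stream invariants.

test_that("default inventory matches the stock syllable tables", {
  inv <- default_inventory()
  expect_equal(inv$target[1:3], c("BA", "BO", "FA"))
  expect_equal(inv$filler[1:3], c("BI", "BU", "DE"))
  expect_equal(inv$pairs[[1]], c("FU", "LA"))
  expect_equal(inv$pairs[[4]], c("WE", "HO"))
  labels <- c(inv$target, inv$filler, unlist(inv$pairs))
  expect_length(labels, 32L)           # 12 + 12 + 8 tokens
  expect_length(unique(labels), 32L)   # all labels distinct
  expect_error(syllable_inventory(inv$target, inv$filler, inv$pairs[1:3]),
               "4 ordered")
  expect_error(
    syllable_inventory(replace(inv$target, 1, "FU"), inv$filler, inv$pairs),
    "distinct")
})

test_that("timing arithmetic: chunk period, rates, epoch length", {
  t <- timing_spec()
  expect_equal(chunk_period(t), 1.58)
  expect_equal(round(chunk_rate(t), 2), 0.63)
  expect_equal(epoch_length(t, 8), 12.64)
  expect_equal(chunk_rate(timing_spec(boundary_silence_s = 0)), 1 / 1.5)
  expect_equal(syllable_rate(t), 6 / 1.58)
})

test_that("within-chunk stream: structure, roles and balancing", {
  ev <- make_within_stream(c("FU", "LA"), 2, seed = 7)
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 24L)                       # 4 chunks x 6 syllables
  expect_equal(length(unique(ev$chunk_index)), 4L)
  dep <- ev[ev$role %in% c("dep_first", "dep_second"), ]
  expect_equal(dep$chunk_index, c(0L, 0L, 2L, 2L))
  expect_equal(dep$position, c(2L, 5L, 2L, 5L))
  expect_equal(dep$syllable, c("FU", "LA", "FU", "LA"))
  # fillers in odd chunks, targets in even chunks
  expect_true(all(ev$role[ev$chunk_index %% 2 == 1] == "filler"))
  expect_error(make_within_stream(c("FU", "LA"), 0), "invalid design")

  # one learning audio: 72 target chunks -> 144 chunks, 864 events
  audio <- make_within_stream(c("FU", "LA"), 72, seed = 1)
  expect_equal(length(unique(audio$chunk_index)), 144L)
  # balanced free-position usage within one occurrence
  inv <- default_inventory()
  counts <- table(audio$syllable[audio$role == "other_target"])
  expect_setequal(names(counts), inv$target)
  expect_lte(diff(range(counts)), 1)
  fcounts <- table(audio$syllable[audio$role == "filler"])
  expect_lte(diff(range(fcounts)), 1)
})

test_that("across-chunk stream: dependency spans consecutive chunks", {
  ev <- make_across_stream(c("TA", "PI"), 2, seed = 3)
  expect_equal(nrow(ev), 12L)
  expect_equal(ev$syllable[5], "TA")   # position 5 of chunk 0
  expect_equal(ev$syllable[8], "PI")   # position 2 of chunk 1
  d <- ev$onset_s[ev$role == "dep_second"] - ev$onset_s[ev$role == "dep_first"]
  expect_equal(d, 3 * 0.25 + 0.08)     # 0.83 s across the boundary
  expect_error(make_across_stream(c("TA", "PI"), 3), "invalid design")
  expect_error(make_across_stream(c("TA", "PI"), 0), "invalid design")
  big <- make_across_stream(c("TA", "PI"), 144, seed = 1)
  expect_equal(length(unique(big$chunk_index)), 144L)
  expect_true(all(big$role != "filler"))
})

test_that("stream timing is bit-exact and dependencies deterministic", {
  for (ev in list(make_within_stream(c("FU", "LA"), 12, seed = 5),
                  make_across_stream(c("KE", "MÖ"), 24, seed = 5))) {
    d <- diff(ev$onset_s)
    cross <- diff(ev$chunk_index) != 0
    expect_true(all(abs(d[!cross] - 0.25) < 1e-12))
    expect_true(all(abs(d[cross] - 0.33) < 1e-12))
    # P(dep_second | dep_first) = 1 at the designed offset
    firsts <- which(ev$role == "dep_first")
    seconds <- which(ev$role == "dep_second")
    expect_equal(length(firsts), length(seconds))
    expect_true(all(seconds > firsts))
  }
  # same seed -> identical table; different seed permutes free slots only
  a <- make_within_stream(c("FU", "LA"), 20, seed = 42)
  b <- make_within_stream(c("FU", "LA"), 20, seed = 42)
  c <- make_within_stream(c("FU", "LA"), 20, seed = 43)
  expect_identical(a, b)
  fixed <- a$role %in% c("dep_first", "dep_second")
  expect_identical(a$syllable[fixed], c$syllable[fixed])
  expect_identical(a$onset_s, c$onset_s)
  expect_false(identical(a$syllable, c$syllable))
})

test_that("test trials form a balanced, randomized 2 x 2 design", {
  pairs <- list(c("FU", "LA"), c("TA", "PI"))
  trials <- make_test_trials(pairs, n_per_cell = 6, seed = 9)
  expect_length(trials, 24L)
  cond <- vapply(trials, attr, "", "condition")
  viol <- vapply(trials, attr, TRUE, "violation")
  expect_identical(as.vector(table(cond, viol)), rep(6L, 4))
  # within trial: 8 chunks (4 target + 4 filler); across trial: 4 chunks
  n_chunks <- vapply(trials, function(tr) length(unique(tr$chunk_index)), 1L)
  expect_true(all(n_chunks[cond == "within"] == 8L))
  expect_true(all(n_chunks[cond == "across"] == 4L))
  # violation trials: no dep_second, at least one dep_second_violation,
  # and the substituted syllable is the other pair's second element
  for (tr in trials[viol]) {
    expect_false(any(tr$role == "dep_second"))
    expect_gte(sum(tr$role == "dep_second_violation"), 1L)
    other <- if (attr(tr, "condition") == "within") "PI" else "LA"
    expect_true(all(tr$syllable[tr$role == "dep_second_violation"] == other))
  }
  # order randomized but balanced; trial_index runs 0..n-1
  ti <- vapply(trials, function(tr) tr$trial_index[1], 1L)
  expect_equal(ti, seq_along(trials) - 1L)
  expect_identical(trials,
                   make_test_trials(pairs, n_per_cell = 6, seed = 9))
})

test_that("concatenated trials form one valid increasing timeline", {
  trials <- make_test_trials(list(c("FU", "LA"), c("TA", "PI")),
                             n_per_cell = 2, seed = 1)
  ev <- concat_trials(trials)
  expect_s3_class(ev, "event_table")
  expect_true(all(diff(ev$onset_s) > 0))
  expect_equal(nrow(ev), sum(vapply(trials, nrow, 1L)))
})

test_that("event table validation catches broken timelines", {
  ev <- make_within_stream(c("FU", "LA"), 2, seed = 1)
  bad <- as.data.frame(ev)
  bad$onset_s[3] <- bad$onset_s[3] + 0.01
  expect_error(event_table(bad), "inter-onset")
  bad2 <- as.data.frame(ev)[-2, ]  # drop a dep_first
  expect_error(event_table(bad2), "inter-onset|unbalanced")
  bad3 <- as.data.frame(ev)
  bad3$role[1] <- "mystery"
  expect_error(event_table(bad3), "unknown event role")
})
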