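test_that("schema construction obeys its invariants", {
  set.seed(1)
  sch <- event_schema(16, 4)
  expect_equal(sch$n_timepoints, 16L)
  expect_equal(rowSums(sch$state_probs), rep(1, 16))
  expect_true(all(sch$state_probs == 0.25))  # baseline strength = uniform
  expect_equal(count_state_sequences(sch), 4^16)

  strong <- event_schema(16, 4, schema_strength = 0.95, parity = 1L)
  expect_equal(rowSums(strong$state_probs), rep(1, 16), tolerance = 1e-12)
  for (t in which(strong$schematic_mask)) {
    expect_equal(sort(strong$state_probs[t, ], decreasing = TRUE),
                 c(0.95, rep(0.05 / 3, 3)), tolerance = 1e-12)
    expect_equal(strong$state_probs[t, strong$prototypes[t]], 0.95)
  }
  expect_true(all(strong$state_probs[!strong$schematic_mask, ] == 0.25))
  # parity flips which half is schematic
  p0 <- event_schema(8, 4, 0.95, parity = 0L)
  p1 <- event_schema(8, 4, 0.95, parity = 1L)
  expect_equal(p0$schematic_mask, !p1$schematic_mask)
  expect_error(event_schema(8, 4, schema_strength = 0.1))
})

test_that("situation sampling follows the schema's categoricals", {
  set.seed(2)
  sch <- event_schema(4, 4)
  draws <- replicate(20000, sample_situation(sch))
  freq <- table(factor(draws[1, ], levels = 1:4)) / 20000
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(freq - 0.25) < 3 * se + 1e-3))

  # strength 1: the prototype always occurs at schematic time points
  det <- event_schema(4, 4, schema_strength = 1, parity = 0L)
  for (k in 1:50) {
    sit <- sample_situation(det)
    expect_equal(sit[det$schematic_mask],
                 det$prototypes[det$schematic_mask])
  }

  # strength 0.95: prototype frequency ~0.95, others ~0.05/3
  st <- event_schema(4, 4, schema_strength = 0.95, parity = 0L)
  tp <- which(st$schematic_mask)[1]
  draws <- replicate(20000, sample_situation(st)[tp])
  f <- mean(draws == st$prototypes[tp])
  expect_true(abs(f - 0.95) < 3 * sqrt(0.95 * 0.05 / 20000) + 1e-3)
})

test_that("trial construction satisfies condition structure", {
  set.seed(3)
  sch <- event_schema(8, 4)
  dm <- build_trial("DM", sch, penalty = 2)
  expect_length(dm$situations, 3)
  expect_identical(dm$situations[[2]], dm$situations[[3]])
  expect_equal(dm$flush_before_event, c(FALSE, FALSE, TRUE))
  rm_ <- build_trial("RM", sch, penalty = 2)
  expect_identical(rm_$situations[[2]], rm_$situations[[3]])
  expect_equal(rm_$flush_before_event, rep(FALSE, 3))
  nm <- build_trial("NM", sch, penalty = 2)
  expect_equal(nm$flush_before_event, c(FALSE, TRUE, TRUE))
  expect_false(identical(nm$situations[[1]], nm$situations[[2]]) &&
                 identical(nm$situations[[2]], nm$situations[[3]]))
  expect_error(build_trial("XX", sch, penalty = 2))
  # default encoding point is the final time point of each event
  expect_equal(dm$encode_at[[1]], 8L)
  # full observation dropping still leaves every target defined
  set.seed(4)
  tr <- build_trial("DM", sch, penalty = 1, obs_drop_prob = 1)
  st <- render_stimuli(tr, sch)
  expect_true(all(!is.na(st[[1]]$target)))
  expect_true(all(st[[1]]$X[, 1:12] == 0))  # no observations in part 1
})

test_that("stimulus rendering follows the input layout", {
  set.seed(5)
  sch <- event_schema(16, 4)
  tr <- build_trial("DM", sch, penalty = 2)
  st <- render_stimuli(tr, sch)
  # 2T + B + 1 input dimensions
  expect_equal(ncol(st[[1]]$X), 37L)
  # queries form the T x T identity in fixed diagonal order
  Q <- st[[1]]$X[, 16 + 4 + 1:16]
  expect_equal(unname(Q), diag(16))
  # penalty input constant across the trial
  for (e in 1:3) expect_true(all(st[[e]]$X[, 37] == 2))
  # targets equal the situation at the queried time point
  expect_equal(st[[2]]$target, tr$situations[[2]])
  # observation one-hots follow observation_order
  ordv <- tr$observation_order[[1]]
  for (s in 1:16) {
    expect_equal(which(st[[1]]$X[s, 1:16] == 1), ordv[s])
    expect_equal(which(st[[1]]$X[s, 16 + 1:4] == 1),
                 tr$situations[[1]][ordv[s]])
  }
})

test_that("query delay presents observations before the first query", {
  set.seed(6)
  sch <- event_schema(8, 4)
  repeat {
    tr <- build_trial("RM", sch, penalty = 0, delay_max = 3)
    if (tr$delay >= 2) break
  }
  st <- render_stimuli(tr, sch)
  d <- tr$delay
  ev <- st[[1]]
  expect_equal(ev$n_steps, 8L + d)
  # no query (and no target) during the delay prefix
  expect_true(all(is.na(ev$queried[seq_len(d)])))
  expect_true(all(is.na(ev$target[seq_len(d)])))
  # observations are presented from step 1
  expect_false(is.na(ev$observed_feature[1]))
  # queries then run 1..T in order
  expect_equal(ev$queried[(d + 1):(d + 8)], 1:8)
  # dropped observation renders as all-zero observation channels
  set.seed(7)
  tr2 <- build_trial("RM", sch, penalty = 0, obs_drop_prob = 0.5)
  st2 <- render_stimuli(tr2, sch)
  dropped <- which(is.na(st2[[1]]$observed_feature[1:8]))
  if (length(dropped)) {
    expect_true(all(st2[[1]]$X[dropped, 1:12] == 0))
  }
})

test_that("trial generation is reproducible and serialises losslessly", {
  sch <- event_schema(8, 4)
  set.seed(99)
  a <- build_trial("DM", sch, penalty = 1.5, obs_drop_prob = 0.3,
                   delay_max = 3)
  set.seed(99)
  b <- build_trial("DM", sch, penalty = 1.5, obs_drop_prob = 0.3,
                   delay_max = 3)
  expect_identical(a, b)
  path <- file.path(tempdir(), "trials.jsonl")
  set.seed(1)
  trials <- lapply(c("RM", "DM", "NM"), build_trial, schema = sch,
                   penalty = 2, obs_drop_prob = 0.3, delay_max = 3)
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back, trials)
})

test_that("observation orders are independent uniform permutations", {
  set.seed(8)
  sch <- event_schema(8, 4)
  first_pos <- matrix(0L, 0, 2)
  for (k in 1:600) {
    tr <- build_trial("DM", sch, penalty = 2)
    first_pos <- rbind(first_pos, c(tr$observation_order[[2]][1],
                                    tr$observation_order[[3]][1]))
  }
  # chi-square sanity on first-position frequencies, both parts
  for (j in 1:2) {
    tab <- table(factor(first_pos[, j], levels = 1:8))
    p <- stats::chisq.test(tab)$p.value
    expect_gt(p, 1e-4)
  }
  # independence: part-1 and part-2 orders differ in most trials
  expect_gt(mean(first_pos[, 1] != first_pos[, 2]), 0.7)
})
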