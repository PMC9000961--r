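# Shared, lazily built artifacts for the acceptance suite: a 3-seed
# reduced-preset cohort (the expensive step, ~15 min) and its evaluation
# rollouts, built once per test session and reused across criteria.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_config <- function() em_config("reduced")

acceptance_cohort <- function() {
  if (is.null(.acceptance_cache$cohort)) {
    cfg <- acceptance_config()
    .acceptance_cache$cohort <- meta_train(cfg, seeds = 1:3)
  }
  .acceptance_cache$cohort
}

# evaluation rollouts per model x condition x penalty, memoised
acceptance_rollouts <- function(condition, penalty = NULL,
                                n_trials = 60L, encode_at = NULL) {
  cfg <- acceptance_config()
  if (is.null(penalty)) penalty <- cfg$test_penalty
  key <- paste(condition, penalty, n_trials,
               paste(encode_at, collapse = "-"), sep = "_")
  if (is.null(.acceptance_cache[[key]])) {
    cohort <- acceptance_cohort()
    .acceptance_cache[[key]] <- lapply(seq_along(cohort), function(m) {
      set.seed(5000L + m)
      meta_test(cohort[[m]]$model, cohort[[m]]$schema, cfg,
                condition = condition, n_trials = n_trials,
                penalty = penalty, encode_at = encode_at)
    })
  }
  .acceptance_cache[[key]]
}

# mean part-2 activation of memories with a provenance tag, per model
mean_part2_activation <- function(rolls_per_model, tag) {
  vapply(rolls_per_model, function(rolls) {
    mean(vapply(rolls, function(r) {
      am <- r$events[[3]]$act_mat
      keep <- r$mem_tag == tag
      if (!any(keep) || nrow(am) == 0) return(NA_real_)
      mean(colSums(am[keep, , drop = FALSE]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
}

mean_part2_stat <- function(rolls_per_model, field) {
  vapply(rolls_per_model, function(rolls) {
    mean(vapply(rolls, function(r) mean(r$events[[3]][[field]]),
                numeric(1)))
  }, numeric(1))
}

# "sign test across seeds" at n = 3: the across-seed mean difference has
# the predicted sign and at least 2 of the 3 seeds agree in direction
expect_sign_across_seeds <- function(diffs, label) {
  testthat::expect_gt(mean(diffs), 0, label = paste(label, "(mean)"))
  testthat::expect_gte(sum(diffs > 0), 2,
                       label = paste(label, "(seed majority)"))
}
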