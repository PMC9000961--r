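## Analyses of frozen-weight evaluation rollouts. All functions consume the
## output of meta_test() (or the cohort list from meta_train()) and return
## tidy data.frames; the across-model summary convention is mean +/- 1 SE.

part2_activation <- function(rollout, tag_filter, label_filter = NULL) {
  keep <- rollout$mem_tag %in% tag_filter
  if (!is.null(label_filter)) keep <- keep & rollout$mem_label %in% label_filter
  am <- rollout$events[[3]]$act_mat
  if (!any(keep) || nrow(am) == 0) return(rep(NA_real_, rollout$events[[3]]$n_steps))
  colSums(am[keep, , drop = FALSE])
}

#' Condition time courses during part 2
#'
#' Evaluates each trained model on fresh trials in the requested conditions
#' and computes, per part-2 time point: the accuracy / mistake / don't-know
#' rate decomposition (which sums to 1), the mean EM gate value, and the
#' summed LCA activation of target and lure memories. In the NM condition
#' no target memory exists, so the target trace is NA by construction.
#'
#' @param cohort list of trained models from [meta_train()].
#' @param config an `em_config`.
#' @param conditions subset of `c("RM", "DM", "NM")`.
#' @param n_trials test trials per model and condition.
#' @param penalty test penalty (defaults to `config$test_penalty`).
#' @return data.frame with one row per model x condition x time point:
#'   `accuracy`, `mistake`, `dontknow`, `em_gate`, `target_act`,
#'   `lure_act`.
#' @export
run_condition_eval <- function(cohort, config,
                               conditions = c("RM", "DM", "NM"),
                               n_trials = 20L, penalty = NULL) {
  out <- list()
  for (m in seq_along(cohort)) {
    for (cond in conditions) {
      rolls <- meta_test(cohort[[m]]$model, cohort[[m]]$schema, config,
                         condition = cond, n_trials = n_trials,
                         penalty = penalty)
      T_ <- cohort[[m]]$schema$n_timepoints
      acc <- mis <- dk <- gate <- numeric(T_)
      tgt <- lur <- matrix(NA_real_, length(rolls), T_)
      for (i in seq_along(rolls)) {
        ev3 <- rolls[[i]]$events[[3]]
        acc <- acc + ev3$correct
        dk <- dk + ev3$dontknow
        mis <- mis + (!ev3$correct & !ev3$dontknow)
        gate <- gate + ev3$gate
        tgt[i, ] <- part2_activation(rolls[[i]], "target")
        lur[i, ] <- part2_activation(rolls[[i]], "lure")
      }
      n <- length(rolls)
      out[[length(out) + 1L]] <- data.frame(
        model = m, condition = cond, timepoint = seq_len(T_),
        accuracy = acc / n, mistake = mis / n, dontknow = dk / n,
        em_gate = gate / n,
        target_act = colMeans(tgt), lure_act = colMeans(lur)
      )
    }
  }
  do.call(rbind, out)
}

#' Summarise a trace across models
#'
#' @param df output of [run_condition_eval()] (or any data.frame with a
#'   `model` column and numeric trace columns).
#' @param value name of the column to summarise.
#' @return data.frame of mean and 1-SE-across-models per condition and
#'   time point.
#' @export
summarise_trace <- function(df, value = "accuracy") {
  split_by <- interaction(df$condition, df$timepoint, drop = TRUE)
  parts <- split(df, split_by)
  res <- lapply(parts, function(p) {
    v <- p[[value]]
    data.frame(condition = p$condition[1], timepoint = p$timepoint[1],
               mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  })
  out <- do.call(rbind, res)
  out[order(out$condition, out$timepoint), ]
}

#' Recall time of the target memory
#'
#' Operationalised as the first part-2 time point at which the summed
#' target-memory activation exceeds a threshold fraction (default 0.5) of
#' its within-trial maximum. Trials where the target is never activated
#' are excluded and counted.
#'
#' @param rollouts list of rollouts from [meta_test()] (DM condition).
#' @param threshold fraction of the trial's maximum activation.
#' @return list with `mean_time`, per-trial `times`, and `n_excluded`.
#' @export
recall_time <- function(rollouts, threshold = 0.5) {
  times <- numeric(0)
  n_excluded <- 0L
  for (r in rollouts) {
    trace <- part2_activation(r, "target")
    if (all(is.na(trace)) || max(trace, na.rm = TRUE) <= 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    times <- c(times, which(trace >= threshold * max(trace))[1])
  }
  list(mean_time = if (length(times)) mean(times) else NA_real_,
       times = times, n_excluded = n_excluded)
}

#' Gate value conditioned on feature recency
#'
#' Splits part-2 time points by whether the feature controlling the
#' upcoming transition was already observed in the current event (at or
#' before the query step, since within a step the observation precedes the
#' query) and returns the mean EM gate per group. A demand-sensitive
#' policy opens the gate more when the feature has not been observed.
#'
#' @param rollouts list of rollouts from [meta_test()] (DM condition).
#' @return data.frame with rows `observed` and `not_observed`: mean gate
#'   and number of time points in each group.
#' @export
conditional_gate_analysis <- function(rollouts) {
  g_obs <- g_not <- numeric(0)
  for (r in rollouts) {
    ev3 <- r$events[[3]]
    for (s in seq_len(ev3$n_steps)) {
      q <- ev3$queried[s]
      if (is.na(q)) next
      seen <- any(ev3$observed_feature[seq_len(s)] == q, na.rm = TRUE)
      if (seen) g_obs <- c(g_obs, ev3$gate[s])
      else g_not <- c(g_not, ev3$gate[s])
    }
  }
  data.frame(
    group = c("observed", "not_observed"),
    mean_gate = c(mean(g_obs), mean(g_not)),
    n = c(length(g_obs), length(g_not))
  )
}

#' Schema-strength sweep
#'
#' Trains a separate model cohort at each schema strength (prototypical
#' state probability at schematic time points) and measures the mean
#' part-2 EM gate value separately for schematic and non-schematic time
#' points. At the baseline strength `1/B` the two groups are generated
#' identically. The default grid follows the 0.25--0.95 range in steps of
#' 0.10.
#'
#' @param config an `em_config`; its `schema_strength` field is overridden
#'   per grid point.
#' @param strengths schema-strength grid.
#' @param n_trials test trials per model.
#' @return data.frame with one row per strength x model x group
#'   (`schematic` / `nonschematic`) holding the mean part-2 gate value.
#' @export
schema_sweep <- function(config, strengths = seq(0.25, 0.95, by = 0.10),
                         n_trials = 20L) {
  out <- list()
  for (s in strengths) {
    cfg <- config
    cfg$schema_strength <- s
    cohort <- meta_train(cfg)
    for (m in seq_along(cohort)) {
      schema <- cohort[[m]]$schema
      rolls <- meta_test(cohort[[m]]$model, schema, cfg,
                         condition = "DM", n_trials = n_trials)
      gates <- rowMeans(vapply(rolls, function(r) r$events[[3]]$gate,
                               numeric(schema$n_timepoints)))
      for (grp in c("schematic", "nonschematic")) {
        keep <- if (grp == "schematic") schema$schematic_mask
                else !schema$schematic_mask
        out[[length(out) + 1L]] <- data.frame(
          strength = s, model = m, group = grp,
          mean_gate = mean(gates[keep])
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Endpoint-only versus midway-plus-endpoint encoding
#'
#' Evaluates each trained model in the DM condition under two imposed
#' encoding policies: snapshots at each event's final time point only, or
#' additionally midway through each event (time point `T/2`). Returns the
#' part-2 accuracy per model and policy, and the mean part-2 activation
#' decomposed by memory provenance (endpoint/midway x target/lure). The
#' encoding policy is applied at test; the retrieval policy was learned
#' under endpoint-only encoding unless the cohort was trained otherwise.
#'
#' @param cohort list of trained models from [meta_train()].
#' @param config an `em_config`.
#' @param n_trials test trials per model and policy.
#' @param penalty test penalty.
#' @return list with `accuracy` (model x policy part-2 accuracy) and
#'   `activation` (model x policy x label x tag mean activation).
#' @export
encoding_policy_experiment <- function(cohort, config, n_trials = 20L,
                                       penalty = NULL) {
  acc_rows <- list(); act_rows <- list()
  for (m in seq_along(cohort)) {
    schema <- cohort[[m]]$schema
    T_ <- schema$n_timepoints
    policies <- list(endpoint = T_, midway = c(T_ %/% 2L, T_))
    for (pname in names(policies)) {
      rolls <- meta_test(cohort[[m]]$model, schema, config,
                         condition = "DM", n_trials = n_trials,
                         penalty = penalty,
                         encode_at = policies[[pname]])
      acc <- mean(vapply(rolls, function(r)
        mean(r$events[[3]]$correct), numeric(1)))
      acc_rows[[length(acc_rows) + 1L]] <-
        data.frame(model = m, policy = pname, accuracy = acc)
      for (lab in c("endpoint", "midway")) {
        for (tag in c("target", "lure")) {
          tr <- vapply(rolls, function(r) {
            v <- part2_activation(r, tag, lab)
            mean(v)
          }, numeric(1))
          act_rows[[length(act_rows) + 1L]] <- data.frame(
            model = m, policy = pname, label = lab, tag = tag,
            mean_activation = mean(tr, na.rm = TRUE),
            n_defined = sum(!is.na(tr))
          )
        }
      }
    }
  }
  list(accuracy = do.call(rbind, acc_rows),
       activation = do.call(rbind, act_rows))
}

cosine_cross <- function(A, B) {
  # columns are observations
  An <- sqrt(colSums(A^2)); Bn <- sqrt(colSums(B^2))
  S <- crossprod(A, B)
  denom <- outer(An, Bn)
  S[denom > 0] <- S[denom > 0] / denom[denom > 0]
  S[denom == 0] <- 0
  S
}

#' Temporal structure of working-memory states
#'
#' From NM rollouts (three unrelated events), computes the time-point-to-
#' time-point cosine similarity matrix between the cell states of the
#' second and third events, averaged over trials, plus a 2-component PCA
#' embedding of cell states across events. Strong temporal coding shows up
#' as a dominant diagonal: states from the same within-event time point
#' are more similar than states from different time points, even across
#' unrelated events.
#'
#' @param rollouts list of rollouts from [meta_test()] (NM condition).
#' @return list with `sim_matrix` (T x T, part 1 rows x part 2 columns),
#'   `same_time_mean`, `diff_time_mean`, and `embedding` (data.frame of
#'   PC1/PC2 per event x time point x trial).
#' @export
similarity_analysis <- function(rollouts) {
  T_ <- rollouts[[1]]$events[[3]]$n_steps
  S <- matrix(0, T_, T_)
  emb_states <- list(); emb_meta <- list()
  for (i in seq_along(rollouts)) {
    c1 <- rollouts[[i]]$events[[2]]$cells
    c2 <- rollouts[[i]]$events[[3]]$cells
    S <- S + cosine_cross(c1, c2)
    for (e in 2:3) {
      cells <- rollouts[[i]]$events[[e]]$cells
      emb_states[[length(emb_states) + 1L]] <- t(cells)
      emb_meta[[length(emb_meta) + 1L]] <- data.frame(
        trial = i, event = e, timepoint = seq_len(ncol(cells)))
    }
  }
  S <- S / length(rollouts)
  X <- do.call(rbind, emb_states)
  meta <- do.call(rbind, emb_meta)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  emb <- cbind(meta, PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  diag_mask <- diag(T_) == 1
  list(sim_matrix = S,
       same_time_mean = mean(S[diag_mask]),
       diff_time_mean = mean(S[!diag_mask]),
       embedding = emb)
}
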