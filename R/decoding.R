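## Multivariate decoding of the working-memory (cell) state, in the spirit
## of MVPA applied to model internals: one L2-regularised multinomial
## linear classifier per situation feature, with trial-stratified
## cross-validation.

#' Build a labelled decoding dataset from evaluation rollouts
#'
#' For each trial the part-1 (second event) and part-2 (third event) cell
#' states are collected. Part-1 labels for feature f are "don't know" at
#' every time point before f was observed and f's observed value from the
#' observation onward. Part-2 labels assume episodic recall reinstates the
#' full situation: every feature takes its true value from the step after
#' the EM-gate peak onward (and from its direct observation onward, if
#' earlier); if the part-2 gate trace never rises above `gate_floor`, no
#' reinstatement labels are applied and only direct observations label
#' part 2.
#'
#' @param rollouts list of rollouts from [meta_test()] (typically DM).
#' @param gate_floor minimum gate peak for the reinstatement rule.
#' @return list of class `decoding_dataset`: `states` (samples x hidden),
#'   `labels` (samples x T character matrix, `"dk"` or `"1".."B"`),
#'   `trial`, `part`, `timepoint` per sample, and `n_features`.
#' @export
build_labels <- function(rollouts, gate_floor = 0.05) {
  states <- list(); labels <- list()
  trial_id <- integer(0); part <- integer(0); timep <- integer(0)
  T_ <- rollouts[[1]]$events[[2]]$n_steps
  for (i in seq_along(rollouts)) {
    r <- rollouts[[i]]
    for (ev_idx in 2:3) {
      ev <- r$events[[ev_idx]]
      n <- ev$n_steps
      lab <- matrix("dk", n, T_)
      obs_step <- rep(NA_integer_, T_)
      for (s in seq_len(n)) {
        f <- ev$observed_feature[s]
        if (!is.na(f) && is.na(obs_step[f])) obs_step[f] <- s
      }
      reinstate_from <- NA_integer_
      if (ev_idx == 3L && max(ev$gate) >= gate_floor) {
        reinstate_from <- which.max(ev$gate) + 1L
      }
      sit <- r$situations[[if (ev_idx == 2L) 2L else 3L]]
      for (f in seq_len(T_)) {
        from <- obs_step[f]
        if (ev_idx == 3L && !is.na(reinstate_from)) {
          from <- min(from, reinstate_from, na.rm = TRUE)
        }
        if (!is.na(from) && from <= n) {
          lab[seq(from, n), f] <- as.character(sit[f])
        }
      }
      states[[length(states) + 1L]] <- t(ev$cells)
      labels[[length(labels) + 1L]] <- lab
      trial_id <- c(trial_id, rep(i, n))
      part <- c(part, rep(ev_idx - 1L, n))
      timep <- c(timep, seq_len(n))
    }
  }
  structure(
    list(states = do.call(rbind, states),
         labels = do.call(rbind, labels),
         trial = trial_id, part = part, timepoint = timep,
         n_features = T_),
    class = "decoding_dataset"
  )
}

fit_feature_decoder <- function(x, y, foldid) {
  y <- factor(y)
  if (nlevels(y) < 2L) {
    # degenerate label set (can happen in tiny folds): constant decoder
    return(list(constant = levels(y)[1]))
  }
  fit <- suppressWarnings(tryCatch(
    glmnet::cv.glmnet(x, y, family = "multinomial", alpha = 0,
                      foldid = foldid, type.measure = "class",
                      nlambda = 30),
    error = function(e) NULL
  ))
  if (!is.null(fit)) {
    return(list(fit = fit$glmnet.fit, lambda = fit$lambda.min,
                levels = levels(y)))
  }
  # inner CV impossible (a class missing from some fold): fit the ridge
  # path once and take a mid-path regularisation strength
  fit <- suppressWarnings(tryCatch(
    glmnet::glmnet(x, y, family = "multinomial", alpha = 0, nlambda = 30),
    error = function(e) NULL
  ))
  if (is.null(fit)) {
    # near-empty classes: fall back to the majority class
    return(list(constant = names(which.max(table(y)))))
  }
  list(fit = fit, lambda = fit$lambda[ceiling(length(fit$lambda) / 2)],
       levels = levels(y))
}

predict_feature_decoder <- function(dec, x) {
  if (!is.null(dec$constant)) return(rep(dec$constant, nrow(x)))
  as.character(stats::predict(dec$fit, newx = x, s = dec$lambda,
                              type = "class"))
}

#' Train per-feature decoders with nested cross-validation
#'
#' Each situation feature gets its own multinomial logistic-regression
#' classifier with an L2 penalty (ridge; `glmnet` with `alpha = 0`),
#' trained on part-1 cell states. The outer loop is a fivefold
#' cross-validation stratified by trial (all states from one trial share a
#' fold, preventing temporal leakage); the regularisation strength is
#' picked by an inner cross-validation within each training set. Reports
#' the mean held-out part-1 accuracy across features and folds, and
#' returns decoders refit on all part-1 data for use with [decode_map()].
#'
#' @param dataset a `decoding_dataset` from [build_labels()].
#' @param nfolds number of outer folds.
#' @return list with `accuracy` (overall mean held-out accuracy, in
#'   percent), `per_feature` data.frame, and `decoders` (one per feature).
#' @export
train_decoders <- function(dataset, nfolds = 5L) {
  stopifnot(inherits(dataset, "decoding_dataset"))
  p1 <- dataset$part == 1L
  x_all <- dataset$states[p1, , drop = FALSE]
  trials <- dataset$trial[p1]
  u_trials <- unique(trials)
  stopifnot(length(u_trials) >= nfolds)
  outer_fold <- (match(trials, u_trials) - 1L) %% nfolds + 1L
  acc <- matrix(NA_real_, dataset$n_features, nfolds)
  decoders <- vector("list", dataset$n_features)
  for (f in seq_len(dataset$n_features)) {
    y_all <- dataset$labels[p1, f]
    for (k in seq_len(nfolds)) {
      tr <- outer_fold != k
      inner_trials <- unique(trials[tr])
      inner_fold <- (match(trials[tr], inner_trials) - 1L) %% nfolds + 1L
      dec <- fit_feature_decoder(x_all[tr, , drop = FALSE], y_all[tr],
                                 inner_fold)
      pred <- predict_feature_decoder(dec, x_all[!tr, , drop = FALSE])
      acc[f, k] <- mean(pred == y_all[!tr])
    }
    full_fold <- (match(trials, u_trials) - 1L) %% nfolds + 1L
    decoders[[f]] <- fit_feature_decoder(x_all, y_all, full_fold)
  }
  list(accuracy = 100 * mean(acc),
       per_feature = data.frame(feature = seq_len(dataset$n_features),
                                accuracy = 100 * rowMeans(acc)),
       decoders = decoders)
}

#' Decode a trial's working-memory contents step by step
#'
#' Applies the trained per-feature decoders to every cell state of a
#' trial's part 1 and part 2 (second and third events) and marks entry
#' (f, t) `TRUE` iff decoder f predicts the true value of feature f at
#' step t. "Don't know" predictions count as not decoded. In a DM trial,
#' features typically become decodable after they are observed during part
#' 1, vanish at the flush, and then flip back on at the retrieval step in
#' part 2 before being observed again.
#'
#' @param decoders the `decoders` element from [train_decoders()].
#' @param rollout one rollout from [meta_test()].
#' @return logical matrix, features x (part-1 + part-2 steps).
#' @export
decode_map <- function(decoders, rollout) {
  cells <- cbind(rollout$events[[2]]$cells, rollout$events[[3]]$cells)
  n_steps <- ncol(cells)
  T_ <- length(decoders)
  truth <- cbind(
    matrix(rollout$situations[[2]], T_, rollout$events[[2]]$n_steps),
    matrix(rollout$situations[[3]], T_, rollout$events[[3]]$n_steps)
  )
  out <- matrix(FALSE, T_, n_steps)
  X <- t(cells)
  for (f in seq_len(T_)) {
    pred <- predict_feature_decoder(decoders[[f]], X)
    out[f, ] <- pred == as.character(truth[f, ])
  }
  out
}
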