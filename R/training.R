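#' Reward function of the event-prediction task
#'
#' A correct next-state prediction earns `reward_correct` (+1 by
#' convention, making the 0-4 penalty range interpretable as a cost
#' ratio), a wrong prediction costs `-penalty`, and the dedicated
#' "don't know" action always earns exactly zero.
#'
#' @param action action index in `1..(B + 1)`; `B + 1` is "don't know".
#' @param target correct state in `1..B`.
#' @param penalty penalty magnitude (>= 0).
#' @param n_states number of states B.
#' @param reward_correct reward for a correct prediction.
#' @return scalar reward in `{-penalty, 0, +reward_correct}`.
#' @export
reward_fn <- function(action, target, penalty, n_states,
                      reward_correct = 1) {
  stopifnot(action >= 1, action <= n_states + 1, target >= 1,
            target <= n_states, penalty >= 0)
  if (action == n_states + 1) 0
  else if (action == target) reward_correct
  else -penalty
}

## ---- optimiser ------------------------------------------------------------

adam_init <- function(par) {
  zeros <- lapply(par, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (any(!is.finite(g))) stop("non-finite gradients in ", nm)
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(par = par, opt = opt)
}

## ---- event rollout --------------------------------------------------------

#' Roll the agent through one event
#'
#' Runs [forward_step()] over every step of a rendered event, sampling (or
#' greedily choosing) an action and collecting the reward at each queried
#' step, and storing episodic snapshots of the post-retrieval cell state at
#' the event's configured encoding time points. Returns everything needed
#' for a gradient step ([a2c_update()] / [supervised_update()]) or for
#' analysis.
#'
#' @param model an `em_agent`.
#' @param ev one rendered event from [render_stimuli()].
#' @param state agent state at event onset (after any flush).
#' @param store the current `em_store`.
#' @param lca an `lca_params`.
#' @param em_on logical; `FALSE` silences the episodic module (no
#'   retrieval, no encoding).
#' @param action_mode `"sample"` or `"greedy"` (see [act()]).
#' @param penalty penalty magnitude used for rewards.
#' @param reward_correct reward for a correct prediction.
#' @param encode_at integer query-aligned time points at which to store a
#'   snapshot.
#' @param need_cache keep per-step caches for backpropagation.
#' @param gate_clamp optional constant overriding the EM gate (test hook).
#' @param provenance list with `trial` and `event` ids recorded with any
#'   stored snapshot.
#' @return list with final `state` and `store`, per-step vectors (`gate`,
#'   `value`, `action`, `reward`, `correct`, `dontknow`, `target`,
#'   `queried`), `policies` (steps x actions), `cells` (hidden x steps,
#'   post-retrieval), `act_mat` (memories x steps LCA activations, rows
#'   padded for memories not yet stored), `n_steps`, and `caches` when
#'   requested.
#' @export
rollout_event <- function(model, ev, state, store, lca = lca_params(),
                          em_on = TRUE, action_mode = "sample",
                          penalty = 0, reward_correct = 1,
                          encode_at = integer(0), need_cache = FALSE,
                          gate_clamp = NULL,
                          provenance = list(trial = NA_integer_,
                                            event = NA_integer_)) {
  n_steps <- ev$n_steps
  H <- model$cfg$hidden_dim
  A <- model$cfg$n_actions
  delay <- n_steps - length(unique(stats::na.omit(ev$queried)))
  encode_steps <- encode_at + (n_steps - model_event_T(ev))

  gate <- numeric(n_steps); value <- numeric(n_steps)
  action <- rep(NA_integer_, n_steps); reward <- rep(NA_real_, n_steps)
  policies <- matrix(NA_real_, n_steps, A)
  cells <- matrix(0, H, n_steps)
  caches <- if (need_cache) vector("list", n_steps) else NULL
  acts <- vector("list", n_steps)

  for (s in seq_len(n_steps)) {
    fs <- forward_step(model, ev$X[s, ], state, store, lca, em_on = em_on,
                       gate_clamp = gate_clamp, need_cache = need_cache)
    state <- fs$state
    gate[s] <- fs$out$em_gate
    value[s] <- fs$out$value
    policies[s, ] <- fs$out$policy
    cells[, s] <- state$c
    acts[[s]] <- fs$retrieval$activations
    if (need_cache) caches[[s]] <- fs$cache
    if (!is.na(ev$queried[s])) {
      action[s] <- act(fs$out$policy, mode = action_mode)
      reward[s] <- reward_fn(action[s], ev$target[s], penalty,
                             model$cfg$n_states, reward_correct)
    }
    if (em_on && s %in% encode_steps) {
      store <- em_encode(store, state$c, trial = provenance$trial,
                         event = provenance$event,
                         timepoint = s - (n_steps - model_event_T(ev)),
                         label = if (s == n_steps) "endpoint" else "midway")
    }
  }
  n_mem_final <- em_size(store)
  act_mat <- matrix(0, n_mem_final, n_steps)
  for (s in seq_len(n_steps)) {
    w <- acts[[s]]
    if (length(w) > 0) act_mat[seq_along(w), s] <- w
  }
  correct <- !is.na(action) & action == ev$target
  dontknow <- !is.na(action) & action == A
  list(state = state, store = store, gate = gate, value = value,
       action = action, reward = reward, correct = correct,
       dontknow = dontknow, target = ev$target, queried = ev$queried,
       observed_feature = ev$observed_feature, policies = policies,
       cells = cells, act_mat = act_mat, n_steps = n_steps,
       caches = caches)
}

model_event_T <- function(ev) sum(!is.na(ev$queried))

## ---- backpropagation through one event ------------------------------------

# Backward pass over a cached event rollout, given per-step gradients on the
# action logits and the value output. BPTT is truncated at event boundaries
# (the gradient step is taken after every event). Stored memories are
# constants (detached snapshots); the gate and the retrieval cue receive
# gradient through the unrolled accumulator cycles and the cosine evidence.
event_backward <- function(model, roll, store_M, dlogits, dv,
                           lca = lca_params()) {
  par <- model$par; cfg <- model$cfg
  H <- cfg$hidden_dim; Hd <- cfg$decision_dim
  input_dim <- cfg$input_dim
  g <- lapply(par, function(p) p * 0)
  tW_pi <- t(par$W_pi); tW_d <- t(par$W_d); tW_lstm <- t(par$W_lstm)
  dh_carry <- rep(0, H); dc_carry <- rep(0, H)
  S <- roll$n_steps
  # per-step factors of the weight gradients, accumulated as matrices so
  # the rank-one updates can be done in one crossproduct per event
  DA <- matrix(0, 4L * H, S); Z <- matrix(0, length(roll$caches[[1]]$z), S)
  DDpre <- matrix(0, Hd, S); Hnew <- matrix(0, H, S)
  DDprov <- matrix(0, Hd, S); Hprov <- matrix(0, H, S)
  Dmat <- matrix(0, Hd, S)

  for (s in rev(seq_len(S))) {
    cc <- roll$caches[[s]]
    dlg <- dlogits[s, ]
    dvs <- dv[s]

    dd <- as.numeric(tW_pi %*% dlg) + par$w_v * dvs
    g$b_pi <- g$b_pi + dlg
    g$w_v <- g$w_v + dvs * cc$d
    g$b_v <- g$b_v + dvs
    Dmat[, s] <- cc$d

    dd_pre <- dd * (cc$d_pre > 0)
    DDpre[, s] <- dd_pre; Hnew[, s] <- cc$h_new
    g$b_d <- g$b_d + dd_pre
    dh_new <- dh_carry + as.numeric(tW_d %*% dd_pre)

    do_ <- dh_new * cc$tanh_c_new
    dc_new <- dh_new * cc$go * (1 - cc$tanh_c_new^2) + dc_carry
    dc_prov <- dc_new

    dh_prov <- rep(0, H); dd_prov <- rep(0, Hd)
    if (cc$use_em && cc$n_mem > 0L) {
      Mn <- store_M[, seq_len(cc$n_mem), drop = FALSE]
      dw_fin <- as.numeric(crossprod(Mn, dc_new))
      lb <- lca_backward(cc$on_hist, cc$x_evid, cc$alpha,
                         lca$competition, dw_fin)
      if (!cc$gate_clamped) {
        dgate_pre <- lb$dgate * cc$alpha * (1 - cc$alpha)
        gate_in <- c(cc$h_prov, cc$d_prov)
        g$u_g <- g$u_g + dgate_pre * gate_in
        g$b_g <- g$b_g + dgate_pre
        dh_prov <- par$u_g[seq_len(H)] * dgate_pre
        dd_prov <- par$u_g[H + seq_len(Hd)] * dgate_pre
      }
      # evidence -> cue: x_i = cosine(c_prov, m_i)
      cue <- cc$c_prov
      cn2 <- sum(cue^2)
      if (cn2 > 0) {
        cn <- sqrt(cn2)
        mn <- sqrt(colSums(Mn^2))
        ok <- mn > 0 & lb$dx != 0
        if (any(ok)) {
          dc_prov <- dc_prov +
            as.numeric(Mn[, ok, drop = FALSE] %*%
                         (lb$dx[ok] / (mn[ok] * cn))) -
            cue * sum(lb$dx[ok] * cc$x_evid[ok]) / cn2
        }
      }
    }
    dd_prov_pre <- dd_prov * (cc$d_prov_pre > 0)
    if (any(dd_prov_pre != 0)) {
      DDprov[, s] <- dd_prov_pre; Hprov[, s] <- cc$h_prov
      g$b_d <- g$b_d + dd_prov_pre
      dh_prov <- dh_prov + as.numeric(tW_d %*% dd_prov_pre)
    }

    do_ <- do_ + dh_prov * cc$tanh_c_prov
    dc_prov <- dc_prov + dh_prov * cc$go * (1 - cc$tanh_c_prov^2)

    dgf <- dc_prov * cc$c_prev
    dgi <- dc_prov * cc$gg
    dgg <- dc_prov * cc$gi
    dc_carry <- dc_prov * cc$gf

    da <- c(dgi * cc$gi * (1 - cc$gi),
            dgf * cc$gf * (1 - cc$gf),
            do_ * cc$go * (1 - cc$go),
            dgg * (1 - cc$gg^2))
    DA[, s] <- da; Z[, s] <- cc$z
    g$b_lstm <- g$b_lstm + da
    dh_carry <- as.numeric(tW_lstm %*% da)[input_dim + seq_len(H)]
  }
  g$W_lstm <- tcrossprod(DA, Z)
  g$W_d <- tcrossprod(DDpre, Hnew) + tcrossprod(DDprov, Hprov)
  g$W_pi <- tcrossprod(t(dlogits), Dmat)
  g
}

## ---- gradient steps -------------------------------------------------------

#' One supervised gradient step on an event rollout
#'
#' Minimises the summed cross-entropy between the first B policy outputs
#' (renormalised by a softmax over the B state logits) and the target state
#' at every queried step. The "don't know" unit is excluded from the loss
#' and receives no gradient, and the episodic module is off during
#' pre-training, so neither the retrieval policy nor the abstention policy
#' is shaped by this phase.
#'
#' @param model an `em_agent`.
#' @param roll a cached rollout from [rollout_event()].
#' @param opt Adam optimiser state from `adam_init`.
#' @param lr learning rate.
#' @param lca the `lca_params` used during the rollout.
#' @return list with updated `model`, `opt`, and the event's summed
#'   cross-entropy `loss`.
#' @export
supervised_update <- function(model, roll, opt, lr = 7e-4,
                              lca = lca_params()) {
  stopifnot(!is.null(roll$caches))
  A <- model$cfg$n_actions; B <- model$cfg$n_states
  n <- roll$n_steps
  dlogits <- matrix(0, n, A)
  dv <- rep(0, n)
  loss <- 0
  for (s in seq_len(n)) {
    if (is.na(roll$queried[s])) next
    logits_b <- roll$caches[[s]]$logits[seq_len(B)]
    p <- softmax(logits_b)
    tgt <- roll$target[s]
    loss <- loss - log(max(p[tgt], 1e-12))
    dlogits[s, seq_len(B)] <- p
    dlogits[s, tgt] <- dlogits[s, tgt] - 1
  }
  if (!is.finite(loss)) stop("non-finite supervised loss")
  grads <- event_backward(model, roll, roll$store$M, dlogits, dv, lca)
  upd <- adam_step(model$par, grads, opt, lr)
  model$par <- upd$par
  list(model = model, opt = upd$opt, loss = loss)
}

#' One advantage actor-critic gradient step on an event rollout
#'
#' Implements the per-event policy-gradient step: for every queried step
#' the log-probability of the chosen action is weighted by the advantage
#' `r_t - v_t` (treated as a constant), an entropy bonus with coefficient
#' `entropy_coef` encourages exploration, and a squared-error value
#' regression term (coefficient `value_coef`) trains the critic. One Adam
#' step is taken on the summed objective.
#'
#' @param model an `em_agent`.
#' @param roll a cached rollout from [rollout_event()] with sampled
#'   actions and rewards.
#' @param opt Adam optimiser state.
#' @param lr learning rate.
#' @param entropy_coef entropy regularisation strength (eta).
#' @param value_coef weight of the critic's squared-error loss.
#' @param lca the `lca_params` used during the rollout (needed to
#'   backpropagate through retrieval).
#' @return list with updated `model`, `opt`, and the summed `loss`.
#' @export
a2c_update <- function(model, roll, opt, lr = 7e-4, entropy_coef = 0,
                       value_coef = 1, lca = lca_params()) {
  stopifnot(!is.null(roll$caches))
  A <- model$cfg$n_actions
  n <- roll$n_steps
  dlogits <- matrix(0, n, A)
  dv <- rep(0, n)
  loss <- 0
  for (s in seq_len(n)) {
    a <- roll$action[s]
    if (is.na(a)) next
    pol <- roll$policies[s, ]
    r <- roll$reward[s]
    v <- roll$value[s]
    adv <- r - v
    logp <- log(pmax(pol, 1e-12))
    ent <- -sum(pol * logp)
    loss <- loss - logp[a] * adv + value_coef * (v - r)^2 -
      entropy_coef * ent
    one_a <- rep(0, A); one_a[a] <- 1
    dlogits[s, ] <- adv * (pol - one_a) +
      entropy_coef * pol * (logp + ent)
    dv[s] <- 2 * value_coef * (v - r)
  }
  if (!is.finite(loss)) stop("non-finite actor-critic loss")
  grads <- event_backward(model, roll, roll$store$M, dlogits, dv, lca)
  upd <- adam_step(model$par, grads, opt, lr)
  model$par <- upd$par
  list(model = model, opt = upd$opt, loss = loss)
}

## ---- trial driver ---------------------------------------------------------

run_training_trial <- function(model, schema, lca, cfg, opt, phase,
                               condition, trial_id, entropy_coef) {
  # the penalty input channel is presented in both phases; rewards (and
  # hence the penalty's consequences) only exist in the RL phase
  penalty <- stats::runif(1, cfg$penalty_range[1], cfg$penalty_range[2])
  trial <- build_trial(condition, schema, penalty = penalty,
                       obs_drop_prob = cfg$obs_drop_prob,
                       delay_max = cfg$delay_max,
                       encode_at = cfg$encode_at)
  stim <- render_stimuli(trial, schema)
  state <- agent_state(model)
  store <- em_store(model$cfg$hidden_dim)
  em_on <- phase == "rl"
  stats_ <- c(loss = 0, reward = 0, correct = 0, dk = 0, n = 0)
  if (phase == "sl") {
    # supervised pre-training backpropagates through the whole trial:
    # the RM trial has no flushes, so the three events form one
    # continuous sequence and the cross-entropy gradient teaches the
    # network to carry situation features across event boundaries.
    # (The per-event update granularity is prescribed for the
    # actor-critic phase only.)
    ev_all <- list(
      X = do.call(rbind, lapply(stim, `[[`, "X")),
      target = unlist(lapply(stim, `[[`, "target")),
      queried = unlist(lapply(stim, `[[`, "queried")),
      observed_feature = unlist(lapply(stim, `[[`, "observed_feature")),
      observed_value = unlist(lapply(stim, `[[`, "observed_value")),
      n_steps = sum(vapply(stim, `[[`, integer(1), "n_steps"))
    )
    roll <- fast_event(model, ev_all, state, store, lca, phase = "sl",
                       penalty = trial$penalty,
                       reward_correct = cfg$reward_correct,
                       em_on = FALSE, value_coef = cfg$value_coef)
    upd <- adam_step_fast(model$par, roll$grads, opt,
                          lr = cfg$learning_rate)
    model$par <- upd$par; opt <- upd$opt
    q <- !is.na(roll$queried)
    preds <- apply(roll$policies[q, seq_len(model$cfg$n_states),
                                 drop = FALSE], 1, which.max)
    stats_["loss"] <- roll$loss
    stats_["correct"] <- sum(preds == roll$target[q])
    stats_["n"] <- sum(q)
    return(list(model = model, opt = opt, stats = stats_))
  }
  for (e in 1:3) {
    if (trial$flush_before_event[e]) state <- flush_state(model, state)
    roll <- fast_event(
      model, stim[[e]], state, store, lca, phase = phase,
      penalty = trial$penalty, reward_correct = cfg$reward_correct,
      encode_at = if (em_on) trial$encode_at[[e]] else integer(0),
      em_on = em_on, entropy_coef = entropy_coef,
      value_coef = cfg$value_coef, gamma = cfg$gamma,
      value_detached = isTRUE(cfg$value_detached),
      adv_norm = isTRUE(cfg$adv_norm),
      provenance = list(trial = trial_id, event = e)
    )
    state <- roll$state
    store <- roll$store
    upd <- adam_step_fast(model$par, roll$grads, opt,
                          lr = cfg$learning_rate)
    model$par <- upd$par; opt <- upd$opt
    q <- !is.na(roll$queried)
    stats_["loss"] <- stats_["loss"] + roll$loss
    stats_["reward"] <- stats_["reward"] + sum(roll$reward[q],
                                               na.rm = TRUE)
    if (phase == "rl") {
      stats_["correct"] <- stats_["correct"] + sum(roll$correct[q])
      stats_["dk"] <- stats_["dk"] + sum(roll$dontknow[q])
    } else {
      preds <- apply(roll$policies[q, seq_len(model$cfg$n_states),
                                   drop = FALSE], 1, which.max)
      stats_["correct"] <- stats_["correct"] +
        sum(preds == roll$target[q])
    }
    stats_["n"] <- stats_["n"] + sum(q)
  }
  list(model = model, opt = opt, stats = stats_)
}

#' Supervised pre-training phase
#'
#' Trains a fresh agent for `epochs_supervised` epochs on recent-memory
#' trials only, with the episodic module off, minimising cross-entropy on
#' the B state outputs; see [supervised_update()]. This phase teaches the
#' network the event schema and how to hold observed features in working
#' memory before reinforcement learning begins.
#'
#' @param model an `em_agent`.
#' @param schema an `event_schema`.
#' @param config an `em_config` (see [em_config()]).
#' @param opt optional Adam state (created if `NULL`).
#' @return list with trained `model`, `opt`, and a per-epoch `log`
#'   data.frame (phase, epoch, loss, mean reward, accuracy, don't-know
#'   rate).
#' @export
supervised_pretrain <- function(model, schema, config, opt = NULL) {
  if (is.null(opt)) opt <- adam_init(model$par)
  lca <- lca_params(config$competition, config$n_cycles)
  n_trials <- if (!is.null(config$sl_trials_per_epoch)) {
    config$sl_trials_per_epoch
  } else {
    config$trials_per_epoch
  }
  log <- vector("list", config$epochs_supervised)
  for (ep in seq_len(config$epochs_supervised)) {
    agg <- c(loss = 0, reward = 0, correct = 0, dk = 0, n = 0)
    for (k in seq_len(n_trials)) {
      res <- run_training_trial(model, schema, lca, config, opt,
                                phase = "sl", condition = "RM",
                                trial_id = k, entropy_coef = 0)
      model <- res$model; opt <- res$opt
      agg <- agg + res$stats
    }
    log[[ep]] <- data.frame(phase = "supervised", epoch = ep,
                            loss = agg[["loss"]] / agg[["n"]],
                            mean_reward = agg[["reward"]] / agg[["n"]],
                            accuracy = agg[["correct"]] / agg[["n"]],
                            dontknow_rate = agg[["dk"]] / agg[["n"]])
  }
  list(model = model, opt = opt, log = do.call(rbind, log))
}

#' Reinforcement learning phase
#'
#' Trains the full agent (episodic module on) for `epochs_rl` epochs with
#' the advantage actor-critic objective; every epoch visits all three
#' conditions (RM, DM, NM), the penalty is drawn uniformly from
#' `penalty_range` on each trial, actions are sampled from the policy, and
#' the entropy coefficient decays linearly to zero over the phase.
#'
#' @inheritParams supervised_pretrain
#' @return list with trained `model`, `opt`, and a per-epoch `log`.
#' @export
a2c_train <- function(model, schema, config, opt = NULL) {
  if (is.null(opt)) opt <- adam_init(model$par)
  lca <- lca_params(config$competition, config$n_cycles)
  conditions <- c("RM", "DM", "NM")
  log <- vector("list", config$epochs_rl)
  for (ep in seq_len(config$epochs_rl)) {
    eta <- config$entropy_coef *
      (1 - (ep - 1) / max(config$epochs_rl - 1, 1))
    agg <- c(loss = 0, reward = 0, correct = 0, dk = 0, n = 0)
    for (cond in conditions) {
      for (k in seq_len(config$trials_per_epoch)) {
        res <- run_training_trial(model, schema, lca, config, opt,
                                  phase = "rl", condition = cond,
                                  trial_id = k, entropy_coef = eta)
        model <- res$model; opt <- res$opt
        agg <- agg + res$stats
      }
    }
    log[[ep]] <- data.frame(phase = "rl", epoch = ep,
                            loss = agg[["loss"]] / agg[["n"]],
                            mean_reward = agg[["reward"]] / agg[["n"]],
                            accuracy = agg[["correct"]] / agg[["n"]],
                            dontknow_rate = agg[["dk"]] / agg[["n"]])
  }
  list(model = model, opt = opt, log = do.call(rbind, log))
}

#' Meta-train a cohort of agents
#'
#' For each seed: initialise a fresh agent and its own event schema (with
#' alternating schematic-parity counterbalancing, `parity = (i - 1) mod
#' 2`), run the supervised pre-training phase and then the reinforcement
#' learning phase. Fully deterministic given the seeds.
#'
#' @param config an `em_config`.
#' @param seeds integer seeds, one per model; defaults to
#'   `config$seed + 1..n_models`.
#' @return list of per-model results, each with `model`, `schema`, `seed`,
#'   `parity`, and the combined training `log`.
#' @export
meta_train <- function(config, seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed + seq_len(config$n_models)
  lapply(seq_along(seeds), function(i) {
    set.seed(seeds[i])
    parity <- (i - 1L) %% 2L
    schema <- event_schema(config$n_timepoints, config$n_states,
                           config$schema_strength, parity = parity)
    model <- agent_init(2L * config$n_timepoints + config$n_states + 1L,
                        config$hidden_dim, config$n_states,
                        decision_dim = config$decision_dim,
                        flush_hidden = config$flush_hidden)
    sl <- supervised_pretrain(model, schema, config)
    model_rl <- sl$model
    if (!is.null(config$gate_bias_rl)) {
      # start the RL phase with a mostly-closed gate, inside the region
      # where the policy gradient can still resolve costs and benefits
      # of retrieval (a wide-open gate floods working memory early on)
      model_rl$par$b_g <- config$gate_bias_rl
    }
    rl <- a2c_train(model_rl, schema, config, opt = sl$opt)
    list(model = rl$model, schema = schema, seed = seeds[i],
         parity = parity, log = rbind(sl$log, rl$log))
  })
}

## ---- meta-testing ---------------------------------------------------------

#' Evaluate a trained agent with frozen weights
#'
#' Generates fresh trials, runs the agent greedily with no gradient
#' updates, and records everything the analyses need: per-step behaviour,
#' gate values, memory activations with provenance, post-retrieval cell
#' states and observation bookkeeping. The episodic store is emptied at
#' every trial boundary; weights are never modified. Observations are
#' never dropped and queries are never delayed at test.
#'
#' @param model a trained `em_agent`.
#' @param schema the `event_schema` the model was trained on.
#' @param config an `em_config`.
#' @param condition `"RM"`, `"DM"` or `"NM"`.
#' @param n_trials number of fresh trials to evaluate.
#' @param penalty test penalty (defaults to `config$test_penalty`).
#' @param encode_at query-aligned encoding time points (defaults to the
#'   config's policy, normally the event endpoint).
#' @param gate_clamp optional constant EM gate (test hook).
#' @param em_on set `FALSE` to disable the episodic store entirely.
#' @return list of rollout records, one per trial; each has `condition`,
#'   `penalty`, `situations`, per-event rollouts (`events`), the final
#'   `store`, and `target_event` tags (`"target"`, `"lure"`, `"current"`)
#'   for each stored memory relative to part 2.
#' @export
meta_test <- function(model, schema, config, condition = "DM",
                      n_trials = 20L, penalty = NULL, encode_at = NULL,
                      gate_clamp = NULL, em_on = TRUE) {
  if (is.null(penalty)) penalty <- config$test_penalty
  if (is.null(encode_at)) encode_at <- config$encode_at
  if (is.null(encode_at)) encode_at <- schema$n_timepoints
  lca <- lca_params(config$competition, config$n_cycles)
  lapply(seq_len(n_trials), function(tid) {
    trial <- build_trial(condition, schema, penalty = penalty,
                         obs_drop_prob = 0, delay_max = 0L,
                         encode_at = encode_at)
    stim <- render_stimuli(trial, schema)
    state <- agent_state(model)
    store <- em_store(model$cfg$hidden_dim)
    events <- vector("list", 3)
    for (e in 1:3) {
      if (trial$flush_before_event[e]) state <- flush_state(model, state)
      roll <- fast_event(
        model, stim[[e]], state, store, lca, phase = "test",
        penalty = penalty, reward_correct = config$reward_correct,
        encode_at = trial$encode_at[[e]], em_on = em_on,
        gate_clamp = gate_clamp,
        provenance = list(trial = tid, event = e)
      )
      state <- roll$state
      store <- roll$store
      roll$store <- NULL
      roll$grads <- NULL
      events[[e]] <- roll
    }
    prov <- store$provenance
    mem_tag <- vapply(seq_len(nrow(prov)), function(i) {
      if (prov$event[i] == 3L) "current"
      else if (identical(trial$situations[[prov$event[i]]],
                         trial$situations[[3]])) "target"
      else "lure"
    }, character(1))
    list(condition = condition, penalty = penalty,
         situations = trial$situations, trial = trial, events = events,
         store = store, mem_tag = mem_tag, mem_label = prov$label,
         mem_event = prov$event)
  })
}
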