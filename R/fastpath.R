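## Compiled fast path. fast_event() mirrors rollout_event() (and, for the
## training phases, the head-gradient + event_backward combination) through
## a single C++ call; the pure-R functions remain the reference
## implementation and the two paths are checked against each other in the
## test suite.

fast_event <- function(model, ev, state, store, lca, phase,
                       penalty = 0, reward_correct = 1,
                       encode_at = integer(0), em_on = TRUE,
                       gate_clamp = NULL, entropy_coef = 0,
                       value_coef = 1, gamma = NULL,
                       value_detached = TRUE, adv_norm = FALSE,
                       provenance = list(trial = NA_integer_,
                                         event = NA_integer_)) {
  n_steps <- ev$n_steps
  T_ <- sum(!is.na(ev$queried))
  delay <- n_steps - T_
  encode_at <- sort(as.integer(encode_at))
  encode_steps <- encode_at + delay
  queried <- ifelse(is.na(ev$queried), 0L, ev$queried)
  target <- ifelse(is.na(ev$target), 0L, ev$target)
  phase_i <- match(phase, c("sl", "rl", "test")) - 1L

  res <- .event_core(model$par, ev$X, as.integer(queried),
                     as.integer(target), state$h, state$c, store$M,
                     phase_i, as.integer(encode_steps), lca$competition,
                     lca$n_cycles, em_on,
                     if (is.null(gate_clamp)) -1 else gate_clamp,
                     penalty, reward_correct, entropy_coef, value_coef,
                     if (is.null(gamma)) -1 else gamma, value_detached,
                     adv_norm)

  new_mem <- res$new_memories
  if (ncol(new_mem) > 0) {
    for (j in seq_len(ncol(new_mem))) {
      store <- em_encode(store, new_mem[, j], trial = provenance$trial,
                         event = provenance$event,
                         timepoint = encode_at[j],
                         label = if (encode_at[j] == T_) "endpoint"
                                 else "midway")
    }
  }
  n_final <- em_size(store)
  act_mat <- res$act_mat[seq_len(n_final), , drop = FALSE]
  if (n_final == 0) act_mat <- matrix(0, 0, n_steps)
  correct <- !is.na(res$action) & res$action == ev$target
  dontknow <- !is.na(res$action) & res$action == model$cfg$n_actions
  list(state = list(h = res$h, c = res$c), store = store,
       gate = res$gate, value = res$value, action = res$action,
       reward = res$reward, correct = correct, dontknow = dontknow,
       target = ev$target, queried = ev$queried,
       observed_feature = ev$observed_feature, policies = res$policies,
       cells = res$cells, act_mat = act_mat, n_steps = n_steps,
       loss = res$loss, grads = res$grads)
}

adam_step_fast <- function(par, grads, opt, lr) {
  opt$t <- opt$t + 1L
  upd <- .adam_core(par, grads, opt$m, opt$v, opt$t, lr, 0.9, 0.999, 1e-8)
  list(par = upd$par, opt = list(m = upd$m, v = upd$v, t = opt$t))
}
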