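#' Initialise the neocortical network
#'
#' The neocortical part of the model is an LSTM core feeding a rectified
#' nonlinear decision layer; the LSTM hidden state and the decision
#' activation jointly drive a scalar episodic-memory (EM) gate through a
#' logistic unit, and the decision activation drives a softmax actor head
#' over `n_states + 1` actions (one per next-state prediction plus a
#' dedicated "don't know" action) and a scalar critic head. Weights are
#' initialised uniformly in `+/- 1/sqrt(fan-in)` from the current RNG
#' stream; the gate bias starts at 0, i.e. a half-open gate.
#'
#' @param input_dim input dimensionality, `2T + B + 1` for the event task.
#' @param hidden_dim LSTM hidden/cell size.
#' @param n_states number of states B; the actor head has `B + 1` units.
#' @param decision_dim size of the decision layer (defaults to
#'   `hidden_dim`).
#' @param flush_hidden if `TRUE` (default) a working-memory flush zeroes
#'   the hidden state as well as the cell state, so no situation
#'   information survives the flush.
#' @return an object of class `em_agent` holding parameters and
#'   configuration.
#' @export
agent_init <- function(input_dim, hidden_dim, n_states,
                       decision_dim = hidden_dim, flush_hidden = TRUE) {
  H <- as.integer(hidden_dim); Hd <- as.integer(decision_dim)
  A <- as.integer(n_states) + 1L
  D <- as.integer(input_dim) + H
  u <- function(nr, nc, fan) {
    k <- 1 / sqrt(fan)
    matrix(stats::runif(nr * nc, -k, k), nrow = nr, ncol = nc)
  }
  b_lstm <- as.numeric(u(4L * H, 1L, H))
  b_lstm[H + seq_len(H)] <- 1          # forget-gate bias: retain by default
  par <- list(
    W_lstm = u(4L * H, D, H),          # rows: input, forget, output, cand
    b_lstm = b_lstm,
    W_d    = u(Hd, H, H),
    b_d    = as.numeric(u(Hd, 1L, H)),
    u_g    = as.numeric(u(H + Hd, 1L, H + Hd)),
    b_g    = 0,
    W_pi   = u(A, Hd, Hd),
    b_pi   = as.numeric(u(A, 1L, Hd)),
    w_v    = as.numeric(u(Hd, 1L, Hd)),
    b_v    = 0
  )
  structure(
    list(par = par,
         cfg = list(input_dim = as.integer(input_dim), hidden_dim = H,
                    decision_dim = Hd, n_states = as.integer(n_states),
                    n_actions = A, flush_hidden = isTRUE(flush_hidden))),
    class = "em_agent"
  )
}

#' A fresh (zeroed) agent state
#' @param model an `em_agent`.
#' @return list with `h` (hidden) and `c` (cell) zero vectors.
#' @export
agent_state <- function(model) {
  H <- model$cfg$hidden_dim
  list(h = rep(0, H), c = rep(0, H))
}

#' Flush working memory
#'
#' Resets the cell state (the working-memory substrate) to zero; by default
#' the hidden state is reset too (`flush_hidden` in [agent_init()]), since a
#' surviving hidden state would leak situation information across the
#' flush. Idempotent.
#'
#' @param model an `em_agent`.
#' @param state an agent state.
#' @return the flushed state.
#' @export
flush_state <- function(model, state) {
  state$c <- rep(0, model$cfg$hidden_dim)
  if (model$cfg$flush_hidden) state$h <- rep(0, model$cfg$hidden_dim)
  state
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' One forward step of the agent
#'
#' The ordered computation within a step: (1) a standard LSTM update from
#' the input yields a provisional hidden/cell state; (2) a provisional
#' decision activation is computed from the provisional hidden state; (3)
#' the EM gate `alpha` is read out from the concatenated hidden and
#' decision activations through a logistic unit; (4) competitive retrieval
#' ([lca_retrieve()]) with the provisional cell state as cue and gate
#' `alpha` returns the retrieved pattern `mu`; (5) `mu` is added to the
#' cell state and the hidden state is recomputed through the LSTM output
#' gate; (6) the final decision activation, the policy over `B + 1`
#' actions, and the value estimate are computed from the updated hidden
#' state. Retrieval therefore informs the very step on which it happens.
#' With an empty store (or `em_on = FALSE`) the step reduces exactly to a
#' plain recurrent step.
#'
#' @param model an `em_agent`.
#' @param x input vector of length `input_dim`.
#' @param state agent state (`h`, `c`).
#' @param store an `em_store` (may be empty).
#' @param lca an `lca_params` object.
#' @param em_on logical; `FALSE` disables the episodic module entirely.
#' @param gate_clamp optional scalar in `[0, 1]`: test hook that overrides
#'   the computed gate value (the clamp is treated as a constant, so no
#'   gradient flows into the gate path).
#' @param need_cache if `TRUE`, return every intermediate needed for
#'   backpropagation.
#' @return list with `out` (`policy`, `value`, `em_gate`, `decision`),
#'   `state` (updated), `retrieval` (`mu`, `activations`, `evidence`), and
#'   optionally `cache`.
#' @export
forward_step <- function(model, x, state, store = NULL,
                         lca = lca_params(), em_on = TRUE,
                         gate_clamp = NULL, need_cache = FALSE) {
  par <- model$par; cfg <- model$cfg
  H <- cfg$hidden_dim
  if (any(!is.finite(x))) stop("non-finite input activations")
  z <- c(x, state$h)
  pre <- as.numeric(par$W_lstm %*% z) + par$b_lstm
  gi <- sigmoid(pre[seq_len(H)])
  gf <- sigmoid(pre[H + seq_len(H)])
  go <- sigmoid(pre[2L * H + seq_len(H)])
  gg <- tanh(pre[3L * H + seq_len(H)])
  c_prov <- gf * state$c + gi * gg
  tanh_c_prov <- tanh(c_prov)
  h_prov <- go * tanh_c_prov

  d_prov_pre <- as.numeric(par$W_d %*% h_prov) + par$b_d
  d_prov <- pmax(d_prov_pre, 0)

  gate_in <- c(h_prov, d_prov)
  gate_pre <- sum(par$u_g * gate_in) + par$b_g
  alpha <- sigmoid(gate_pre)
  clamped <- !is.null(gate_clamp)
  if (clamped) alpha <- gate_clamp

  use_em <- em_on && !is.null(store) && em_size(store) > 0L
  if (use_em) {
    ret <- lca_retrieve(store, c_prov, alpha, lca, history = need_cache)
    mu <- ret$mu
  } else {
    ret <- list(mu = rep(0, H), activations = numeric(0),
                evidence = numeric(0))
    mu <- ret$mu
  }
  c_new <- c_prov + mu
  tanh_c_new <- tanh(c_new)
  h_new <- go * tanh_c_new

  d_pre <- as.numeric(par$W_d %*% h_new) + par$b_d
  d <- pmax(d_pre, 0)
  logits <- as.numeric(par$W_pi %*% d) + par$b_pi
  policy <- softmax(logits)
  value <- sum(par$w_v * d) + par$b_v
  if (any(!is.finite(policy)) || !is.finite(value)) {
    stop("non-finite activations in forward step (training divergence)")
  }

  out <- list(
    out = list(policy = policy, value = value, em_gate = alpha,
               decision = d),
    state = list(h = h_new, c = c_new),
    retrieval = list(mu = mu, activations = ret$activations,
                     evidence = ret$evidence)
  )
  if (need_cache) {
    out$cache <- list(
      z = z, gi = gi, gf = gf, go = go, gg = gg,
      c_prev = state$c, c_prov = c_prov, tanh_c_prov = tanh_c_prov,
      h_prov = h_prov, d_prov_pre = d_prov_pre, d_prov = d_prov,
      alpha = alpha, gate_clamped = clamped, use_em = use_em,
      n_mem = if (use_em) length(ret$activations) else 0L,
      x_evid = ret$evidence, w_hist = ret$w_hist,
      on_hist = ret$on_hist, w = ret$activations,
      mu = mu, c_new = c_new, tanh_c_new = tanh_c_new, h_new = h_new,
      d_pre = d_pre, d = d, logits = logits, policy = policy,
      value = value
    )
  }
  out
}

#' Select an action from a policy
#'
#' @param policy probability vector over the `B + 1` actions.
#' @param mode `"sample"` (training) draws from the distribution;
#'   `"greedy"` (evaluation) takes the argmax with lowest-index
#'   tie-breaking.
#' @return action index in `1..(B + 1)`; the last index is "don't know".
#' @export
act <- function(policy, mode = c("sample", "greedy")) {
  mode <- match.arg(mode)
  stopifnot(all(policy >= 0), abs(sum(policy) - 1) < 1e-6)
  if (mode == "greedy") which.max(policy)
  else sample.int(length(policy), 1L, prob = policy)
}
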