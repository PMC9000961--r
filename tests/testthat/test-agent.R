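test_that("forward step produces a valid policy and bounded gate", {
  ts <- tiny_setup()
  set.seed(11)
  x <- rnorm(ts$model$cfg$input_dim)
  state <- agent_state(ts$model)
  store <- em_store(ts$model$cfg$hidden_dim)
  for (k in 1:20) {
    fs <- forward_step(ts$model, x + rnorm(length(x), sd = 0.5), state,
                       store, ts$lca)
    state <- fs$state
    expect_true(all(fs$out$policy >= 0))
    expect_equal(sum(fs$out$policy), 1, tolerance = 1e-6)
    expect_gte(fs$out$em_gate, 0)
    expect_lte(fs$out$em_gate, 1)
  }
  expect_error(forward_step(ts$model, rep(NaN, ts$model$cfg$input_dim),
                            state, store, ts$lca), "non-finite")
})

test_that("empty store reduces to a plain recurrent step", {
  ts <- tiny_setup(seed = 2)
  set.seed(12)
  x <- rnorm(ts$model$cfg$input_dim)
  state <- agent_state(ts$model)
  empty <- em_store(ts$model$cfg$hidden_dim)
  a <- forward_step(ts$model, x, state, empty, ts$lca, em_on = TRUE)
  b <- forward_step(ts$model, x, state, empty, ts$lca, em_on = FALSE)
  expect_equal(a$out, b$out)
  expect_equal(a$state, b$state)
  expect_equal(a$retrieval$mu, rep(0, ts$model$cfg$hidden_dim))
})

test_that("a zero-clamped gate reproduces the no-retrieval dynamics", {
  ts <- tiny_setup(seed = 3)
  set.seed(13)
  store <- em_store(ts$model$cfg$hidden_dim)
  for (i in 1:3) store <- em_encode(store, rnorm(ts$model$cfg$hidden_dim))
  x <- rnorm(ts$model$cfg$input_dim)
  state <- list(h = rnorm(10) * 0.1, c = rnorm(10) * 0.3)
  clamped <- forward_step(ts$model, x, state, store, ts$lca,
                          gate_clamp = 0)
  silenced <- forward_step(ts$model, x, state, store, ts$lca,
                           em_on = FALSE)
  expect_equal(clamped$state, silenced$state)
  expect_equal(clamped$out$policy, silenced$out$policy)
  # and the clamped step's cell equals the provisional (pre-retrieval) cell
  expect_equal(clamped$retrieval$mu, rep(0, 10))
})

test_that("determinism: identical inputs give bit-identical outputs", {
  ts <- tiny_setup(seed = 4)
  set.seed(14)
  store <- em_store(10)
  for (i in 1:2) store <- em_encode(store, rnorm(10))
  x <- rnorm(ts$model$cfg$input_dim)
  state <- list(h = rnorm(10), c = rnorm(10))
  a <- forward_step(ts$model, x, state, store, ts$lca)
  b <- forward_step(ts$model, x, state, store, ts$lca)
  expect_identical(a, b)
})

test_that("action selection: tie-breaks, sampling frequencies", {
  expect_equal(act(c(0, 0, 1, 0), "greedy"), 3L)
  expect_equal(act(c(0, 0, 1, 0), "sample"), 3L)
  expect_equal(act(rep(0.25, 4), "greedy"), 1L)  # lowest-index tie-break
  set.seed(15)
  p <- c(0.5, 0.3, 0.15, 0.05)
  draws <- replicate(20000, act(p, "sample"))
  freq <- tabulate(draws, 4) / 20000
  se <- sqrt(p * (1 - p) / 20000)
  expect_true(all(abs(freq - p) < 3 * se + 1e-3))
})

test_that("flush zeroes working memory, idempotently and historylessly", {
  ts <- tiny_setup(seed = 5)
  set.seed(16)
  state <- list(h = rnorm(10), c = rnorm(10))
  f1 <- flush_state(ts$model, state)
  expect_equal(f1$c, rep(0, 10))
  expect_equal(f1$h, rep(0, 10))
  expect_identical(flush_state(ts$model, f1), f1)
  # post-flush processing with an empty store is independent of history
  x <- rnorm(ts$model$cfg$input_dim)
  store <- em_store(10)
  from_flushed <- forward_step(ts$model, x, f1, store, ts$lca)
  from_fresh <- forward_step(ts$model, x, agent_state(ts$model), store,
                             ts$lca)
  expect_equal(from_flushed$out, from_fresh$out)
  # cell-only flush is available as a configuration switch
  m2 <- ts$model; m2$cfg$flush_hidden <- FALSE
  f2 <- flush_state(m2, state)
  expect_equal(f2$c, rep(0, 10))
  expect_equal(f2$h, state$h)
})

test_that("compiled event core agrees with the reference forward pass", {
  set.seed(21)
  T_ <- 6L; B <- 4L; H <- 8L
  schema <- event_schema(T_, B)
  model <- agent_init(2L * T_ + B + 1L, H, B)
  lca <- lca_params(0.8, 10)
  trial <- build_trial("DM", schema, penalty = 2, delay_max = 2)
  stim <- render_stimuli(trial, schema)
  store <- em_store(H)
  for (i in 1:3) store <- em_encode(store, rnorm(H))
  state <- list(h = rnorm(H) * 0.1, c = rnorm(H) * 0.3)
  for (e in 2:3) {
    ref <- rollout_event(model, stim[[e]], state, store, lca,
                         action_mode = "greedy", penalty = 2,
                         encode_at = c(3L, T_), need_cache = FALSE)
    fast <- emagent:::fast_event(model, stim[[e]], state, store, lca,
                                 phase = "test", penalty = 2,
                                 encode_at = c(3L, T_))
    expect_equal(fast$policies, ref$policies, tolerance = 1e-12)
    expect_equal(fast$gate, ref$gate, tolerance = 1e-12)
    expect_equal(fast$cells, ref$cells, tolerance = 1e-12)
    expect_equal(fast$act_mat, ref$act_mat, tolerance = 1e-12)
    expect_identical(fast$action, ref$action)
    expect_equal(fast$store$M, ref$store$M, tolerance = 1e-12)
    state <- ref$state
    store <- ref$store
  }
})

test_that("compiled gradients agree with the reference backward pass", {
  set.seed(22)
  T_ <- 5L; B <- 3L; H <- 7L
  schema <- event_schema(T_, B)
  model <- agent_init(2L * T_ + B + 1L, H, B)
  lca <- lca_params(0.8, 10)
  trial <- build_trial("RM", schema, penalty = 1.5, delay_max = 1)
  stim <- render_stimuli(trial, schema)
  store <- em_store(H)
  for (i in 1:2) store <- em_encode(store, rnorm(H))
  state <- list(h = rnorm(H) * 0.1, c = rnorm(H) * 0.2)
  ev <- stim[[1]]
  A <- B + 1L
  # actor-critic: force the same actions in the reference path
  fast <- emagent:::fast_event(model, ev, state, store, lca, phase = "rl",
                               penalty = 1.5, encode_at = integer(0),
                               entropy_coef = 0.02, value_coef = 1,
                               value_detached = FALSE)
  ref <- rollout_event(model, ev, state, store, lca,
                       action_mode = "greedy", penalty = 1.5,
                       encode_at = integer(0), need_cache = TRUE)
  ref$action <- fast$action
  ref$reward <- fast$reward
  dlogits <- matrix(0, ref$n_steps, A)
  dv <- rep(0, ref$n_steps)
  for (s in seq_len(ref$n_steps)) {
    a <- ref$action[s]
    if (is.na(a)) next
    pol <- ref$policies[s, ]
    logp <- log(pmax(pol, 1e-12))
    ent <- -sum(pol * logp)
    adv <- ref$reward[s] - ref$value[s]
    one <- rep(0, A); one[a] <- 1
    dlogits[s, ] <- adv * (pol - one) + 0.02 * pol * (logp + ent)
    dv[s] <- 2 * (ref$value[s] - ref$reward[s])
  }
  grads <- emagent:::event_backward(model, ref, ref$store$M, dlogits, dv,
                                    lca)
  for (nm in names(grads)) {
    expect_equal(fast$grads[[nm]], grads[[nm]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("analytic event gradients match finite differences", {
  set.seed(23)
  T_ <- 4L; B <- 3L; H <- 5L
  schema <- event_schema(T_, B)
  model <- agent_init(2L * T_ + B + 1L, H, B)
  lca <- lca_params(0.8, 10)
  trial <- build_trial("RM", schema, penalty = 1.5, delay_max = 2)
  ev <- render_stimuli(trial, schema)[[1]]
  store <- em_store(H)
  for (i in 1:3) store <- em_encode(store, rnorm(H))
  state0 <- list(h = rnorm(H) * 0.1, c = rnorm(H) * 0.3)
  set.seed(7)
  roll <- rollout_event(model, ev, state0, store, lca,
                        action_mode = "sample", penalty = 1.5,
                        encode_at = integer(0), need_cache = TRUE)
  eta <- 0.013
  adv0 <- roll$reward - roll$value  # frozen advantages
  A <- B + 1L
  dlogits <- matrix(0, roll$n_steps, A)
  dv <- rep(0, roll$n_steps)
  for (s in seq_len(roll$n_steps)) {
    a <- roll$action[s]
    if (is.na(a)) next
    pol <- roll$policies[s, ]
    logp <- log(pmax(pol, 1e-12))
    ent <- -sum(pol * logp)
    one <- rep(0, A); one[a] <- 1
    dlogits[s, ] <- adv0[s] * (pol - one) + eta * pol * (logp + ent)
    dv[s] <- 2 * (roll$value[s] - roll$reward[s])
  }
  ga <- emagent:::event_backward(model, roll, roll$store$M, dlogits, dv,
                                 lca)
  # surrogate loss with frozen advantages and actions
  loss_fn <- function(par) {
    m2 <- model; m2$par <- par
    st <- state0; L <- 0
    for (s in seq_len(ev$n_steps)) {
      fs <- forward_step(m2, ev$X[s, ], st, store, lca)
      st <- fs$state
      a <- roll$action[s]
      if (!is.na(a)) {
        pol <- fs$out$policy
        logp <- log(pmax(pol, 1e-12))
        ent <- -sum(pol * logp)
        L <- L - logp[a] * adv0[s] +
          (fs$out$value - roll$reward[s])^2 - eta * ent
      }
    }
    L
  }
  eps <- 1e-6
  set.seed(9)
  for (nm in names(model$par)) {
    p <- model$par[[nm]]
    idx <- if (length(p) > 4) sample(seq_along(p), 4) else seq_along(p)
    for (i in idx) {
      pp <- model$par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model$par; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(ga[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})
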