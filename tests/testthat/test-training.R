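test_that("rewards take only the three allowed values", {
  expect_equal(reward_fn(5, 2, penalty = 4, n_states = 4), 0)   # don't know
  expect_equal(reward_fn(2, 2, penalty = 2, n_states = 4), 1)   # correct
  expect_equal(reward_fn(1, 2, penalty = 2, n_states = 4), -2)  # wrong
  expect_equal(reward_fn(3, 3, penalty = 0, n_states = 4), 1)
  expect_equal(reward_fn(1, 3, penalty = 0, n_states = 4), 0)   # no cost
  set.seed(31)
  for (k in 1:200) {
    pen <- runif(1, 0, 4)
    a <- sample(1:5, 1); tgt <- sample(1:4, 1)
    r <- reward_fn(a, tgt, pen, 4)
    expect_true(r %in% c(-pen, 0, 1))
  }
})

test_that("an a2c step moves the policy in the advantage direction", {
  set.seed(32)
  T_ <- 4L; B <- 3L; H <- 8L
  schema <- event_schema(T_, B)
  model <- agent_init(2L * T_ + B + 1L, H, B)
  lca <- lca_params(0.8, 10)
  ev <- render_stimuli(build_trial("RM", schema, penalty = 0), schema)[[1]]
  state <- agent_state(model)
  store <- em_store(H)
  # single-step rollout with a hand-set positive advantage: the chosen
  # action's probability must increase after the update
  roll <- rollout_event(model, ev, state, store, lca,
                        action_mode = "sample", penalty = 0,
                        need_cache = TRUE)
  roll$action[] <- NA
  roll$action[1] <- 2L
  roll$reward[] <- NA
  roll$reward[1] <- 1        # value starts near 0 -> positive advantage
  roll$store <- store
  before <- roll$policies[1, 2]
  opt <- adam_init(model$par)
  upd <- a2c_update(model, roll, opt, lr = 0.01, entropy_coef = 0)
  probe <- rollout_event(upd$model, ev, state, store, lca,
                         action_mode = "greedy", penalty = 0)
  expect_gt(probe$policies[1, 2], before)
})

test_that("the entropy term alone raises policy entropy", {
  set.seed(33)
  T_ <- 4L; B <- 3L; H <- 8L
  schema <- event_schema(T_, B)
  model <- agent_init(2L * T_ + B + 1L, H, B)
  lca <- lca_params(0.8, 10)
  ev <- render_stimuli(build_trial("RM", schema, penalty = 0), schema)[[1]]
  state <- agent_state(model)
  store <- em_store(H)
  roll <- rollout_event(model, ev, state, store, lca,
                        action_mode = "sample", penalty = 0,
                        need_cache = TRUE)
  # zero advantage everywhere: set rewards equal to values
  roll$reward[!is.na(roll$action)] <- roll$value[!is.na(roll$action)]
  roll$store <- store
  ent <- function(p) -sum(p * log(pmax(p, 1e-12)))
  before <- mean(apply(roll$policies, 1, ent))
  opt <- adam_init(model$par)
  upd <- a2c_update(model, roll, opt, lr = 0.01, entropy_coef = 0.5,
                    value_coef = 0)
  probe <- rollout_event(upd$model, ev, state, store, lca,
                         action_mode = "greedy", penalty = 0)
  expect_gt(mean(apply(probe$policies, 1, ent)), before)
})

test_that("supervised pre-training leaves the abstention unit untouched
           and beats chance at small scale", {
  cfg <- em_config("reduced", n_timepoints = 6L, hidden_dim = 24L,
                   decision_dim = 24L, epochs_supervised = 12L,
                   epochs_rl = 1L, sl_trials_per_epoch = 60L,
                   trials_per_epoch = 4L, n_models = 1L)
  set.seed(34)
  schema <- event_schema(cfg$n_timepoints, cfg$n_states)
  model <- agent_init(2L * cfg$n_timepoints + cfg$n_states + 1L,
                      cfg$hidden_dim, cfg$n_states)
  dk <- cfg$n_states + 1L
  w_dk_before <- model$par$W_pi[dk, ]
  b_dk_before <- model$par$b_pi[dk]
  sl <- supervised_pretrain(model, schema, cfg)
  # the don't-know row of the actor head receives no gradient
  expect_equal(sl$model$par$W_pi[dk, ], w_dk_before)
  expect_equal(sl$model$par$b_pi[dk], b_dk_before)
  # chance-level loss at the start, above-chance accuracy at the end
  expect_equal(sl$log$loss[1], log(cfg$n_states), tolerance = 0.12)
  expect_gt(mean(tail(sl$log$accuracy, 3)), 1 / cfg$n_states + 0.05)
  expect_equal(nrow(sl$log), 12L)
})

test_that("meta-training is reproducible and logs every epoch", {
  cfg <- em_config("reduced", n_timepoints = 4L, hidden_dim = 12L,
                   decision_dim = 12L, epochs_supervised = 2L,
                   epochs_rl = 2L, trials_per_epoch = 3L,
                   sl_trials_per_epoch = 3L, n_models = 2L)
  c1 <- meta_train(cfg, seeds = c(7L, 8L))
  c2 <- meta_train(cfg, seeds = c(7L, 8L))
  expect_equal(c1[[1]]$model$par, c2[[1]]$model$par)
  expect_equal(c1[[2]]$model$par, c2[[2]]$model$par)
  expect_equal(nrow(c1[[1]]$log), 4L)
  expect_equal(c1[[1]]$parity, 0L)
  expect_equal(c1[[2]]$parity, 1L)
  # schematic counterbalancing by parity
  expect_equal(c1[[1]]$schema$schematic_mask,
               !c1[[2]]$schema$schematic_mask)
})

test_that("gate-layer weights change during reinforcement learning", {
  cfg <- em_config("reduced", n_timepoints = 4L, hidden_dim = 12L,
                   decision_dim = 12L, epochs_supervised = 1L,
                   epochs_rl = 3L, trials_per_epoch = 6L,
                   sl_trials_per_epoch = 2L, n_models = 1L,
                   gate_bias_rl = NULL)
  set.seed(36)
  schema <- event_schema(cfg$n_timepoints, cfg$n_states)
  model <- agent_init(2L * cfg$n_timepoints + cfg$n_states + 1L,
                      cfg$hidden_dim, cfg$n_states)
  sl <- supervised_pretrain(model, schema, cfg)
  # EM is off in pre-training: gate weights still at initialisation
  expect_equal(sl$model$par$u_g, model$par$u_g)
  rl <- a2c_train(sl$model, schema, cfg, opt = sl$opt)
  expect_false(isTRUE(all.equal(rl$model$par$u_g, model$par$u_g)))
  expect_false(identical(rl$model$par$b_g, model$par$b_g))
})

test_that("meta-testing freezes weights, empties the store per trial and
           uses greedy actions", {
  cfg <- em_config("reduced", n_timepoints = 5L, hidden_dim = 14L,
                   decision_dim = 14L, epochs_supervised = 1L,
                   epochs_rl = 1L, trials_per_epoch = 2L,
                   sl_trials_per_epoch = 2L, n_models = 1L)
  set.seed(37)
  schema <- event_schema(cfg$n_timepoints, cfg$n_states)
  model <- agent_init(2L * cfg$n_timepoints + cfg$n_states + 1L,
                      cfg$hidden_dim, cfg$n_states)
  par_before <- model$par
  rolls <- meta_test(model, schema, cfg, condition = "DM", n_trials = 5)
  expect_identical(model$par, par_before)
  for (r in rolls) {
    # store holds exactly this trial's snapshots (one per event)
    expect_equal(em_size(r$store), 3L)
    expect_equal(r$store$provenance$event, 1:3)
    # part-2 rate decomposition sums to 1 at every time point
    ev3 <- r$events[[3]]
    rates <- ev3$correct + ev3$dontknow +
      (!ev3$correct & !ev3$dontknow)
    expect_equal(as.numeric(rates), rep(1, ev3$n_steps))
    # memory tags: event-1 memory is a lure, event-2 the target
    expect_equal(r$mem_tag, c("lure", "target", "current"))
  }
  # penalty sampling during training stays within the configured range
  set.seed(38)
  pens <- replicate(300, {
    tr <- build_trial("DM", schema,
                      penalty = runif(1, cfg$penalty_range[1],
                                      cfg$penalty_range[2]))
    tr$penalty
  })
  expect_true(all(pens >= 0 & pens <= 4))
  ks <- suppressWarnings(stats::ks.test(pens, "punif", 0, 4))
  expect_gt(ks$p.value, 1e-4)
})
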