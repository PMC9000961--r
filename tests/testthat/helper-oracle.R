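# Independent straight-line oracle for the competitive accumulator:
# iterates the printed synchronous update directly, one accumulator at a
# time, reading previous-cycle activations. Deliberately naive (scalar
# loops, no shared code with the package implementation).
lca_oracle <- function(x, alpha, beta, n_cycles) {
  n <- length(x)
  w <- rep(0, n)
  for (tau in seq_len(n_cycles)) {
    w_new <- numeric(n)
    for (i in seq_len(n)) {
      drive <- alpha * x[i] - beta * sum(w[-i])
      w_new[i] <- max(0, drive)
    }
    w <- w_new
  }
  w
}

# build an em_store holding the given vectors (columns)
make_store <- function(M) {
  store <- em_store(nrow(M))
  for (j in seq_len(ncol(M))) store <- em_encode(store, M[, j])
  store
}

# a small trained-free agent + environment bundle for mechanical tests
tiny_setup <- function(T_ = 6L, B = 3L, H = 10L, seed = 1) {
  set.seed(seed)
  schema <- event_schema(T_, B)
  model <- agent_init(2L * T_ + B + 1L, H, B)
  list(schema = schema, model = model, lca = lca_params(0.8, 10L))
}

# Synthetic "working memory" states with a planted linear code: feature f's
# value v is written into a dedicated block of units once observed, plus
# small isotropic noise. Separable by construction; used by the decoding
# sanity checks.
planted_rollouts <- function(n_trials = 30L, T_ = 4L, B = 3L,
                             noise = 0.05, seed = 1) {
  set.seed(seed)
  H <- T_ * B
  lapply(seq_len(n_trials), function(i) {
    situation <- sample.int(B, T_, replace = TRUE)
    obs_order <- sample.int(T_)
    mk_event <- function(gate) {
      cells <- matrix(rnorm(H * T_, sd = noise), H, T_)
      for (s in seq_len(T_)) {
        seen <- obs_order[seq_len(s)]
        for (f in seen) {
          cells[(f - 1L) * B + situation[f], s] <-
            cells[(f - 1L) * B + situation[f], s] + 1
        }
      }
      list(cells = cells, n_steps = T_, gate = gate,
           observed_feature = obs_order, queried = seq_len(T_))
    }
    list(situations = list(situation, situation, situation),
         events = list(NULL, mk_event(rep(0, T_)),
                       mk_event(rep(0.01, T_))))
  })
}
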