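#' Build an event schema
#'
#' An event schema is the generative graph of the task: a sequence of
#' `n_timepoints` time points, each with `n_states` possible states and a
#' categorical distribution over them. At a *schematic* time point one
#' "prototypical" state occurs with probability `schema_strength` and the
#' remaining states share `(1 - s) / (B - 1)`; at non-schematic time points
#' all states are equally likely. The default strength `1/B` makes every
#' time point uniform (the baseline environment).
#'
#' Schematic time points alternate with non-schematic ones; `parity = 0`
#' makes even time points schematic, `parity = 1` odd ones, so that cohorts
#' of agents can be counterbalanced (`parity = model_index mod 2`).
#' Prototypical states are drawn once, at schema construction, from the
#' current RNG stream.
#'
#' @param n_timepoints number of time points T (default 16).
#' @param n_states number of states per time point B (default 4).
#' @param schema_strength probability of the prototypical state at
#'   schematic time points, in `[1/B, 1]`.
#' @param parity 0 or 1; which alternating half of the time points is
#'   schematic.
#' @return an object of class `event_schema` with fields `n_timepoints`,
#'   `n_states`, `state_probs` (T x B, rows sum to 1), `schematic_mask`,
#'   and `prototypes` (NA at non-schematic time points).
#' @export
event_schema <- function(n_timepoints = 16L, n_states = 4L,
                         schema_strength = 1 / n_states, parity = 0L) {
  T_ <- as.integer(n_timepoints); B <- as.integer(n_states)
  stopifnot(T_ >= 1, B >= 2, parity %in% c(0L, 1L))
  stopifnot(schema_strength >= 1 / B - 1e-12, schema_strength <= 1)
  mask <- (seq_len(T_) %% 2L) == parity
  prototypes <- rep(NA_integer_, T_)
  probs <- matrix(1 / B, nrow = T_, ncol = B)
  for (t in which(mask)) {
    proto <- sample.int(B, 1L)
    prototypes[t] <- proto
    probs[t, ] <- (1 - schema_strength) / (B - 1)
    probs[t, proto] <- schema_strength
  }
  schema <- structure(
    list(n_timepoints = T_, n_states = B, state_probs = probs,
         schematic_mask = mask, prototypes = prototypes,
         schema_strength = schema_strength, parity = as.integer(parity)),
    class = "event_schema"
  )
  validate_schema(schema)
  schema
}

validate_schema <- function(schema) {
  stopifnot(inherits(schema, "event_schema"))
  stopifnot(all(abs(rowSums(schema$state_probs) - 1) < 1e-9))
  stopifnot(all(schema$state_probs >= 0))
  invisible(schema)
}

#' Number of distinct state sequences an event can follow
#'
#' Each time point independently takes one of B states, so the event space
#' has cardinality `B^T` (about 4.3e9 at the default T = 16, B = 4 -- far
#' too many to memorise, which is what makes schema learning necessary).
#'
#' @param schema an `event_schema`.
#' @return the count `B^T`, as a double.
#' @export
count_state_sequences <- function(schema) {
  validate_schema(schema)
  as.numeric(schema$n_states)^schema$n_timepoints
}

#' Sample a situation from a schema
#'
#' A situation is one feature value per time point, drawn independently from
#' that time point's categorical state distribution. The situation
#' deterministically controls the state transitions of any event generated
#' from it.
#'
#' @param schema an `event_schema`.
#' @return integer vector of length T with values in `1..B`.
#' @export
sample_situation <- function(schema) {
  validate_schema(schema)
  vapply(seq_len(schema$n_timepoints), function(t) {
    sample.int(schema$n_states, 1L, prob = schema$state_probs[t, ])
  }, integer(1))
}

#' Build one trial of the event-prediction task
#'
#' Every trial contains exactly three events. In the recent-memory (RM) and
#' distant-memory (DM) conditions the agent first processes a distractor
#' event from one situation and then two related events sharing a second
#' situation ("part 1" and "part 2" of the movie); in the no-memory (NM)
#' condition the three events come from three independently drawn
#' situations. In DM the working memory state is flushed before the third
#' event (capturing a one-day gap between the movie parts); in RM nothing
#' is flushed; in NM the flush happens before every event after the first,
#' so no working-memory content survives across events.
#'
#' During training-mode generation each observation in the first two events
#' is independently dropped with probability `obs_drop_prob` (so the agent
#' only sees ~70 percent of part-1 features at the default 0.3), and the
#' prediction demand of every event is delayed by a shared random number of
#' time points in `0..delay_max`; at test both are disabled.
#'
#' @param condition one of "RM", "DM", "NM".
#' @param schema an `event_schema`.
#' @param penalty penalty magnitude for wrong predictions on this trial
#'   (>= 0), presented to the agent as a raw scalar input.
#' @param obs_drop_prob per-feature probability of dropping an observation
#'   in part-1 events.
#' @param delay_max maximum query delay (inclusive); the delay is drawn
#'   uniformly from `0..delay_max`.
#' @param encode_at integer time points (query-aligned) at which a snapshot
#'   is stored in each event; the default is the final time point only.
#' @return an object of class `em_trial`.
#' @export
build_trial <- function(condition, schema, penalty = 2,
                        obs_drop_prob = 0, delay_max = 0L,
                        encode_at = NULL) {
  condition <- match.arg(condition, c("RM", "DM", "NM"))
  validate_schema(schema)
  stopifnot(penalty >= 0, obs_drop_prob >= 0, obs_drop_prob <= 1,
            delay_max >= 0)
  T_ <- schema$n_timepoints
  if (is.null(encode_at)) encode_at <- T_
  stopifnot(all(encode_at >= 1), all(encode_at <= T_))

  if (condition == "NM") {
    situations <- list(sample_situation(schema), sample_situation(schema),
                       sample_situation(schema))
    flush <- c(FALSE, TRUE, TRUE)
  } else {
    distractor <- sample_situation(schema)
    shared <- sample_situation(schema)
    situations <- list(distractor, shared, shared)
    flush <- if (condition == "DM") c(FALSE, FALSE, TRUE) else rep(FALSE, 3)
  }
  obs_order <- lapply(1:3, function(e) sample.int(T_))
  obs_mask <- lapply(1:3, function(e) {
    if (e < 3 && obs_drop_prob > 0) stats::runif(T_) >= obs_drop_prob
    else rep(TRUE, T_)
  })
  delay <- if (delay_max > 0) sample.int(delay_max + 1L, 1L) - 1L else 0L

  structure(
    list(condition = condition, situations = situations,
         observation_order = obs_order, observation_mask = obs_mask,
         penalty = penalty, delay = as.integer(delay),
         flush_before_event = flush,
         encode_at = rep(list(sort(as.integer(encode_at))), 3)),
    class = "em_trial"
  )
}

#' Render a trial as input/target vector sequences
#'
#' Each event is rendered as a sequence of `T + delay` steps. At step s the
#' input vector concatenates four components: the observed situation
#' feature (T-dim one-hot; all-zero when the observation was dropped or the
#' observation stream is exhausted), its value (B-dim one-hot), the queried
#' feature (T-dim one-hot; queries follow the fixed diagonal order t =
#' 1..T, starting after the delay prefix), and the trial's penalty scalar
#' -- `2T + B + 1` input dimensions in total. Observations follow the
#' event's random `observation_order` while queries are always in time
#' order, so a feature may be queried before it has been observed (working
#' memory cannot answer; episodic memory might) or after (working memory
#' suffices). During the delay prefix observations are presented but no
#' query is posed and no target is defined.
#'
#' @param trial an `em_trial`.
#' @param schema the `event_schema` the trial was generated from.
#' @return a list with one element per event, each containing `X` (steps x
#'   `2T+B+1` input matrix), `target` (queried feature value per step, NA at
#'   non-query steps), `queried` (queried time point per step, NA in the
#'   delay prefix), `observed_feature` and `observed_value` (NA when
#'   nothing is observed), and `n_steps`.
#' @export
render_stimuli <- function(trial, schema) {
  stopifnot(inherits(trial, "em_trial"))
  validate_schema(schema)
  T_ <- schema$n_timepoints; B <- schema$n_states
  delay <- trial$delay
  n_steps <- T_ + delay
  input_dim <- 2L * T_ + B + 1L
  lapply(1:3, function(e) {
    situation <- trial$situations[[e]]
    ord <- trial$observation_order[[e]]
    mask <- trial$observation_mask[[e]]
    X <- matrix(0, nrow = n_steps, ncol = input_dim)
    target <- rep(NA_integer_, n_steps)
    queried <- rep(NA_integer_, n_steps)
    obs_feature <- rep(NA_integer_, n_steps)
    obs_value <- rep(NA_integer_, n_steps)
    for (s in seq_len(n_steps)) {
      if (s <= T_) {
        f <- ord[s]
        if (mask[f]) {
          X[s, f] <- 1
          X[s, T_ + situation[f]] <- 1
          obs_feature[s] <- f
          obs_value[s] <- situation[f]
        }
      }
      q <- s - delay
      if (q >= 1 && q <= T_) {
        X[s, T_ + B + q] <- 1
        queried[s] <- q
        target[s] <- situation[q]
      }
      X[s, input_dim] <- trial$penalty
    }
    list(X = X, target = target, queried = queried,
         observed_feature = obs_feature, observed_value = obs_value,
         n_steps = n_steps)
  })
}

#' Serialize trials to JSON-lines
#'
#' One trial per line: condition, situations, observation orders and masks,
#' penalty, delay, flush flags and encoding time points. `read_trials`
#' round-trips exactly.
#'
#' @param trials a list of `em_trial` objects.
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` a list of
#'   `em_trial` objects.
#' @export
write_trials <- function(trials, path) {
  lines <- vapply(trials, function(tr) {
    jsonlite::toJSON(unclass(tr), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  as_list_of <- function(x, cast) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) cast(x[i, ]))
    else lapply(x, cast)
  }
  lapply(readLines(path), function(line) {
    raw <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    structure(
      list(condition = raw$condition,
           situations = as_list_of(raw$situations, as.integer),
           observation_order = as_list_of(raw$observation_order, as.integer),
           observation_mask = as_list_of(raw$observation_mask, as.logical),
           penalty = raw$penalty, delay = as.integer(raw$delay),
           flush_before_event = as.logical(raw$flush_before_event),
           encode_at = as_list_of(raw$encode_at, as.integer)),
      class = "em_trial"
    )
  })
}
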