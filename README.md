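# emagent

When should an agent retrieve an episodic memory, and when should it
store one? `emagent` implements a computational model of
neocortical-hippocampal interaction that answers these questions by
*learning* a retrieval policy: a recurrent (LSTM) network predicts
upcoming states of unfolding events, and a trainable scalar gate decides
on every time step how strongly to consult an episodic store of past
network states. The package is aimed at computational cognitive
neuroscientists studying event cognition and memory-system interactions.

## The model in brief

The neocortical network maintains a *situation model* in its LSTM cell
state `c` (working memory), extracts task regularities into its weights
(semantic memory), and controls an episodic-memory gate `α ∈ [0, 1]`.
The hippocampal store holds snapshots `m_i` of past cell states; retrieval
is a leaky-competing-accumulator competition without leak or noise,

    x_i = cosine(c, m_i)
    w_i ← relu(α x_i − β Σ_{j≠i} w_j),   β = 0.8, w_i(0) = 0

run to completion within one time step; the activation-weighted pattern
`μ = Σ_i w_i m_i` is added back to the cell state before the step's
prediction. The agent answers next-state queries with `B + 1` actions
(`B` states plus an explicit "don't know" worth exactly zero reward;
wrong answers cost a penalty). Meta-training is supervised pre-training
(cross-entropy, recent-memory condition only, episodic module off)
followed by advantage actor-critic with entropy regularisation
(`∑_t log π(a_t)(r_t − v_t) + η H`), one gradient step per event, Adam at
7e-4. Evaluation freezes all weights: only working memory and the
episodic store carry trial-specific information.

The synthetic environment generates event schemas (T time points, B
states each), situations that deterministically control transitions, and
three-event trials in the recent-memory (RM), distant-memory (DM, working
memory flushed before part 2) and no-memory (NM) conditions, with
configurable penalty, schema strength, observation dropping and query
delays.

## Worked example

```r
library(emagent)
set.seed(1)

# a uniform event schema: 8 time points, 4 states each
schema <- event_schema(n_timepoints = 8, n_states = 4)
trial <- build_trial("DM", schema, penalty = 2)
stim <- render_stimuli(trial, schema)
cat("input dimensions per step:", ncol(stim[[1]]$X), "\n")
cat("shared situation (events 2 and 3):",
    paste(trial$situations[[3]], collapse = " "), "\n")

# competitive retrieval from a two-memory store
store <- em_store(dim = 4)
store <- em_encode(store, c(1, 0.2, 0, 0), label = "endpoint")  # target-ish
store <- em_encode(store, c(0, 0, 1, 0.2), label = "endpoint")  # lure-ish
cue <- c(0.9, 0.1, 0.2, 0)
ret <- lca_retrieve(store, cue, gate = 1, params = lca_params(0.8, 10))
cat("evidence:   ", paste(round(ret$evidence, 3), collapse = "  "), "\n")
cat("activations:", paste(round(ret$activations, 3), collapse = "  "), "\n")
```

prints

```
input dimensions per step: 21
shared situation (events 2 and 3): 4 3 1 3 4 1 3 1
evidence:    0.973  0.211
activations: 0.973  0
```

The input has `2T + B + 1 = 21` dimensions (observed feature, observed
value, query, penalty). The cue resembles the first memory (cosine 0.97
vs 0.21); with competition 0.8 the accumulator race is winner-take-all,
so the lure is fully suppressed and the retrieved pattern is ~0.97 times
the target memory.

End-to-end runs go through `meta_train()` / `meta_test()` and the
analysis functions (`run_condition_eval()`, `recall_time()`,
`conditional_gate_analysis()`, `schema_sweep()`,
`encoding_policy_experiment()`, `similarity_analysis()`,
`build_labels()` / `train_decoders()` / `decode_map()`), or the
command-line wrapper `inst/scripts/emagent.R`:

```sh
Rscript inst/scripts/emagent.R conditions --seed 1 --out out/
```

See the vignette (`vignettes/retrieval-policy.Rmd`) for the full model
description, every tunable parameter, and the design decisions behind the
desk-scale (reduced) preset.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch at the reduced scale:
it meta-trains an agent (supervised pre-training then actor-critic),
evaluates it with frozen weights in the RM/DM/NM conditions, runs the
penalty, encoding-policy and working-memory-similarity analyses, trains
the working-memory decoders, logs the resulting summary numbers to the
console, and writes the results JSON to `--out`. Expect roughly 6-8
minutes on one CPU.
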