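---
title: "Learning when to retrieve: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning when to retrieve: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`emagent` simulates neocortical-hippocampal interaction during event
understanding. The *neocortical* part is an LSTM whose cell state `c` acts
as working memory, feeding a rectified decision layer, a softmax actor
over `B + 1` actions (one per candidate next state plus a dedicated
"don't know"), a linear critic, and a scalar *episodic-memory gate*
`alpha` read out from the hidden and decision activations through a
logistic unit. The *hippocampal* part is an append-only store of cell-state
snapshots. Retrieval is competitive evidence accumulation: memory `i`
receives evidence `x_i = cosine(c, m_i)` and the accumulators iterate

    w_i <- relu(alpha * x_i - beta * sum_{j != i} w_j)

synchronously (each accumulator reads the others' previous-cycle
activations) for a fixed number of cycles, with no leak and no noise. The
retrieved pattern `mu = sum_i w_i m_i` is added to the cell state *within*
the current step, before the step's prediction, so retrieval can inform
the very answer that prompted it. `alpha = 0` silences retrieval;
`beta = 0.8` keeps it strongly competitive (near winner-take-all).

Within one forward step the order is: (1) LSTM update; (2) provisional
decision activation; (3) gate read-out; (4) retrieval with the provisional
cell state as cue; (5) `c <- c + mu`, hidden state recomputed through the
LSTM output gate; (6) final decision activation, policy, value.

## The task

An *event schema* is a sequence of `T` time points with `B` possible states
each; a *situation* assigns one value per time point and deterministically
controls the transitions. At each step the agent observes one situation
feature (in random order) and is queried about the upcoming state (in
fixed order), so a feature may be queried before it has been observed —
working memory cannot answer, episodic memory might. Inputs concatenate
observed-feature one-hot (T), observed-value one-hot (B), query one-hot
(T), and the trial's penalty scalar: `2T + B + 1` dimensions.

Every trial has three events. In RM (recent memory) and DM (distant
memory) a distractor event `a1` precedes two events `b1`, `b2` sharing a
situation; DM flushes working memory (cell state zeroed) between `b1` and
`b2`, RM does not. NM (no memory) uses three unrelated situations with a
flush before every event after the first, so nothing carries over.
Snapshots are stored, by an imposed policy, at the final time point of
each event (optionally also midway). During part 2 of a DM trial the only
route to the shared situation is retrieving `b1`'s endpoint snapshot while
rejecting `a1`'s lure.

Rewards: +1 for a correct prediction, `-penalty` for a wrong one, exactly
0 for "don't know". The penalty is drawn uniformly from [0, 4] per
training trial (and is an input), fixed at 2 for testing.

## Training

Meta-training has two phases at learning rate 7e-4 (Adam):

1. **Supervised pre-training** on RM trials only, episodic module off,
   cross-entropy on the B state outputs with the "don't know" unit
   excluded from the loss (so neither the abstention policy nor the
   retrieval policy is shaped here).
2. **Advantage actor-critic** on all three conditions, one gradient step
   after every event: the summed per-step log-probability of the chosen
   action weighted by the advantage (treated as constant), an entropy
   bonus decaying linearly to zero, and a squared-error critic term.

During training 30% of part-1 observations are dropped and the prediction
demand of each event is delayed by a uniform 0–3 steps (observations are
presented during the prefix, queries withheld, no reward); both are
disabled at test. Meta-testing freezes all weights, empties the store at
each trial boundary, and acts greedily.

## Tunable parameters

| parameter | default (paper / reduced) | meaning |
|---|---|---|
| `n_timepoints` T | 16 / 8 | event length = number of situation features |
| `n_states` B | 4 | states per time point; chance = 1/B |
| `hidden_dim` | 194 / 64 | LSTM size; working-memory capacity |
| `competition` beta | 0.8 | lateral inhibition between accumulators |
| `n_cycles` | 10 | accumulation cycles per step (runs to completion) |
| `learning_rate` | 7e-4 | Adam step size, both phases |
| `epochs_supervised/rl` | 600+400 / 100+100 | phase lengths |
| `trials_per_epoch` | 256 / 56 (RL), 576 (supervised) | epoch size per condition |
| `penalty_range` | [0, 4] | per-trial training penalty (uniform) |
| `test_penalty` | 2 | evaluation penalty |
| `entropy_coef` eta | 0.01 / 0.05 | entropy bonus, decays linearly to 0 |
| `obs_drop_prob` | 0.3 | part-1 observation dropping (training only) |
| `delay_max` | 3 | maximum query delay (training only) |
| `schema_strength` | 0.25 | prototypical-state probability (0.25 = uniform) |

The number of accumulation cycles is unstated in the source material
("a fixed number of time steps"); 10 suffices for the competition to
resolve in every regime we tested and is exposed in the configuration.

## Numerical and design choices

* **Synchronous accumulator update.** The printed recurrence references
  the other accumulators at the same cycle, which is circular; we use the
  previous cycle's activations on the right-hand side (the standard
  discretisation).
* **Zero-norm cosine.** The cue is all-zero at trial start; its cosine is
  defined as 0 (no retrieval pull). Same for zero-norm memories.
* **Gradients.** Stored memories are constants (detached snapshots); the
  gate and the retrieval cue receive gradients through the unrolled
  accumulator cycles and the cosine evidence. BPTT truncates at event
  boundaries in the RL phase (one update per event). All gradients are
  verified against finite differences and an independent pure-R reference
  implementation in the test suite.
* **Flush scope.** A flush zeroes the cell state; by default it zeroes the
  hidden state too (a surviving hidden state leaks situation information
  across the gap), switchable via `flush_hidden`.
* **Value head.** The printed objective has no critic loss; without one
  the advantage is meaningless, so a squared-error regression term is
  added. In the reduced preset it trains the value head only
  (`value_detached`), see below.
* **Ties and degenerate cases.** Greedy action selection breaks ties at
  the lowest index. Decoders fall back to a mid-path ridge penalty (or a
  majority-class constant) when a label class is too sparse for inner
  cross-validation. The decode map counts "don't know" predictions as not
  decoded. The EM-gate "peak" for decoding labels is the global maximum of
  the part-2 gate trace; below a floor of 0.05 no reinstatement labels are
  applied.

## The reduced preset: what desk-scale training needs, and why

The full-scale world (T = 16, 194 hidden units, 600+400 epochs, 15
models) takes hours per model on one CPU. The `"reduced"` preset is a
desk-scale world (T = 8, 64 hidden units, 100+100 epochs, 3 models) used
by the test suite. Four of its choices deviate from a naive scale-down and
were forced by measurement, not taste:

1. **64 hidden units (not 32).** At H = 32 the supervised phase never
   learns to carry situation features across event boundaries: RM part-2
   accuracy stays at the within-event ceiling (~0.67) after 100k+ trials,
   whereas at H = 64 it reaches 0.99 given a long enough supervised phase
   (~100k trials; the budget-constrained preset trains ~58k and lands
   around 0.7-0.9). Every retrieval phenomenon depends on that carryover
   (the endpoint snapshot is only informative if working memory
   accumulated the situation).
2. **Trial-level BPTT in the supervised phase.** Per-event truncation
   removes the gradient that teaches event-2 encoding to serve event-3
   queries; the per-event step is prescribed for the actor-critic phase
   only.
3. **Detached critic and per-event advantage standardisation.** With the
   critic loss backpropagating into shared weights, its large, initially
   uncalibrated gradients drive the EM gate to zero before a retrieval
   policy can form; unnormalised advantages let rare large penalties
   dominate the gate's credit.
4. **Gate-bias warm start (alpha ~ 0.19) at the RL hand-off.** Direct
   measurement of the policy-gradient landscape in the reduced world shows
   retrieval is beneficial only for alpha in roughly [0.1, 0.3]: below,
   the accumulator competition cannot resolve and the retrieved pattern is
   a corrupting blend; above, lures flood working memory. Reinforcement
   learning must start inside that basin to sample it.

**Known limitation.** Even with these aids, the learned equilibrium gate
level in the reduced world is very small. The cause is quantitative, not
mechanical: with T = 8, observations resolve most queries within a few
steps, so the expected-reward margin of retrieval (~ +0.05 per step,
confined to DM part 2) is outweighed by its risks elsewhere (clamping the
gate open at 0.3–0.5 raises DM part-2 accuracy by ~0.1, confirming the
mechanism works when exercised). The learned *gate* is demand-sensitive in
direction — higher in DM than RM in every seed we trained — but memory
*activation* is gate times cosine evidence, and the evidence term is
larger in RM (a fully specified working memory resembles the target
snapshot more than a flushed one does), so with near-zero gates the
DM-versus-RM contrast in target-memory activation inverts relative to the
full-scale regime; accuracy-level retrieval effects (DM over NM) are
present but marginal. The strong forms of both effects belong to the
T = 16 regime, where working-memory gaps persist for half an event and
the gate equilibrium is far from zero. A green reduced-scale test
therefore establishes the machinery and the direction of the learned
policy, not the full-scale effect sizes; conversely a red directional
test at this scale may reflect the scaled world, not a defect in the
method.

## What the generator does and does not emulate

The synthetic environment reproduces the structure that matters for
encoding/retrieval policy: situation-controlled deterministic transitions,
fixed query order against random observation order, partial observability
(dropping), variable prediction-demand onset (delays), penalty variation,
and the RM/DM/NM manipulation of memory demand and availability. It does
not emulate hierarchical or multi-schema events, repeated queries within a
sequence, feature values that drift within an event, or any perceptual
front end — so green tests say nothing about those.
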