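#' Create an empty episodic memory store
#'
#' The episodic store is an append-only list of snapshots of the agent's
#' working-memory substrate (the LSTM cell state). Each stored memory keeps a
#' provenance record (trial, event, time point and an encoding-policy label)
#' so that later analyses can separate target from lure memories and
#' endpoint-encoded from midway-encoded ones.
#'
#' @param dim dimensionality of the stored vectors (the agent's hidden size).
#' @return an object of class `em_store`.
#' @export
em_store <- function(dim) {
  stopifnot(is.numeric(dim), length(dim) == 1L, dim >= 1)
  structure(
    list(
      M = matrix(numeric(0), nrow = as.integer(dim), ncol = 0L),
      provenance = data.frame(
        trial = integer(0), event = integer(0), timepoint = integer(0),
        label = character(0), stringsAsFactors = FALSE
      )
    ),
    class = "em_store"
  )
}

#' Number of memories in a store
#' @param store an `em_store`.
#' @return integer count.
#' @export
em_size <- function(store) ncol(store$M)

#' Encode (append) a snapshot into the episodic store
#'
#' Appends an exact copy of `cell`; stored memories are never mutated
#' afterwards and their order is preserved.
#'
#' @param store an `em_store`.
#' @param cell numeric vector to snapshot (the current cell state).
#' @param trial,event,timepoint integer provenance fields.
#' @param label encoding-policy label, e.g. `"endpoint"` or `"midway"`.
#' @return the grown `em_store`.
#' @export
em_encode <- function(store, cell, trial = NA_integer_, event = NA_integer_,
                      timepoint = NA_integer_, label = "endpoint") {
  stopifnot(inherits(store, "em_store"), length(cell) == nrow(store$M))
  store$M <- cbind(store$M, as.numeric(cell))
  store$provenance <- rbind(
    store$provenance,
    data.frame(trial = as.integer(trial), event = as.integer(event),
               timepoint = as.integer(timepoint), label = label,
               stringsAsFactors = FALSE)
  )
  store
}

#' Cosine-similarity evidence for every stored memory
#'
#' Evidence for memory i is `cosine(cue, m_i)`, in `[-1, 1]`. A zero-norm cue
#' or memory yields evidence 0 by convention: at the start of a trial the
#' cell state is all zeros and should exert no retrieval pull.
#'
#' @param store an `em_store` (or a plain matrix with memories as columns).
#' @param cue numeric cue vector (the current cell state).
#' @return numeric vector of evidence values, one per memory.
#' @export
em_evidence <- function(store, cue) {
  M <- if (inherits(store, "em_store")) store$M else store
  if (ncol(M) == 0L) return(numeric(0))
  cue_norm <- sqrt(sum(cue^2))
  if (cue_norm == 0) return(rep(0, ncol(M)))
  m_norms <- sqrt(colSums(M^2))
  x <- as.numeric(crossprod(M, cue)) / (m_norms * cue_norm)
  x[m_norms == 0] <- 0
  x
}

#' Parameters of the competitive accumulator retrieval process
#'
#' Retrieval runs a simplified leaky competing accumulator: no leak, no
#' noise, and a single gate and competition value shared by all
#' accumulators. `competition` is the lateral-inhibition strength; 0.8 keeps
#' retrieval strongly competitive (closer to winner-take-all than to
#' averaging across memories).
#'
#' @param competition lateral inhibition strength (beta), >= 0.
#' @param n_cycles number of synchronous accumulation cycles; the process
#'   runs to completion within a single time step of the agent.
#' @return an object of class `lca_params`.
#' @export
lca_params <- function(competition = 0.8, n_cycles = 10L) {
  stopifnot(is.numeric(competition), length(competition) == 1L,
            competition >= 0, is.finite(competition))
  stopifnot(is.numeric(n_cycles), length(n_cycles) == 1L, n_cycles >= 1)
  structure(list(competition = competition, n_cycles = as.integer(n_cycles)),
            class = "lca_params")
}

#' Competitive retrieval from the episodic store
#'
#' Accumulator activations start at zero and are updated synchronously for
#' `n_cycles` cycles:
#' \deqn{w_i \leftarrow \mathrm{relu}(\alpha x_i - \beta \sum_{j \ne i} w_j)}
#' where each accumulator reads the other accumulators' previous-cycle
#' activations, `x_i` is the cosine evidence for memory i, `alpha` is the
#' retrieval gate set by the neocortical network and `beta` the competition.
#' The retrieved pattern is the activation-weighted sum of all memories,
#' `mu = sum_i w_i m_i`. The process is fully deterministic.
#'
#' @param store an `em_store`.
#' @param cue current cell-state cue.
#' @param gate scalar retrieval gate alpha in `[0, 1]`; 0 silences retrieval.
#' @param params an `lca_params` object.
#' @param history if `TRUE`, also return the per-cycle activation history
#'   and rectifier masks needed to backpropagate through the accumulation.
#' @return list with `mu` (retrieved vector, zero vector if the store is
#'   empty), `activations` (final `w_i`, all >= 0), `evidence`, and
#'   optionally `w_hist` / `on_hist`.
#' @export
lca_retrieve <- function(store, cue, gate, params = lca_params(),
                         history = FALSE) {
  stopifnot(inherits(store, "em_store"), inherits(params, "lca_params"))
  n <- ncol(store$M)
  if (n == 0L) {
    return(list(mu = rep(0, nrow(store$M)), activations = numeric(0),
                evidence = numeric(0)))
  }
  x <- em_evidence(store, cue)
  beta <- params$competition
  w <- rep(0, n)
  on_hist <- if (history) matrix(FALSE, n, params$n_cycles) else NULL
  w_hist <- if (history) matrix(0, n, params$n_cycles) else NULL
  for (tau in seq_len(params$n_cycles)) {
    inhib <- sum(w) - w
    pre <- gate * x - beta * inhib
    on <- pre > 0
    w <- ifelse(on, pre, 0)
    if (history) {
      on_hist[, tau] <- on
      w_hist[, tau] <- w
    }
  }
  mu <- as.numeric(store$M %*% w)
  out <- list(mu = mu, activations = w, evidence = x)
  if (history) {
    out$w_hist <- w_hist
    out$on_hist <- on_hist
  }
  out
}

# Reverse-mode pass through the accumulation cycles. Given the gradient on
# the final activations, returns the gradients on the gate and on the
# per-memory evidence. The synchronous update reads previous-cycle
# activations, so the adjoint walks the cycles backwards using the saved
# rectifier masks.
lca_backward <- function(on_hist, x, gate, beta, dw_final) {
  n <- length(x)
  dw <- dw_final
  dgate <- 0
  dx <- rep(0, n)
  for (tau in rev(seq_len(ncol(on_hist)))) {
    dpre <- ifelse(on_hist[, tau], dw, 0)
    dgate <- dgate + sum(dpre * x)
    dx <- dx + gate * dpre
    dw <- -beta * (sum(dpre) - dpre)
  }
  list(dgate = dgate, dx = dx)
}

#' Write / read an episodic store as plain-text CSV
#'
#' The memory matrix and the provenance table are written as two CSV files
#' (`<path>_memories.csv`, `<path>_provenance.csv`); the round-trip is exact
#' at full double precision.
#'
#' @param store an `em_store`.
#' @param path base path (without suffix).
#' @return `write_store` returns `path` invisibly; `read_store` returns the
#'   reconstructed `em_store`.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "em_store"))
  mem <- as.data.frame(store$M)
  names(mem) <- paste0("m", seq_len(max(ncol(store$M), 0)))[seq_len(ncol(store$M))]
  utils::write.csv(format(mem, digits = 17, scientific = TRUE, trim = TRUE),
                   paste0(path, "_memories.csv"), row.names = FALSE)
  utils::write.csv(store$provenance, paste0(path, "_provenance.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_store
#' @param dim hidden dimensionality, needed to reconstruct an empty store.
#' @export
read_store <- function(path, dim) {
  mem_path <- paste0(path, "_memories.csv")
  prov_path <- paste0(path, "_provenance.csv")
  mem <- utils::read.csv(mem_path)
  store <- em_store(dim)
  if (ncol(mem) > 0 && nrow(mem) > 0) {
    store$M <- as.matrix(vapply(mem, as.numeric, numeric(nrow(mem))))
    if (nrow(mem) == 1L) store$M <- matrix(as.numeric(unlist(mem)), nrow = 1L)
    dimnames(store$M) <- NULL
    stopifnot(nrow(store$M) == dim)
  }
  prov <- utils::read.csv(prov_path, stringsAsFactors = FALSE)
  if (nrow(prov) > 0) store$provenance <- prov
  store
}
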