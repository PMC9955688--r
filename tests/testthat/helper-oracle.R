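# Independent brute-force simulator: evaluates the updating rule naively from
# the lookup tables, one node at a time, with no shared code with the package's
# C++ engine. Only supports models with explicit (non-hashed) tables.
oracle_run <- function(model, periods, init, n_steps) {
  n <- model$topology$n_nodes
  stopifnot(!any(model$rules$hashed))
  states <- matrix(0L, n_steps, n)
  states[1, ] <- init
  s <- as.integer(init)
  for (t in seq_len(n_steps - 1)) {
    new <- s
    for (a in seq_len(n)) {
      if (t %% periods[a] == 0) {
        idx <- 0L
        for (b in model$topology$in_neighbors[[a]]) idx <- idx * 2L + s[b]
        new[a] <- model$rules$tables[[a]][idx + 1L]
      }
    }
    s <- new
    states[t + 1, ] <- s
  }
  states
}

new_topology_for_test <- function(n, inn) rbnhet:::new_topology(n, inn)

# All 2^n initial states of an n-node network, as rows.
all_initial_states <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
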