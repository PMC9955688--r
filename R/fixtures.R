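#' The two-node XOR/NOT example network
#'
#' Node 1 computes the XOR of nodes (1, 2); node 2 computes the NOT of
#' node 1. Under synchronous updating the state (1, 0) is a fixed point:
#' 1 XOR 0 = 1 and NOT 1 = 0.
#'
#' @return an `rbn_model`.
#' @examples
#' m <- xor_not_model()
#' s <- build_schedule("synchronous", m$topology)
#' rbn_step(m, s, c(1L, 0L), 1)
#' @export
xor_not_model <- function() {
  rbn_model_from_parts(list(c(1L, 2L), 1L),
                       list(c(0L, 1L, 1L, 0L), c(1L, 0L)))
}

#' Generate the bundled tiny-network fixture set
#'
#' Writes small (N <= 4) models and their trajectories for exhaustive
#' verification: the hand-checked XOR/NOT pair plus `n_random` random
#' models. Each model goes to `<name>.json` (with human-readable rule
#' tables) and its synchronous trajectory from every possible initial
#' state to `<name>_init<i>.csv`. Generation is idempotent for a fixed
#' seed.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param n_random number of random models.
#' @param n_steps trajectory length.
#' @return invisibly, the named list of generated models.
#' @export
make_fixtures <- function(dir, seed = 0, n_random = 3, n_steps = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- list(xor_not = xor_not_model())
  for (i in seq_len(n_random)) {
    n <- 2L + ((i - 1L) %% 3L)  # sizes 2, 3, 4, ...
    models[[sprintf("random%d_n%d", i, n)]] <-
      build_rbn(n, degree_spec("poisson", 2), bias_spec("point", 0.5),
                seed = derive_seed(seed, "fixture", i))
  }
  for (nm in names(models)) {
    model <- models[[nm]]
    write_rbn_model(model, file.path(dir, paste0(nm, ".json")))
    n <- model$topology$n_nodes
    schedule <- build_schedule("synchronous", model$topology)
    for (s in 0:(2^n - 1)) {
      init <- as.integer(intToBits(s)[seq_len(n)])
      traj <- rbn_run(model, schedule, init, n_steps)
      write_trajectory(traj, file.path(dir,
                                       sprintf("%s_init%d.csv", nm, s)))
    }
  }
  invisible(models)
}
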