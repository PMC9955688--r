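#' Derive a reproducible child seed from a master seed and a component path
#'
#' Hierarchical seeding: every stochastic stage of an experiment (a grid
#' point, a replicate, a fixture) obtains its own seed as a deterministic
#' hash of the master seed plus a stable path of labels. Adding replicates
#' or grid points therefore never perturbs the seeds of existing ones.
#'
#' @param master integer master seed.
#' @param ... path components (coerced to character): labels, grid values,
#'   replicate indices.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "curve", 2.5, 7)
#' @export
derive_seed <- function(master, ...) {
  parts <- c(as.character(master),
             vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                    character(1)))
  h <- 17
  # 2147483629 is the largest prime below 2^31; keeps arithmetic exact in doubles
  for (p in parts) {
    for (cc in utf8ToInt(p)) h <- (h * 31 + cc) %% 2147483629
    h <- (h * 31 + 7) %% 2147483629
  }
  as.integer(h + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the R RNG, evaluates `expr`, and restores the caller's RNG state,
#' so seeded computations do not disturb the surrounding random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @examples
#' with_seed(1, runif(2))
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
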