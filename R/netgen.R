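#' Wire a topology from realized out-degrees
#'
#' Each node `a` with out-degree `d_a` regulates `min(d_a, N)` distinct
#' target nodes chosen uniformly at random (self-loops allowed). Sampling
#' targets without replacement is equivalent to drawing with replacement and
#' redrawing duplicate `a -> b` arcs until targets are distinct, so a node's
#' in-neighbor list contains distinct regulators, matching the lookup-table
#' formalism.
#'
#' @param out_degrees integer vector of nonnegative out-degrees.
#' @return an `rbn_topology`: list with `n_nodes`, `in_neighbors` (one
#'   integer vector per node, 1-based, in wiring order), and `out_degree`
#'   (realized out-degrees after capping at N).
#' @examples
#' set.seed(1)
#' wire_from_out_degrees(c(2, 2, 2))
#' @export
wire_from_out_degrees <- function(out_degrees) {
  if (any(out_degrees < 0)) stop("out-degrees must be >= 0", call. = FALSE)
  n <- length(out_degrees)
  inn <- vector("list", n)
  for (a in seq_len(n)) inn[[a]] <- integer(0)
  realized <- integer(n)
  for (a in seq_len(n)) {
    d <- min(out_degrees[a], n)
    realized[a] <- d
    if (d > 0) {
      targets <- sample.int(n, d)   # distinct, uniform; self-loops allowed
      for (b in targets) inn[[b]] <- c(inn[[b]], a)
    }
  }
  new_topology(n, inn, realized)
}

#' Build a k-in regular topology (classical RBN wiring)
#'
#' Every node receives exactly `k` distinct in-neighbors chosen uniformly at
#' random (self-connections allowed), the classical Kauffman construction
#' with fixed in-degree.
#'
#' @param n_nodes number of nodes N.
#' @param k in-degree of every node (positive integer; capped at N).
#' @return an `rbn_topology`.
#' @examples
#' set.seed(1)
#' top <- build_regular_topology(9, 2)
#' lengths(top$in_neighbors)
#' @export
build_regular_topology <- function(n_nodes, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_nodes)
  k <- as.integer(min(k, n))
  inn <- vector("list", n)
  for (a in seq_len(n)) inn[[a]] <- sample.int(n, k)
  out_deg <- tabulate(unlist(inn), nbins = n)
  new_topology(n, inn, out_deg)
}

new_topology <- function(n_nodes, in_neighbors, out_degree = NULL) {
  in_neighbors <- lapply(in_neighbors, as.integer)
  if (is.null(out_degree)) {
    out_degree <- tabulate(unlist(in_neighbors), nbins = n_nodes)
  }
  idx <- unlist(in_neighbors)
  if (length(idx) && (any(idx < 1L) || any(idx > n_nodes))) {
    stop("in-neighbor index out of range", call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 in_neighbors = in_neighbors,
                 out_degree = as.integer(out_degree)),
            class = "rbn_topology")
}

#' In-degrees of a topology
#' @param topology an `rbn_topology`.
#' @return integer vector of in-degrees (number of distinct regulators).
#' @export
in_degrees <- function(topology) {
  vapply(topology$in_neighbors, length, integer(1))
}

#' @export
print.rbn_topology <- function(x, ...) {
  kin <- in_degrees(x)
  cat(sprintf("<rbn_topology: %d nodes, %d arcs, mean in-degree %.2f>\n",
              x$n_nodes, sum(kin), mean(kin)))
  invisible(x)
}

#' Generate random Boolean rules for a topology
#'
#' For a node with in-degree k and bias `p`, the rule is a lookup table of
#' `2^k` output bits, each independently 1 with probability `p`; the input
#' tuple is encoded with the first listed in-neighbor as the most
#' significant bit. A node with in-degree 0 gets a single-entry table: it
#' holds that constant value whenever it updates.
#'
#' Nodes whose in-degree exceeds `max_table_k` do not get a materialized
#' `2^k` table; instead the rule is a reproducible pseudo-random Boolean
#' function of the input tuple (a per-node 64-bit seed drives a hash that is
#' thresholded at `p`), which has the same law and is fully deterministic.
#'
#' @param topology an `rbn_topology`.
#' @param biases numeric vector of per-node biases in `[0, 1]`.
#' @param max_table_k largest in-degree for which an explicit table is
#'   stored (default `getOption("rbnhet.max_table_k", 16)`).
#' @return an `rbn_rules` object: `bias`, `tables` (integer 0/1 vectors, or
#'   `NULL` for hashed nodes), `hashed` flags, and per-node hash seeds.
#' @examples
#' set.seed(1)
#' top <- build_regular_topology(5, 2)
#' build_rules(top, rep(0.5, 5))
#' @export
build_rules <- function(topology, biases,
                        max_table_k = getOption("rbnhet.max_table_k", 16L)) {
  stopifnot(inherits(topology, "rbn_topology"))
  n <- topology$n_nodes
  if (length(biases) != n) {
    stop("`biases` must have one entry per node", call. = FALSE)
  }
  if (any(biases < 0 | biases > 1)) {
    stop("biases must lie in [0, 1]", call. = FALSE)
  }
  kin <- in_degrees(topology)
  tables <- vector("list", n)
  hashed <- kin > max_table_k
  seed_hi <- integer(n)
  seed_lo <- integer(n)
  for (a in seq_len(n)) {
    if (hashed[a]) {
      seed_hi[a] <- sample.int(2147483647L, 1L)
      seed_lo[a] <- sample.int(2147483647L, 1L)
    } else {
      tables[[a]] <- as.integer(runif(2^kin[a]) < biases[a])
    }
  }
  structure(list(bias = as.numeric(biases), tables = tables, hashed = hashed,
                 seed_hi = seed_hi, seed_lo = seed_lo,
                 max_table_k = as.integer(max_table_k)),
            class = "rbn_rules")
}

#' @export
print.rbn_rules <- function(x, ...) {
  cat(sprintf("<rbn_rules: %d nodes, mean bias %.3f, %d hashed rule(s)>\n",
              length(x$bias), mean(x$bias), sum(x$hashed)))
  invisible(x)
}

#' Build a complete random Boolean network model
#'
#' Composes out-degree sampling, wiring, bias sampling, and rule generation
#' into a full dynamical system. With a seed the construction is fully
#' reproducible; the generating configuration is recorded in `$meta`.
#'
#' @param n_nodes number of nodes N.
#' @param structural a [degree_spec()] (out-degree distribution), or a
#'   single positive integer k for classical k-in regular wiring.
#' @param functional a [bias_spec()], or a single number p for a uniform
#'   point bias.
#' @param seed optional integer seed; when given, the R RNG state is
#'   restored on exit.
#' @return an `rbn_model`: list with `topology`, `rules`, `meta`.
#' @examples
#' m <- build_rbn(20, degree_spec("poisson", 2), bias_spec("point", 0.5), seed = 1)
#' m
#' @export
build_rbn <- function(n_nodes, structural, functional = bias_spec("point", 0.5),
                      seed = NULL) {
  if (is.numeric(functional) && length(functional) == 1L) {
    functional <- bias_spec("point", functional)
  }
  stopifnot(inherits(functional, "rbn_bias_spec"))
  regular_in <- is.numeric(structural) && length(structural) == 1L
  if (!regular_in) stopifnot(inherits(structural, "rbn_degree_spec"))
  gen <- function() {
    topology <- if (regular_in) {
      build_regular_topology(n_nodes, structural)
    } else {
      wire_from_out_degrees(sample_out_degrees(structural, n_nodes))
    }
    biases <- sample_biases(functional, n_nodes)
    rules <- build_rules(topology, biases)
    structure(list(topology = topology, rules = rules,
                   meta = list(n_nodes = as.integer(n_nodes),
                               structural = if (regular_in)
                                 list(kind = "regular_in", k = structural)
                               else unclass(structural),
                               functional = unclass(functional),
                               seed = seed)),
              class = "rbn_model")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Assemble an RBN model from explicit parts
#'
#' For hand-built examples and fixtures: supply in-neighbor lists and the
#' full lookup tables directly.
#'
#' @param in_neighbors list of integer vectors (1-based node indices); the
#'   first listed in-neighbor is the most significant bit of the table index.
#' @param tables list of 0/1 integer vectors; entry `a` must have length
#'   `2^length(in_neighbors[[a]])`.
#' @param bias optional per-node bias vector recorded alongside the tables
#'   (defaults to each table's fraction of ones).
#' @return an `rbn_model`.
#' @examples
#' # node 1 = XOR of nodes (1, 2); node 2 = NOT of node 1
#' m <- rbn_model_from_parts(list(c(1, 2), 1),
#'                           list(c(0, 1, 1, 0), c(1, 0)))
#' @export
rbn_model_from_parts <- function(in_neighbors, tables, bias = NULL) {
  n <- length(in_neighbors)
  if (length(tables) != n) stop("one table per node required", call. = FALSE)
  topology <- new_topology(n, in_neighbors)
  kin <- in_degrees(topology)
  for (a in seq_len(n)) {
    if (length(tables[[a]]) != 2^kin[a]) {
      stop(sprintf("table %d must have length 2^%d", a, kin[a]), call. = FALSE)
    }
    if (!all(tables[[a]] %in% c(0L, 1L))) {
      stop("table entries must be 0 or 1", call. = FALSE)
    }
  }
  if (is.null(bias)) bias <- vapply(tables, function(tb) mean(tb), numeric(1))
  rules <- structure(list(bias = as.numeric(bias),
                          tables = lapply(tables, as.integer),
                          hashed = rep(FALSE, n),
                          seed_hi = integer(n), seed_lo = integer(n),
                          max_table_k = max(kin, 0L)),
                     class = "rbn_rules")
  structure(list(topology = topology, rules = rules,
                 meta = list(n_nodes = as.integer(n), structural = "explicit",
                             functional = "explicit", seed = NULL)),
            class = "rbn_model")
}

#' @export
print.rbn_model <- function(x, ...) {
  kin <- in_degrees(x$topology)
  cat(sprintf("<rbn_model: N = %d, mean in-degree %.2f, mean bias %.3f>\n",
              x$topology$n_nodes, mean(kin), mean(x$rules$bias)))
  invisible(x)
}
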