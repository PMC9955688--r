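#' Normalized Shannon entropy of a binary series
#'
#' `I = -(1/log2(b)) * sum_i p_i log(p_i)` with `b = 2` symbols and `p_i`
#' the empirical symbol frequencies; zero-frequency terms contribute 0, so
#' `I` lies in `[0, 1]` (0 for a constant series, 1 for a balanced one).
#'
#' @param series nonempty binary (0/1) vector.
#' @return entropy in `[0, 1]`.
#' @examples
#' shannon_entropy(c(0, 0, 0, 0))        # 0
#' shannon_entropy(c(0, 1, 0, 1))        # 1
#' shannon_entropy(c(1, 1, 1, 0))        # 0.8112781
#' @export
shannon_entropy <- function(series) {
  if (length(series) == 0) stop("`series` must be nonempty", call. = FALSE)
  binary_entropy(mean(series))
}

# H(p) in bits, vectorized, with 0 log 0 = 0.
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

#' Complexity of a node from its entropy
#'
#' `C = 4 * I * (1 - I)`: the product of entropy ("change", chaos) and its
#' complement ("stability", order), normalized to `[0, 1]` and maximal at
#' `I = 0.5`, where ordered and chaotic tendencies balance.
#'
#' @param entropy entropy value(s) in `[0, 1]`.
#' @return complexity value(s) in `[0, 1]`.
#' @examples
#' node_complexity(0.5)   # 1
#' node_complexity(c(0, 1))
#' @export
node_complexity <- function(entropy) {
  if (any(entropy < 0 | entropy > 1)) {
    stop("`entropy` must lie in [0, 1]", call. = FALSE)
  }
  4 * entropy * (1 - entropy)
}

#' Complexity of a trajectory
#'
#' The complexity of each node is computed from its own temporal series
#' (one column of the trajectory, initial state included), and the node
#' complexities are then averaged to give the network complexity.
#'
#' @param traj an `rbn_trajectory` (or any T x N binary matrix).
#' @return an `rbn_complexity`: list with `node_entropy`, `node_complexity`,
#'   and `network_complexity`.
#' @examples
#' traj <- matrix(c(0, 0, 0, 0, 1, 0, 1, 0), ncol = 2)
#' trajectory_complexity(traj)
#' @export
trajectory_complexity <- function(traj) {
  if (!is.matrix(traj) || nrow(traj) < 1) {
    stop("`traj` must be a T x N matrix with T >= 1", call. = FALSE)
  }
  p1 <- colMeans(traj)
  i <- binary_entropy(p1)
  c_node <- 4 * i * (1 - i)
  structure(list(node_entropy = i, node_complexity = c_node,
                 network_complexity = mean(c_node)),
            class = "rbn_complexity")
}

#' @export
print.rbn_complexity <- function(x, ...) {
  cat(sprintf("<rbn_complexity: network C = %.4f (N = %d nodes)>\n",
              x$network_complexity, length(x$node_complexity)))
  invisible(x)
}

#' Degree of perturbation of a protocol
#'
#' `delta_x = X * (T / O) / (N * T)`, which simplifies to `X / (N * O)`:
#' the expected fraction of node-steps flipped, in `[0, 1]` (1 when every
#' node is flipped every step).
#'
#' @param x nodes flipped per event.
#' @param o event period (>= 1).
#' @param n_nodes network size N.
#' @param t_max runtime T (kept for the defining formula; the value does
#'   not depend on it).
#' @return perturbation degree in `[0, 1]`.
#' @examples
#' perturbation_degree(3, 5, 100)   # 0.006
#' @export
perturbation_degree <- function(x, o, n_nodes, t_max = NULL) {
  if (o < 1) stop("`o` must be >= 1", call. = FALSE)
  if (x < 0 || x > n_nodes) stop("`x` must be in [0, N]", call. = FALSE)
  if (!is.null(t_max) && t_max < 1) stop("`t_max` must be >= 1", call. = FALSE)
  x / (n_nodes * o)
}

#' Complexity gain under perturbation
#'
#' `delta_C = C - C0`, the network complexity with perturbations minus the
#' complexity of the unperturbed run.
#'
#' @param c_perturbed network complexity with perturbations.
#' @param c_baseline network complexity without perturbations.
#' @return value in `[-1, 1]`.
#' @export
complexity_gain <- function(c_perturbed, c_baseline) {
  stopifnot(c_perturbed >= 0, c_perturbed <= 1,
            c_baseline >= 0, c_baseline <= 1)
  c_perturbed - c_baseline
}

#' Fragility of a network under a perturbation protocol
#'
#' Runs the same (model, schedule, initial state) twice -- once without and
#' once with the protocol (a paired comparison) -- and returns
#' `A = -delta_C * delta_x`. `A < 0` means antifragile (the network gains
#' complexity from perturbation), `A ~ 0` robust, `A > 0` fragile.
#'
#' @param model an `rbn_model`.
#' @param schedule an `rbn_schedule`.
#' @param init binary initial state.
#' @param protocol a [perturbation_protocol()].
#' @return an `rbn_fragility`: list with `c0`, `c`, `delta_c`, `delta_x`,
#'   `fragility`. Consumes the R RNG (perturbation draws).
#' @examples
#' m <- build_rbn(20, degree_spec("poisson", 1), seed = 1)
#' s <- build_schedule("synchronous", m$topology)
#' set.seed(2)
#' fragility(m, s, random_state(20), perturbation_protocol(5, 1, 50))
#' @export
fragility <- function(model, schedule, init, protocol) {
  stopifnot(inherits(protocol, "rbn_protocol"))
  n <- model$topology$n_nodes
  if (protocol$x > n) stop("protocol X exceeds N", call. = FALSE)
  c0 <- trajectory_complexity(
    rbn_run(model, schedule, init, protocol$t_max))$network_complexity
  cp <- trajectory_complexity(
    rbn_run(model, schedule, init, protocol$t_max, protocol))$network_complexity
  dx <- perturbation_degree(protocol$x, protocol$o, n, protocol$t_max)
  structure(list(c0 = c0, c = cp, delta_c = cp - c0, delta_x = dx,
                 fragility = -(cp - c0) * dx),
            class = "rbn_fragility")
}

#' @export
print.rbn_fragility <- function(x, ...) {
  verdict <- if (x$fragility < 0) "antifragile"
             else if (x$fragility > 0) "fragile" else "robust"
  cat(sprintf("<rbn_fragility: A = %.5f (%s); C0 = %.4f, C = %.4f, dx = %.4f>\n",
              x$fragility, verdict, x$c0, x$c, x$delta_x))
  invisible(x)
}

#' Mean fragility over an ensemble
#'
#' Averages [fragility()] over `n_reps` freshly generated (model, initial
#' state) pairs drawn from one generating configuration, reporting the mean
#' and its standard error. With `regenerate = "init_only"` a single model is
#' generated and only initial states are redrawn per replicate.
#'
#' @param case a [case_label()] describing the heterogeneity combination.
#' @param n_nodes network size N.
#' @param mean_k average connectivity K.
#' @param protocol a [perturbation_protocol()].
#' @param n_reps number of replicates (>= 1).
#' @param seed master seed (child seeds are derived per replicate).
#' @param regenerate `"model"` (fresh model and state per replicate) or
#'   `"init_only"`.
#' @return list with `mean`, `se`, and the per-replicate `values`.
#' @export
mean_fragility <- function(case, n_nodes, mean_k, protocol, n_reps,
                           seed = 0, regenerate = c("model", "init_only")) {
  regenerate <- match.arg(regenerate)
  stopifnot(n_reps >= 1)
  shared_model <- if (regenerate == "init_only") {
    generate_case_model(case, n_nodes, mean_k,
                        seed = derive_seed(seed, "frag-model", mean_k))
  } else NULL
  vals <- vapply(seq_len(n_reps), function(r) {
    s <- derive_seed(seed, "frag", mean_k, r)
    with_seed(s, {
      model <- if (is.null(shared_model)) {
        generate_case_model(case, n_nodes, mean_k)
      } else shared_model
      schedule <- case_schedule(case, model$topology, mean_k)
      init <- random_state(n_nodes)
      fragility(model, schedule, init, protocol)$fragility
    })
  }, numeric(1))
  list(mean = mean(vals),
       se = if (n_reps > 1) sd(vals) / sqrt(n_reps) else NA_real_,
       values = vals)
}

#' Critical connectivity of a classical RBN
#'
#' The Derrida--Pomeau order/chaos phase boundary for bias p:
#' `Kc = 1 / (2 p (1 - p))`. Below `Kc` small perturbations die out
#' (ordered phase); above, they propagate (chaotic phase). At `p = 0.5`,
#' `Kc = 2`.
#'
#' @param p rule bias, strictly between 0 and 1.
#' @return the critical average connectivity.
#' @examples
#' critical_connectivity(0.5)   # 2
#' @export
critical_connectivity <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  1 / (2 * p * (1 - p))
}
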