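#' Build an update schedule for a topology
#'
#' Temporal homogeneity/heterogeneity is realized through per-node update
#' periods P_a: node `a` recomputes its rule at steps t with `t mod P_a == 0`
#' and holds its state otherwise.
#'
#' * `"synchronous"` — all periods 1 (classical, temporally homogeneous).
#' * `"out_degree"` — `P_a = max(K_a+, 1)`: the more nodes a node affects,
#'   the slower it is updated (temporally heterogeneous).
#' * `"ceil"` — every node shares the single period `ceiling(mean_k)`, the
#'   maximum activation period of the sweep point (a temporally homogeneous
#'   contrast to out-degree updating). With `ceil_use_max = TRUE` the shared
#'   period is instead the maximum realized out-degree in the network.
#'
#' @param scheme one of `"synchronous"`, `"out_degree"`, `"ceil"`.
#' @param topology an `rbn_topology`.
#' @param mean_k average connectivity of the sweep point (required for
#'   `"ceil"`).
#' @param ceil_use_max alternative "ceil" interpretation: use the maximum
#'   realized out-degree as the shared period.
#' @return an `rbn_schedule`: list with `scheme` and integer `period`.
#' @examples
#' set.seed(1)
#' top <- build_regular_topology(5, 2)
#' build_schedule("out_degree", top)
#' @export
build_schedule <- function(scheme = c("synchronous", "out_degree", "ceil"),
                           topology, mean_k = NULL, ceil_use_max = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(topology, "rbn_topology"))
  n <- topology$n_nodes
  period <- switch(scheme,
    synchronous = rep.int(1L, n),
    out_degree = pmax(topology$out_degree, 1L),
    ceil = {
      p <- if (ceil_use_max) {
        max(topology$out_degree, 1L)
      } else {
        if (is.null(mean_k)) {
          stop("`mean_k` is required for the ceil scheme", call. = FALSE)
        }
        max(ceiling(mean_k), 1)
      }
      rep.int(as.integer(p), n)
    }
  )
  structure(list(scheme = scheme, period = as.integer(period)),
            class = "rbn_schedule")
}

#' @export
print.rbn_schedule <- function(x, ...) {
  cat(sprintf("<rbn_schedule: %s, periods %s>\n", x$scheme,
              if (length(unique(x$period)) == 1L)
                sprintf("all %d", x$period[1])
              else sprintf("%d..%d", min(x$period), max(x$period))))
  invisible(x)
}

#' Draw a uniform random initial state
#'
#' @param n_nodes number of nodes.
#' @return integer vector of i.i.d. uniform bits.
#' @examples
#' set.seed(1)
#' random_state(10)
#' @export
random_state <- function(n_nodes) {
  if (n_nodes < 1) stop("`n_nodes` must be >= 1", call. = FALSE)
  as.integer(runif(n_nodes) < 0.5)
}

#' Advance an RBN state by one time step
#'
#' All nodes due at step `t` read the state at step `t - 1` (deterministic
#' generalized-asynchronous semantics: no sequential cascade within a step).
#'
#' @param model an `rbn_model`.
#' @param schedule an `rbn_schedule`.
#' @param state binary vector of length N (state at step `t - 1`).
#' @param t step index (>= 1).
#' @return binary integer vector: the state at step `t`.
#' @examples
#' m <- rbn_model_from_parts(list(c(1, 2), 1), list(c(0, 1, 1, 0), c(1, 0)))
#' s <- build_schedule("synchronous", m$topology)
#' rbn_step(m, s, c(1L, 0L), 1)   # fixed point of the XOR/NOT pair
#' @export
rbn_step <- function(model, schedule, state, t) {
  stopifnot(inherits(model, "rbn_model"), inherits(schedule, "rbn_schedule"))
  if (length(state) != model$topology$n_nodes) {
    stop("`state` must have one bit per node", call. = FALSE)
  }
  fl <- flatten_model(model)
  step_rbn_core(fl$nbr, fl$nbr_off, fl$tab, fl$tab_off, fl$hashed,
                fl$seed_hi, fl$seed_lo, fl$bias, schedule$period,
                as.integer(state), as.integer(t))
}

#' Flip X randomly chosen node states
#'
#' @param state binary vector.
#' @param x number of distinct nodes to flip (0 <= x <= N).
#' @return the perturbed state. Consumes the R RNG.
#' @examples
#' set.seed(1)
#' apply_perturbation(rep(0L, 10), 3)
#' @export
apply_perturbation <- function(state, x) {
  n <- length(state)
  if (x < 0 || x > n) stop("`x` must be in [0, N]", call. = FALSE)
  if (x == 0) return(as.integer(state))
  idx <- sample.int(n, x)
  state <- as.integer(state)
  state[idx] <- 1L - state[idx]
  state
}

#' Perturbation protocol specification
#'
#' Flip `x` randomly chosen node states whenever the time step t is a
#' positive multiple of `o`, over a runtime of `t_max` steps.
#'
#' @param x number of nodes flipped per event.
#' @param o event period in steps (>= 1).
#' @param t_max total runtime T in steps.
#' @return an `rbn_protocol`.
#' @examples
#' perturbation_protocol(3, 5, 100)
#' @export
perturbation_protocol <- function(x, o, t_max) {
  if (o < 1) stop("`o` must be >= 1", call. = FALSE)
  if (t_max < 1) stop("`t_max` must be >= 1", call. = FALSE)
  if (x < 0) stop("`x` must be >= 0", call. = FALSE)
  structure(list(x = as.integer(x), o = as.integer(o),
                 t_max = as.integer(t_max)),
            class = "rbn_protocol")
}

#' @export
print.rbn_protocol <- function(x, ...) {
  cat(sprintf("<rbn_protocol: flip X = %d nodes every O = %d steps, T = %d>\n",
              x$x, x$o, x$t_max))
  invisible(x)
}

#' Run an RBN trajectory
#'
#' Produces the T x N binary state history. Row 1 is the initial state; for
#' each t = 1 .. T-1 the state is advanced one step and then, if a protocol
#' is given and `t mod O == 0`, X random nodes are flipped (perturbations act
#' after the step update and never on the initial state). Without a
#' protocol the run is a deterministic function of (model, schedule, init)
#' and does not touch the R RNG.
#'
#' @param model an `rbn_model`.
#' @param schedule an `rbn_schedule`.
#' @param init binary initial state of length N.
#' @param n_steps runtime T (number of rows, including the initial state).
#' @param protocol optional [perturbation_protocol()]; its `t_max` must
#'   equal `n_steps`.
#' @return an `rbn_trajectory`: T x N integer 0/1 matrix.
#' @examples
#' m <- build_rbn(10, degree_spec("poisson", 2), seed = 1)
#' s <- build_schedule("synchronous", m$topology)
#' traj <- rbn_run(m, s, random_state(10), 20)
#' dim(traj)
#' @export
rbn_run <- function(model, schedule, init, n_steps, protocol = NULL) {
  stopifnot(inherits(model, "rbn_model"), inherits(schedule, "rbn_schedule"))
  n <- model$topology$n_nodes
  if (length(init) != n) stop("`init` must have one bit per node", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "rbn_protocol"))
    if (protocol$t_max != n_steps) {
      stop("protocol runtime must equal `n_steps`", call. = FALSE)
    }
    if (protocol$x > n) stop("protocol X exceeds N", call. = FALSE)
    times <- seq.int(protocol$o, n_steps - 1L, by = protocol$o)
    times <- times[times >= 1L]
    if (protocol$x > 0 && length(times) > 0) {
      pert_nodes <- vapply(times, function(t) sample.int(n, protocol$x),
                           integer(protocol$x))
      pert_nodes <- matrix(pert_nodes, nrow = protocol$x)
    } else {
      times <- integer(0)
      pert_nodes <- matrix(integer(0), nrow = 0, ncol = 0)
    }
  } else {
    times <- integer(0)
    pert_nodes <- matrix(integer(0), nrow = 0, ncol = 0)
  }
  fl <- flatten_model(model)
  states <- run_rbn_core(fl$nbr, fl$nbr_off, fl$tab, fl$tab_off, fl$hashed,
                         fl$seed_hi, fl$seed_lo, fl$bias, schedule$period,
                         as.integer(init), n_steps,
                         as.integer(times), pert_nodes)
  structure(states, class = c("rbn_trajectory", class(states)))
}

#' @export
print.rbn_trajectory <- function(x, ...) {
  cat(sprintf("<rbn_trajectory: %d steps x %d nodes, density %.3f>\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

# Flatten a model into the contiguous arrays the C++ core consumes.
flatten_model <- function(model) {
  top <- model$topology
  rules <- model$rules
  nbr <- as.integer(unlist(top$in_neighbors))
  nbr_off <- c(0L, cumsum(vapply(top$in_neighbors, length, integer(1))))
  tabs <- rules$tables
  tab_len <- vapply(tabs, function(tb) length(tb), integer(1))
  tab <- as.integer(unlist(tabs))
  tab_off <- c(0L, cumsum(tab_len))
  list(nbr = nbr, nbr_off = as.integer(nbr_off),
       tab = if (length(tab)) tab else integer(0),
       tab_off = as.integer(tab_off),
       hashed = rules$hashed, seed_hi = rules$seed_hi, seed_lo = rules$seed_lo,
       bias = rules$bias)
}
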