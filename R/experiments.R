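#' Label a homogeneity/heterogeneity combination
#'
#' The three heterogeneity axes and their realizations:
#' * structural: `"HoS"` = Poisson out-degrees, `"HeS"` = exponential
#'   out-degrees (the heavier-tailed, "more heterogeneous" distribution);
#' * temporal: `"HoT"` = synchronous updating, `"HeT"` = out-degree periods
#'   (or the shared-period `"ceil"` strategy via `het_temporal`);
#' * functional: `"HoF"` = point bias at `hof_bias`, `"HeF"` = per-node
#'   biases from `functional_spec` (default triangular, mean 0.5 on the
#'   unit interval).
#'
#' @param structural `"HoS"` or `"HeS"`.
#' @param temporal `"HoT"` or `"HeT"`.
#' @param functional `"HoF"` or `"HeF"`.
#' @param het_temporal scheme used when `temporal = "HeT"`: `"out_degree"`
#'   (default) or `"ceil"`.
#' @param functional_spec [bias_spec()] used when `functional = "HeF"`.
#' @param hof_bias point bias used when `functional = "HoF"`.
#' @return an `rbn_case`.
#' @examples
#' case_label("HeS", "HeT", "HeF")        # the triple-heterogeneity case
#' case_label("HoS", "HoT", "HoF")        # the fully homogeneous case
#' @export
case_label <- function(structural = c("HoS", "HeS"),
                       temporal = c("HoT", "HeT"),
                       functional = c("HoF", "HeF"),
                       het_temporal = c("out_degree", "ceil"),
                       functional_spec = bias_spec("triangular", 0.5,
                                                   domain = c(0, 1)),
                       hof_bias = 0.5) {
  structural <- match.arg(structural)
  temporal <- match.arg(temporal)
  functional <- match.arg(functional)
  het_temporal <- match.arg(het_temporal)
  stopifnot(inherits(functional_spec, "rbn_bias_spec"))
  structure(list(structural = structural, temporal = temporal,
                 functional = functional, het_temporal = het_temporal,
                 functional_spec = functional_spec,
                 hof_bias = hof_bias),
            class = "rbn_case")
}

#' @export
print.rbn_case <- function(x, ...) {
  cat(sprintf("<rbn_case: %s>\n", case_name(x)))
  invisible(x)
}

#' @rdname case_label
#' @param case an `rbn_case`.
#' @export
case_name <- function(case) {
  paste(case$structural, case$temporal, case$functional, sep = "-")
}

#' Generate a model for a heterogeneity case
#'
#' @param case an [case_label()].
#' @param n_nodes network size N.
#' @param mean_k average connectivity K.
#' @param seed optional seed (otherwise consumes the current RNG stream).
#' @return an `rbn_model`.
#' @export
generate_case_model <- function(case, n_nodes, mean_k, seed = NULL) {
  stopifnot(inherits(case, "rbn_case"))
  structural <- if (case$structural == "HoS") {
    degree_spec("poisson", mean_k)
  } else {
    degree_spec("exponential", mean_k)
  }
  functional <- if (case$functional == "HoF") {
    bias_spec("point", case$hof_bias)
  } else {
    case$functional_spec
  }
  build_rbn(n_nodes, structural, functional, seed = seed)
}

#' Schedule for a heterogeneity case
#'
#' @inheritParams generate_case_model
#' @param topology the model's topology.
#' @return an `rbn_schedule`.
#' @export
case_schedule <- function(case, topology, mean_k) {
  if (case$temporal == "HoT") {
    build_schedule("synchronous", topology)
  } else {
    build_schedule(case$het_temporal, topology, mean_k = mean_k)
  }
}

# plain-list view of a case label (JSON-serializable)
case_plain <- function(case) {
  x <- unclass(case)
  x$functional_spec <- unclass(x$functional_spec)
  x
}

new_curve <- function(x, y_mean, y_se, n_reps, label, config) {
  stopifnot(length(x) == length(y_mean), length(x) == length(y_se))
  structure(data.frame(x = x, y_mean = y_mean, y_se = y_se,
                       n_reps = n_reps),
            label = label, config = config,
            class = c("rbn_curve", "data.frame"))
}

#' @export
print.rbn_curve <- function(x, ...) {
  cat(sprintf("<rbn_curve \"%s\": %d points, x in [%g, %g], peak y = %.4f>\n",
              attr(x, "label"), nrow(x), min(x$x), max(x$x), max(x$y_mean)))
  invisible(as.data.frame(x))
}

#' Complexity-versus-connectivity curve for one heterogeneity case
#'
#' For each K on the grid, generates `n_networks` models per the case
#' mapping, runs each for `n_steps` from a fresh random initial state, and
#' averages the network complexities. Replicate seeds are derived from
#' (seed, K, replicate) only, so different cases run under shared seed
#' streams and can be compared pairwise.
#'
#' @param case a [case_label()].
#' @param n_nodes network size N.
#' @param k_grid increasing vector of average connectivities (the classic
#'   full-scale grid is `seq(1, 9.8, by = 0.2)`, 45 points).
#' @param n_networks networks per grid point (full scale: 1000).
#' @param n_steps trajectory length T (full scale: 2000).
#' @param seed master seed.
#' @return an `rbn_curve` with columns `x`, `y_mean`, `y_se`, `n_reps`.
#' @examples
#' cv <- complexity_curve(case_label("HoS", "HoT", "HoF"), 30,
#'                        k_grid = c(1, 2, 3), n_networks = 5, n_steps = 50,
#'                        seed = 1)
#' @export
complexity_curve <- function(case, n_nodes, k_grid, n_networks, n_steps,
                             seed = 0) {
  stopifnot(inherits(case, "rbn_case"), n_networks >= 1, all(k_grid > 0))
  stats <- vapply(k_grid, function(k) {
    vals <- vapply(seq_len(n_networks), function(r) {
      with_seed(derive_seed(seed, "cx", k, r), {
        model <- generate_case_model(case, n_nodes, k)
        schedule <- case_schedule(case, model$topology, k)
        init <- random_state(n_nodes)
        traj <- rbn_run(model, schedule, init, n_steps)
        trajectory_complexity(traj)$network_complexity
      })
    }, numeric(1))
    c(mean(vals),
      if (n_networks > 1) sd(vals) / sqrt(n_networks) else NA_real_)
  }, numeric(2))
  new_curve(k_grid, stats[1, ], stats[2, ], n_networks,
            label = case_name(case),
            config = list(case = case_plain(case), n_nodes = n_nodes,
                          n_networks = n_networks, n_steps = n_steps,
                          seed = seed))
}

#' Complexity curves for all eight heterogeneity combinations
#'
#' @inheritParams complexity_curve
#' @param het_temporal scheme realizing temporal heterogeneity.
#' @param functional_spec bias distribution realizing functional
#'   heterogeneity.
#' @return a named list of 8 `rbn_curve`s (names like `"HeS-HeT-HeF"`), all
#'   run under shared replication settings and seed streams.
#' @export
eight_case_comparison <- function(n_nodes, k_grid, n_networks, n_steps,
                                  seed = 0,
                                  het_temporal = "out_degree",
                                  functional_spec = bias_spec("triangular",
                                                              0.5,
                                                              domain = c(0, 1))) {
  combos <- expand.grid(structural = c("HoS", "HeS"),
                        temporal = c("HoT", "HeT"),
                        functional = c("HoF", "HeF"),
                        stringsAsFactors = FALSE)
  curves <- lapply(seq_len(nrow(combos)), function(i) {
    case <- case_label(combos$structural[i], combos$temporal[i],
                       combos$functional[i], het_temporal = het_temporal,
                       functional_spec = functional_spec)
    complexity_curve(case, n_nodes, k_grid, n_networks, n_steps, seed = seed)
  })
  names(curves) <- vapply(seq_len(nrow(combos)), function(i) {
    paste(combos$structural[i], combos$temporal[i], combos$functional[i],
          sep = "-")
  }, character(1))
  curves
}

#' Trapezoidal area under a curve
#'
#' @param curve an `rbn_curve` (or data frame with `x` and `y_mean`).
#' @return the trapezoidal integral of `y_mean` over `x`.
#' @examples
#' cv <- data.frame(x = c(0, 1), y_mean = c(1, 1))
#' curve_auc(cv)   # 1
#' @export
curve_auc <- function(curve) {
  x <- curve$x; y <- curve$y_mean
  if (length(x) < 2) stop("need at least 2 grid points", call. = FALSE)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Smallest connectivity from which a reference curve dominates
#'
#' Returns the smallest grid value from which the reference curve's mean
#' strictly exceeds every other curve's mean at that point and at all later
#' grid points, or `NULL` if it never dominates through the end of the grid.
#'
#' @param curves a list of `rbn_curve`s sharing the same `x` grid.
#' @param reference name or index of the reference curve in `curves`.
#' @return a grid value, or `NULL`.
#' @export
crossover_k <- function(curves, reference) {
  ref <- curves[[reference]]
  others <- curves[setdiff(seq_along(curves),
                           if (is.character(reference))
                             match(reference, names(curves))
                           else reference)]
  x <- ref$x
  for (cv in others) {
    if (length(cv$x) != length(x) || any(cv$x != x)) {
      stop("curves must share the same x grid", call. = FALSE)
    }
  }
  other_max <- apply(vapply(others, function(cv) cv$y_mean,
                            numeric(length(x))), 1, max)
  dominates <- ref$y_mean > other_max
  if (!dominates[length(x)]) return(NULL)
  run_start <- length(x)
  for (i in rev(seq_along(x))) {
    if (dominates[i]) run_start <- i else break
  }
  x[run_start]
}

#' Fragility sweep curves
#'
#' One fragility-versus-X (or versus-O) curve per connectivity value, under
#' one heterogeneity case. Full scale uses steps of 1 over the whole range,
#' 1000 replicates per point, and T = 200 steps.
#'
#' @param case a [case_label()].
#' @param n_nodes network size N.
#' @param k_values integer set of average connectivities, one curve each.
#' @param sweep `"vs_X"` (sweep nodes flipped, fixed O) or `"vs_O"`
#'   (sweep period, fixed X).
#' @param fixed the fixed O (for `"vs_X"`) or X (for `"vs_O"`).
#' @param sweep_grid grid of swept values; defaults to `0:n_nodes` for
#'   `"vs_X"` and `1:50` for `"vs_O"`.
#' @param t_max runtime T per run.
#' @param n_reps replicates (fresh model + initial state) per point.
#' @param seed master seed.
#' @return a named list of `rbn_curve`s, one per K (`y_mean` = mean
#'   fragility A).
#' @export
fragility_curves <- function(case, n_nodes, k_values,
                             sweep = c("vs_X", "vs_O"), fixed,
                             sweep_grid = NULL, t_max = 200, n_reps = 1000,
                             seed = 0) {
  sweep <- match.arg(sweep)
  stopifnot(length(k_values) >= 1)
  if (is.null(sweep_grid)) {
    sweep_grid <- if (sweep == "vs_X") 0:n_nodes else 1:50
  }
  out <- lapply(k_values, function(k) {
    stats <- vapply(sweep_grid, function(v) {
      protocol <- if (sweep == "vs_X") {
        perturbation_protocol(v, fixed, t_max)
      } else {
        perturbation_protocol(fixed, v, t_max)
      }
      mf <- mean_fragility(case, n_nodes, k, protocol, n_reps,
                           seed = derive_seed(seed, "fragcurve", sweep, k, v))
      c(mf$mean, mf$se)
    }, numeric(2))
    new_curve(sweep_grid, stats[1, ], stats[2, ], n_reps,
              label = sprintf("%s K=%g %s", case_name(case), k, sweep),
              config = list(case = case_plain(case), n_nodes = n_nodes,
                            mean_k = k, sweep = sweep, fixed = fixed,
                            t_max = t_max, n_reps = n_reps, seed = seed))
  })
  names(out) <- paste0("K", k_values)
  out
}

#' Functional-parameter variation suite
#'
#' Runs the triple-heterogeneity case with only the functional (bias)
#' distribution varied, under shared seed streams so variants can be
#' compared pairwise:
#' * `"distribution_kind"`: point-like, Gaussians at several sd values,
#'   uniform, triangular (all mean 0.5, domain \[0, 1\]);
#' * `"mean"`: triangular with modes `means`;
#' * `"domain_triangular"` / `"domain_uniform"`: nested symmetric domains.
#'
#' @param variant which functional parameter to vary.
#' @param n_nodes,k_grid,n_networks,n_steps,seed as in [complexity_curve()].
#' @param gaussian_sds sd values for the Gaussian variants.
#' @param means mode values for the mean variants.
#' @param domains list of domain intervals for the domain variants.
#' @return a named list of `rbn_curve`s.
#' @export
functional_variation_suite <- function(variant = c("distribution_kind", "mean",
                                                   "domain_triangular",
                                                   "domain_uniform"),
                                       n_nodes, k_grid, n_networks, n_steps,
                                       seed = 0,
                                       gaussian_sds = c(0.1, 0.25, 0.5, 1),
                                       means = c(0, 0.25, 0.5, 0.75, 1),
                                       domains = list(c(0, 1), c(0.1, 0.9),
                                                      c(0.2, 0.8), c(0.3, 0.7),
                                                      c(0.4, 0.6))) {
  variant <- match.arg(variant)
  specs <- switch(variant,
    distribution_kind = {
      sp <- c(list(point_like = bias_spec("point", 0.5)),
              stats::setNames(lapply(gaussian_sds, function(s)
                bias_spec("gaussian", 0.5, sd = s)),
                paste0("gaussian_sd", gaussian_sds)),
              list(uniform = bias_spec("uniform", 0.5),
                   triangular = bias_spec("triangular", 0.5)))
      sp
    },
    mean = stats::setNames(lapply(means, function(m)
      bias_spec("triangular", m, domain = c(0, 1))),
      paste0("mu", means)),
    domain_triangular = stats::setNames(lapply(domains, function(d)
      bias_spec("triangular", 0.5, domain = d)),
      vapply(domains, function(d) sprintf("D[%g,%g]", d[1], d[2]),
             character(1))),
    domain_uniform = stats::setNames(lapply(domains, function(d)
      bias_spec("uniform", mean(d), domain = d)),
      vapply(domains, function(d) sprintf("D[%g,%g]", d[1], d[2]),
             character(1)))
  )
  lapply(specs, function(sp) {
    case <- case_label("HeS", "HeT", "HeF", functional_spec = sp)
    if (sp$kind == "point") case <- case_label("HeS", "HeT", "HoF",
                                               hof_bias = sp$mean)
    complexity_curve(case, n_nodes, k_grid, n_networks, n_steps, seed = seed)
  })
}

#' Out-degree versus Ceil temporal strategies
#'
#' Compares the two heterogeneous-update strategies under otherwise
#' triple-heterogeneous settings, for a triangular or uniform functional
#' distribution.
#'
#' @param functional `"triangular"` or `"uniform"` (mean 0.5, domain
#'   \[0, 1\]).
#' @param n_nodes,k_grid,n_networks,n_steps,seed as in [complexity_curve()].
#' @return a list of two `rbn_curve`s: `out_degree` and `ceil`.
#' @export
temporal_strategy_comparison <- function(functional = c("triangular",
                                                        "uniform"),
                                         n_nodes, k_grid, n_networks,
                                         n_steps, seed = 0) {
  functional <- match.arg(functional)
  sp <- if (functional == "triangular") {
    bias_spec("triangular", 0.5)
  } else {
    bias_spec("uniform", 0.5)
  }
  lapply(stats::setNames(c("out_degree", "ceil"), c("out_degree", "ceil")),
         function(scheme) {
           case <- case_label("HeS", "HeT", "HeF", het_temporal = scheme,
                              functional_spec = sp)
           complexity_curve(case, n_nodes, k_grid, n_networks, n_steps,
                            seed = seed)
         })
}
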