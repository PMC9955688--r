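#' Out-degree distribution specification
#'
#' Describes how node out-degrees are drawn when building a network.
#' `"regular"` gives every node exactly `mean_k` out-edges; `"poisson"`
#' draws i.i.d. Poisson(`mean_k`) out-degrees (the structurally homogeneous
#' case); `"exponential"` draws i.i.d. exponential variates with mean
#' `mean_k`, rounded to the nearest integer (the structurally heterogeneous
#' case, with variance `mean_k^2` instead of `mean_k`).
#'
#' @param kind one of `"regular"`, `"poisson"`, `"exponential"`.
#' @param mean_k average connectivity K (positive; integer when `kind` is
#'   `"regular"`).
#' @param floor_at_one if `TRUE`, exponential draws are floored at 1 instead
#'   of 0, disallowing leaf (out-degree-0) nodes.
#' @return an object of class `rbn_degree_spec`.
#' @seealso [sample_out_degrees()], [build_rbn()]
#' @examples
#' degree_spec("poisson", 2)
#' degree_spec("exponential", 5)
#' @export
degree_spec <- function(kind = c("regular", "poisson", "exponential"),
                        mean_k, floor_at_one = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(mean_k) || length(mean_k) != 1L || !is.finite(mean_k) ||
      mean_k <= 0) {
    stop("`mean_k` must be a single positive number", call. = FALSE)
  }
  if (kind == "regular" && mean_k != round(mean_k)) {
    stop("`mean_k` must be a positive integer when kind = \"regular\"",
         call. = FALSE)
  }
  structure(list(kind = kind, mean_k = as.numeric(mean_k),
                 floor_at_one = isTRUE(floor_at_one)),
            class = "rbn_degree_spec")
}

#' Rule-bias distribution specification
#'
#' Describes how the per-node bias p_a (the probability that a rule-table
#' entry is 1) is drawn. `"point"` assigns every node the same bias `mean`
#' (the functionally homogeneous case). `"gaussian"` draws from a normal
#' with mean `mean` and sd `sd`, truncated to `domain` by rejection.
#' `"uniform"` draws uniformly on `domain`. `"triangular"` draws from a
#' triangular density on `domain` with mode `mean`.
#'
#' @param kind one of `"point"`, `"gaussian"`, `"uniform"`, `"triangular"`.
#' @param mean central bias value in `[0, 1]` (ignored for `"uniform"`,
#'   where the domain midpoint is the mean).
#' @param sd standard deviation (Gaussian only).
#' @param domain length-2 interval `[a, b]` contained in `[0, 1]`.
#' @return an object of class `rbn_bias_spec`.
#' @seealso [sample_biases()], [build_rbn()]
#' @examples
#' bias_spec("point", 0.5)
#' bias_spec("triangular", 0.5, domain = c(0.1, 0.9))
#' bias_spec("gaussian", 0.5, sd = 0.25)
#' @export
bias_spec <- function(kind = c("point", "gaussian", "uniform", "triangular"),
                      mean = 0.5, sd = 0, domain = c(0, 1)) {
  kind <- match.arg(kind)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] > domain[2]) {
    stop("`domain` must be an interval c(a, b) with a <= b", call. = FALSE)
  }
  if (domain[1] < 0 || domain[2] > 1) {
    stop("`domain` must be contained in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(mean) || length(mean) != 1L || mean < domain[1] ||
      mean > domain[2]) {
    stop("`mean` must lie inside `domain`", call. = FALSE)
  }
  if (kind == "gaussian" && (!is.numeric(sd) || sd < 0)) {
    stop("`sd` must be nonnegative for kind = \"gaussian\"", call. = FALSE)
  }
  structure(list(kind = kind, mean = as.numeric(mean), sd = as.numeric(sd),
                 domain = as.numeric(domain)),
            class = "rbn_bias_spec")
}

#' Sample node out-degrees from a degree specification
#'
#' @param spec an [degree_spec()] object.
#' @param n_nodes number of nodes N.
#' @return integer vector of length `n_nodes` of nonnegative out-degrees.
#'   Consumes the R random number stream (seed with [set.seed()] or
#'   [with_seed]-style wrappers for reproducibility).
#' @examples
#' set.seed(1)
#' sample_out_degrees(degree_spec("poisson", 2), 10)
#' @export
sample_out_degrees <- function(spec, n_nodes) {
  stopifnot(inherits(spec, "rbn_degree_spec"))
  if (!is.numeric(n_nodes) || n_nodes < 1) {
    stop("`n_nodes` must be >= 1", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  d <- switch(spec$kind,
    regular = rep.int(as.integer(spec$mean_k), n_nodes),
    poisson = rpois(n_nodes, spec$mean_k),
    exponential = as.integer(round(rexp(n_nodes, rate = 1 / spec$mean_k)))
  )
  if (spec$kind == "exponential" && spec$floor_at_one) d <- pmax(d, 1L)
  as.integer(d)
}

#' Sample per-node rule biases from a bias specification
#'
#' @param spec a [bias_spec()] object.
#' @param n_nodes number of nodes N.
#' @return numeric vector of length `n_nodes`, all values inside
#'   `spec$domain`. Gaussian draws outside the domain are rejected and
#'   redrawn (truncated normal).
#' @examples
#' set.seed(1)
#' sample_biases(bias_spec("triangular", 0.5), 5)
#' @export
sample_biases <- function(spec, n_nodes) {
  stopifnot(inherits(spec, "rbn_bias_spec"))
  n_nodes <- as.integer(n_nodes)
  a <- spec$domain[1]; b <- spec$domain[2]
  switch(spec$kind,
    point = rep.int(spec$mean, n_nodes),
    uniform = runif(n_nodes, a, b),
    triangular = rtri(n_nodes, a, b, mode = spec$mean),
    gaussian = {
      if (spec$sd == 0) {
        rep.int(spec$mean, n_nodes)
      } else {
        x <- rnorm(n_nodes, spec$mean, spec$sd)
        for (iter in seq_len(10000L)) {
          out <- which(x < a | x > b)
          if (length(out) == 0L) break
          x[out] <- rnorm(length(out), spec$mean, spec$sd)
        }
        if (any(x < a | x > b)) {
          stop("truncated-Gaussian rejection sampling failed to converge",
               call. = FALSE)
        }
        x
      }
    }
  )
}

# Inverse-CDF sampler for the triangular distribution on [a, b] with mode c.
rtri <- function(n, a, b, mode) {
  if (a == b) return(rep.int(a, n))
  u <- runif(n)
  fc <- (mode - a) / (b - a)
  lo <- u < fc
  x <- numeric(n)
  x[lo] <- a + sqrt(u[lo] * (b - a) * (mode - a))
  x[!lo] <- b - sqrt((1 - u[!lo]) * (b - a) * (b - mode))
  x
}

#' @export
print.rbn_degree_spec <- function(x, ...) {
  extra <- if (x$kind == "exponential" && x$floor_at_one) ", floor at 1" else ""
  cat(sprintf("<out-degree spec: %s, mean K = %g%s>\n", x$kind, x$mean_k, extra))
  invisible(x)
}

#' @export
print.rbn_bias_spec <- function(x, ...) {
  cat(sprintf("<bias spec: %s, mean = %g%s, domain [%g, %g]>\n",
              x$kind, x$mean,
              if (x$kind == "gaussian") sprintf(", sd = %g", x$sd) else "",
              x$domain[1], x$domain[2]))
  invisible(x)
}
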