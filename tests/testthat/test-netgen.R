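test_that("degree and bias specs validate their parameters", {
  expect_error(degree_spec("regular", 2.5), "positive integer")
  expect_error(degree_spec("poisson", -1), "positive")
  expect_error(bias_spec("point", 0.5, domain = c(-0.1, 1)), "contained")
  expect_error(bias_spec("point", 0.95, domain = c(0, 0.9)), "inside")
  expect_error(bias_spec("gaussian", 0.5, sd = -1), "nonnegative")
  expect_silent(degree_spec("exponential", 5))
})

test_that("out-degree sampling follows the requested distribution", {
  expect_identical(
    with_seed(1, sample_out_degrees(degree_spec("regular", 2), 9)),
    rep(2L, 9))

  d_pois <- with_seed(11, sample_out_degrees(degree_spec("poisson", 5), 10000))
  expect_lt(abs(mean(d_pois) - 5), 3 * sqrt(5 / 10000))

  d_exp <- with_seed(12, sample_out_degrees(degree_spec("exponential", 5),
                                            10000))
  # exponential variance (K^2) exceeds Poisson variance (K)
  expect_gt(var(d_exp), var(d_pois))
  expect_true(all(d_exp >= 0))
  d_exp1 <- with_seed(12, sample_out_degrees(
    degree_spec("exponential", 5, floor_at_one = TRUE), 10000))
  expect_true(all(d_exp1 >= 1))
})

test_that("sampled out-degree distributions match their targets (GOF)", {
  n <- 10000
  d <- with_seed(21, sample_out_degrees(degree_spec("poisson", 5), n))
  kmax <- max(d)
  probs <- dpois(0:kmax, 5)
  probs <- c(probs, 1 - sum(probs))
  obs <- c(tabulate(d + 1L, nbins = kmax + 1L), 0)
  keep <- probs * n >= 5
  pval <- suppressWarnings(
    chisq.test(obs[keep], p = probs[keep] / sum(probs[keep]))$p.value)
  expect_gt(pval, 0.01)

  # exponential: compare against the rounding discretization
  # P(k) = P(k - 0.5 < Exp(5) <= k + 0.5), P(0) = P(Exp <= 0.5)
  d2 <- with_seed(22, sample_out_degrees(degree_spec("exponential", 5), n))
  kmax2 <- max(d2)
  cdf <- function(x) pexp(x, rate = 1 / 5)
  probs2 <- c(cdf(0.5), cdf(1:kmax2 + 0.5) - cdf(1:kmax2 - 0.5))
  probs2 <- c(probs2, 1 - sum(probs2))
  obs2 <- c(tabulate(d2 + 1L, nbins = kmax2 + 1L), 0)
  keep2 <- probs2 * n >= 5
  pval2 <- suppressWarnings(
    chisq.test(obs2[keep2], p = probs2[keep2] / sum(probs2[keep2]))$p.value)
  expect_gt(pval2, 0.01)
})

test_that("wiring conserves edges and realizes out-degrees", {
  top0 <- with_seed(1, wire_from_out_degrees(c(0, 0, 0)))
  expect_identical(lengths(top0$in_neighbors), rep(0L, 3))

  top1 <- with_seed(1, wire_from_out_degrees(3))  # N = 1, forced self-loop
  expect_identical(top1$in_neighbors[[1]], 1L)    # duplicates collapsed
  expect_identical(top1$out_degree, 1L)

  for (s in 1:20) {
    d <- with_seed(s, sample_out_degrees(degree_spec("poisson", 3), 40))
    top <- with_seed(s + 100, wire_from_out_degrees(d))
    expect_identical(sum(in_degrees(top)), sum(top$out_degree))
    expect_identical(top$out_degree, pmin(d, 40L))
    # in-neighbor lists hold distinct regulators
    expect_true(all(vapply(top$in_neighbors,
                           function(v) !anyDuplicated(v), logical(1))))
  }

  # symmetry: E[in-degree of each node] equals the shared out-degree
  acc <- rowSums(vapply(1:300, function(s) {
    in_degrees(with_seed(s, wire_from_out_degrees(c(2, 2))))
  }, numeric(2)))
  expect_lt(abs(acc[1] / 300 - 2), 0.2)
  expect_lt(abs(acc[2] / 300 - 2), 0.2)
})

test_that("regular topologies have exact in-degree and conserve edges", {
  top <- with_seed(2, build_regular_topology(9, 2))
  expect_identical(lengths(top$in_neighbors), rep(2L, 9))

  top1 <- with_seed(1, build_regular_topology(1, 1))
  expect_identical(top1$in_neighbors[[1]], 1L)  # forced self-loop

  for (s in 1:10) {
    top <- with_seed(s, build_regular_topology(50, 5))
    expect_equal(mean(top$out_degree), 5)  # conservation, exact
  }
  expect_error(build_regular_topology(5, 0), "positive integer")
})

test_that("bias sampling respects kind, domain, and moments", {
  expect_identical(sample_biases(bias_spec("point", 0.5), 5), rep(0.5, 5))

  tri <- with_seed(3, sample_biases(bias_spec("triangular", 0.5), 10000))
  expect_lt(abs(mean(tri) - 0.5), 0.01)
  expect_true(all(tri >= 0 & tri <= 1))

  unif <- with_seed(4, sample_biases(bias_spec("uniform", 0.5), 10000))
  expect_lt(abs(sd(unif) - 0.288), 0.01)  # 1/sqrt(12) = 0.2887

  g <- with_seed(5, sample_biases(bias_spec("gaussian", 0.5, sd = 0.5,
                                            domain = c(0.2, 0.8)), 5000))
  expect_true(all(g >= 0.2 & g <= 0.8))

  # asymmetric triangular: mode at the stated mean, support = domain
  ta <- with_seed(6, sample_biases(bias_spec("triangular", 0.25), 5000))
  expect_true(all(ta >= 0 & ta <= 1))
  expect_lt(mean(ta), 0.5)
})

test_that("rule tables have the right sizes and bias fraction", {
  top <- with_seed(7, build_regular_topology(50, 4))
  rules <- with_seed(8, build_rules(top, rep(0.7, 50)))
  expect_true(all(lengths(rules$tables) == 16L))
  pooled <- unlist(rules$tables)
  se <- sqrt(0.7 * 0.3 / length(pooled))
  expect_lt(abs(mean(pooled) - 0.7), 3 * se)

  rules1 <- build_rules(top, rep(1, 50))
  expect_true(all(unlist(rules1$tables) == 1L))
  rules0 <- build_rules(top, rep(0, 50))
  expect_true(all(unlist(rules0$tables) == 0L))

  # zero in-degree node gets a single-entry table
  top0 <- wire_from_out_degrees(c(0, 0))
  r0 <- with_seed(9, build_rules(top0, c(0.5, 0.5)))
  expect_identical(lengths(r0$tables), c(1L, 1L))

  # in-degree above the threshold switches to a hashed rule
  topb <- new_topology_for_test(3, list(1:3, 1L, 2L))
  rb <- with_seed(10, build_rules(topb, rep(0.5, 3), max_table_k = 2))
  expect_identical(rb$hashed, c(TRUE, FALSE, FALSE))
  expect_null(rb$tables[[1]])
})

test_that("model construction is reproducible and records provenance", {
  m1 <- build_rbn(30, degree_spec("poisson", 5), bias_spec("point", 0.5),
                  seed = 42)
  m2 <- build_rbn(30, degree_spec("poisson", 5), bias_spec("point", 0.5),
                  seed = 42)
  expect_identical(m1, m2)
  expect_equal(m1$meta$structural$mean_k, 5)
  expect_equal(m1$meta$seed, 42)

  # HoS-HoF: mean in-degree tracks K by edge conservation
  m3 <- build_rbn(500, degree_spec("poisson", 5), bias_spec("point", 0.5),
                  seed = 7)
  expect_lt(abs(mean(in_degrees(m3$topology)) - 5), 0.5)

  # HeS-HeF: continuous per-node biases are almost surely distinct
  m4 <- build_rbn(100, degree_spec("exponential", 5),
                  bias_spec("triangular", 0.5), seed = 8)
  expect_identical(anyDuplicated(m4$rules$bias), 0L)
})
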