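test_that("schedules realize the three update schemes", {
  top <- with_seed(1, build_regular_topology(10, 2))
  expect_identical(build_schedule("synchronous", top)$period, rep(1L, 10))

  sch <- build_schedule("out_degree", top)
  expect_identical(sch$period, pmax(top$out_degree, 1L))

  expect_identical(build_schedule("ceil", top, mean_k = 4.2)$period,
                   rep(5L, 10))
  expect_identical(build_schedule("ceil", top, ceil_use_max = TRUE)$period,
                   rep(max(top$out_degree), 10L))
  expect_error(build_schedule("ceil", top), "mean_k")
})

test_that("out-degree updating fires exactly at multiples of the period", {
  # single node with out-degree 3 (self-loop x3 collapses; build by hand)
  m <- rbn_model_from_parts(list(2L, 1L, 1L),   # node1 <- node2; 2,3 <- node1
                            list(c(1L, 0L), c(1L, 0L), c(1L, 0L)))
  # node 1 has out-degree 2, nodes 2,3 out-degree 1
  sch <- build_schedule("out_degree", m$topology)
  expect_identical(sch$period, c(2L, 1L, 1L))
  # with period 2, node 1 must hold its state at odd steps
  s0 <- c(0L, 0L, 0L)
  s1 <- rbn_step(m, sch, s0, 1)      # nodes 2,3 update (NOT of node1 = 1)
  expect_identical(s1[1], 0L)
  s2 <- rbn_step(m, sch, s1, 2)      # node 1 due: NOT of node2 = 0
  expect_identical(s2[1], 1L - s1[2])
})

test_that("random states are uniform bits", {
  expect_identical(with_seed(5, random_state(5)),
                   with_seed(5, random_state(5)))
  x <- with_seed(6, random_state(1e5))
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_true(with_seed(7, random_state(1)) %in% c(0L, 1L))
})

test_that("single-step semantics match hand evaluation", {
  m <- xor_not_model()
  sch <- build_schedule("synchronous", m$topology)
  expect_identical(rbn_step(m, sch, c(1L, 0L), 1), c(1L, 0L))  # fixed point
  expect_identical(rbn_step(m, sch, c(1L, 1L), 1), c(0L, 0L))
  expect_identical(rbn_step(m, sch, c(0L, 1L), 1), c(1L, 1L))

  # no node due -> state unchanged
  sch7 <- structure(list(scheme = "ceil", period = rep(7L, 2)),
                    class = "rbn_schedule")
  expect_identical(rbn_step(m, sch7, c(0L, 1L), 3), c(0L, 1L))

  # zero in-degree node freezes at its constant table bit once it updates
  m0 <- rbn_model_from_parts(list(integer(0), 1L), list(1L, c(0L, 1L)))
  tr <- rbn_run(m0, build_schedule("synchronous", m0$topology),
                c(0L, 0L), 10)
  expect_true(all(tr[-1, 1] == 1L))
})

test_that("perturbations flip exactly the requested number of bits", {
  s <- rep(0L, 10)
  expect_identical(apply_perturbation(s, 0), s)
  expect_identical(with_seed(1, apply_perturbation(rep(0L, 4), 4)),
                   rep(1L, 4))
  for (r in 1:10) {
    out <- with_seed(r, apply_perturbation(s, 3))
    expect_identical(sum(out != s), 3L)
  }
  expect_error(apply_perturbation(s, 11), "\\[0, N\\]")
})

test_that("trajectories have the stated shape and perturbation timing", {
  m <- build_rbn(10, degree_spec("poisson", 2), seed = 1)
  sch <- build_schedule("synchronous", m$topology)
  init <- with_seed(2, random_state(10))

  tr1 <- rbn_run(m, sch, init, 1)
  expect_identical(dim(unclass(tr1)), c(1L, 10L))
  expect_identical(as.integer(tr1[1, ]), init)

  # X = N, O = 5, T = 100: all bits flip at t = 5, 10, ..., 95 and only there
  prot <- perturbation_protocol(10, 5, 100)
  set.seed(3)
  trp <- rbn_run(m, sch, init, 100, prot)
  trf <- rbn_run(m, sch, init, 100)
  expect_identical(dim(unclass(trp)), c(100L, 10L))
  # the first perturbation event is at t = 5 (row 6); rows 1..5 match the
  # free-running trajectory
  expect_identical(unclass(trp)[1:5, ], unclass(trf)[1:5, ])
  expect_true(any(trp[6, ] != trf[6, ]))
  # full flip: row at t=5 is the complement of the unperturbed step output
  st5 <- rbn_step(m, sch, as.integer(trp[5, ]), 5)
  expect_identical(as.integer(trp[6, ]), 1L - st5)

  expect_error(rbn_run(m, sch, init, 50, prot), "runtime")
})

test_that("engine agrees with the brute-force oracle on small networks", {
  for (rep in 1:12) {
    set.seed(rep * 13)
    n <- sample(2:4, 1)
    m <- build_rbn(n, degree_spec("poisson", 2), bias_spec("point", 0.5))
    for (scheme in c("synchronous", "out_degree", "ceil")) {
      sch <- build_schedule(scheme, m$topology, mean_k = 2.3)
      inits <- all_initial_states(n)
      for (i in seq_len(nrow(inits))) {
        got <- rbn_run(m, sch, inits[i, ], 20)
        want <- oracle_run(m, sch$period, inits[i, ], 20)
        expect_identical(unclass(got), want)
      }
    }
  }
})

test_that("unperturbed runs are deterministic and frozen nets fix by t=1", {
  m <- build_rbn(20, degree_spec("exponential", 3),
                 bias_spec("triangular", 0.5), seed = 4)
  sch <- build_schedule("out_degree", m$topology)
  init <- with_seed(5, random_state(20))
  expect_identical(rbn_run(m, sch, init, 50), rbn_run(m, sch, init, 50))

  frozen <- build_rbn(15, degree_spec("poisson", 2), bias_spec("point", 1),
                      seed = 6)
  trf <- rbn_run(frozen, build_schedule("synchronous", frozen$topology),
                 with_seed(7, random_state(15)), 10)
  for (t in 2:10) expect_identical(trf[t, ], trf[2, ])
})

test_that("hashed rules are deterministic and match the bias statistically", {
  withr::local_options(rbnhet.max_table_k = 3)
  m <- build_rbn(40, degree_spec("poisson", 6), bias_spec("point", 0.7),
                 seed = 8)
  expect_true(any(m$rules$hashed))
  sch <- build_schedule("synchronous", m$topology)
  init <- with_seed(9, random_state(40))
  expect_identical(rbn_run(m, sch, init, 30), rbn_run(m, sch, init, 30))
  # outputs of hashed nodes across many random input states ~ Bernoulli(0.7)
  hnodes <- which(m$rules$hashed)
  outs <- unlist(lapply(1:200, function(r) {
    s <- with_seed(r, random_state(40))
    rbn_step(m, sch, s, 1)[hnodes]
  }))
  se <- sqrt(0.7 * 0.3 / length(outs))
  expect_lt(abs(mean(outs) - 0.7), 4 * se)
})
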