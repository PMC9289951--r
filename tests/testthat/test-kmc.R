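test_that("a single kMC step draws the right target and waiting time", {
  rm2 <- rate_model(two_state(2), 1)
  set.seed(1)
  draws <- replicate(1000, kmc_step(rm2, 1)$next_node)
  expect_true(all(draws == 2))
  set.seed(1)
  waits <- replicate(1e4, kmc_step(rm2, 1)$waiting)
  expect_lt(abs(mean(waits) - 0.5), 3 * 0.5 / sqrt(1e4))

  # empirical branching frequencies: P = (0.25, 0.75) via barrier ln 3
  net <- ktn(data.frame(id = 1:3, energy = 0),
             data.frame(min1 = c(1, 1), min2 = c(2, 3),
                        energy = c(log(3), 0)))
  rm3 <- rate_model(net, 1)
  set.seed(5)
  nxt <- replicate(1e4, kmc_step(rm3, 1)$next_node)
  stderr3 <- sqrt(0.25 * 0.75 / 1e4)
  expect_lt(abs(mean(nxt == 2) - 0.25), 3 * stderr3)

  # fixed seed gives identical draws
  set.seed(33); a <- kmc_step(rm3, 1)
  set.seed(33); b <- kmc_step(rm3, 1)
  expect_identical(a, b)

  iso <- suppressWarnings(
    rate_model(ktn(data.frame(id = 1:3, energy = 0),
                   data.frame(min1 = 1, min2 = 2, energy = 1)), 1))
  expect_error(kmc_step(iso, 3), "no outgoing")
})

test_that("standard kMC reproduces exact MFPTs within Monte Carlo error", {
  ap <- two_state_problem(k = 2)
  ens <- run_kmc(ap, 1e5, seed = 4)
  expect_lt(abs(mean(ens$samples$t) - 0.5), 3 * 0.5 / sqrt(1e5))
  expect_true(all(ens$samples$s == 1))
  expect_true(all(ens$samples$path_end == 2))

  ens3 <- run_kmc(chain_problem(3), 1e5, seed = 4)
  se <- stats::sd(ens3$samples$t) / sqrt(1e5)
  expect_lt(abs(mean(ens3$samples$t) - 3), 3 * se)

  # reproducibility under the seed
  again <- run_kmc(chain_problem(3), 100, seed = 4)
  first <- run_kmc(chain_problem(3), 100, seed = 4)
  expect_identical(again$samples, first$samples)
})

test_that("trajectories beyond the step budget are flagged censored", {
  # mean absorption takes 25 steps; a budget of 20 censors a fraction
  ens <- run_kmc(chain_problem(6), 500, seed = 9, max_steps = 20)
  expect_true(any(ens$samples$censored))
  expect_true(any(!ens$samples$censored))
  expect_true(all(ens$samples$s[ens$samples$censored] == 20))
  h <- fpt_histogram(ens, "t")
  expect_equal(attr(h, "n_censored"), sum(ens$samples$censored))
})

test_that("the geometric recrossing sampler has the printed law", {
  set.seed(2)
  expect_true(all(sample_recross_count(0, 1000) == 0))
  draws <- sample_recross_count(0.5, 1e6)
  expect_lt(abs(mean(draws) - 1), 3 * sqrt(2) / sqrt(1e6))  # var = b/(1-b)^2
  # empirical pmf against (1-b) b^n
  emp <- tabulate(draws + 1, nbins = 5) / 1e6
  expect_equal(emp, 0.5^(1:5), tolerance = 0.02)
  # the printed worked value: x = 0.75, beta = 0.5 integerizes to 1
  expect_equal(ceiling(log1p(-0.75) / log(0.5)) - 1, 1)
  expect_error(sample_recross_count(1), "beta")
})

test_that("recrossing allocation matches multinomial moments both ways", {
  expect_equal(allocate_recrossings(7, 1), 7)
  expect_equal(allocate_recrossings(0, c(0.3, 0.7)), c(0, 0))
  q <- c(0.3, 0.7)
  N <- 1e4
  for (method in c("multinomial", "multinormal")) {
    set.seed(8)
    draws <- t(replicate(1e4, allocate_recrossings(N, q, method = method)))
    expect_true(all(rowSums(draws) == N))
    expect_true(all(draws >= 0))
    expect_true(all(draws == round(draws)))
    se_mean <- sqrt(N * q[1] * (1 - q[1])) / sqrt(1e4)
    expect_lt(abs(mean(draws[, 1]) - N * q[1]), 3 * se_mean)
    # variance within 3 stderr of N q (1 - q) (normal-theory stderr)
    v <- stats::var(draws[, 1])
    se_var <- N * q[1] * (1 - q[1]) * sqrt(2 / (1e4 - 1))
    expect_lt(abs(v - N * q[1] * (1 - q[1])), 3 * se_var)
    expect_lt(abs(stats::cov(draws[, 1], draws[, 2]) + N * q[1] * q[2]),
              3 * se_var)
  }
  expect_error(allocate_recrossings(3, numeric(0)), "neighbours")
})

test_that("leapfrog bookkeeping matches two-step path enumeration", {
  # chain b - i - a, all rates 1, current i
  ap <- chain_problem(3)
  tb <- leapfrog_table(ap, 2)
  expect_equal(tb$beta, 0.5, tolerance = 1e-14)
  expect_equal(tb$one_minus_beta, 0.5, tolerance = 1e-14)
  expect_equal(unname(tb$q), 1)
  expect_equal(tb$lf_probs$prob, 1)
  expect_equal(tb$lf_probs$target, 3)
  # tau_lf = (tau_i + P_bi tau_b) / (1 - beta) = (0.5 + 0.5 * 1) / 0.5 = 2
  expect_equal(tb$tau_lf, 2, tolerance = 1e-14)

  # node with all neighbours absorbing: beta = 0, exits are the branching
  # probabilities themselves
  net <- ktn(data.frame(id = 1:3, energy = 0),
             data.frame(min1 = c(1, 1), min2 = c(2, 3),
                        energy = c(log(3), 0)))
  ap2 <- absorbing_problem(rate_model(net, 1), products = c(2, 3),
                           reactants = 1)
  tb2 <- leapfrog_table(ap2, 1)
  expect_equal(tb2$beta, 0)
  expect_equal(sort(tb2$lf_probs$prob), c(0.25, 0.75), tolerance = 1e-12)

  # the stable 1 - beta identity against direct subtraction (beta <= 0.9)
  for (seed in 1:6) {
    ap_r <- random_problem(n = 8, extra = 4, seed = seed, temperature = 1.5)
    for (i in as.integer(names(ap_r$p0))) {
      tb_i <- leapfrog_table(ap_r, i)
      if (tb_i$beta <= 0.9) {
        expect_lt(abs(tb_i$one_minus_beta - (1 - tb_i$beta)), 1e-12)
      }
    }
  }
})

test_that("leapfrog exit probabilities always sum to one exactly", {
  for (Tt in c(1, 2)) {
    ap <- landscape_problem(fixture_landscape(), Tt)
    for (i in as.integer(names(ap$p0))) {
      tb <- leapfrog_table(ap, i)
      expect_lt(abs(sum(tb$lf_probs$prob) - 1), 1e-12)
      if (tb$beta > 0) expect_lt(abs(sum(tb$q) - 1), 1e-12)
    }
  }
})

test_that("a leapfrog move conserves the MFPT from its node", {
  # chain b - i - a from i: exact MFPT T_i = 2
  ap <- chain_problem(3)
  set.seed(14)
  moves <- replicate(1e5, leapfrog_step(ap, 2)$waiting)
  expect_lt(abs(mean(moves) - 2), 3 * stats::sd(moves) / sqrt(1e5))
  ends <- replicate(200, leapfrog_step(ap, 2)$next_node)
  expect_true(all(ends == 3))

  # all three waiting modes agree in expectation
  for (w in c("pair", "gamma", "mean")) {
    set.seed(15)
    mv <- replicate(2e4, leapfrog_step(ap, 2, wait = w)$waiting)
    expect_lt(abs(mean(mv) - 2), 3 * stats::sd(mv) / sqrt(2e4))
  }
})

test_that("leapfrog ensembles agree with standard kMC and GT", {
  # full-distribution agreement on the chain (two-sample KS, alpha = 0.001)
  ap <- chain_problem(4)
  std <- run_kmc(ap, 1e5, seed = 21)
  lf <- run_leapfrog(ap, 1e5, threshold = 0.1, seed = 22)
  ks <- suppressWarnings(stats::ks.test(std$samples$t, lf$samples$t))
  expect_gt(ks$p.value, 0.001)
  # implicit step counts agree in expectation
  se_s <- sqrt(stats::var(std$samples$s) / 1e5 + stats::var(lf$samples$s) / 1e5)
  expect_lt(abs(mean(std$samples$s) - mean(lf$samples$s)), 3 * se_s)

  # ensemble mean vs the GT reference on the fixture at T = 2
  ap2 <- landscape_problem(fixture_landscape(), 2)
  gt <- gt_mfpt(ap2)$mfpt
  lf2 <- run_leapfrog(ap2, 2e4, seed = 23)
  se <- stats::sd(lf2$samples$t) / sqrt(2e4)
  expect_lt(abs(mean(lf2$samples$t) - gt), 3 * se)

  # threshold insensitivity across the recommended range
  lo <- run_leapfrog(ap2, 2e4, threshold = 0.1, seed = 24)
  hi <- run_leapfrog(ap2, 2e4, threshold = 0.9, seed = 25)
  se2 <- sqrt(stats::var(lo$samples$t) / 2e4 + stats::var(hi$samples$t) / 2e4)
  expect_lt(abs(mean(lo$samples$t) - mean(hi$samples$t)), 3 * se2)

  # fixed seed reproducibility
  a <- run_leapfrog(ap2, 50, seed = 30)
  b <- run_leapfrog(ap2, 50, seed = 30)
  expect_identical(a$samples, b$samples)
})
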