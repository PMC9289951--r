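test_that("absorbing generator has the defining structure", {
  # two states, rate k = 2: M = [[-2]]
  ap <- two_state_problem(k = 2)
  M <- fpt_generator(ap)
  expect_equal(unname(M), matrix(-2), tolerance = 1e-14)

  # chain b - i - a, all rates 1: columns (b, i)
  ap3 <- chain_problem(3)
  M3 <- fpt_generator(ap3)
  expect_equal(unname(M3), matrix(c(-1, 1, 1, -2), 2), tolerance = 1e-14)

  # column sums of -M equal the rates into the absorbing set only
  expect_equal(-colSums(M3), c(0, 1), ignore_attr = TRUE, tolerance = 1e-14)

  # a node with no path to the products is rejected up front
  net <- ktn(data.frame(id = 1:4, energy = 0),
             data.frame(min1 = c(1, 3), min2 = c(2, 4), energy = 1))
  expect_error(absorbing_problem(rate_model(net, 1), products = 2, reactants = 1),
               "disconnected from products")
})

test_that("two-state decomposition is a single exponential", {
  sp <- spectral_fpt(two_state_problem(k = 2))
  expect_equal(sp$nu, 2, tolerance = 1e-14)
  expect_equal(sp$amp, 2, tolerance = 1e-14)
  expect_equal(fpt_density(sp, 0), 2, tolerance = 1e-12)
  expect_equal(fpt_density(sp, log(2) / 2), 1, tolerance = 1e-12)
  # moments n!/k^n and the variance 1/k^2
  for (n in 1:3) expect_equal(fpt_moments(sp, n), factorial(n) / 2^n)
  expect_equal(fpt_moments(sp, 2) - fpt_moments(sp, 1)^2, 1 / 4)
})

test_that("three-state chain matches the closed-form eigenproblem", {
  sp <- spectral_fpt(chain_problem(3))
  # eigenvalues of -M for the 2x2 block: (3 -+ sqrt(5))/2
  expect_equal(sp$nu, c((3 - sqrt(5)) / 2, (3 + sqrt(5)) / 2),
               tolerance = 1e-12)
  expect_equal(sum(sp$amp / sp$nu), 1, tolerance = 1e-10)
  # MFPT solves T_b = tau_b + T_i, T_i = tau_i + T_b / 2
  expect_equal(fpt_moments(sp, 1), 3, tolerance = 1e-12)
})

test_that("spectral density matches the matrix-exponential flux oracle", {
  for (seed in c(2, 5)) {
    ap <- random_problem(n = 9, extra = 4, seed = seed)
    sp <- spectral_fpt(ap)
    tt <- exp(seq(log(1e-2 / max(sp$nu)), log(3 / min(sp$nu)),
                  length.out = 20))
    expect_equal(fpt_density(sp, tt), flux_oracle(ap, tt),
                 tolerance = 1e-6)
  }
  # and pointwise at t = 1 on the chain, tighter
  ap3 <- chain_problem(3)
  expect_equal(fpt_density(spectral_fpt(ap3), 1), flux_oracle(ap3, 1),
               tolerance = 1e-10)
})

test_that("log-time density is the Jacobian transform and normalizes", {
  sp1 <- spectral_fpt(two_state_problem(k = 1))
  # mode of e^y p(e^y) at y = -ln k and value e^-1 at y = 0 for k = 1
  expect_equal(log_time_density(sp1, 0), exp(-1), tolerance = 1e-12)
  y <- seq(-8, 8, length.out = 2001)
  dens <- log_time_density(sp1, y)
  expect_equal(y[which.max(dens)], 0, tolerance = 0.01)

  sp2 <- spectral_fpt(two_state_problem(k = 2))
  y <- seq(-9, 7, length.out = 4001)
  expect_equal(y[which.max(log_time_density(sp2, y))], -log(2),
               tolerance = 0.01)

  # quadrature normalization on the chain
  sp3 <- spectral_fpt(chain_problem(3))
  q <- stats::integrate(function(z) log_time_density(sp3, z), -12, 12,
                        rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("numerically degenerate modes are merged before reporting", {
  # two identical uncoupled reactant branches feeding one absorbing state
  net <- ktn(data.frame(id = 1:3, energy = 0),
             data.frame(min1 = c(1, 2), min2 = c(3, 3), energy = 0))
  rm3 <- rate_model(net, 1)
  ap <- absorbing_problem(rm3, products = 3, reactants = c(1, 2),
                          p0 = c("1" = 0.5, "2" = 0.5))
  sp <- spectral_fpt(ap)
  expect_length(sp$nu, 1)
  expect_equal(sp$nu, 1, tolerance = 1e-12)
  expect_equal(sum(sp$amp / sp$nu), 1, tolerance = 1e-10)
})

test_that("truncated MFPT has the closed form and the long-time limit", {
  k <- 2
  sp <- spectral_fpt(two_state_problem(k = k))
  t_obs <- c(0.1, 0.5, 2, 10)
  res <- truncated_mfpt(sp, t_obs)
  closed <- (1 / k) * (1 - exp(-k * t_obs) * (1 + k * t_obs)) /
    (1 - exp(-k * t_obs))
  expect_equal(res$mean_fpt, closed, tolerance = 1e-12)
  expect_equal(res$z, 1 - exp(-k * t_obs), tolerance = 1e-12)

  # t_obs far beyond the slowest scale recovers the full MFPT and z -> 1
  sp3 <- spectral_fpt(chain_problem(4))
  lim <- truncated_mfpt(sp3, 1e3 / min(sp3$nu))
  expect_equal(lim$mean_fpt, fpt_moments(sp3, 1), tolerance = 1e-6)
  expect_equal(lim$z, 1, tolerance = 1e-10)

  # below the normalization floor the result is an explicit signal, not NaN
  tiny <- truncated_mfpt(sp, 1e-300)
  expect_false(tiny$feasible)
  expect_true(is.na(tiny$mean_fpt))
})

test_that("truncated MFPT is nondecreasing for positive-amplitude spectra", {
  set.seed(42)
  for (rep in 1:20) {
    L <- sample(2:6, 1)
    nu <- sort(exp(stats::runif(L, -4, 4)))
    w <- stats::runif(L)
    w <- w / sum(w)
    sp <- structure(list(nu = nu, amp = w * nu,
                         meta = list(temperature = 1)),
                    class = "spectral_fpt")
    grid <- exp(seq(log(1e-3 / max(nu)), log(1e3 / min(nu)),
                    length.out = 80))
    vals <- truncated_mfpt(sp, grid)$mean_fpt
    vals <- vals[is.finite(vals)]
    expect_true(all(diff(vals) > -1e-9 * vals[-length(vals)]))
  }
})

test_that("partial sums reproduce the MFPT and hand-evaluated truncations", {
  sp3 <- spectral_fpt(chain_problem(3))
  expect_equal(partial_sum_mfpt(sp3, length(sp3$nu)), fpt_moments(sp3, 1),
               tolerance = 1e-12)

  # 2-mode toy: keep = 1 retains only the fast mode
  nu <- c(1, 100)
  w <- c(0.6, 0.4)
  sp <- structure(list(nu = nu, amp = w * nu, meta = list()),
                  class = "spectral_fpt")
  expect_equal(partial_sum_mfpt(sp, 1), (w[2] / nu[2]) / w[2])
  expect_equal(partial_sum_mfpt(sp, 2),
               sum(w / nu) / sum(w))
  expect_error(partial_sum_mfpt(sp, 3), "keep")

  # plateau sequence nondecreasing in keep for positive amplitudes
  set.seed(7)
  for (rep in 1:10) {
    L <- sample(3:7, 1)
    nu <- sort(exp(stats::runif(L, -5, 5)))
    w <- stats::runif(L); w <- w / sum(w)
    spr <- structure(list(nu = nu, amp = w * nu, meta = list()),
                     class = "spectral_fpt")
    vals <- vapply(seq_len(L), function(k) partial_sum_mfpt(spr, k),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12 * vals[-L]))
  }
})

test_that("lowering the temperature shifts the slow peaks to larger ln t", {
  net <- fixture_landscape()
  pos <- lapply(c(2, 1), function(Tt) {
    sp <- spectral_fpt(landscape_problem(net, Tt))
    y <- seq(0, 40, length.out = 2000)
    detect_peaks(tibble::tibble(y = y, density = log_time_density(sp, y)))$y
  })
  # slowest three peaks move to significantly larger y at T = 1
  p2 <- utils::tail(pos[[1]], 3)
  p1 <- utils::tail(pos[[2]], 3)
  expect_true(all(p1 > p2 + 2))
})
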