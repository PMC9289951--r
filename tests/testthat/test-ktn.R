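test_that("validation reports structural violations without raising", {
  ok <- ktn(data.frame(id = 1:2, energy = 0),
            data.frame(min1 = 1, min2 = 2, energy = 2))
  expect_equal(nrow(validate_ktn(ok)), 0)

  dangling <- ktn(data.frame(id = 1:2, energy = 0),
                  data.frame(min1 = 1, min2 = 99, energy = 2))
  v <- validate_ktn(dangling)
  expect_equal(nrow(v), 1)
  expect_match(v$rule, "absent minimum id 99")

  low_ts <- ktn(data.frame(id = 1:2, energy = c(0, 1)),
                data.frame(min1 = 1, min2 = 2, energy = 0.5))
  v <- validate_ktn(low_ts)
  expect_equal(v$rule, "barrier below endpoints")

  expect_error(ktn(data.frame(id = 1, energy = 0),
                   data.frame(min1 = 1, min2 = 1, energy = 2)),
               "Self-loop")
})

test_that("permissive mode clamps low transition states with a warning", {
  expect_warning(
    net <- ktn(data.frame(id = 1:2, energy = c(0, 1)),
               data.frame(min1 = 1, min2 = 2, energy = 0.5), strict = FALSE),
    "clamped")
  expect_equal(net$ts$energy, 1)
  expect_equal(nrow(validate_ktn(net)), 0)
})

test_that("rate model reproduces hand-solved Boltzmann factors", {
  # symmetric pair: barrier 2, T = 1
  net <- ktn(data.frame(id = 1:2, energy = 0),
             data.frame(min1 = 1, min2 = 2, energy = 2))
  rm2 <- rate_model(net, 1)
  expect_equal(rm2$rates$k, rep(exp(-2), 2))
  expect_equal(rm2$states$tau, rep(exp(2), 2))
  expect_equal(rm2$rates$p, rep(1, 2))

  # asymmetric pair: detailed balance by construction
  net <- ktn(data.frame(id = 1:2, energy = c(0, -1)),
             data.frame(min1 = 1, min2 = 2, energy = 2))
  rm2 <- rate_model(net, 1)
  k12 <- rm2$rates$k[rm2$rates$from == 1]
  k21 <- rm2$rates$k[rm2$rates$from == 2]
  pi <- setNames(rm2$states$pi, rm2$states$id)
  expect_equal(k12 * pi["1"], k21 * pi["2"], ignore_attr = TRUE)
  # barrier from 1 is 2, from the deeper minimum 2 it is 3
  expect_equal(k12 / k21, exp(1))

  # 3-minimum chain with printed energies, hand-solved branching
  net <- ktn(data.frame(id = 1:3, energy = c(0, -1, 0.5)),
             data.frame(min1 = c(1, 2), min2 = c(2, 3), energy = c(1, 1.5)))
  rm3 <- rate_model(net, 2)
  # from minimum 2: barriers 2 and 2.5 -> rates e^-1, e^-1.25
  k_out <- rm3$rates[rm3$rates$from == 2, ]
  expect_equal(sort(k_out$k), sort(c(exp(-1), exp(-1.25))))
  expect_equal(rm3$states$tau[2], 1 / (exp(-1) + exp(-1.25)))
  expect_equal(sum(k_out$p), 1)
})

test_that("parallel transition states add their rates", {
  one <- rate_model(two_state(1), 1)
  three <- rate_model(two_state(3), 1)
  expect_equal(three$rates$k, 3 * one$rates$k)
})

test_that("rate model invariances hold on random networks", {
  for (seed in 1:5) {
    net <- random_ktn(n = 8, extra = 4, seed = seed)
    rm1 <- rate_model(net, 0.7)
    # branching probabilities sum to one
    psums <- tapply(rm1$rates$p, rm1$rates$from, sum)
    expect_true(all(abs(psums - 1) < 1e-12))
    # detailed balance edge by edge
    pi <- setNames(rm1$states$pi, rm1$states$id)
    flow <- rm1$rates$k * pi[as.character(rm1$rates$from)]
    rev_flow <- flow[match(paste(rm1$rates$from, rm1$rates$to),
                           paste(rm1$rates$to, rm1$rates$from))]
    expect_true(all(abs(flow - rev_flow) / flow < 1e-10))

    # global energy shift leaves everything unchanged
    shifted <- net
    shifted$minima$energy <- shifted$minima$energy + 5
    shifted$ts$energy <- shifted$ts$energy + 5
    rm2 <- rate_model(shifted, 0.7)
    expect_equal(rm2$rates$k, rm1$rates$k, tolerance = 1e-12)
    expect_equal(rm2$states$tau, rm1$states$tau, tolerance = 1e-12)

    # raising all barriers by delta scales every k by exp(-delta/T) and
    # leaves branching probabilities unchanged
    delta <- 0.8
    raised <- net
    raised$ts$energy <- raised$ts$energy + delta
    rm3 <- rate_model(raised, 0.7)
    expect_equal(rm3$rates$k, rm1$rates$k * exp(-delta / 0.7),
                 tolerance = 1e-12)
    expect_equal(rm3$rates$p, rm1$rates$p, tolerance = 1e-12)
  }
})

test_that("point-group orders enter rates and weights consistently", {
  net <- ktn(data.frame(id = 1:2, energy = 0, pg_order = c(2L, 1L)),
             data.frame(min1 = 1, min2 = 2, energy = 2))
  rm2 <- rate_model(net, 1)
  pi <- setNames(rm2$states$pi, rm2$states$id)
  k12 <- rm2$rates$k[rm2$rates$from == 1]
  k21 <- rm2$rates$k[rm2$rates$from == 2]
  expect_equal(k12 * pi["1"], k21 * pi["2"], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("zero-degree minima are flagged", {
  net <- ktn(data.frame(id = 1:3, energy = 0),
             data.frame(min1 = 1, min2 = 2, energy = 1))
  expect_warning(rm3 <- rate_model(net, 1), "zero-degree")
  expect_true(is.infinite(rm3$states$tau[3]))
  # acceptable when the isolated node is absorbing, rejected otherwise
  expect_error(absorbing_problem(rm3, products = 2, reactants = 1),
               "disconnected")
})

test_that("rate restriction masks without renormalizing and round-trips", {
  rm3 <- rate_model(chain_ktn(3), 1)
  id_view <- restrict_rates(rm3, integer())
  expect_false(any(id_view$p$masked))
  expect_equal(id_view$p$p, rm3$rates$p)

  masked <- restrict_rates(rm3, 1)
  expect_true(all(masked$p$masked[masked$p$from == 1]))
  # surviving rows untouched: still sum to one over all targets
  surviving <- masked$p[!masked$p$masked, ]
  psums <- tapply(surviving$p, surviving$from, sum)
  expect_true(all(abs(psums - 1) < 1e-12))
  # unmasking returns the original exactly
  expect_identical(restrict_rates(rm3, integer())$p$p, rm3$rates$p)
})
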