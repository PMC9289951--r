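# Shared fixtures, built in code.

# two states, total rate k from 1 to 2 realized as k parallel zero-barrier TSs
two_state <- function(k = 1) {
  ktn(data.frame(id = 1:2, energy = 0),
      data.frame(min1 = rep(1, k), min2 = rep(2, k), energy = 0))
}

two_state_problem <- function(k = 1, temperature = 1) {
  absorbing_problem(rate_model(two_state(k), temperature),
                    products = 2, reactants = 1)
}

# linear chain of n minima, all energies 0, zero-barrier TSs (all rates 1)
chain_ktn <- function(n = 3) {
  ktn(data.frame(id = seq_len(n), energy = 0),
      data.frame(min1 = seq_len(n - 1), min2 = seq_len(n - 1) + 1, energy = 0))
}

chain_problem <- function(n = 3, temperature = 1) {
  absorbing_problem(rate_model(chain_ktn(n), temperature),
                    products = n, reactants = 1)
}

# random connected reversible network: a spanning chain plus extra edges,
# random energies; deterministic under the supplied seed
random_ktn <- function(n = 10, extra = 5, seed = 1, emax = 3) {
  set.seed(seed)
  e_min <- round(stats::runif(n, -2, 0), 3)
  ts <- data.frame(min1 = seq_len(n - 1), min2 = seq_len(n - 1) + 1)
  for (k in seq_len(extra)) {
    pair <- sample.int(n, 2)
    ts <- rbind(ts, data.frame(min1 = pair[1], min2 = pair[2]))
  }
  hi <- pmax(e_min[ts$min1], e_min[ts$min2])
  ts$energy <- hi + round(stats::runif(nrow(ts), 0.1, emax), 3)
  ktn(data.frame(id = seq_len(n), energy = e_min), ts)
}

random_problem <- function(n = 10, extra = 5, seed = 1, temperature = 1) {
  absorbing_problem(rate_model(random_ktn(n, extra, seed), temperature),
                    products = n, reactants = 1)
}

# the frozen model landscape, shared across tests
fixture_landscape <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- multifunnel_landscape()
    net
  }
})

# dense matrix exponential by scaling and squaring with a Taylor core;
# independent of the package's eigendecomposition route
expm_dense <- function(A) {
  nrm <- max(colSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^j
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (q in 1:30) {
    term <- term %*% As / q
    E <- E + term
  }
  for (q in seq_len(j)) E <- E %*% E
  E
}

# oracle FPT density: flux into the absorbing set, -d/dt 1^T exp(Mt) P0
flux_oracle <- function(ap, t) {
  M <- fpt_generator(ap)
  p0 <- ap$p0
  vapply(t, function(tt) {
    -sum(M %*% (expm_dense(M * tt) %*% p0))
  }, numeric(1))
}
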