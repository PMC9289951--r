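# ---- engine table construction --------------------------------------------
# Engine node indexing: transient nodes first (order of names(ap$p0)), then
# absorbing nodes.  C++ kernels consume flat CSR-style arrays built here.

branching_matrix <- function(ap) {
  rm <- ap$rm
  ids <- rm$states$id
  P <- matrix(0, length(ids), length(ids),
              dimnames = list(as.character(ids), as.character(ids)))
  if (nrow(rm$rates) > 0) {
    P[cbind(match(rm$rates$to, ids), match(rm$rates$from, ids))] <- rm$rates$p
  }
  P
}

engine_nodes <- function(ap) {
  c(as.integer(names(ap$p0)), ap$products)
}

standard_tables <- function(ap) {
  if (!is.null(ap$cache) && !is.null(ap$cache$st)) return(ap$cache$st)
  nodes <- engine_nodes(ap)
  trans <- as.integer(names(ap$p0))
  n <- length(trans)
  P <- branching_matrix(ap)
  key <- as.character(nodes)
  ptr <- integer(n + 1)
  tgt <- integer(0); cum <- numeric(0)
  for (j in seq_len(n)) {
    col <- P[key, key[j]]
    nz <- which(col > 0)
    pr <- col[nz] / sum(col[nz])
    ptr[j + 1] <- ptr[j] + length(nz)
    tgt <- c(tgt, as.integer(nz - 1L))
    cum <- c(cum, cumsum(pr))
  }
  tau <- ap$rm$states$tau[match(trans, ap$rm$states$id)]
  out <- list(ptr = ptr, tgt = tgt, cum = cum, tau = tau)
  if (!is.null(ap$cache)) ap$cache$st <- out
  out
}

# Leapfrog bookkeeping per transient node i:
#   beta    recrossing probability sum over non-absorbing neighbours j,
#           beta_i = sum_j P_ji P_ij
#   omb     1 - beta computed by the stable identity
#           sum_{j in A} P_ji + sum_{j notin A} P_ji sum_{k != i} P_kj
#           (never as 1 - beta_i when beta_i is close to 1)
#   q       conditional recrossing distribution q_j = P_ji P_ij / beta_i
#   exits   renormalized leapfrog exit probabilities: to second neighbour k
#           (sum_j P_kj P_ji) / omb, to absorbing first neighbour j, P_ji / omb
#   tau_lf  renormalized waiting time (tau_i + sum_{j notin A} P_ji tau_j)/omb
leapfrog_tables <- function(ap) {
  if (!is.null(ap$cache) && !is.null(ap$cache$lf)) return(ap$cache$lf)
  nodes <- engine_nodes(ap)
  trans <- as.integer(names(ap$p0))
  n <- length(trans)
  nall <- length(nodes)
  P <- branching_matrix(ap)[as.character(nodes), as.character(nodes),
                            drop = FALSE]
  tau_all <- ap$rm$states$tau[match(nodes, ap$rm$states$id)]
  is_abs <- seq_len(nall) > n

  beta <- omb <- tau_lf <- taubar <- numeric(n)
  rc_ptr <- ex_ptr <- integer(n + 1)
  rc_j <- integer(0); rc_q <- rc_tau <- numeric(0)
  ex_tgt <- ex_kind <- integer(0); ex_cum <- numeric(0)
  ex_iptr <- 0L
  im_j <- integer(0); im_cum <- im_tau <- numeric(0)

  for (i in seq_len(n)) {
    nb <- which(P[, i] > 0)
    nb_t <- nb[!is_abs[nb]]          # non-absorbing neighbours
    nb_a <- nb[is_abs[nb]]           # absorbing first neighbours
    b_terms <- P[nb_t, i] * P[i, nb_t]
    beta[i] <- sum(b_terms)
    # stable 1 - beta
    omb_t <- vapply(nb_t, function(j) {
      ks <- which(P[, j] > 0)
      P[j, i] * sum(P[ks[ks != i], j])
    }, numeric(1))
    omb[i] <- sum(P[nb_a, i]) + sum(omb_t)
    if (omb[i] <= 0) {
      abort(sprintf(
        "Node %d and its neighbours admit no escape (beta = 1): trapped pair.",
        trans[i]))
    }
    q <- if (beta[i] > 0) b_terms / beta[i] else numeric(0)
    keep_q <- q > 0
    rc_ptr[i + 1] <- rc_ptr[i] + sum(keep_q)
    rc_j <- c(rc_j, as.integer(nb_t[keep_q] - 1L))
    rc_q <- c(rc_q, q[keep_q])
    rc_tau <- c(rc_tau, tau_all[nb_t[keep_q]])
    tau_lf[i] <- (tau_all[i] + sum(P[nb_t, i] * tau_all[nb_t])) / omb[i]
    taubar[i] <- sum(q[keep_q] * (tau_all[i] + tau_all[nb_t[keep_q]]))

    # exits: absorbing first neighbours (kind 0), second neighbours (kind 1)
    probs <- numeric(0); tgts <- integer(0); kinds <- integer(0)
    inter <- list()
    for (j in nb_a) {
      probs <- c(probs, P[j, i] / omb[i])
      tgts <- c(tgts, as.integer(j - 1L))
      kinds <- c(kinds, 0L)
      inter <- c(inter, list(NULL))
    }
    for (j in nb_t) {
      ks <- which(P[, j] > 0)
      ks <- ks[ks != i]
      for (k in ks) {
        probs <- c(probs, P[k, j] * P[j, i] / omb[i])
        tgts <- c(tgts, as.integer(k - 1L))
        kinds <- c(kinds, 1L)
        inter <- c(inter, list(list(j = as.integer(j - 1L), tau = tau_all[j])))
      }
    }
    stopifnot(abs(sum(probs) - 1) < 1e-9)
    ex_ptr[i + 1] <- ex_ptr[i] + length(probs)
    ex_tgt <- c(ex_tgt, tgts)
    ex_kind <- c(ex_kind, kinds)
    ex_cum <- c(ex_cum, cumsum(probs / sum(probs)))
    for (e in seq_along(probs)) {
      if (kinds[e] == 0L) {
        ex_iptr <- c(ex_iptr, ex_iptr[length(ex_iptr)])
      } else {
        ii <- inter[[e]]
        ex_iptr <- c(ex_iptr, ex_iptr[length(ex_iptr)] + 1L)
        im_j <- c(im_j, ii$j)
        im_cum <- c(im_cum, 1)
        im_tau <- c(im_tau, ii$tau)
      }
    }
  }
  out <- list(beta = beta, omb = omb, tau_lf = tau_lf, taubar = taubar,
              rc_ptr = rc_ptr, rc_j = rc_j, rc_q = rc_q, rc_tau = rc_tau,
              ex_ptr = ex_ptr, ex_tgt = ex_tgt, ex_kind = ex_kind,
              ex_cum = ex_cum, ex_iptr = as.integer(ex_iptr),
              im_j = im_j, im_cum = im_cum, im_tau = im_tau)
  if (!is.null(ap$cache)) ap$cache$lf <- out
  out
}

p0_cum <- function(ap) cumsum(ap$p0)

make_ensemble <- function(res, ap, nodes, engine, config) {
  samples <- tibble(
    t = as.numeric(res$t),
    s = as.numeric(res$s),
    path_end = nodes[res$end + 1L],
    censored = as.logical(res$censored)
  )
  structure(
    list(samples = samples, engine = engine, config = config),
    class = "fpt_ensemble"
  )
}

#' @export
print.fpt_ensemble <- function(x, ...) {
  ok <- !x$samples$censored
  cat(sprintf("<fpt_ensemble> %s kMC: %d runs (%d censored)\n",
              x$engine, nrow(x$samples), sum(!ok)))
  if (any(ok)) {
    cat(sprintf("  mean t = %.6g, mean s = %.6g\n",
                mean(x$samples$t[ok]), mean(x$samples$s[ok])))
  }
  invisible(x)
}

#' @export
tidy.fpt_ensemble <- function(x, ...) x$samples

#' @export
glance.fpt_ensemble <- function(x, ...) {
  ok <- !x$samples$censored
  tibble(engine = x$engine, n = nrow(x$samples), n_censored = sum(!ok),
         mean_t = mean(x$samples$t[ok]),
         se_t = stats::sd(x$samples$t[ok]) / sqrt(sum(ok)),
         mean_s = mean(x$samples$s[ok]),
         seed = x$config$seed %||% NA_integer_)
}

#' Plot the log-time histogram of an FPT ensemble
#'
#' @param object An `fpt_ensemble`.
#' @param which `"t"` or `"s"`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @export
autoplot.fpt_ensemble <- function(object, which = "t", bins = 120, ...) {
  h <- fpt_histogram(object, which = which, bins = bins)
  ggplot(h, aes(x = .data$y, y = .data$density)) +
    geom_col(width = diff(h$y[1:2]), fill = "grey40") +
    labs(x = sprintf("ln %s", which), y = "density",
         title = sprintf("%s kMC (%d runs)", object$engine,
                         nrow(object$samples))) +
    theme_minimal()
}

# ---- elementary moves ------------------------------------------------------

#' One rejection-free kMC step
#'
#' Draws the next node with the branching probabilities of the current node
#' and a waiting time from the Poisson escape distribution,
#' \eqn{-\tau_j \ln x} for \eqn{x} uniform on (0, 1].
#'
#' @param rm A [rate_model()].
#' @param current Current (non-absorbing) node id.
#' @return A list with `next_node` and `waiting`.
#' @export
kmc_step <- function(rm, current) {
  stopifnot(inherits(rm, "rate_model"))
  out <- rm$rates[rm$rates$from == current, ]
  if (nrow(out) == 0) abort(sprintf("Node %d has no outgoing transitions.", current))
  tau <- rm$states$tau[match(current, rm$states$id)]
  nxt <- out$to[sample_cum_r(cumsum(out$p / sum(out$p)))]
  list(next_node = nxt, waiting = -tau * log(runif(1)))
}

sample_cum_r <- function(cum) {
  x <- runif(1)
  min(which(x <= cum), length(cum))
}

#' Geometric recrossing-count sampler
#'
#' Samples the total number of recrossings \eqn{N} with
#' \eqn{P(N = n) = (1-\beta)\beta^n} by inverting the closed cumulative form
#' \eqn{P(N \le n) = 1 - \beta^{n+1}}: for \eqn{x} uniform,
#' \eqn{N = \lceil \ln(1-x)/\ln\beta \rceil - 1}, the smallest \eqn{n} with
#' \eqn{F(n) \ge x} (integerization of the continuous inverse
#' \eqn{\ln(1-x)/\ln\beta - 1}).
#'
#' @param beta Recrossing probability in \eqn{[0, 1)}.
#' @param n Number of draws.
#' @return Numeric vector of counts.
#' @export
sample_recross_count <- function(beta, n = 1) {
  if (beta < 0 || beta >= 1) abort("`beta` must lie in [0, 1).")
  cpp_sample_recross(beta, as.integer(n))
}

#' Allocate recrossings over neighbours
#'
#' Splits `N` total recrossings over the neighbours according to the
#' conditional distribution `q`, either by exact multinomial sampling or by
#' the multinormal approximation (mean \eqn{Nq}, covariance
#' \eqn{N(diag(q) - q\otimes q)}) realized with \eqn{m-1} standard normals
#' and a Householder rotation whose final column is \eqn{\sqrt{q}}.  The
#' default route applies the multinormal form when `beta > 0.95` and
#' `N > 1000`, where it is accurate, and exact sampling otherwise; a single
#' neighbour receives all `N` directly.
#'
#' @param N Total recrossing count (non-negative).
#' @param q Conditional neighbour distribution (sums to 1).
#' @param beta Recrossing probability used by the switch rule.
#' @param method `"auto"`, `"multinomial"`, or `"multinormal"`.
#' @return Integer-valued numeric vector of counts summing to `N`.
#' @export
allocate_recrossings <- function(N, q, beta = 0, method = "auto") {
  if (length(q) == 0) {
    if (N > 0) abort("Cannot allocate recrossings without neighbours.")
    return(numeric(0))
  }
  if (abs(sum(q) - 1) > 1e-8) abort("`q` must sum to 1.")
  cpp_allocate(N, q, beta, method)
}

#' Leapfrog bookkeeping for one node
#'
#' Returns the renormalized quantities used by a leapfrog move from node
#' `i`: the recrossing probability \eqn{\beta_i}, its stable complement, the
#' conditional recrossing distribution, the renormalized exit probabilities
#' (which sum to one), and the renormalized waiting time
#' \eqn{\tau^{lf}_i = (\tau_i + \sum_{j \notin A} P_{ji}\tau_j)/(1-\beta_i)},
#' which conserves the MFPT to products.
#'
#' @param ap An [absorbing_problem()].
#' @param i Non-absorbing node id.
#' @return A list with `beta`, `one_minus_beta`, `q` (named by neighbour
#'   id), `lf_probs` (tibble: `target`, `via`, `prob`, `kind`), `tau_lf`.
#' @export
leapfrog_table <- function(ap, i) {
  stopifnot(inherits(ap, "absorbing_problem"))
  nodes <- engine_nodes(ap)
  idx <- match(i, nodes)
  if (is.na(idx) || idx > length(ap$p0)) {
    abort("`i` must be a non-absorbing node of the problem.")
  }
  tb <- leapfrog_tables(ap)
  rs <- (tb$rc_ptr[idx] + 1):(tb$rc_ptr[idx + 1])
  has_rc <- tb$rc_ptr[idx + 1] > tb$rc_ptr[idx]
  es <- (tb$ex_ptr[idx] + 1):(tb$ex_ptr[idx + 1])
  pr <- diff(c(0, tb$ex_cum[es]))
  via <- rep(NA_integer_, length(es))
  second <- tb$ex_kind[es] == 1L
  if (any(second)) {
    ii <- tb$ex_iptr[es][second] + 1L
    via[second] <- nodes[tb$im_j[ii] + 1L]
  }
  list(
    beta = tb$beta[idx],
    one_minus_beta = tb$omb[idx],
    q = if (has_rc) setNames(tb$rc_q[rs], nodes[tb$rc_j[rs] + 1L]) else numeric(0),
    lf_probs = tibble(target = nodes[tb$ex_tgt[es] + 1L], via = via,
                      prob = pr, kind = ifelse(second, "second_neighbour",
                                               "absorbing_neighbour")),
    tau_lf = tb$tau_lf[idx]
  )
}

#' One leapfrog move
#'
#' Samples the recrossing count, allocates it over neighbours, accumulates
#' the associated waiting time, and draws the exit transition with the
#' renormalized probabilities.  See [run_leapfrog()] for the waiting-time
#' modes.
#'
#' @param ap An [absorbing_problem()].
#' @param i Current (non-absorbing) node id.
#' @param wait One of `"gamma"` (exact; default), `"pair"`, `"mean"`.
#' @return List with `next_node` (id), `waiting`, `steps` (implicit
#'   conventional steps, \eqn{2N} plus exit hops).
#' @export
leapfrog_step <- function(ap, i, wait = c("gamma", "pair", "mean")) {
  wait <- match.arg(wait)
  nodes <- engine_nodes(ap)
  idx <- match(i, nodes)
  n_trans <- length(ap$p0)
  if (is.na(idx) || idx > n_trans) {
    abort("`i` must be a non-absorbing node of the problem.")
  }
  st <- standard_tables(ap)
  lf <- leapfrog_tables(ap)
  res <- cpp_lf_move(idx - 1L, st, lf, n_trans,
                     match(wait, c("pair", "gamma", "mean")) - 1L)
  list(next_node = nodes[res$next_node + 1L],
       waiting = res$waiting, steps = res$steps)
}

# ---- trajectory ensembles --------------------------------------------------

#' Standard rejection-free kinetic Monte Carlo
#'
#' Samples `n_runs` first-passage trajectories from the initial condition of
#' `ap` until absorption, recording the first passage time `t`, the step
#' count `s` (dynamical activity), and the absorbing node reached.  Waiting
#' times follow the Poisson escape distribution of each visited node; the
#' per-trajectory total is accumulated as per-node Gamma(visits,
#' \eqn{\tau}) sums, identical in distribution to adding the individual
#' exponential waits.  Trajectories exceeding `max_steps` are flagged
#' censored (at low temperature the step count grows beyond any practical
#' budget -- that regime belongs to [run_leapfrog()] or [gt_mfpt()]).
#'
#' @param ap An [absorbing_problem()].
#' @param n_runs Number of trajectories.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param max_steps Per-trajectory step budget (default `1e9`).
#' @return An `fpt_ensemble`.
#' @export
run_kmc <- function(ap, n_runs, seed = NULL, max_steps = 1e9) {
  stopifnot(inherits(ap, "absorbing_problem"))
  if (!is.null(seed)) set.seed(seed)
  st <- standard_tables(ap)
  nodes <- engine_nodes(ap)
  res <- cpp_run_standard(as.integer(n_runs), p0_cum(ap),
                          st$ptr, st$tgt, st$cum, st$tau,
                          length(ap$p0), max_steps)
  make_ensemble(res, ap, nodes, "standard",
                list(seed = seed, n_runs = n_runs, max_steps = max_steps,
                     temperature = ap$rm$temperature, p0 = ap$p0_kind))
}

#' Leapfrog kinetic Monte Carlo
#'
#' Accelerated kMC: whenever the recrossing probability \eqn{\beta_i} of the
#' current node exceeds `threshold`, the full flickering episode is sampled
#' in one move -- a geometric total recrossing count, its allocation over
#' neighbours, the associated waiting time, and a renormalized exit to a
#' second neighbour or adjacent absorbing state; otherwise a standard kMC
#' step is taken.  Step counts record the implicit conventional steps
#' (2 per recrossing plus the exit hops), so `s` is comparable between
#' engines.  Results are insensitive to `threshold` over a wide range.
#'
#' @param ap An [absorbing_problem()].
#' @param n_runs Number of trajectories.
#' @param threshold Leapfrog activation threshold on \eqn{\beta_i}
#'   (default 0.5, the centre of the well-behaved range).
#' @param wait Waiting-time mode for the recrossing episode: `"gamma"`
#'   (default; exact Gamma sums of the per-visit exponential waits, so the
#'   sampled FPT distribution is exact at every recrossing count), `"pair"`
#'   (the per-neighbour expectation \eqn{n_j(\tau_i+\tau_j)}, accurate for
#'   large \eqn{N} but visibly too narrow when flickering episodes are
#'   short), or `"mean"` (mean single-recrossing waiting time times the
#'   count).  All three conserve the MFPT.
#' @param seed Optional integer seed.
#' @param max_steps Conventional-equivalent step budget per trajectory.
#' @return An `fpt_ensemble`.
#' @export
run_leapfrog <- function(ap, n_runs, threshold = 0.5,
                         wait = c("gamma", "pair", "mean"),
                         seed = NULL, max_steps = 1e15) {
  stopifnot(inherits(ap, "absorbing_problem"))
  wait <- match.arg(wait)
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  if (!is.null(seed)) set.seed(seed)
  st <- standard_tables(ap)
  lf <- leapfrog_tables(ap)
  nodes <- engine_nodes(ap)
  res <- cpp_run_leapfrog(as.integer(n_runs), p0_cum(ap), st, lf,
                          length(ap$p0), threshold,
                          match(wait, c("pair", "gamma", "mean")) - 1L,
                          max_steps)
  make_ensemble(res, ap, nodes, "leapfrog",
                list(seed = seed, n_runs = n_runs, threshold = threshold,
                     wait = wait, max_steps = max_steps,
                     temperature = ap$rm$temperature, p0 = ap$p0_kind))
}
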