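#' Convert a KTN into temperature-resolved rate constants
#'
#' Applies a harmonic, unit-prefactor rate convention with \eqn{k_B = 1}: the
#' rate for the transition from minimum \eqn{j} to minimum \eqn{i} through a
#' transition state is
#' \deqn{k_{ij} = o_j \exp[-((E_{ts}-E_j) + T(\Lambda_{ts}-\Lambda_j))/T],}
#' where \eqn{\Lambda} is the log product of frequencies and \eqn{o_j} the
#' point-group order of the starting minimum (its symmetry number, which also
#' enters the equilibrium weights \eqn{\pi_j \propto o_j^{-1}
#' e^{-E_j/T-\Lambda_j}} so that detailed balance \eqn{k_{ij}\pi_j =
#' k_{ji}\pi_i} holds exactly).  Parallel transition states contribute
#' additively.  Temperature is measured in the same units as the energies and
#' the time unit is the inverse of the unit prefactor.
#'
#' @param net A [ktn()] object.
#' @param temperature Positive temperature in energy units.
#' @return An object of class `rate_model` with components
#'   \describe{
#'     \item{states}{tibble: `id`, `energy`, `tau` (waiting time
#'       \eqn{\tau_j = 1/\sum_i k_{ij}}), `pi` (normalized equilibrium
#'       weight), `degree`.}
#'     \item{rates}{tibble of directed rates: `from`, `to`, `k` (rate of the
#'       `from` \eqn{\to} `to` transition) and branching probability `p`.}
#'   }
#'   Zero-degree minima are flagged with `tau = Inf` and a warning; they are
#'   only acceptable downstream if designated absorbing.
#' @examples
#' net <- ktn(data.frame(id = 1:2, energy = 0),
#'            data.frame(min1 = 1, min2 = 2, energy = 2))
#' rm2 <- rate_model(net, temperature = 1)
#' rm2$states$tau     # both exp(2)
#' @export
rate_model <- function(net, temperature) {
  stopifnot(inherits(net, "ktn"))
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    abort("`temperature` must be a single positive number.")
  }
  viol <- validate_ktn(net)
  if (nrow(viol) > 0) {
    abort(paste0("KTN fails validation; first violation: ",
                 viol$where[1], " ", viol$id[1], ": ", viol$rule[1]))
  }
  Tt <- temperature
  mins <- net$minima
  ts <- net$ts

  # directed rates: one row per TS per direction, then aggregate parallels
  if (nrow(ts) > 0) {
    both <- bind_rows(
      tibble(from = ts$min1, to = ts$min2, e_ts = ts$energy, l_ts = ts$log_freq_product),
      tibble(from = ts$min2, to = ts$min1, e_ts = ts$energy, l_ts = ts$log_freq_product)
    )
    idx <- match(both$from, mins$id)
    logk <- -((both$e_ts - mins$energy[idx]) / Tt +
                (both$l_ts - mins$log_freq_product[idx])) +
      log(mins$pg_order[idx])
    both$k <- exp(logk)
    rates <- both %>%
      group_by(.data$from, .data$to) %>%
      summarise(k = sum(.data$k), .groups = "drop")
  } else {
    rates <- tibble(from = integer(), to = integer(), k = double())
  }

  out_rate <- tapply(rates$k, factor(rates$from, levels = mins$id), sum)
  out_rate <- as.numeric(out_rate)
  out_rate[is.na(out_rate)] <- 0
  tau <- ifelse(out_rate > 0, 1 / out_rate, Inf)
  if (any(!is.finite(tau))) {
    warn(sprintf("%d zero-degree minimum/minima with infinite waiting time (ids: %s).",
                 sum(!is.finite(tau)),
                 paste(mins$id[!is.finite(tau)], collapse = ", ")))
  }

  # equilibrium weights via log-sum-exp
  logw <- -mins$energy / Tt - mins$log_freq_product - log(mins$pg_order)
  logw <- logw - max(logw)
  pi <- exp(logw) / sum(exp(logw))

  states <- tibble(
    id = mins$id, energy = mins$energy, tau = tau, pi = pi,
    degree = as.integer(
      table(factor(c(ts$min1, ts$min2), levels = mins$id)))
  )

  rates$p <- rates$k * states$tau[match(rates$from, states$id)]

  rm <- structure(
    list(states = states, rates = rates, temperature = Tt, ktn = net),
    class = "rate_model"
  )
  check_rate_model(rm)
  rm
}

# internal invariant checks: branching probabilities sum to one and
# detailed balance holds edge by edge
check_rate_model <- function(rm, p_tol = 1e-12, db_tol = 1e-10) {
  if (nrow(rm$rates) == 0) return(invisible(rm))
  psum <- tapply(rm$rates$p, factor(rm$rates$from, levels = rm$states$id), sum)
  psum <- psum[!is.na(psum)]
  if (any(abs(psum - 1) > p_tol)) {
    abort("Branching probabilities do not sum to 1 within tolerance.")
  }
  r <- rm$rates
  pi <- rm$states$pi[match(r$from, rm$states$id)]
  flow <- r$k * pi
  key_fwd <- paste(r$from, r$to)
  key_rev <- paste(r$to, r$from)
  rev_flow <- flow[match(key_fwd, key_rev)]
  rel <- abs(flow - rev_flow) / pmax(abs(flow), abs(rev_flow))
  if (any(rel > db_tol, na.rm = TRUE)) {
    abort("Detailed balance violated beyond tolerance.")
  }
  invisible(rm)
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> T = %g, %d states, %d directed rates\n",
              x$temperature, nrow(x$states), nrow(x$rates)))
  invisible(x)
}

#' @export
tidy.rate_model <- function(x, ...) x$rates

#' @export
glance.rate_model <- function(x, ...) {
  tibble(temperature = x$temperature,
         n_states = nrow(x$states),
         n_rates = nrow(x$rates),
         min_tau = min(x$states$tau),
         max_tau = max(x$states$tau))
}

#' Restrict branching probabilities and waiting times to a node subset
#'
#' Returns a bookkeeping view in which the outgoing entries of the excluded
#' nodes are masked.  Probabilities are \emph{not} renormalized: the rows of
#' surviving nodes are untouched, so their branching probabilities still sum
#' to one over all targets including excluded ones.  Unmasking (`exclude =
#' integer()`) returns the original quantities exactly.
#'
#' @param rm A [rate_model()].
#' @param exclude Integer vector of node ids whose outgoing transitions are
#'   masked.
#' @return A list with `p` (branching tibble with a logical `masked` column),
#'   `tau` (named waiting-time vector over non-excluded nodes) and `exclude`.
#' @export
restrict_rates <- function(rm, exclude = integer()) {
  stopifnot(inherits(rm, "rate_model"))
  if (!all(exclude %in% rm$states$id)) {
    abort("`exclude` contains unknown node ids.")
  }
  p <- rm$rates[, c("from", "to", "p")]
  p$masked <- p$from %in% exclude
  keep <- !(rm$states$id %in% exclude)
  structure(
    list(p = p,
         tau = setNames(rm$states$tau[keep], rm$states$id[keep]),
         exclude = as.integer(exclude)),
    class = "rate_restriction"
  )
}

# dense rate matrix K with K[i, j] = rate j -> i, dimnames = state ids
rate_matrix <- function(rm) {
  ids <- rm$states$id
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(as.character(ids), as.character(ids)))
  if (nrow(rm$rates) > 0) {
    K[cbind(match(rm$rates$to, ids), match(rm$rates$from, ids))] <- rm$rates$k
  }
  K
}
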