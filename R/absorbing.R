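#' Define an absorbing first-passage problem on a rate model
#'
#' Splits the network into absorbing products \eqn{A}, reactants \eqn{B}, and
#' intervening states \eqn{I}, and fixes the initial occupation distribution
#' over the non-absorbing states \eqn{B \cup I}.  First passage to \eqn{A} is
#' well defined only if every non-absorbing state has a path to \eqn{A}.
#'
#' @param rm A [rate_model()].
#' @param products Integer ids of the absorbing product minima (nonempty).
#' @param reactants Integer ids of the reactant minima (nonempty, disjoint
#'   from `products`).
#' @param p0 Initial condition: `"delta"` (all mass on `start`; the default,
#'   used with a high-lying starting minimum in the worked examples),
#'   `"boltzmann"` (equilibrium-weighted within the reactant set), or a named
#'   numeric vector of occupation probabilities over non-absorbing states.
#' @param start Minimum id carrying the delta initial condition; defaults to
#'   the first reactant.
#' @return An object of class `absorbing_problem`.
#' @export
absorbing_problem <- function(rm, products, reactants,
                              p0 = c("delta", "boltzmann"), start = NULL) {
  stopifnot(inherits(rm, "rate_model"))
  products <- as.integer(products)
  reactants <- as.integer(reactants)
  ids <- rm$states$id
  if (length(products) == 0 || length(reactants) == 0) {
    abort("`products` and `reactants` must both be nonempty.")
  }
  if (!all(c(products, reactants) %in% ids)) {
    abort("Unknown node id in `products` or `reactants`.")
  }
  if (length(intersect(products, reactants)) > 0) {
    abort("`products` and `reactants` must be disjoint.")
  }
  trans <- setdiff(ids, products)  # non-absorbing: B and I

  # every non-absorbing node must reach A through the network
  g <- ktn_graph(rm$ktn)
  dist <- igraph::distances(g, v = as.character(trans),
                            to = as.character(products))
  unreachable <- trans[!is.finite(apply(dist, 1, min))]
  if (length(unreachable) > 0) {
    abort(paste0("Node(s) disconnected from products: ",
                 paste(unreachable, collapse = ", "), "."))
  }
  iso <- trans[!is.finite(rm$states$tau[match(trans, ids)])]
  if (length(iso) > 0) {
    abort(paste0("Non-absorbing node(s) with no outgoing rate: ",
                 paste(iso, collapse = ", "), "."))
  }

  if (is.character(p0)) {
    p0 <- match.arg(p0)
    if (p0 == "delta") {
      if (is.null(start)) start <- reactants[1]
      if (!start %in% trans) abort("`start` must be a non-absorbing node.")
      p0_vec <- setNames(as.numeric(trans == start), trans)
      p0_kind <- sprintf("delta(%d)", start)
    } else {
      w <- rm$states$pi[match(reactants, ids)]
      p0_vec <- setNames(numeric(length(trans)), trans)
      p0_vec[as.character(reactants)] <- w / sum(w)
      p0_kind <- "boltzmann(B)"
    }
  } else {
    if (is.null(names(p0))) abort("A numeric `p0` must be named by node id.")
    if (any(p0 < 0)) abort("`p0` must be non-negative.")
    p0_vec <- setNames(numeric(length(trans)), trans)
    if (!all(names(p0) %in% as.character(trans))) {
      abort("`p0` may only place mass on non-absorbing nodes.")
    }
    p0_vec[names(p0)] <- p0
    if (abs(sum(p0_vec) - 1) > 1e-12) abort("`p0` must sum to 1 within 1e-12.")
    p0_kind <- "custom"
  }

  structure(
    list(rm = rm, products = products, reactants = reactants,
         intervening = setdiff(trans, reactants),
         p0 = p0_vec, p0_kind = p0_kind,
         cache = new.env(parent = emptyenv())),
    class = "absorbing_problem"
  )
}

#' @export
print.absorbing_problem <- function(x, ...) {
  cat(sprintf("<absorbing_problem> T = %g: |A| = %d, |B| = %d, |I| = %d, p0 = %s\n",
              x$rm$temperature, length(x$products), length(x$reactants),
              length(x$intervening), x$p0_kind))
  invisible(x)
}

#' Generator matrix of the absorbing master equation
#'
#' Builds the matrix \eqn{M = K - D} over the non-absorbing states: the
#' off-diagonal entries are the inter-state rates \eqn{k_{ij}} and the
#' diagonal holds minus the total escape rate of each state, including escape
#' into the absorbing set, so that column sums are non-positive and strictly
#' negative for states adjacent to the products.  The occupation probabilities
#' evolve as \eqn{dP/dt = M P}.
#'
#' @param ap An [absorbing_problem()].
#' @return A dense matrix with dimnames given by the non-absorbing node ids.
#' @export
fpt_generator <- function(ap) {
  stopifnot(inherits(ap, "absorbing_problem"))
  ids <- ap$rm$states$id
  trans <- as.integer(names(ap$p0))
  K <- rate_matrix(ap$rm)
  tot_escape <- colSums(K)  # includes flow into absorbing targets
  tk <- as.character(trans)
  M <- K[tk, tk, drop = FALSE]
  diag(M) <- diag(M) - tot_escape[tk]
  M
}
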