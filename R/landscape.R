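#' Generate a synthetic multifunnel model landscape
#'
#' Builds the package's model KTN: a main path of `main_path_length` minima
#' (reactant at one end, product at the other) with side branches that descend
#' into kinetic traps of increasing depth.  Each branch is a dangling chain of
#' `minima_per_trap` minima at the trap-bottom energy, pairwise separated by
#' the low `internal_barrier` so that trajectories flicker rapidly inside the
#' trap, while escape back to the main path must surmount
#' `trap_depths[j] + branch_entry_barrier` -- strictly increasing with the
#' branch index.  This produces a hierarchy of well-separated relaxation time
#' scales: one peak in the log-time FPT density per trap.
#'
#' Deeper traps are attached closer to the product end of the main path, where
#' an unbiased walk from the reactant makes fewer visits, so the slow channels
#' carry progressively less weight.  The default parameters are frozen so
#' that the four trap peaks resolve in \eqn{\tilde p(\ln t)} at both T = 1 and
#' T = 2 while conventional kMC remains feasible at T = 2 (see the package
#' vignette for the calibration record).
#'
#' @param n_branches Number of trap branches (default 4).
#' @param trap_depths Depth of each trap bottom below the main path, one value
#'   per branch, increasing.
#' @param branch_entry_barrier Barrier from the main path into each branch
#'   (TS energy above the main level); a scalar, or one value per branch
#'   (typically increasing, so that deeper traps are entered more rarely and
#'   the slow relaxation channels carry less weight).  Must exceed
#'   `internal_barrier`.
#' @param internal_barrier Barrier between adjacent trap minima (low, to
#'   induce flickering).
#' @param minima_per_trap Number of minima per trap chain (>= 2).
#' @param main_path_length Number of main-path minima (>= 2).
#' @param main_barrier Barrier between adjacent main-path minima; a scalar or
#'   one value per main-path edge.  The default raises the barrier of the
#'   edge just past the first branch point (a "gate"), so that trajectories
#'   explore the shallowest trap before committing to the rest of the path
#'   and essentially no trajectory relaxes without sampling at least one
#'   trap.
#' @param seed Unused for the deterministic construction; accepted so a
#'   landscape specification can carry one.
#' @return A [ktn()] with attributes `reactant` and `product` (minimum ids)
#'   and `landscape_spec` (the parameter list).
#' @examples
#' net <- multifunnel_landscape()
#' nrow(net$minima)   # main_path_length + n_branches * minima_per_trap
#' @export
multifunnel_landscape <- function(n_branches = 4,
                                  trap_depths = c(2, 9.5, 14.8, 20),
                                  branch_entry_barrier = c(1.2, 2, 2.8, 3.6),
                                  internal_barrier = 1,
                                  minima_per_trap = 3,
                                  main_path_length = 6,
                                  main_barrier = c(1, 3.6, 1, 1, 1),
                                  seed = NULL) {
  if (length(trap_depths) != n_branches) {
    abort("`trap_depths` must have one entry per branch.")
  }
  if (n_branches > 0) {
    branch_entry_barrier <- rep_len(branch_entry_barrier, n_branches)
    if (any(diff(trap_depths) <= 0)) abort("`trap_depths` must be increasing.")
    if (any(trap_depths <= 0)) abort("`trap_depths` must be positive.")
    if (any(internal_barrier >= branch_entry_barrier)) {
      abort("`internal_barrier` must be below `branch_entry_barrier`.")
    }
    if (main_path_length < n_branches + 2) {
      abort("Not enough interior main-path nodes to attach all branches.")
    }
  }
  if (minima_per_trap < 2) abort("`minima_per_trap` must be at least 2.")
  if (main_path_length < 2) abort("`main_path_length` must be at least 2.")

  L <- main_path_length
  main_barrier <- rep_len(main_barrier, L - 1)
  mins <- tibble(id = seq_len(L), energy = 0)
  ts <- tibble(min1 = seq_len(L - 1), min2 = seq_len(L - 1) + 1,
               energy = main_barrier)

  if (n_branches > 0) {
    # interior attachment nodes: shallowest trap nearest the reactant (id 1),
    # deepest nearest the product (id L)
    attach_at <- seq(2, L - 1, length.out = n_branches)
    attach_at <- as.integer(round(attach_at))
    next_id <- L
    for (j in seq_len(n_branches)) {
      d <- trap_depths[j]
      trap_ids <- next_id + seq_len(minima_per_trap)
      next_id <- max(trap_ids)
      mins <- bind_rows(mins, tibble(id = trap_ids, energy = -d))
      ts <- bind_rows(
        ts,
        # entry TS: escape barrier from the trap bottom is d + entry barrier
        tibble(min1 = attach_at[j], min2 = trap_ids[1],
               energy = branch_entry_barrier[j]),
        # low internal barriers along the trap chain (flicker pairs)
        if (minima_per_trap > 1) {
          tibble(min1 = trap_ids[-minima_per_trap],
                 min2 = trap_ids[-1],
                 energy = -d + internal_barrier)
        }
      )
    }
  }
  ts$id <- seq_len(nrow(ts))

  net <- ktn(mins, ts, strict = TRUE)
  attr(net, "reactant") <- 1L
  attr(net, "product") <- L
  attr(net, "landscape_spec") <- list(
    n_branches = n_branches, trap_depths = trap_depths,
    branch_entry_barrier = branch_entry_barrier,
    internal_barrier = internal_barrier,
    minima_per_trap = minima_per_trap,
    main_path_length = main_path_length,
    main_barrier = main_barrier, seed = seed)
  net
}

#' Absorbing problem for a generated landscape
#'
#' Convenience wrapper: absorbs at the product minimum of a
#' [multifunnel_landscape()] and starts from a delta distribution on the
#' reactant minimum.
#'
#' @param net A landscape KTN carrying `reactant`/`product` attributes.
#' @param temperature Temperature in energy units.
#' @return An [absorbing_problem()].
#' @export
landscape_problem <- function(net, temperature) {
  r <- attr(net, "reactant"); p <- attr(net, "product")
  if (is.null(r) || is.null(p)) {
    abort("`net` does not carry reactant/product placement tags.")
  }
  absorbing_problem(rate_model(net, temperature),
                    products = p, reactants = r, p0 = "delta")
}
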