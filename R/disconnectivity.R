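#' Disconnectivity tree of a KTN
#'
#' Builds the superbasin merge tree over a descending ladder of energy
#' thresholds: at threshold \eqn{e}, two minima belong to the same superbasin
#' iff they are connected by a path whose every transition state lies at or
#' below \eqn{e} -- equivalently, branches merge when the energy exceeds the
#' highest transition state on the lowest-energy path between the minima.
#' Implemented with union--find per level, from the bottom of the ladder up.
#'
#' @param net A [ktn()].
#' @param delta_e Threshold spacing (positive).
#' @param e_max Top threshold; defaults to the highest TS energy plus
#'   `delta_e`.
#' @return A `disconnectivity_tree`: list with
#'   \describe{
#'     \item{leaves}{tibble `id`, `energy`, `x` (plot position chosen to
#'       keep each subtree contiguous, deepest subtrees ordered first).}
#'     \item{nodes}{tibble of internal merge nodes: `node`, `threshold`,
#'       `members` (list-column of minimum ids), `parent`.}
#'   }
#' @export
disconnectivity_tree <- function(net, delta_e, e_max = NULL) {
  stopifnot(inherits(net, "ktn"))
  if (delta_e <= 0) abort("`delta_e` must be positive.")
  ids <- net$minima$id
  energies <- setNames(net$minima$energy, ids)
  if (is.null(e_max)) {
    e_max <- if (nrow(net$ts) > 0) max(net$ts$energy) + delta_e
             else max(energies) + delta_e
  }
  lo <- min(energies)
  thresholds <- seq(e_max, lo, by = -delta_e)
  thresholds <- sort(thresholds)  # ascending: build bottom-up

  # union-find
  parent_uf <- seq_along(ids)
  find <- function(a) {
    while (parent_uf[a] != a) {
      parent_uf[a] <<- parent_uf[parent_uf[a]]
      a <- parent_uf[a]
    }
    a
  }
  # cluster id (index into `nodes` list) currently representing each root;
  # 0 means a bare leaf cluster
  nodes <- list()
  clus <- setNames(rep(NA_integer_, length(ids)), ids)

  comp_members <- function() {
    split(ids, vapply(seq_along(ids), function(a) find(a), integer(1)))
  }

  for (th in thresholds) {
    es <- net$ts[net$ts$energy <= th, ]
    changed <- FALSE
    if (nrow(es) > 0) {
      for (k in seq_len(nrow(es))) {
        a <- find(match(es$min1[k], ids))
        b <- find(match(es$min2[k], ids))
        if (a != b) { parent_uf[a] <- b; changed <- TRUE }
      }
    }
    if (changed) {
      # record merge nodes at this threshold for components holding >1
      # previous cluster/leaf
      comps <- comp_members()
      for (members in comps) {
        if (length(members) < 2) next
        sub <- unique(clus[as.character(members)])
        reps <- sub[!is.na(sub)]
        n_child <- length(reps) + sum(is.na(clus[as.character(members)]))
        existing <- if (length(reps) > 0) {
          any(vapply(reps, function(r) {
            setequal(nodes[[r]]$members, members)
          }, logical(1)))
        } else FALSE
        if (!existing && n_child > 1) {
          nodes[[length(nodes) + 1L]] <- list(
            node = length(nodes) + 1L, threshold = th,
            members = sort(members), children = reps)
          clus[as.character(members)] <- length(nodes)
        }
      }
    }
  }

  node_tbl <- if (length(nodes) > 0) {
    tibble(
      node = vapply(nodes, `[[`, integer(1), "node"),
      threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
      members = lapply(nodes, `[[`, "members")
    )
  } else {
    tibble(node = integer(), threshold = double(), members = list())
  }
  # parent: smallest strictly-larger member set
  node_tbl$parent <- vapply(seq_len(nrow(node_tbl)), function(k) {
    mk <- node_tbl$members[[k]]
    sup <- which(vapply(seq_len(nrow(node_tbl)), function(q) {
      q != k && all(mk %in% node_tbl$members[[q]]) &&
        length(node_tbl$members[[q]]) > length(mk)
    }, logical(1)))
    if (length(sup) == 0) NA_integer_
    else sup[which.min(lengths(node_tbl$members[sup]))]
  }, integer(1))

  leaves <- tibble(id = ids, energy = unname(energies[as.character(ids)]))
  leaves$x <- order_leaves(node_tbl, leaves)

  structure(list(leaves = leaves, nodes = node_tbl,
                 delta_e = delta_e, e_max = e_max),
            class = "disconnectivity_tree")
}

# leaf layout: recursive, children ordered by subtree minimum energy
# (deepest funnel first) -- keeps subtrees contiguous and minimizes crossings
order_leaves <- function(node_tbl, leaves) {
  if (nrow(node_tbl) == 0) return(seq_len(nrow(leaves)))
  roots <- which(is.na(node_tbl$parent))
  pos <- numeric(nrow(leaves))
  counter <- 0L
  emin <- function(ids_in) min(leaves$energy[leaves$id %in% ids_in])
  assign_pos <- function(members, node_idx) {
    kids <- which(!is.na(node_tbl$parent) & node_tbl$parent == node_idx)
    covered <- integer(0)
    subsets <- list()
    for (k in kids) {
      subsets[[length(subsets) + 1L]] <- list(type = "node", k = k,
                                              m = node_tbl$members[[k]])
      covered <- c(covered, node_tbl$members[[k]])
    }
    for (l in setdiff(members, covered)) {
      subsets[[length(subsets) + 1L]] <- list(type = "leaf", id = l, m = l)
    }
    ord <- order(vapply(subsets, function(s) emin(s$m), numeric(1)))
    for (s in subsets[ord]) {
      if (s$type == "leaf") {
        counter <<- counter + 1L
        pos[leaves$id == s$id] <<- counter
      } else {
        assign_pos(s$m, s$k)
      }
    }
  }
  all_in_nodes <- unique(unlist(node_tbl$members[roots]))
  for (r in roots[order(vapply(roots, function(r) emin(node_tbl$members[[r]]),
                               numeric(1)))]) {
    assign_pos(node_tbl$members[[r]], r)
  }
  for (l in setdiff(leaves$id, all_in_nodes)) {
    counter <- counter + 1L
    pos[leaves$id == l] <- counter
  }
  pos
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat(sprintf("<disconnectivity_tree> %d minima, %d merge nodes, dE = %g\n",
              nrow(x$leaves), nrow(x$nodes), x$delta_e))
  invisible(x)
}

#' @export
tidy.disconnectivity_tree <- function(x, ...) {
  tibble(node = x$nodes$node, threshold = x$nodes$threshold,
         n_members = lengths(x$nodes$members), parent = x$nodes$parent)
}

#' Superbasin membership at one threshold
#'
#' @param x A `disconnectivity_tree` or [ktn()].
#' @param threshold Energy threshold.
#' @param net The KTN (required when `x` is a tree without one embedded).
#' @return A named integer vector: superbasin label per minimum id.
#' @export
superbasins <- function(x, threshold, net = NULL) {
  net <- if (inherits(x, "ktn")) x else net
  if (is.null(net)) abort("Provide the KTN via `net`.")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(net$ts$min1[net$ts$energy <= threshold]),
                   to = as.character(net$ts$min2[net$ts$energy <= threshold])),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$minima$id)))
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), names(comp))
}

#' Plot a disconnectivity tree
#'
#' Classic representation: vertical leaf stems from each minimum energy up
#' to its first merge level, then merged stems continuing upward.
#'
#' @param object A `disconnectivity_tree`.
#' @param ... Unused.
#' @export
autoplot.disconnectivity_tree <- function(object, ...) {
  lv <- object$leaves
  nd <- object$nodes
  node_x <- vapply(seq_len(nrow(nd)), function(k) {
    mean(lv$x[lv$id %in% nd$members[[k]]])
  }, numeric(1))
  first_merge <- vapply(lv$id, function(id) {
    holds <- which(vapply(nd$members, function(m) id %in% m, logical(1)))
    if (length(holds) == 0) object$e_max else min(nd$threshold[holds])
  }, numeric(1))
  seg_leaf <- tibble(x = lv$x, xend = lv$x, y = lv$energy, yend = first_merge)
  segs <- seg_leaf
  if (nrow(nd) > 0) {
    up <- vapply(seq_len(nrow(nd)), function(k) {
      p <- nd$parent[k]
      if (is.na(p)) object$e_max else nd$threshold[p]
    }, numeric(1))
    segs <- bind_rows(
      segs,
      tibble(x = node_x, xend = node_x, y = nd$threshold, yend = up)
    )
  }
  ggplot(segs) +
    geom_segment(aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    labs(x = NULL, y = "energy") +
    theme_minimal()
}
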