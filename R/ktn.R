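#' Construct a kinetic transition network
#'
#' A kinetic transition network (KTN) is a weighted multigraph whose nodes are
#' local minima of an energy landscape and whose edges are the transition
#' states (TSs) connecting them.  Energies are in model units; `log_freq_product`
#' holds the log product of normal-mode frequencies used by the harmonic rate
#' convention (zero for model landscapes), and `pg_order` is the point-group
#' order of each minimum.
#'
#' @param minima Data frame with columns `id` (unique integer), `energy`, and
#'   optionally `log_freq_product` (default 0) and `pg_order` (default 1).
#' @param transition_states Data frame with columns `min1`, `min2`, `energy`,
#'   and optionally `id` (default sequential) and `log_freq_product` (default
#'   0).  Parallel edges (several TSs between one pair of minima) are allowed;
#'   self-loops are not.
#' @param strict If `TRUE` (default), a TS lying below either of its endpoint
#'   minima is treated as a violation by [validate_ktn()]; if `FALSE`, such TS
#'   energies are clamped up to the higher endpoint with a warning.
#' @param comment Optional free-text metadata.
#'
#' @return An object of class `ktn` with tibble components `minima` and `ts`.
#' @examples
#' net <- ktn(
#'   minima = data.frame(id = 1:2, energy = c(0, 0)),
#'   transition_states = data.frame(min1 = 1, min2 = 2, energy = 2)
#' )
#' validate_ktn(net)
#' @export
ktn <- function(minima, transition_states, strict = TRUE, comment = NULL) {
  minima <- as_tibble(as.data.frame(minima))
  if (!all(c("id", "energy") %in% names(minima))) {
    abort("`minima` needs columns `id` and `energy`.")
  }
  if (!"log_freq_product" %in% names(minima)) minima$log_freq_product <- 0
  if (!"pg_order" %in% names(minima)) minima$pg_order <- 1L
  minima <- minima[, c("id", "energy", "log_freq_product", "pg_order")]
  minima$id <- as.integer(minima$id)

  ts <- as_tibble(as.data.frame(transition_states))
  if (nrow(ts) > 0 && !all(c("min1", "min2", "energy") %in% names(ts))) {
    abort("`transition_states` needs columns `min1`, `min2` and `energy`.")
  }
  if (nrow(ts) == 0) {
    ts <- tibble(id = integer(), energy = double(), min1 = integer(),
                 min2 = integer(), log_freq_product = double())
  } else {
    if (!"id" %in% names(ts)) ts$id <- seq_len(nrow(ts))
    if (!"log_freq_product" %in% names(ts)) ts$log_freq_product <- 0
    ts <- ts[, c("id", "energy", "min1", "min2", "log_freq_product")]
    ts$id <- as.integer(ts$id)
    ts$min1 <- as.integer(ts$min1)
    ts$min2 <- as.integer(ts$min2)
  }

  if (any(ts$min1 == ts$min2)) {
    abort(paste0("Self-loop transition state(s) rejected: edge id(s) ",
                 paste(ts$id[ts$min1 == ts$min2], collapse = ", "), "."))
  }

  if (!strict && nrow(ts) > 0) {
    e1 <- minima$energy[match(ts$min1, minima$id)]
    e2 <- minima$energy[match(ts$min2, minima$id)]
    lo <- pmax(e1, e2)
    bad <- !is.na(lo) & ts$energy < lo
    if (any(bad)) {
      warn(sprintf("%d transition state(s) below an endpoint minimum; energies clamped.",
                   sum(bad)))
      ts$energy[bad] <- lo[bad]
    }
  }

  structure(
    list(minima = minima, ts = ts, strict = strict, comment = comment),
    class = "ktn"
  )
}

#' Check a KTN against its structural invariants
#'
#' Reports (rather than raises) violations: duplicated minimum ids,
#' non-positive point-group orders, TSs referencing absent minima, and -- in
#' strict mode -- TS energies below either endpoint minimum ("barrier below
#' endpoints").
#'
#' @param net A [ktn()] object.
#' @return A tibble with columns `where` (`"minimum"` or `"ts"`), `id`, and
#'   `rule`; zero rows when the network is well formed.
#' @export
validate_ktn <- function(net) {
  stopifnot(inherits(net, "ktn"))
  v <- list()
  dup <- unique(net$minima$id[duplicated(net$minima$id)])
  for (d in dup) {
    v[[length(v) + 1L]] <- tibble(where = "minimum", id = d,
                                  rule = "duplicate minimum id")
  }
  bad_pg <- net$minima$id[net$minima$pg_order < 1]
  for (d in bad_pg) {
    v[[length(v) + 1L]] <- tibble(where = "minimum", id = d,
                                  rule = "pg_order must be >= 1")
  }
  if (nrow(net$ts) > 0) {
    for (k in seq_len(nrow(net$ts))) {
      row <- net$ts[k, ]
      for (m in c(row$min1, row$min2)) {
        if (!m %in% net$minima$id) {
          v[[length(v) + 1L]] <- tibble(
            where = "ts", id = row$id,
            rule = sprintf("references absent minimum id %d", m))
        }
      }
    }
    if (net$strict) {
      e1 <- net$minima$energy[match(net$ts$min1, net$minima$id)]
      e2 <- net$minima$energy[match(net$ts$min2, net$minima$id)]
      lo <- pmax(e1, e2)
      bad <- which(!is.na(lo) & net$ts$energy < lo)
      for (k in bad) {
        v[[length(v) + 1L]] <- tibble(where = "ts", id = net$ts$id[k],
                                      rule = "barrier below endpoints")
      }
    }
  }
  if (length(v) == 0) {
    tibble(where = character(), id = integer(), rule = character())
  } else {
    bind_rows(v)
  }
}

#' @export
print.ktn <- function(x, ...) {
  cat(sprintf("<ktn> %d minima, %d transition states\n",
              nrow(x$minima), nrow(x$ts)))
  if (!is.null(attr(x, "reactant"))) {
    cat(sprintf("  reactant minimum %d, product minimum %d\n",
                attr(x, "reactant"), attr(x, "product")))
  }
  er <- range(x$minima$energy)
  cat(sprintf("  minimum energies in [%.4g, %.4g]\n", er[1], er[2]))
  invisible(x)
}

# igraph view of the network (undirected, one edge per TS)
ktn_graph <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(net$ts$min1),
                   to = as.character(net$ts$min2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$minima$id))
  )
}
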