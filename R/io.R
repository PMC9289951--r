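#' Read a PATHSAMPLE-style minima/transition-state database
#'
#' Parses the ecosystem's plain-text `min.data` / `ts.data` dialect:
#' `min.data` rows hold `energy, log product of frequencies, point-group
#' order, Ix, Iy, Iz` (the inertia components are ignored); `ts.data` rows
#' hold `energy, log freq product, point-group order, min1, min2, Ix, Iy,
#' Iz`.  Indices are 1-based row numbers of `min.data`.  Malformed rows and
#' out-of-range indices are reported with their line numbers.
#'
#' @param min_path Path to `min.data`.
#' @param ts_path Path to `ts.data`.
#' @param strict Passed to [ktn()].
#' @return A [ktn()].
#' @export
read_pathsample <- function(min_path, ts_path, strict = TRUE) {
  parse_rows <- function(path, ncol_min, what) {
    if (!file.exists(path)) abort(sprintf("%s: file `%s` not found.", what, path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
      if (length(v) < ncol_min || anyNA(v)) {
        abort(sprintf("%s line %d: malformed row (need >= %d numeric fields).",
                      what, ln, ncol_min))
      }
      v
    })
    rows
  }
  mrows <- parse_rows(min_path, 3, "min.data")
  minima <- tibble(
    id = seq_along(mrows),
    energy = vapply(mrows, `[`, numeric(1), 1),
    log_freq_product = vapply(mrows, `[`, numeric(1), 2),
    pg_order = as.integer(vapply(mrows, `[`, numeric(1), 3))
  )
  trows <- parse_rows(ts_path, 5, "ts.data")
  n_min <- nrow(minima)
  ts <- purrr::map_dfr(seq_along(trows), function(ln) {
    v <- trows[[ln]]
    m1 <- as.integer(v[4]); m2 <- as.integer(v[5])
    if (m1 < 1 || m1 > n_min || m2 < 1 || m2 > n_min) {
      abort(sprintf("ts.data line %d: minimum index out of range (%d or %d of %d).",
                    ln, m1, m2, n_min))
    }
    tibble(id = ln, energy = v[1], min1 = m1, min2 = m2,
           log_freq_product = v[2])
  })
  if (length(trows) == 0) {
    ts <- tibble(id = integer(), energy = double(), min1 = integer(),
                 min2 = integer(), log_freq_product = double())
  }
  ktn(minima, ts, strict = strict)
}

#' Write a KTN as PATHSAMPLE-style files
#'
#' Emits the dialect read by [read_pathsample()], with zero inertia
#' components.  Minima are written in id order and transition-state indices
#' refer to the written row numbers.
#'
#' @param net A [ktn()].
#' @param min_path,ts_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_pathsample <- function(net, min_path, ts_path) {
  stopifnot(inherits(net, "ktn"))
  m <- net$minima[order(net$minima$id), ]
  row_of <- setNames(seq_len(nrow(m)), m$id)
  writeLines(sprintf("%.10g %.10g %d 0 0 0",
                     m$energy, m$log_freq_product, m$pg_order),
             min_path)
  ts <- net$ts
  if (nrow(ts) > 0) {
    writeLines(sprintf("%.10g %.10g 1 %d %d 0 0 0",
                       ts$energy, ts$log_freq_product,
                       row_of[as.character(ts$min1)],
                       row_of[as.character(ts$min2)]),
               ts_path)
  } else {
    writeLines(character(0), ts_path)
  }
  invisible(c(min_path, ts_path))
}

#' Write a KTN in the native tabular dialect
#'
#' Two tab-separated tables plus a JSON metadata file: `<stem>_minima.tsv`
#' (columns `id, energy, log_freq_product, pg_order`), `<stem>_ts.tsv`
#' (columns `id, energy, min1, min2, log_freq_product`), and
#' `<stem>_meta.json` (units and free-text comment).  Ids are written
#' 1-based as they appear in the object.
#'
#' @param net A [ktn()].
#' @param stem Path stem for the three files.
#' @return Invisibly, the paths written.
#' @export
write_ktn <- function(net, stem) {
  stopifnot(inherits(net, "ktn"))
  paths <- paste0(stem, c("_minima.tsv", "_ts.tsv", "_meta.json"))
  utils::write.table(net$minima, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(net$ts, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(units = "model energy units (k_B = 1)",
         comment = net$comment %||% "",
         strict = net$strict),
    paths[3], auto_unbox = TRUE)
  invisible(paths)
}

#' Read a KTN written by [write_ktn()]
#'
#' @param stem Path stem used when writing.
#' @return A [ktn()].
#' @export
read_ktn <- function(stem) {
  paths <- paste0(stem, c("_minima.tsv", "_ts.tsv", "_meta.json"))
  minima <- utils::read.delim(paths[1])
  ts <- utils::read.delim(paths[2])
  meta <- if (file.exists(paths[3])) jsonlite::read_json(paths[3]) else list()
  ktn(minima, ts, strict = meta$strict %||% TRUE,
      comment = meta$comment %||% NULL)
}
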