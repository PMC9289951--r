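#' Log-scale histogram of a first-passage ensemble
#'
#' Bins `ln t` (or `ln s`) with uniform bin widths in log space and returns a
#' normalized density (the histogram integrates to 1 over the bins).
#' Censored samples (trajectories that hit the step budget) are excluded and
#' their count reported in the `n_censored` attribute.
#'
#' @param ens An `fpt_ensemble` from [run_kmc()] or [run_leapfrog()].
#' @param which `"t"` for first passage times or `"s"` for step counts
#'   (dynamical activity).
#' @param bins Number of bins.
#' @param range Optional log-scale range `c(lo, hi)`; defaults to the data
#'   range padded by half a bin.
#' @return A tibble with `y` (bin centers in log space), `count`, `density`,
#'   and attributes `edges` and `n_censored`.
#' @export
fpt_histogram <- function(ens, which = c("t", "s"), bins = 120, range = NULL) {
  stopifnot(inherits(ens, "fpt_ensemble"))
  which <- match.arg(which)
  keep <- !ens$samples$censored
  n_censored <- sum(!keep)
  v <- ens$samples[[which]][keep]
  if (length(v) == 0) abort("No uncensored samples to histogram.")
  y <- log(v)
  if (is.null(range)) {
    pad <- diff(base::range(y)) / (2 * bins)
    if (pad == 0) pad <- 0.5
    range <- base::range(y) + c(-pad, pad)
  }
  edges <- seq(range[1], range[2], length.out = bins + 1)
  y <- y[y >= range[1] & y <= range[2]]
  cnt <- graphics::hist(y, breaks = edges, plot = FALSE)$counts
  wid <- diff(edges)
  dens <- cnt / (sum(cnt) * wid)
  out <- tibble(y = (edges[-1] + edges[-(bins + 1)]) / 2,
                count = cnt, density = dens)
  attr(out, "edges") <- edges
  attr(out, "n_censored") <- n_censored
  out
}

#' Detect peaks in a density over a uniform log-time grid
#'
#' Finds local maxima and ranks them by topographic prominence: for each peak
#' the reference saddle on each side is the minimum of the curve between the
#' peak and the nearest higher point (or the grid border), and the prominence
#' is the peak height above the higher of the two saddles.  Peaks with
#' prominence below `prominence_frac` times the global maximum are discarded.
#' A monotone density reports its single boundary maximum as one peak only if
#' it is an interior local maximum; a strictly monotone curve yields zero
#' peaks (borders are not counted).
#'
#' @param density Tibble with columns `y` (uniform grid) and `density`, e.g.
#'   from [fpt_histogram()] or built from [log_time_density()].
#' @param prominence_frac Prominence floor as a fraction of the global
#'   maximum (default 0.05).
#' @return A tibble (`peaks` report) with `y`, `height`, `prominence`,
#'   sorted by position.
#' @export
detect_peaks <- function(density, prominence_frac = 0.05) {
  y <- density$y
  f <- density$density
  n <- length(f)
  if (n < 3) return(tibble(y = double(), height = double(), prominence = double()))
  is_max <- which(vapply(2:(n - 1), function(i) {
    f[i] > f[i - 1] && f[i] >= f[i + 1]
  }, logical(1))) + 1L
  prom <- vapply(is_max, function(i) {
    h <- f[i]
    left <- if (i > 1) f[1:(i - 1)] else numeric(0)
    right <- if (i < n) f[(i + 1):n] else numeric(0)
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(left[(max(hi_l) + 1):length(left)]) else min(left)
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(right[1:(min(hi_r) - 1)]) else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= prominence_frac * max(f)
  tibble(y = y[is_max][keep], height = f[is_max][keep],
         prominence = prom[keep]) %>% arrange(.data$y)
}

#' Detect steps in the truncated-MFPT curve
#'
#' Locates the steps of \eqn{\langle t \rangle_{obs}} as a function of
#' \eqn{\ln t_{obs}}.  Because successive plateaus differ by orders of
#' magnitude, the detector works on the logarithmic derivative
#' \eqn{d\ln\langle t\rangle_{obs}/d\ln t_{obs}}: contiguous grid regions
#' where it exceeds `slope_frac` times its maximum are steps; the step
#' position is the in-region derivative maximum and the plateau values are
#' the curve values flanking the region.  When a spectral decomposition is
#' supplied, each trailing plateau is matched against the
#' [partial_sum_mfpt()] prediction for `keep = l_max, l_max-1, ...` and the
#' relative mismatch is reported.
#'
#' @param curve Tibble from [truncated_mfpt()] evaluated on a log-spaced
#'   `t_obs` grid (columns `t_obs`, `mean_fpt`).
#' @param sp Optional [spectral_fpt()] used for the plateau predictions.
#' @param slope_frac Detection threshold as a fraction of the maximum
#'   logarithmic derivative (default 0.1).
#' @param min_rise Minimum total rise of \eqn{\ln\langle t\rangle_{obs}}
#'   across a candidate region for it to count as a step (default 0.5);
#'   suppresses sub-threshold wiggles from mixed-sign amplitudes.
#' @return A tibble (`steps` report) with `ln_t_obs` (step position, where
#'   half of the region's rise is complete), `plateau_before`,
#'   `plateau_after`, and -- if `sp` is given -- `keep`, `predicted`
#'   (partial-sum value matched to `plateau_after`) and `rel_mismatch`.
#' @details With `sp` supplied, grid points below \eqn{0.5/\nu_{max}} are
#'   discarded first: far below the fastest relaxation time the spectral sums
#'   for the conditional mean are cancellation-dominated and carry no usable
#'   signal (nothing is resolved there physically either).
#' @export
detect_steps <- function(curve, sp = NULL, slope_frac = 0.1, min_rise = 0.5) {
  ok <- curve$feasible %||% rep(TRUE, nrow(curve))
  ok <- ok & is.finite(curve$mean_fpt) & curve$mean_fpt > 0
  if (!is.null(sp)) ok <- ok & curve$t_obs >= 0.5 / max(sp$nu)
  x <- log(curve$t_obs[ok])
  m <- log(curve$mean_fpt[ok])
  if (length(x) < 3) abort("`curve` needs at least 3 feasible grid points.")
  slope <- diff(m) / diff(x)
  thr <- slope_frac * max(slope)
  above <- slope > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regs <- which(r$values)
  if (length(regs) > 0) {
    i1 <- starts[regs]
    i2 <- ends[regs]
    # total rise of the region (slope intervals i1..i2 span m[i1] .. m[i2+1])
    rise <- m[i2 + 1L] - m[i1]
    keep_reg <- rise >= min_rise
    i1 <- i1[keep_reg]; i2 <- i2[keep_reg]
  } else {
    i1 <- i2 <- integer(0)
  }
  if (length(i1) == 0) {
    return(tibble(ln_t_obs = double(), plateau_before = double(),
                  plateau_after = double()))
  }
  # plateau value after region k: sample where the curve is flattest between
  # region k and region k+1 (or the grid end), where the restricted mean has
  # converged to its partial-sum value
  nreg <- length(i1)
  plateau_idx <- vapply(seq_len(nreg), function(k) {
    lo <- i2[k] + 1L
    hi <- if (k < nreg) i1[k + 1L] - 1L else length(m)
    if (hi <= lo) return(hi)
    seg <- lo:(hi - 1L)
    seg[which.min(slope[pmin(seg, length(slope))])]
  }, integer(1))
  steps <- tibble(
    ln_t_obs = vapply(seq_along(i1), function(k) {
      # half-rise position within the region
      seg <- i1[k]:(i2[k] + 1L)
      half <- m[i1[k]] + (m[i2[k] + 1L] - m[i1[k]]) / 2
      x[seg][which.max(m[seg] >= half)]
    }, numeric(1)),
    plateau_before = exp(c(m[i1[1]], m[plateau_idx[-length(plateau_idx)]])),
    plateau_after = exp(m[plateau_idx])
  )
  if (!is.null(sp) && nrow(steps) > 0) {
    L <- length(sp$nu)
    ns <- nrow(steps)
    # the plateau after the final step is the full MFPT (keep = l_max), the
    # previous one drops the slowest mode (keep = l_max - 1), and so on
    keeps <- pmax(L - (ns - seq_len(ns)), 1L)
    steps$keep <- keeps
    steps$predicted <- vapply(keeps, function(k) partial_sum_mfpt(sp, k),
                              numeric(1))
    steps$rel_mismatch <- abs(steps$plateau_after - steps$predicted) /
      steps$predicted
  }
  steps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
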