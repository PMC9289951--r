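#' Exact first-passage-time distribution by eigendecomposition
#'
#' Solves the absorbing master equation spectrally.  Because the underlying
#' Markov process is reversible, \eqn{M} is conjugate to a symmetric matrix by
#' the detailed-balance similarity transform \eqn{S =
#' \Pi^{-1/2} M \Pi^{1/2}} with \eqn{\Pi = diag(\pi)}; a symmetric
#' eigensolver then guarantees a real spectrum.  The first-passage density is
#' \deqn{p(t) = \sum_l A_l e^{-\nu_l t},}
#' with \eqn{-\nu_l < 0} the eigenvalues of \eqn{M} and amplitudes assembled
#' from the left/right eigenvectors and the initial condition,
#' \eqn{A_l = \nu_l (\mathbf{1}^T w_l^R)(w_l^L \cdot P_0)}.  The amplitudes
#' satisfy the normalization \eqn{\sum_l A_l/\nu_l = 1}, which fixes the sign
#' convention.  Modes are reported with \eqn{\nu_l} ascending (slowest
#' relaxation first); amplitudes of numerically degenerate eigenvalues
#' (relative spacing below `degeneracy_tol`) are summed before reporting.
#'
#' At low temperatures the eigendecomposition loses precision (the fixed
#' floating-point range cannot resolve extreme rate ratios).  The
#' decomposition fails loudly in that regime -- with a pointer to the
#' kinetic Monte Carlo and graph-transformation routes, which remain stable --
#' rather than returning an unreliable spectrum.
#'
#' @param ap An [absorbing_problem()].
#' @param imag_tol Relative imaginary-part tolerance for the general-solver
#'   cross-check (default `1e-8`).
#' @param norm_tol Tolerance on \eqn{|\sum_l A_l/\nu_l - 1|} (default `1e-8`).
#' @param degeneracy_tol Relative eigenvalue spacing under which amplitudes
#'   are merged (default `1e-10`).
#' @return An object of class `spectral_fpt` with fields `nu` (ascending),
#'   `amp`, and `meta`.
#' @examples
#' net <- ktn(data.frame(id = 1:2, energy = 0),
#'            data.frame(min1 = 1, min2 = 2, energy = 0))
#' ap <- absorbing_problem(rate_model(net, 1), products = 2, reactants = 1)
#' sp <- spectral_fpt(ap)
#' sp$nu    # single mode, rate 1
#' @export
spectral_fpt <- function(ap, imag_tol = 1e-8, norm_tol = 1e-8,
                         degeneracy_tol = 1e-10) {
  stopifnot(inherits(ap, "absorbing_problem"))
  M <- fpt_generator(ap)
  trans <- rownames(M)
  pi_t <- ap$rm$states$pi[match(as.integer(trans), ap$rm$states$id)]
  if (any(pi_t <= 0)) {
    abort("Equilibrium weights underflow: decomposition unstable at this temperature; use kMC or graph transformation instead.")
  }
  d <- sqrt(pi_t)
  S <- sweep(sweep(M, 1, d, "/"), 2, d, "*")
  asym <- max(abs(S - t(S))) / max(abs(S))
  if (asym > 1e-8) {
    # no detailed-balance symmetrization available: general solver + checks
    eg <- eigen(M)
    if (max(abs(Im(eg$values))) > imag_tol * max(abs(eg$values))) {
      abort("Non-real eigenvalues: numerical instability; use kMC or graph transformation instead.")
    }
    nu <- -Re(eg$values)
    WR <- Re(eg$vectors)
    WL <- solve(WR)
  } else {
    S <- (S + t(S)) / 2
    eg <- eigen(S, symmetric = TRUE)
    nu <- -eg$values
    WR <- eg$vectors * d          # right eigenvectors of M (columns)
    WL <- t(eg$vectors / d)       # left eigenvectors of M (rows)
  }
  if (any(nu <= 0)) {
    abort("Non-positive relaxation rate encountered: numerical instability; use kMC or graph transformation instead.")
  }
  p0 <- ap$p0[trans]
  amp <- nu * colSums(WR) * as.numeric(WL %*% p0)

  # merge numerically degenerate eigenvalues
  ord <- order(nu)
  nu <- nu[ord]; amp <- amp[ord]
  grp <- cumsum(c(TRUE, diff(nu) > degeneracy_tol * nu[-1]))
  nu <- as.numeric(tapply(nu, grp, function(z) z[1]))
  amp <- as.numeric(tapply(amp, grp, sum))

  norm <- sum(amp / nu)
  if (abs(norm - 1) > norm_tol) {
    abort(sprintf(
      "Amplitude normalization sum(A/nu) = %.6g deviates from 1: numerical instability; use kMC or graph transformation instead.",
      norm))
  }

  # dense symmetric eigensolvers carry an absolute eigenvalue error of order
  # eps * ||S||; the smallest rate inherits it as a relative error.  This
  # estimate bounds how tightly spectrally derived quantities (e.g. the
  # MFPT, dominated by 1/nu_1) can be expected to agree with exact
  # references such as graph transformation.  When the estimate approaches
  # unity the slow eigenvalues are numerically meaningless even if they came
  # out positive, so the decomposition is refused outright.
  nu_rel_err <- .Machine$double.eps * max(nu) / min(nu)
  if (nu_rel_err > 1e-3) {
    abort(sprintf(
      "Slowest relaxation rate (%.3g) is below eigensolver resolution (relative error ~ %.2g): numerical instability; use kMC or graph transformation instead.",
      min(nu), nu_rel_err))
  }

  structure(
    list(nu = nu, amp = amp,
         meta = list(temperature = ap$rm$temperature,
                     products = ap$products, reactants = ap$reactants,
                     p0_kind = ap$p0_kind, n_states = length(trans),
                     nu_rel_err = nu_rel_err)),
    class = "spectral_fpt"
  )
}

#' @export
print.spectral_fpt <- function(x, ...) {
  cat(sprintf("<spectral_fpt> %d modes, T = %g, p0 = %s\n",
              length(x$nu), x$meta$temperature, x$meta$p0_kind))
  cat(sprintf("  slowest rate nu_1 = %.6g, MFPT = %.6g\n",
              x$nu[1], fpt_moments(x, 1)))
  invisible(x)
}

#' @export
tidy.spectral_fpt <- function(x, ...) {
  tibble(mode = seq_along(x$nu), nu = x$nu, amp = x$amp,
         weight = x$amp / x$nu)
}

#' @export
glance.spectral_fpt <- function(x, ...) {
  m1 <- fpt_moments(x, 1)
  m2 <- fpt_moments(x, 2)
  tibble(n_modes = length(x$nu), temperature = x$meta$temperature,
         mfpt = m1, fpt_var = m2 - m1^2,
         norm = sum(x$amp / x$nu))
}

#' First-passage-time density
#'
#' Evaluates \eqn{p(t) = \sum_l A_l e^{-\nu_l t}} (vectorized over `t`).
#'
#' @param sp A [spectral_fpt()] object.
#' @param t Non-negative times.
#' @return Numeric vector of densities.
#' @export
fpt_density <- function(sp, t) {
  stopifnot(inherits(sp, "spectral_fpt"))
  if (any(t < 0)) abort("`t` must be non-negative.")
  vapply(t, function(tt) sum(sp$amp * exp(-sp$nu * tt)), numeric(1))
}

#' Log-time first-passage density
#'
#' The distribution of \eqn{y = \ln t}: \eqn{\tilde p(y) = e^y p(e^y)}, the
#' Jacobian-transformed density that separates well-spaced time scales into
#' distinct peaks.  Computed mode-wise in log space to avoid overflow.
#'
#' @param sp A [spectral_fpt()] object.
#' @param y Log-times (any real values).
#' @return Numeric vector of densities in `y`.
#' @export
log_time_density <- function(sp, y) {
  stopifnot(inherits(sp, "spectral_fpt"))
  la <- log(abs(sp$amp))
  sg <- sign(sp$amp)
  vapply(y, function(yy) {
    sum(sg * exp(yy + la - sp$nu * exp(yy)))
  }, numeric(1))
}

#' Moments of the first-passage-time distribution
#'
#' \eqn{\langle t^n \rangle = n! \sum_l A_l/\nu_l^{n+1}}; `n = 1` is the mean
#' first passage time (MFPT).
#'
#' @param sp A [spectral_fpt()] object.
#' @param n Positive integer moment order.
#' @return The moment \eqn{\langle t^n \rangle}.
#' @export
fpt_moments <- function(sp, n = 1) {
  stopifnot(inherits(sp, "spectral_fpt"))
  if (n < 1 || n != round(n)) abort("`n` must be a positive integer.")
  factorial(n) * sum(sp$amp / sp$nu^(n + 1))
}

#' Observation-time-truncated mean first passage time
#'
#' Restricts the FPT distribution to events completing within the observation
#' time `t_obs` and reports the conditional mean,
#' \deqn{\langle t \rangle_{obs} = \frac{\int_0^{t_{obs}} t\,p(t)\,dt}
#'   {z(t_{obs})}, \qquad
#'   z(t_{obs}) = \sum_l \frac{A_l}{\nu_l}\left(1 - e^{-\nu_l t_{obs}}\right),}
#' using the closed per-mode form
#' \eqn{\int_0^{t} t' A e^{-\nu t'} dt' = (A/\nu^2)[1 - e^{-\nu t}(1+\nu t)]}
#' evaluated with `expm1` for small \eqn{\nu t}.  As \eqn{t_{obs} \to \infty}
#' the value converges to the MFPT and \eqn{z \to 1}.
#'
#' @param sp A [spectral_fpt()] object.
#' @param t_obs Positive observation-time cutoffs (vectorized).
#' @param z_floor Normalizations below this floor are reported as no feasible
#'   events (`feasible = FALSE`, `mean_fpt = NA`) rather than as 0/0.
#' @return A tibble with columns `t_obs`, `z`, `mean_fpt`, `feasible`.
#' @export
truncated_mfpt <- function(sp, t_obs, z_floor = 1e-280) {
  stopifnot(inherits(sp, "spectral_fpt"))
  if (any(t_obs <= 0)) abort("`t_obs` must be positive.")
  w <- sp$amp / sp$nu
  res <- vapply(t_obs, function(tt) {
    x <- sp$nu * tt
    em <- -expm1(-x)                      # 1 - exp(-x), stable
    z <- sum(w * em)
    num <- sum((w / sp$nu) * (em - x * exp(-x)))
    c(z, num)
  }, numeric(2))
  z <- res[1, ]; num <- res[2, ]
  feasible <- z > z_floor
  tibble(t_obs = t_obs, z = z,
         mean_fpt = ifelse(feasible, num / z, NA_real_),
         feasible = feasible)
}

#' Mean first passage time restricted to the fastest relaxation modes
#'
#' Evaluates the eigenmode sum for the MFPT keeping only the `keep` fastest
#' modes (the slowest are dropped first), with both the first-moment sum and
#' its normalization truncated consistently:
#' \deqn{\langle t \rangle_{keep} = \frac{\sum_{l \in keep} A_l/\nu_l^2}
#'   {\sum_{l \in keep} A_l/\nu_l}.}
#' With all modes kept this is the exact MFPT.  The sequence of values for
#' `keep = l_max, l_max-1, ...` predicts the plateau heights of the truncated
#' MFPT as successive slow processes become unobservable.
#'
#' @param sp A [spectral_fpt()] object (modes ordered ascending in
#'   \eqn{\nu}, slowest first; `keep = k` keeps the k largest-\eqn{\nu} modes).
#' @param keep Number of fastest modes retained, between 1 and the mode count.
#' @return The restricted MFPT (plateau value).
#' @export
partial_sum_mfpt <- function(sp, keep) {
  stopifnot(inherits(sp, "spectral_fpt"))
  L <- length(sp$nu)
  if (keep < 1 || keep > L || keep != round(keep)) {
    abort(sprintf("`keep` must be an integer in [1, %d].", L))
  }
  sel <- seq.int(L - keep + 1, L)   # ascending nu: fastest are at the end
  sum(sp$amp[sel] / sp$nu[sel]^2) / sum(sp$amp[sel] / sp$nu[sel])
}

#' Plot the log-time first-passage density
#'
#' @param object A [spectral_fpt()] object.
#' @param y Optional log-time grid; defaults to 600 points spanning
#'   \eqn{[\ln(10^{-3}/\nu_{max}), \ln(10^{3}/\nu_{min})]}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_fpt <- function(object, y = NULL, ...) {
  if (is.null(y)) y <- default_ygrid(object)
  dat <- tibble(y = y, density = log_time_density(object, y))
  ggplot(dat, aes(x = .data$y, y = .data$density)) +
    geom_line() +
    labs(x = "ln t", y = expression(tilde(p)(ln ~ t)),
         title = sprintf("Log-time FPT density (T = %g)",
                         object$meta$temperature)) +
    theme_minimal()
}

#' Default log-time grid for FPT diagnostics
#'
#' 600 points spanning \eqn{[\ln(10^{-3}/\nu_{max}), \ln(10^{3}/\nu_{min})]},
#' three decades beyond the fastest and slowest relaxation times.
#'
#' @param sp A [spectral_fpt()] object.
#' @param n Number of grid points.
#' @return Numeric vector of \eqn{y = \ln t} values.
#' @export
default_ygrid <- function(sp, n = 600) {
  seq(log(1e-3 / max(sp$nu)), log(1e3 / min(sp$nu)), length.out = n)
}
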