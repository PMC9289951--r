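---
title: "Decoding multifunnel energy landscapes from first-passage-time statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding multifunnel energy landscapes from first-passage-time statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktnfpt)
```

## The model

A kinetic transition network (KTN) coarse-grains an energy landscape into
local minima (nodes) and the transition states (TSs) connecting them
(edges).  With rate constants $k_{ij}$ for the $j \to i$ transition, the
occupation probabilities follow the linear master equation.  `ktnfpt`
analyses the first passage time (FPT): the time for a trajectory started in
the reactant region $B$ to first reach the product region $A$.  When a
landscape contains several funnels, competing funnels act as kinetic traps,
and the FPT distribution carries one slow component per trap.  Reading
those components off — as peaks of the log-time density, or as steps of the
mean FPT versus the observation time — reveals the funnel organisation of
the landscape directly from kinetics.

### Rates, waiting times, equilibrium

Energies and temperature share one unit system with $k_B = 1$; the time
unit is the inverse of the unit rate prefactor.  `rate_model()` applies a
harmonic, unit-prefactor convention:

$$k_{ij} = o_j\,
  \exp\!\big[-\big((E_{ts}-E_j) + T(\Lambda_{ts}-\Lambda_j)\big)/T\big],$$

with $\Lambda$ the log product of normal-mode frequencies (zero for model
landscapes) and $o_j$ the point-group order of the departing minimum.  The
symmetry number appears in both the rates and the equilibrium weights
$\pi_j \propto o_j^{-1} e^{-E_j/T - \Lambda_j}$, so detailed balance
$k_{ij}\pi_j = k_{ji}\pi_i$ holds identically for every input, including
databases with nontrivial point groups.  Parallel TSs add their rates.
Waiting times are $\tau_j = 1/\sum_i k_{ij}$ and branching probabilities
$P_{ij} = k_{ij}\tau_j$.

## Exact FPT distributions from the absorbing master equation

Making $A$ absorbing leaves the dynamics unchanged up to absorption.  Over
the non-absorbing states the generator is $M$ (off-diagonals $k_{ij}$,
diagonal minus total escape rates, including escape into $A$), and the FPT
density equals the probability flux into $A$:

$$p(t) = \sum_l A_l e^{-\nu_l t}, \qquad
  A_l = \nu_l\,(\mathbf 1^{T} w_l^{R})\,(w_l^{L}\cdot P_0),$$

where $-\nu_l$ are the eigenvalues of $M$ and $w^{L/R}$ its left/right
eigenvectors.  Reversibility guarantees a real spectrum: `spectral_fpt()`
conjugates $M$ by $\mathrm{diag}(\sqrt\pi)$ and calls a symmetric
eigensolver, falling back to a general solver (with an explicit
imaginary-part check) only if the detailed-balance symmetrisation is not
available.  The amplitudes satisfy $\sum_l A_l/\nu_l = 1$, which fixes
their sign convention and is verified to $10^{-8}$ on every decomposition.
Moments follow as $\langle t^n\rangle = n!\sum_l A_l/\nu_l^{\,n+1}$.

Two derived quantities carry the multifunnel diagnostics:

* the **log-time density** $\tilde p(y) = e^y p(e^y)$, $y = \ln t$, which
  separates well-spaced time scales into distinct peaks (each mode
  contributes a fixed-width bump of standard deviation $\pi/\sqrt 6
  \approx 1.28$ in $y$, so two equal-weight scales need a spacing of
  roughly 2.5 or more to resolve);
* the **truncated MFPT** $\langle t\rangle_{obs}$, the mean over events
  completing within an observation time $t_{obs}$, with normalisation
  $z(t_{obs}) = \sum_l (A_l/\nu_l)(1-e^{-\nu_l t_{obs}})$ and a closed
  per-mode form for the numerator (evaluated with `expm1`).  As $t_{obs}$
  sweeps past each slow scale the curve climbs a step; after the step the
  plateau equals the MFPT of the spectrum restricted to the modes already
  feasible.  `partial_sum_mfpt(sp, keep)` evaluates exactly that
  restriction — both the first-moment sum and its normalisation truncated
  to the `keep` fastest modes — so `keep = l_max, l_max-1, ...` predicts
  the plateau heights, and `keep = l_max` is the exact MFPT.

### Numerical validity range

A dense symmetric eigensolver carries an absolute eigenvalue error of order
$\varepsilon\lVert S\rVert$, so the smallest rate has relative error about
$\varepsilon\,\nu_{max}/\nu_{min}$ — the estimate is returned as
`meta$nu_rel_err`.  Once the spread of time scales exceeds
$\sim\!10^{13}$ the slow eigenvalues are numerically meaningless even when
they come out positive (the amplitude normalisation cannot catch this,
because $A_l/\nu_l$ is insensitive to errors in $\nu_l$), and
`spectral_fpt()` refuses with a pointer to the sampling and
graph-transformation routes.  On the bundled model landscape this limits
the spectral route to roughly $T \gtrsim 0.9$; the MFPT agrees with graph
transformation to $10^{-8}$ relative wherever `nu_rel_err` supports that
comparison (e.g. $2.5\times10^{-10}$ at $T=2$) and to `nu_rel_err`
otherwise ($1.6\times10^{-5}$ at $T=1$, observed gap of the same size).

## Sampling engines

`run_kmc()` is standard rejection-free kMC: hop with probabilities
$P_{ij}$, wait $-\tau_j\ln x$.  Two implementation details keep it exact
while fast: per-trajectory waiting totals are accumulated as per-node
$\Gamma(\text{visits},\tau)$ draws (a sum of iid exponentials *is*
Gamma-distributed, so the sampled FPT distribution is unchanged), and the
inner categorical draw uses a dedicated xoshiro256++ stream seeded from R's
RNG, so results remain a deterministic function of `set.seed()`.
Trajectories exceeding a step budget (default $10^9$) are flagged censored
and excluded from histograms with an explicit count.

Low barriers between adjacent minima make trajectories *flicker* — recross
the same edge enormous numbers of times — which stalls conventional kMC in
deep traps.  `run_leapfrog()` collapses a whole flickering episode at node
$i$ into one move whenever the recrossing probability

$$\beta_i = \sum_{j \in \Gamma_i \setminus A} P_{ji}P_{ij}$$

exceeds a threshold (default 0.5; results are insensitive across
0.1–0.9, which is tested):

1. the total recrossing count is geometric,
   $P(N = n) = (1-\beta_i)\beta_i^n$, sampled by inverting the closed CDF
   $1-\beta_i^{\,N+1}$ as $N = \lceil \ln(1-x)/\ln\beta_i\rceil - 1$;
2. $N$ is allocated over neighbours with the conditional distribution
   $q_j = P_{ji}P_{ij}/\beta_i$ — exactly multinomially, or for
   $\beta_i > 0.95$ and $N > 1000$ by the multinormal limit (mean $Nq$,
   covariance $N(\mathrm{diag}(q) - q\otimes q)$) realised with $m-1$
   standard normals and a Householder reflection whose final column is
   $\sqrt q$, then integerised by clipping and largest-remainder repair; a
   single recrossing partner takes all of $N$ directly;
3. the exit leaves to a second neighbour $k$ or an adjacent absorbing
   state with renormalised probabilities
   $P^{lf}_{k} = \sum_j P_{kj}P_{ji}/(1-\beta_i)$ and
   $P^{lf}_{j} = P_{ji}/(1-\beta_i)$, which sum to one exactly; exit-hop
   waits are Poisson-escape samples.

To avoid catastrophic cancellation as $\beta_i \to 1$, $1-\beta_i$ is
always computed by the expanded two-step identity
$\sum_{j\in\Gamma_i\cap A} P_{ji} + \sum_{j\notin A} P_{ji}\sum_{k\ne i}
P_{kj}$ rather than by subtraction (on the bundled landscape
$1-\beta \sim 10^{-9}$ at $T=1$).  The renormalised waiting time
$\tau_i^{lf} = (\tau_i + \sum_{j\notin A} P_{ji}\tau_j)/(1-\beta_i)$
conserves the MFPT; this is validated against graph transformation in the
tests.

Three waiting-time modes are offered for the recrossing episode.  The
default, `"gamma"`, samples the exact law — $\Gamma(N, \tau_i)$ plus
$\Gamma(n_j, \tau_j)$ per partner — so leapfrog reproduces the full FPT
distribution at every $N$ (verified by two-sample Kolmogorov–Smirnov
against standard kMC).  `"pair"` uses the per-pair expectation
$n_j(\tau_i+\tau_j)$ and `"mean"` the mean single-recrossing wait times
$N$; both conserve the mean exactly and the distribution asymptotically
for large $N$, but narrow it visibly when flickering episodes are short,
which is why they are not the default.  Recrossings contribute $2N$ to the
dynamical activity $s$, so step counts remain comparable across engines.

## Graph transformation

`gt_mfpt()` provides the deterministic, numerically stable MFPT reference:
nodes are eliminated one at a time (ascending degree, recomputed greedily;
the result is order-invariant to $10^{-10}$ and that is tested) with

$$P'_{ba} = P_{ba} + \frac{P_{bx}P_{xa}}{1-P_{xx}}, \qquad
  \tau'_a = \tau_a + \frac{P_{xa}\tau_x}{1-P_{xx}},$$

until only a source and the absorbing set remain, whence
$T_b = \tau'_b/(1-P'_{bb})$.  Both $1-P_{xx}$ and the final $1-P'_{bb}$
are evaluated as sums of the complementary column entries (column
stochasticity makes this exact), never by subtraction; with that, GT stays
accurate far below the spectral route's temperature range (checked against
leapfrog ensembles at $T = 0.75$ and against barrier asymptotics at
$T = 0.25$, where the MFPT reaches $10^{36}$).

## The model multifunnel landscape

`multifunnel_landscape()` generates the package's test system: a main path
of six minima at energy zero (reactant at one end, absorbing product at
the other) with four dangling trap branches attached at the interior
nodes.  Each branch is a chain of three minima at the trap-bottom energy
separated by low internal barriers (1 unit), so trajectories flicker
inside the trap, while escape must surmount the trap depth plus the entry
barrier — the four escape barriers increase branch by branch, giving four
well-separated slow time scales, one peak in $\tilde p(\ln t)$ and one
step in $\langle t\rangle_{obs}$ per trap.

The frozen default constants are a one-off calibration (the derivation is
committed as `scripts/calibrate_landscape.R`) against four simultaneous
requirements: four peaks resolve at prominence 0.05 at both $T=1$ and
$T=2$; four steps with plateaus matching the partial sums at $T=1$;
conventional kMC feasible at $T=2$ (mean dynamical activity
$\sim\!10^5$, computed exactly from the fundamental matrix); slowest-rate
separation $\ge 10\times$ at $T=1$.  Those constraints interact: peak
resolution in $\ln t$ needs adjacent slow rates to differ by a factor
$\gtrsim\!14$, which with four traps fixes the depth spacing; deeper traps
get higher entry barriers (1.2 to 3.6) so the slow channels carry
decreasing weight — otherwise the deepest trap's fat left tail buries its
neighbours — but not so little that a peak drops below the prominence
floor; and the main-path barrier just past the first branch point is
raised to 3.6 (a "gate"), so that essentially every trajectory samples the
first trap and the direct-relaxation channel merges into the fastest peak
instead of contributing a fifth one.  The frozen values are
`trap_depths = c(2, 9.5, 14.8, 20)`,
`branch_entry_barrier = c(1.2, 2, 2.8, 3.6)`, `internal_barrier = 1`,
`minima_per_trap = 3`, `main_path_length = 6`,
`main_barrier = c(1, 3.6, 1, 1, 1)`.

What the generator emulates: a hierarchy of kinetic traps with flickering
bottoms, detailed balance by construction, and escape-barrier-ordered
relaxation scales.  What it deliberately omits: frequency prefactors
(all $\Lambda = 0$), nontrivial point groups, the dense low-barrier
connectivity and fat spectra of real molecular databases, and any
configurational meaning of the nodes.  Passing the bundled checks
therefore demonstrates the correctness of the machinery on a landscape
with known structure — not that any particular molecular system has four
traps.

## Diagnostics

`fpt_histogram()` bins $\ln t$ or $\ln s$ with uniform log-space bins and
normalises to unit integral.  `detect_peaks()` ranks local maxima by
topographic prominence and applies a floor of 5% of the global maximum by
default.  `detect_steps()` works on $d\ln\langle t\rangle_{obs}/d\ln
t_{obs}$ (the plateaus differ by orders of magnitude, so a raw derivative
threshold would only ever find the last step), marks contiguous regions
above 10% of the maximum slope with a minimum rise of 0.5 ln-units,
reports half-rise positions, samples each plateau where the curve is
flattest, and — given a spectrum — matches the trailing plateaus to
`partial_sum_mfpt()` predictions.  Grid points below $0.5/\nu_{max}$ are
discarded first: below the fastest relaxation time the spectral sums for
the conditional mean are cancellation-dominated and physically nothing is
resolved there.  On the bundled landscape the four steps and their
plateaus are a $T=1$ statement: at $T=2$ the adjacent scales sit only
$\sim\!2.6$ ln-units apart while each rise spans $\sim\!4$, so the rises
overlap and no flat plateaus exist between them (the peaks of
$\tilde p$ still resolve, because a mode's bump is narrower than its
step).

## Problem sizes and reproducibility

The bundled checks use the 18-node model landscape (17-dimensional
spectral problems), ensembles of $2\times10^5$ trajectories for
distributional comparisons (Kolmogorov–Smirnov distances of
$\sim\!2\times10^{-3}$ against the exact CDF, comfortably under the 0.01
acceptance band), $10^6$ draws for scalar sampler moments, and $10^4$
replicates for allocation moments at $N = 10^4$.  Every stochastic result
is a deterministic function of one integer seed.

## Known limitations

* No committor probabilities, no free-energy regrouping of minima, no
  rate estimation from trajectories, and no full FPT distribution from
  graph transformation (mean only).
* The spectral route's temperature range is bounded by eigensolver
  resolution as described above; outside it the package fails loudly
  rather than degrading silently.
* `run_kmc()` is practical only while the mean dynamical activity fits
  the step budget; deep-trap regimes belong to `run_leapfrog()` or
  `gt_mfpt()`.
* Multi-level traps (chains of minima descending far below their
  entrance) defeat single-pair leapfrog acceleration: each move collapses
  one neighbourhood's flicker, but climbing several levels still takes
  exponentially many moves.  The bundled landscape uses flat-bottomed
  traps, for which one move spans the whole escape.
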