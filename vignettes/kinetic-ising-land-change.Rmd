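---
title: "Modelling binary land-pattern change with a kinetic Ising model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling binary land-pattern change with a kinetic Ising model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landising)
```

## The model

Land-change studies often reduce a categorical land-cover map to two
classes: a *focus* category whose change is under investigation
(forest, cropland, wetland, barren land, ...) and the *background*
(everything else). `landising` treats such a binary map as a
configuration of a two-dimensional Ising model: a square grid of cells
$x_k \in \{-1, +1\}$, with $+1$ the focus category, evolving on a torus
(periodic boundaries, so every cell has exactly four neighbours).

A pattern $\omega$ has the dimensionless energy

$$E(\omega) = -J \sum_{k \sim \ell} x_k x_\ell \;-\; B \sum_k x_k,$$

where the first sum runs over nearest-neighbour pairs. $J$ measures the
propensity of neighbouring cells to share a category — in land terms,
the strength of the processes that produce spatial autocorrelation
(logistics of land conversion, diffusion of a spreading class,
ecological feedbacks). $B$ is an external force favouring the focus
category when positive (e.g. a reforestation policy) and the background
when negative (e.g. wetland drainage). Temperature is not carried as a
separate parameter; it is absorbed into the scale of $B$ and $J$.

Time evolution uses single-flip Glauber dynamics: each *dynamic step*
picks one cell uniformly at random and flips it with probability

$$P(x_k \to -x_k) = \frac{1}{1 + e^{\Delta E_k}}, \qquad
\Delta E_k = -(x_k^{af} - x_k^{bf})\,(J S_k + B) + Q_{\text{applied}},$$

with $S_k \in \{-4,-2,0,2,4\}$ the sum of the four neighbour states.
The flip probability is $1/2$ at $\Delta E = 0$ and decays to zero for
strongly unfavourable moves.

### The noise-suppression term Q

Plain Glauber dynamics occasionally creates isolated focus cells in the
middle of uniform background — salt-and-pepper noise that real
land-cover time series do not show. The constant $Q$ is added to
$\Delta E_k$ *only* when the selected cell is background **and** all
four of its neighbours are background ($x^{bf}_k = -1$, $S_k = -4$).
The rule is deliberately one-sided: a focus cell inside all-focus
surroundings is never penalized, so existing isolated focus cells can
still disappear.

The default is $Q = 100$. Any value that makes
$e^{-(Q - 8J + 2B)}$ negligible works identically in practice —
with $Q = 100$ the acceptance probability of the suppressed move is
below $10^{-40}$, i.e. it never happens in any feasible simulation —
and $Q$ remains configurable (set `Q = 0` in `ising_params()` for the
unmodified dynamics).

One consequence worth knowing: with $Q$ active and $B = 0$ the dynamics
are *not* symmetric between the categories. Isolated focus cells die
and are never reborn, so a long balanced run drifts toward background.
This is intended during transition simulation (it is exactly the noise
suppression), but it matters when *preparing* synthetic initial
patterns — see below.

## Time scale and step counts

A simulated transition spanning $\Delta t$ years is given a step count
proportional to $\Delta t$. Two conventions are supported by
`steps_for_transition()` and `schedule_steps()`:

* a fixed per-step duration in hours (`step_hours`): e.g. 3 years at
  0.876 h per step is 30 000 steps, and the observation years
  2001, 2004, 2006, 2008, 2011, 2013, 2016, 2019 yield step counts
  30 000 / 20 000 / 20 000 / 30 000 / 20 000 / 30 000 / 30 000;
* a per-year rate (`steps_per_year`), default $n = d^2$ steps per year,
  under which each cell has on average one flip opportunity per year.

The year is fixed at 365 days (8 760 h) so the 3-year / 30 000-step
example reproduces 0.876 h exactly. Step counts are rounded to the
nearest integer; a transition that rounds to zero steps is an error
rather than a silent no-op.

## Pattern summaries and the fitting criterion

Two indices summarize a pattern:

* **composition imbalance** $m = 2f - 1$, with $f$ the focus fraction;
* **texture index** $C(1)$, a lag-one spatial autocorrelation. The
  package computes it as
  $C(1) = (\bar p - m^2) / (1 - m^2)$ where $\bar p$ is the mean of
  $x_k x_\ell$ over all $2n$ torus-adjacent pairs. The centring and
  normalization pin the two nominal endpoints: an i.i.d. random pattern
  scores $\approx 0$ (fine texture) and a coherent single-phase pattern
  scores $\approx 1$ (coarse texture). The exact normalization of this
  index is a design choice of this package; the raw pair mean $\bar p$
  is exposed (`texture_index(x, raw = TRUE)`) for sensitivity checks.
  Anti-correlated patterns (e.g. a checkerboard) produce negative
  values, which are reported as computed and flagged
  (`pattern_summary()$c1_in_range`). A uniform pattern makes the
  denominator vanish; it is defined as $C(1) = 1$ and flagged
  `degenerate`.

The goodness of fit between an observed and a simulated pattern is the
Euclidean distance between their $(m, C(1))$ pairs
(`summary_distance()`). Cell-level agreement is scored separately by
`prediction_scores()` (accuracy, recall, precision from the 2×2
confusion matrix, focus positive); note that a stochastic simulator can
match composition, texture and patch structure perfectly while scoring
low on cell-level accuracy — a one-cell shift of an otherwise perfect
fine pattern can drive accuracy to zero — which is why the fitting
criterion uses the summary indices, not the confusion matrix.

## Inferring (B, J) for an observed transition

Given an observed pattern at $t_i$ (the initial condition), an observed
pattern at $t_{i+1}$ (the target) and the step count for
$\Delta t_i$, `anneal_fit()` minimizes the summary distance over
$(B, J)$ by simulated annealing. The optimizer's internals are design
choices of this package (the search problem only fixes the objective):

* bounds $B \in [-2, 2]$, $J \in [0, 2]$ — generous brackets around
  every value we have seen in practice (transitions of real sites sit
  within $|B| \lesssim 0.8$, $J \in [0.3, 0.6]$);
* 500 objective evaluations per run; geometric cooling from a
  temperature of 0.1 (the objective's scale is a distance on
  $[-1,1]^2$, so 0.1 accepts early exploratory moves) down to $10^{-3}$;
* Gaussian proposals whose standard deviation shrinks geometrically
  from 0.3 to 0.02, reflected at the bounds;
* one simulation per objective evaluation. The objective is stochastic,
  but the ensemble spreads of $m_{\text{sim}}$ and $C(1)_{\text{sim}}$
  are small (the acceptance checks verify coefficients of variation
  below 5% at side 100), so averaging several simulations per
  evaluation buys less than spending the same budget on search moves.

Because each run is stochastic, `ensemble_fit()` repeats the search
(200 replicates by default; the acceptance checks use 50 to keep run
time down) with independent child seeds, bins the replicate $(B, J)$
pairs into a 2-D histogram — bin widths 0.02 in $B$ and 0.05 in $J$,
matching the precision at which fitted parameters are conventionally
reported — and returns the centroid of the pairs in the most populated
bin. Ties are broken by lower mean objective, then lower $J$. The
replicate scatter is typically much wider in $J$ than in $B$ (the
distance surface is narrowly constrained in $B$ but shallow along $J$
above the coarsening threshold), which is exactly why modal selection
over an ensemble is used instead of a single run.

All randomness flows through R's RNG; `ensemble_fit(seed = )` spawns
per-replicate child seeds, so results are bit-reproducible and
replicates could be distributed.

## Synthetic data: what it emulates, and what it does not

`random_landscape()` (i.i.d. placement, exact focus count),
`equilibrated_landscape()` (a burn-in under chosen parameters, giving
coarse, patchy mosaics) and `generate_series()` (forward simulation
with known per-transition $(B_i, J_i)$) provide ground-truth data for
every stage. Since the package's defining claim is that $(B, J)$ can be
recovered from a pattern transition, the headline integration check is
`recovery_trial()`: generate, transition, re-infer, compare.

Conditions used by the recovery checks (chosen once, as the package's
standard study design):

* side $d = 100$ (10 000 cells) — large enough that the summary indices
  have small sampling noise, small enough that a 50-replicate ensemble
  fit runs in tens of seconds; the generator supports larger sites;
* burn-in of 100 sweeps with plain Glauber dynamics ($Q = 0$, $B = 0$)
  at the generating $J$. Burning in with $Q$ active would drain the
  focus category toward uniform background (see above), which both
  misrepresents observed mosaics and degrades identifiability;
* transitions of 2–3 years at one sweep per year, matching the cadence
  of real land-cover epochs;
* generating values $(B^*, J^*)$ spanning the empirically relevant
  range, including a negative force: $(0.16, 0.50)$, $(-0.05, 0.33)$,
  $(0.48, 0.40)$.

The response-surface check uses a different initial condition: a coarse
*majority-focus* mosaic (a 65% focus start, neutrally burned in), i.e.
a site already dominated by the focus class undergoing further gain.
Coefficients of variation are only meaningful away from $m = 0$: the
absolute ensemble spread of $m_{\text{sim}}$ is of order $10^{-3}$
regardless of composition, but dividing by a near-zero mean would
inflate the relative spread into meaninglessness, so the CV claim is
assessed where observed sites actually sit — at compositions well away
from balance.

Synthetic mosaics reproduce the composition, texture and patch-size
behaviour of observed sites but **not** their anthropogenic geometry:
real patterns contain linear features (roads, field boundaries,
survey-grid edges) and directional shifts (e.g. a mine pit migrating
westward) that an isotropic, local model cannot generate. A passing
recovery test therefore demonstrates that the inference machinery is
correct and well-identified under the model's own dynamics; it does not
certify fit quality on landscapes dominated by linear features or
pattern translation.

## Patches

`label_patches()` extracts focus patches by connected-components
labelling, by default with 4-connectivity (the same von Neumann
neighbourhood as the interaction term); 8-connectivity is available.
Labelling is done on the *plane*: patches do not wrap across the torus
seam, because patch statistics describe the mapped tract while
periodicity is a simulation device. `size_ccdf()` and `area_ccdf()`
give complementary cumulative distributions with strict inequality:
the probability that a random patch (respectively a random unit of
focus area) lies in a patch *larger than* the threshold.

## Numerical choices and degenerate inputs

* Flip probabilities are evaluated as the logistic of $-\Delta E$ on
  the stable branch, so $|\Delta E| > 700$ neither overflows nor yields
  NaN.
* The simulation core precomputes the ten possible acceptance
  probabilities (two cell states × five neighbour sums, plus the
  $Q$-modified case) once per run; a step then costs two uniform draws
  and four neighbour reads (~4×10⁷ steps/s on one core).
* Rasters are stored on disk as `{0, 1}` integers for GIS
  interoperability and recoded to `{-1, +1}` in memory. Reclassifying
  categorical rasters maps nodata cells to background with a warning —
  the two-state model has no third state.
* Uniform landscapes, empty patch sets, zero-denominator scores and
  zero-step transitions are all either defined conventions (flagged) or
  loud errors — never silent zeros.

## Reproducing the numbers

`scripts/acceptance.R` re-derives the package's headline quantities
(worked time-unit examples, energy-oracle agreement, suppression
guarantee, parameter-recovery errors at the conditions above,
response-surface structure, patch-oracle agreement) from scratch
against the installed package and writes them to JSON; see the README
for invocation.
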