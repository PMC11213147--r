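---
title: "Hybrid expert/learned-CV weighted-ensemble sampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid expert/learned-CV weighted-ensemble sampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, every tunable that matters, and the choices made
where the design was genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Weighted ensemble

A weighted ensemble (WE) run maintains walkers $(x_i, w_i)$ with
$\sum_i w_i = 1$. Every resampling time $\tau$, walkers are assigned to bins
over a collective-variable (CV) space and each occupied bin is brought to a
target count $M$: bins below target repeatedly split their heaviest walker in
two (each child taking half the weight); bins above target repeatedly merge
their two lightest walkers, the survivor chosen with probability
proportional to weight and inheriting the summed weight. Both operations
leave the expected weight in every region of configuration space unchanged,
which is why WE estimates of populations and rates are unbiased for any
binning — the binning only controls the *variance*.

Implementation decisions:

* **Split/merge variant.** The literature contains several equivalent-mean
  variants; we split the heaviest and merge the two lightest (ties broken by
  lineage id) because it minimises weight disparity and pruning variance and
  is the common default in WE toolkits. Benchmarks against other codes
  should note this choice.
* **Weight conservation is audited, never repaired.** Resampling verifies
  $\sum w = 1$ to $10^{-12}$ and errors out on violation; silent
  renormalisation would mask estimator bugs.
* **Out-of-grid CVs clamp** to the nearest edge bin (with a logged count)
  rather than erroring: exploration must not crash at the frontier.
* **No sinks/recycling.** Runs are at equilibrium; rates come from analysis
  (Section 5), not steady-state flux into absorbing states.

## 2. The toy propagator

The built-in dynamics is first-order (overdamped) Langevin,
$x' = x - (D\,\Delta t/k_BT)\,\nabla U(x) + \sqrt{2 D \Delta t}\,\xi$, on
analytic 2D potentials (flat, harmonic, double well with tunable barrier,
three Gaussian wells with tunable depth/width/centers). Overdamped rather
than underdamped dynamics because the resampler is propagator-agnostic and
the first-order form has closed-form checks (free-diffusion MSD,
equipartition variance, Boltzmann histograms, Kramers-scale rates).
Boundaries reflect at the domain edge, keeping walkers inside the binned
region without touching interior kinetics. Default units: $k_BT = 1$,
$D = 1$, $\Delta t = 0.002$; with these, well-to-well rates on the toy
systems fall in $10^{-3}$–$10^{-1}$ per time unit, so every test can watch
many transitions in seconds of CPU.

Each walker draws from its own counter-based RNG stream (splitmix64 +
Box–Muller) seeded by hash(run seed, lineage id, iteration). Consequences:
trajectories are bitwise reproducible, sibling walkers decorrelate
immediately after a split, and a killed run resumed at an iteration boundary
is bit-identical to an uninterrupted one. Merge draws and minibatch
shuffles use R's RNG seeded per iteration / per training from the same run
seed.

The brute-force oracle (`generate_reference_ensemble`) runs one long
unweighted trajectory and reports history-labelled flux rates (Section 5)
with block standard errors; it refuses to report ("oracle unconverged") if
any state is entered fewer than 20 times.

## 3. The state predictive information bottleneck

The SPIB couples an encoder $x \mapsto \mathcal N(\mu(x), \sigma^2(x))$ over
a 2D latent space with a decoder that predicts the metastable-state label of
the same lineage $\Delta t$ frames later. The loss is the weighted
cross-entropy of that prediction from a latent *sample* plus
$\beta\,\mathrm{KL}(q(z\mid x)\,\|\,\mathcal N(0, I))$. Because only coarse
future labels must be predicted, intrawell fluctuations carry no usable
information and are compressed away; $\Delta t$ acts as a fast-mode filter,
and states with lifetimes $\lesssim \Delta t$ cannot keep their own label.

Training alternates gradient epochs with **label refinement**: every frame
is relabelled to the decoder argmax at its latent mean; states whose
population drops below $10^{-3}$ are deleted, their frames reassigned to the
next-best state; the loop stops when under 1% of the (weighted) frames
change label, or after 20 rounds (the model is then flagged unconverged).
K is therefore an output. Initial labels come from a deterministic coarse
grid over the *input features* (first two principal components when the
feature dimension exceeds two). A grid over the expert CVs would be the
obvious alternative, but with a degenerate expert CV it could never
over-segment the degenerate basins, and refinement only merges states — so
basin discovery would be impossible by construction. Over-segmentation is
harmless; refinement removes it.

Defaults and their reasons:

* lag $\Delta t$ = half the frames saved per WE iteration (i.e. half the
  resampling time);
* encoder/decoder: two hidden ReLU layers of width 64 (tests and the
  protocol runs here use 32 — the toy feature space is 2D), $\beta=10^{-3}$,
  Adam at $2\times10^{-3}$, minibatch 1024 — desk-scale CPU training in
  seconds;
* latent prior: standard normal. The contract is only that the regulariser
  bounds the information carried by the latent code;
* feature z-scoring is computed on the training window and stored in the
  model, so later encodings are consistent;
* training pairs connect frames $\Delta t$ apart **on one walker lineage**,
  following parent pointers across resampling; a pruned branch ends its
  lineage. Pair weights are the target frame's walker weight — except that
  all weights are treated as equal while the run is younger than 100
  iterations, because newly discovered states still carry weights far below
  the $10^{-3}$ deletion threshold and would be discarded before the weights
  equilibrate. During that phase state populations are frame counts;
  afterwards they are weighted.
* retraining warm-starts the **encoder** from the previous checkpoint when
  the feature dimensionality matches. The decoder and labels restart fresh
  each retraining: relabelling new data under the old decoder can only ever
  merge states, so a warm-started decoder would lock K at its first value
  and newly explored basins could never surface.

## 4. Hybrid binning and the iterative protocol

After each SPIB training the latent CVs are binned on a square grid whose
edge $h$ is set by bisection so the *occupied* bin count lands within 20% of
a target $B^*$ (default 100; the desk-scale protocol runs here use 50), with
the closest achievable count flagged when fewer distinct latent points
exist. The bounding box is the training window's latent min/max padded by
one bin; outside walkers clamp to edge bins.

Undersampled regions are expert bins whose **unweighted** sample count over
the training window falls strictly below the mean over occupied expert bins
(unoccupied bins are always undersampled). The mask is recomputed only at
SPIB trainings. Assignment is two-pass: candidate occupancies $n(i_e)$,
$n(i_s)$ are tallied once over the full pre-resampling walker set, then each
walker goes to its expert bin iff its expert bin is undersampled *and*
$n(i_e) < n(i_s)$ (strict; ties go to the latent bin). A sequential variant
that updates occupancies walker-by-walker is available behind a flag, but
the two-pass form is the default because it is order-independent and
deterministic.

The protocol: $N_0$ expert-only iterations (default 20), then SPIB training
at iteration $N_0$ and every $N_\mathrm{update}$ (default 20) iterations
after, each on the last $N_\mathrm{last}$ (default 500) iterations, followed
by latent-grid refit, mask recomputation and mapper swap — all logged with
iteration stamps so the mapper in force at any iteration is reconstructible
from the store. A training failure logs a warning and keeps the previous
mapper; a long run never halts on a retraining hiccup. The run is
checkpointed each iteration (RDS) and resumes deterministically. "Enough
sampling" is operationalised as a fixed iteration budget; expert CVs can be
swapped at an iteration boundary (`swap_expert_cvs`), the swap recorded,
with an identical grid being a strict no-op.

The run store keeps, per iteration: saved frames, walker weights, parent
segment indices, lineage ids, bin assignments, history labels, and the
routing/retraining logs. It lives in memory and serialises to RDS — an
R-native archive with the same per-iteration layout a segment-based WE
toolkit would keep; readers tolerate missing optional fields.

## 5. Analysis

**Free-energy surfaces.** $F_b = -\ln(\sum_{i \in b} w_i / \sum_i w_i)$ in
units of $k_BT$, anchored at min 0; bins with fewer than 10 unweighted
samples are masked, never extrapolated. Across runs, per-run probability
surfaces are averaged *before* the log.

**Rate constants.** Each saved frame carries its walker's history label
(last-visited defined state, inherited along lineages). The estimator is the
history-labelled flux form:
$k(A\to B) = \Phi(A \to B) / T_A$, the weight flux arriving in $B$ while
labelled $A$ per unit time, over the time-integrated weight labelled $A$.
It is well defined on equilibrium WE data without committor surfaces, and on
a long unweighted trajectory it reduces to the inverse mean first-passage
time between two states — which is exactly how the oracle computes its
reference values, so WE and oracle are compared estimator-for-estimator.
Burn-in defaults to 10% of the run. Run-to-run means and SEMs come from
independent runs (`combine_rates`).

**Bayesian bootstrap.** Credible intervals for any per-unit statistic:
$n_\mathrm{boot}$ Dirichlet(1, …, 1) weight draws over units, the statistic
recomputed under each, equal-tailed quantiles reported.

**State network.** Weighted label-jump matrix at lag $\Delta t$ along
lineages, row-normalised (diagonal kept), with weighted stationary
populations per state.

## 6. Study conditions used by the tests and acceptance script

All inputs are generated in code; problem sizes are chosen so the whole
suite runs on one desk-scale CPU:

* *Oracle equivalence / FES*: double well with 5 kT (rates) and 3 kT (FES)
  barriers, expert grid of width 0.2 over $x$, $\tau = 50$ steps, $M = 4$,
  3 independent runs of 400 (rates) / 150 (FES) iterations vs an
  $8\times10^6$-step brute-force run.
* *State discovery*: three Gaussian wells (depth 4 kT, $\sigma = 0.4$) at
  $(-1, 1)$, $(-1, -1)$, $(1, 0)$; SPIB at lags of 10, 50 and 400 saved
  frames spans the below-intrawell, interwell and beyond-slowest regimes;
  K = 3 is expected at the intermediate lag, and K must never increase with
  the lag.
* *Degenerate-CV experiment*: wells at $(-1, 0.9)$, $(-1, -0.9)$, $(1, 0)$
  (depth 6 kT, $\sigma = 0.35$) with the expert CV the bare $x$ coordinate,
  which maps the two left wells to the same value — the canonical degeneracy
  failure. Runs of 300 iterations starting in the upper-left well;
  $N_0 = 10$, $N_\mathrm{update} = 30$, $B^* = 50$, weights ignored for the
  first 60 iterations. The monitored observable is the return rate into the
  start well from its degenerate partner: its estimator conditions on
  time spent in the hard-to-reach well, making it the most variance-prone
  rate under a degenerate expert CV; the comparison is the 3-run SEM under
  hybrid vs expert-only binning, median over 5 replications.
* SPIB training data are capped at 8000 pairs per retraining by
  deterministic thinning.

What the toy conditions do *not* emulate: high-dimensional feature sets,
metastable states unknown to the state definitions, force-field error, or
propagator cost — passing tests show the sampler, model and estimators are
correct and internally consistent at desk scale, not that any particular
molecular system converges in a given wall time.

## 7. Numerical notes and limitations

* Half-open bins $[\mathrm{lo}, \mathrm{hi})$ with the last bin closed;
  1-based indices throughout, row-major composition across dimensions.
* The latent-grid bisection works on $\log h$ (60 iterations max); occupied
  count is monotone under halving, so the band $[0.8B^*, 1.2B^*]$ is found
  whenever it is reachable.
* Encoder log-variances are clamped to $[-10, 10]$; decoder softmax is
  max-shifted; refinement guards against deleting every state.
* The split of a weight $w$ into $m$ children assigns the last child the
  remainder $w - (m-1)\lfloor w/m \rfloor_\mathrm{fp}$, so conservation is
  exact in floating point.
* Known limitations: rectilinear (equal-size) bins only — no Voronoi,
  string or adaptive-size schemes; no steady-state (sink) mode; SPIB
  training is plain CPU matrix code, adequate for $10^4$-pair windows but
  not for large molecular feature sets; rate estimates on runs much shorter
  than the slowest relaxation time inherit the usual WE transient bias,
  which no estimator choice removes.
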