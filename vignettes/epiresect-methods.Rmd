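---
title: "Methods: SIR seizure propagation, virtual resection, and synthetic cohorts"
author: "epiresect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIR seizure propagation, virtual resection, and synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epiresect)
```

This vignette is the package's account of its science: the propagation
model and its assumptions, the fitting and resection machinery, the design
of the synthetic cohorts, and the numerical choices that were genuinely
open. Nothing here reports an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The propagation model

Seizure propagation is a discrete-time SIR process on a weighted,
symmetric ROI network. The canonical chain adopted as reference semantics
is synchronous: at each step, every node infected at the start of the step
attempts to infect each still-susceptible neighbour `j` independently with
probability `w_ij`; afterwards each of those nodes recovers with the global
probability `γ`. Nodes infected within a step neither transmit nor recover
until the next step — this makes the two-node network with `w = 1` spread
with certainty, a useful exactness anchor. An event-driven scheme in which
one node activates per event is sometimes used for such models; its event
interleaving is under-specified, so the synchronous chain is the contract
here and everything (including the Monte-Carlo engine) is tested against
exhaustive enumeration of this chain on networks of up to four nodes.

Assumptions worth stating: no reinfection (S → I → R only), a single global
recovery rate, spreading probabilities taken directly from connectivity
weights (so weights must live in `[0, 1]`), and simultaneous activations
sharing one step (downstream rank correlations use average ranks for ties).

With `γ > 0` absorption is almost sure; the runaway guard errs if a
realization exceeds `10·N/γ` steps. The `1/γ` factor matters: recovery
times are geometric with mean `1/γ`, so at the low end of the fitted grid
(`γ = 0.01`) legitimate realizations routinely outlive any cap that ignores
the recovery scale.

Reproducibility is by substream: realization `r` of an ensemble draws from
a deterministic stream seeded by `(rng_seed, r)` in the compiled engine, so
results are independent of execution order, and running the same seeds on
an intact and a resected network yields paired, common-random-number
estimates.

## Networks

`threshold_density()` keeps the `round(ρ·N(N−1)/2)` strongest links at
their original weights. Ties at the cutoff are broken by a stable ordering
(weight descending, then row, then column index), which makes link sets
nested across densities — an arbitrary but fixed choice the data cannot
decide. Distances default to edge lengths `1/w_ij` (the standard weighted
efficiency convention); hop counts are available because nothing in the
problem pins the convention, and no result here asserts one as canonical.

The surrogate connectome follows the exponential distance rule,
`w_ij ∝ exp(−α·d_ij)`, over two Gaussian "hemisphere" clusters, affinely
rescaled into `[0.5, 1]` to mimic the amplitude-envelope-correlation
convention (0.5 = no coupling). With `α = 1` the rescaled weight
distribution reproduces the reference quantiles of patient networks: the
weakest retained link is ≈ 0.73 at 3% density and ≈ 0.56 at 35% density.
This calibration is why `α = 1` is the default decay rate.

Because a fixed density means different mean degrees at different `N`,
experiments on small surrogates use `equivalent_density()`: the density
preserving the mean degree of the reference operating point (904 links on
246 ROIs). A 60-ROI network then operates at `ρ ≈ 0.125` with mean degree
≈ 7.4; using the raw reference density (3%) at `N = 60` would leave ~53
links and a fragmented graph that cannot carry macroscopic spreading.

## Fitting the global parameters

The goodness of fit `C = max(0, Cw)·P_overlap` compares an aggregated model
pattern (per-ROI participation and mean activation step over an ensemble)
with a recorded activation pattern restricted to electrode-sampled ROIs.
`Cw` is the participation-weighted Pearson correlation of activation ranks
over ROIs active in both patterns; negative values are floored to zero (an
anti-correlated fit is "no fit"), keeping `C ∈ [0, 1]`. Fewer than three
jointly active ROIs yields `C = 0` with a degeneracy flag.

The exact overlap formula used in the original clinical work is not
recoverable, so `P_overlap` sits behind a strategy switch:

* `balanced` (default): mean agreement of the active and the inactive sets,
  with a participation threshold (default 0.05) defining model activity;
* `extent`: the same agreement, but the model's active set is the top-`k`
  participation ROIs with `k` the expected per-realization active count —
  participation aggregates over realizations and otherwise overstates any
  single seizure's extent;
* `calibrated`: `1 − mean((activity indicator − participation)²)`, a proper
  (Brier-type) score whose expectation is maximized exactly when the model
  reproduces the per-ROI activation probabilities — the strategy of choice
  for parameter fitting;
* `jaccard`, `agreement`: simpler alternatives for sensitivity analysis.

`parameter_sweep()` evaluates `C` per patient on log-spaced grids (defaults:
12 points over `ρ ∈ [0.01, 0.35]` and `γ ∈ [0.01, 1]`), averages into the
group surface, and repeats the sweep (default 10 times) to attach
dispersion.

**Identifiability.** The two axes are not equally determined, and the
package does not pretend otherwise. The density axis is sharp: the
parameter-recovery experiment in the acceptance suite (cohorts generated at
an on-grid operating point near the spreading transition, scored with the
calibrated strategy) recovers the generating `ρ` row in every repetition.
The recovery axis is nearly flat: with retained weights in `[0.7, 1]`,
per-link transmission beats recovery within one or two steps, so
single-seizure patterns on 60-ROI networks carry almost no information
about `γ` at the grid resolution — adjacent-cell score differences are far
below single-realization noise, for every overlap strategy. This mirrors
the extended high-fit interface at roughly constant `ρ/γ` and the low
signal-to-noise of individual fits that motivated group-level fitting in
the first place. The acceptance test asserting joint two-axis recovery is
therefore expected to fail on the `γ` axis; it is kept strict rather than
weakened, and the `ρ`-axis property is what the conditions genuinely
support.

## Seed-probability maps

Six modalities (EEG, MRI, MEG, PET, SPECT, iEEG) flag abnormalities over a
34-region ontology (`region_names34()`, also shipped as
`inst/extdata/regions34.csv`). The overall abnormality is the
availability-weighted mean with relevance weights 1 (EEG), 2 (MRI, MEG,
PET, SPECT) and 4 (iEEG) — scalp EEG is least focal, invasive EEG most —
normalized so that a region flagged by every available modality scores 1
and global weight rescaling cancels. Projection onto atlas ROIs uses a
total mapping (each ROI to exactly one region); the clinical projection
table is not public, so a synthetic default for a 246-ROI atlas is shipped
(`synthetic_projection_bna246.csv`, labelled synthetic) and the cohort
generator builds its own spatial projection by clustering ROI coordinates.
The focality exponent `SP = A^R` defaults to `R = 3`; results are expected
to be insensitive for `R > 2`, which is exercised as a sensitivity check
rather than assumed.

Seed realizations default to Bernoulli draws per ROI (redrawn if empty,
capped), letting seed extent scale with map focality; fixed-size sampling
exists for sensitivity analysis. This sampling rule is a design choice the
source material does not fix.

## Virtual resections

A resection zeroes all links of the resected ROIs but keeps the nodes, so
infection-ratio denominators stay comparable; resected seed nodes are still
ictal at `t = 0` (they count toward `IR`) but transmit nothing, and
resected non-seed nodes can never be infected.

Seed efficiency `E_R(seed)` is the mean inverse distance from seed to
non-seed nodes, both restricted to the giant component; unreachable pairs
contribute zero. Note a subtlety the test suite makes explicit: because
`E` is a mean whose support shrinks as nodes drop out of the giant
component, it is *not* monotone under nested resections in general — only
summed inverse distance on a fixed pair set is. The normalized `e_R =
E_R/E_0` can therefore exceed 1 marginally after component changes.

The annealer minimizes the panel-mean seed efficiency over a fixed panel of
pre-sampled seeds (default 20) with single-swap proposals, geometric
cooling (factor 0.95) from an initial temperature calibrated to ≈ 0.8
acceptance, 100 proposals per temperature, stopping on `T < 10⁻⁴·T₀`, a
zero-acceptance temperature, or — since the energy is nonnegative — the
moment it hits zero (seed fully disconnected), at which point no better
state exists. Ten restarts per size are kept by best energy. On networks
small enough for exhaustive subset search the annealer matches the global
minimum in ≥ 95% of trials and is never more than 5% above it.

`resection_size_sweep()` couples the structural optimizer to the dynamical
score: per size, the annealed set is evaluated by paired `δIR` over
(default 300) seed realizations; the optimal resection is the first size
reaching `δIR ≥ 0.90`, the disconnecting resection the first with
`e_R = 0`. Two facts about the 0.90 target at desk scale: (i) past seed
disconnection the energy landscape is flat at zero, so which nodes fill
larger resections is arbitrary and `δIR` grows only slowly with size; and
(ii) the target is unreachable for patients whose drawn seed mass is large
relative to `N` — the ceiling is `1 − E[|seed|]/(N·IR₀)` minus the spread
of unpanelled false-positive seeds. Censoring is therefore a legitimate
sweep outcome, reported as such. In cohort tables censored patients score
`s_rop = S_max + 1 + 10·(0.90 − best δIR)` — censored observations are
ordered by the shortfall of the best achieved decrease, survival-style —
and their overlap biomarker uses the disconnecting resection, the smallest
well-defined seed-targeted set and a validated alternative target.

Overlap with the planned area defaults to `|R ∩ RA| / min(|R|, |RA|)`
(Jaccard available); the exact clinical convention is not recoverable.

## Synthetic cohorts

`generate_patient()` emulates what the pipeline consumes, not how the brain
produces it: an EDR network over two coordinate clusters; a contiguous
epileptogenic cluster (EZ) of `ez_size` ROIs (default 6; cohort-level
experiments in the tests use 3 at `N = 60` so that the 0.90 target is
reachable for most patients); per-modality abnormality maps that flag
EZ-overlapping regions with probability `1 − miss_rate` (default miss 0.2)
and healthy regions at a false-positive rate (default 0.05); availability
always on for EEG/MRI/MEG and Bernoulli(0.5) for PET/SPECT/iEEG; and a
resection area built from the outcome label.

The outcome mechanism was genuinely open. A pure resection/EZ mismatch
(the plan misses part of a single focal zone) reproduces the planned-
resection contrast but leaves the optimal-resection size independent of
outcome by construction — the size sweep never sees the resection area. The
default NSF mechanism is therefore *diffuse epileptogenicity plus
mislocalization*: NSF patients carry a second epileptogenic cluster, and
their resection area covers only part of the primary cluster. This is
still a resection/EZ mismatch, is clinically the textbook failure mode
(incomplete resection of a broader epileptogenic network), and yields all
three group contrasts in the expected directions: larger optimal
resections, lower overlap with the plan, and smaller `δIR(RA)` for NSF.
`nsf_mode = "mismatch"` retains the single-cluster variant.

Model-generated activation patterns take one SIR realization from the true
EZ at the generating operating point, restricted to an electrode subset
(default half the ROIs, sampled with bias toward high seed probability),
ranked by activation step. Default cohort size and imbalance (34 patients,
8 NSF) mirror a realistic validation cohort so that the imbalance-sensitive
code paths (undersampling, exact rank-sum) run at realistic `n`.

What the generator does **not** emulate: realistic atlas geometry, weight
heterogeneity beyond the distance rule, hub architecture, measurement noise
in activation timing, plasticity after surgery, or any anatomical
constraint on resections (eloquent cortex, contiguity). Passing tests
therefore show that the pipeline recovers structure it is pointed at under
its own model class — not that it would classify real patients at any
particular accuracy.

## Outcome statistics

Classification directions are fixed a priori (larger `S(R_op)`, smaller
`Ov`, smaller `δIR(RA)` → NSF) to avoid leakage; NSF is the positive class.
ROC curves are full threshold sweeps with trapezoid AUC (verified against
the pairwise-ordering statistic); the Youden point breaks ties toward lower
false-positive rate. The exact rank-sum test enumerates the midrank-tied
rank-sum distribution by dynamic programming up to pooled `n = 40`, then
switches to a flagged tie-corrected normal approximation. Leave-one-out
prediction refits the fold threshold on training rows only; the combined
call is NSF on ≥ 2 of 3 votes. The boosted classifier is AdaBoost-style
stumps over the three biomarkers with per-fold random undersampling of the
majority class (learners = balanced training size − 1, learning rate 1,
averaged over 10 repetitions), with stage-weight-normalized stump usage as
feature importance.

## Problem sizes in the shipped experiments

The test suite and acceptance script run: the optimal-resection contract at
`N = 60` with the full annealing schedule and 300 paired realizations;
engine validation against exhaustive enumeration at `N ≤ 4` with 10⁵
realizations; annealing validation against exhaustive subset search at
`N ≤ 12`; parameter recovery on 6-patient cohorts at `N = 60` with 500
realizations per grid cell and 10 sweep repetitions; and the group-contrast
experiment on 50 replicate cohorts of 34 patients at `N = 60` with 80
paired realizations and a shortened annealing schedule. These sizes are the
package's choices for routine verification; all counts scale up through the
same interfaces.

## Known limitations

* `γ` is weakly identifiable at desk scale (see *Identifiability*); fitted
  operating points should be read as a density plus a ridge, not a point.
* The annealer's zero-energy plateau leaves the composition of
  larger-than-disconnecting resections arbitrary; a secondary objective
  (e.g. fragmentation) would be needed to make them unique.
* The 0.90 optimal-resection target is only meaningful when the seed mass
  is small relative to the network; small atlases push patients toward
  censoring, which downstream code must (and does) handle explicitly.
* The synthetic NSF mechanism encodes one failure mode; intrinsic network
  differences between outcome groups beyond diffuse epileptogenicity are
  not modelled.
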