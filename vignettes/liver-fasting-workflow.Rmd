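---
title: "Attributing plasma metabolite changes to liver metabolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing plasma metabolite changes to liver metabolism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflux)
```

## The problem

During a short fast, the liver switches its glucose supply from glycogen
breakdown toward gluconeogenesis from glycerol, lactate and amino acids,
and ramps up ketogenesis from fatty acids. These flux changes leave a
signature in the plasma metabolome — but the plasma also integrates
contributions from every other organ. `hepaflux` implements a
constraint-based workflow for asking, metabolite by metabolite, whether
an observed plasma change is *consistent with a hepatic origin*:

1. a genome-scale (or toy) liver network is constrained with
   physiological exchange fluxes and measured central-carbon fluxes for
   an **early** (~5–7 h) and a **late** (~10–13 h) fasting condition;
2. each exchangeable metabolite gets a **production score**: the sign of
   the z-transformed difference in network demand for producing it under
   the two conditions, predicting a plasma rise (positive) or fall
   (negative);
3. observed plasma directions are called from multi-study MS count
   tables by a pooled percentile bootstrap of the mean late/early fold
   change with a 99% confidence interval;
4. predictions and observations are compared, with per-class and
   per-pathway accuracies and exact binomial significance.

## Production scoring

For a target metabolite with secretion exchange flux $v_x$, the network
**demand** is the minimum weighted total flux needed to sustain a
required production rate:

$$X_{\mathrm{met}} \;=\; \min \sum_j w_j\,|v_j|
\quad\text{s.t.}\quad S\,v = 0,\;\; v_{lb} \le v \le v_{ub},\;\;
v_x \ge v_{\mathrm{opt}} .$$

A low demand means the bounds make production cheap. The two demands per
metabolite are combined into a raw score

$$X_{\mathrm{raw}} = \frac{X_{\mathrm{early}} - X_{\mathrm{late}}}
{X_{\mathrm{early}} + X_{\mathrm{late}}} \in [-1, 1],$$

which is positive when production is cheaper late, i.e. the metabolite
is predicted to **rise** in plasma; and the raw scores are z-transformed
across all scored metabolites ($X_s = (X_{\mathrm{raw}} - \mu)/\sigma$,
population $\sigma$), so the sign is read relative to the network-wide
mean. The sign conventions are the single most error-prone spot in this
workflow, so they are stated wherever a score is produced: positive
$X_s$ = predicted elevated.

### The production target

The required rate $v_{\mathrm{opt}}$ is a fraction (default
`v_opt_fraction = 0.9`) of the metabolite's maximal production
capability, computed by flux balance analysis. Two readings are
possible: each condition chasing a fraction of *its own* capability, or
both conditions chasing one shared target. `run_timbr()` uses a
**shared target**, $v_{\mathrm{opt}} = f \cdot \min(\mathrm{cap}_{e},
\mathrm{cap}_{l})$, and this is a deliberate design choice: with
per-condition targets, a condition that merely *permits* more production
is charged for producing more, so relaxing a bottleneck late would
*raise* the late demand and flip the score against the obvious reading.
With a shared target the two demands price the same task under two
bound sets, and the score isolates how the bounds changed — which is the
question being asked. `production_demand()` still exposes both: its
default target is a fraction of its own model's capability, and
`target_flux` overrides it (which is what `run_timbr()` does).

The default fraction 0.9 (rather than 1.0) keeps the demand LP off the
optimal face of the capability LP, where solver tolerances make the
problem fragile. On the bundled toy network the planted score signs are
stable for fractions of roughly 0.75 and above; much smaller fractions
push the shared target below the production levels already forced by
the condition bounds, and the early/late contrast collapses. Keep the
fraction high unless you have a reason not to.

### Handling of degenerate cases

* Metabolites with zero production capability under either condition
  (e.g. uptake-only exchanges) are flagged `zero_capability` and
  excluded from the z-transform population; $X_{\mathrm{raw}}$ for a
  (0, 0) demand pair is undefined, not 0.
* An infeasible demand LP flags the metabolite `infeasible` and likewise
  excludes it.
* $X_s = 0$ exactly is treated downstream as "no prediction" and counted
  discordant by default (`no_prediction = "exclude"` removes such rows
  instead).
* All raw scores identical (e.g. both conditions the same) is a
  degenerate z-transform and errors rather than emitting NaNs.

### Weights

Reaction weights default to 1 — the flux-parsimony reading — because the
intended regime is short-term fasting, where metabolic gene expression
barely moves and flux bounds carry the signal. A named weight vector can
be supplied to reproduce expression-weighted variants; scaling all
weights by $c>0$ scales every demand by $c$ and leaves
$X_{\mathrm{raw}}$ and $X_s$ unchanged (this invariance is tested).

### The LP core

No linear-programming package is assumed: the solver in `lp_solve()` is
a dense two-phase bounded-variable simplex with Bland's rule —
deterministic, cycle-free, and sized for networks of tens to a few
hundred reactions. Absolute values in the demand objective are
linearised by splitting each flux into nonnegative forward/reverse
parts. Pivot tolerance is $10^{-9}$; phase-1 feasibility is accepted
below $10^{-7}$; the test suite checks returned optima against
brute-force vertex enumeration of the flux polytope on small instances
and steady-state residuals $\max|Sv| \le 10^{-6}\max(1, \max|v|)$ on all
solves it inspects. For genome-scale models a sparse interior-point
solver would be the right tool; the simplex here is exact and fast at
desk scale.

## Condition bounds

`condition_bounds` objects carry two kinds of overrides: exchange bounds
(uptake/secretion rates; positive flux = secretion into plasma, the
usual convention) and measured central-carbon flux bounds. Overrides are
intersected with the model's hard bounds — the tighter interval wins —
and applying a condition is idempotent.

Fractional precursor contributions (the glycogen / glycerol /
lactate-and-amino-acids split of glucose output) are converted to
absolute bounds by `fractions_to_bounds()`: each route gets
$\mathrm{fraction} \times \mathrm{total}\ (1 \pm
\mathrm{tolerance\_fraction})$. The total output is always a user input:
published fractions are transcribable, absolute fluxes often are not.
Measured fluxes are best applied as intervals (mean $\pm k\,$SE, $k=1$ a
reasonable default) rather than point constraints; point-fixing many
fluxes at once invites LP infeasibility from measurement inconsistency.

## Direction calling from MS counts

Each study contributes an early and a late group of different animals
(terminal sampling), so fold changes cannot be paired within animals.
The caller:

1. **imputes** missing counts with the per-metabolite minimum observed
   value, by default within each study (`per_study`) since each platform
   has its own detection floor — minimum imputation is only sensible
   under left-censoring;
2. **bootstraps**: per replicate, animals are resampled with replacement
   within each study and time point, a per-study fold change is formed,
   and study values are pooled weighted by study size; `B = 1e5`
   replicates by default;
3. takes the **percentile CI** (linear-interpolation / type-7
   percentiles; 0.5th–99.5th for the default `ci_level = 0.99`);
4. calls **elevated** iff the lower bound exceeds 1, **depressed** iff
   the upper bound is below 1, otherwise **unchanged** (intervals
   touching 1 exactly are unchanged).

### Estimator choice

Two pooled estimators are implemented. `paired_ratio` forms elementwise
late/early ratios of index-aligned resampled draws and averages all
$\sum_s n_s$ ratios; `ratio_of_means` (the default) forms one ratio of
resampled means per study and averages those, weighted by $n_s$. The
per-pair ratio is the more literal reading of a pooled fold-change
distribution, but it is structurally biased upward under multiplicative
noise: for log-normal noise with scale $\sigma$ per group,
$E[X/Y] = e^{\sigma^2} \cdot \mathrm{fc}$, about $+9\%$ at
$\sigma = 0.3$. Because the bootstrap distribution concentrates around
the biased estimand as $n$ grows, the 99% CI drifts away from 1 under
the null and the false "elevated" rate rises well above nominal (about
5% in our simulations at $n = 8/8/9$, versus about 2% for the ratio of
means, which is biased only by $e^{\sigma^2/n}$). The ratio of means is
therefore the default; `estimator = "paired_ratio"` restores the
per-pair pooling for comparison with analyses that used it.

Reproducibility: one master seed; each metabolite's replicate stream is
derived from the seed and the metabolite id, so the processing order
cannot change any call.

## Concordance and significance

A prediction is concordant when $\mathrm{sign}(X_s)$ matches the
observed direction. Accuracies are reported per class (elevated /
depressed), overall, and per pathway, both at full precision and
rounded to integer percents. The overall accuracy is tested one-sided
(the question is "at least this good by chance?"); pathway accuracies
are tested two-sided; both against $p_0 = 0.5$ with the exact binomial
tail, `two_sided` being twice the smaller tail capped at 1.

## What the synthetic data do and do not show

`make_toy_liver_network()` builds a ~45-reaction carbon-skeleton network
(no cofactors, no ATP/redox bookkeeping) with lumped gluconeogenic
routes in hexose units, and two bound sets following the fasting
trajectory: glycogen share of a 100-unit glucose output 48% early; 2.3%
of a 70-unit output late; glycerol and lactate/amino-acid shares rising
to compensate; fatty-acid uptake and ketone secretion forced up late;
alanine uptake (hence urea output) forced up late. Planted truths are
*constructed*: glucose capability falls (depressed); ketone and urea
production are forced late but costly early (elevated); and sentinel
metabolites carry route-switch motifs — a 1-step production route open
in only one condition with a 5–6-step detour always available — giving
known-direction cost contrasts. Two auxiliary exchangeables with
condition-invariant routes anchor the z-transform centre near the
common background. Bound half-widths are ±10%.

`make_ms_counts()` draws log-normal counts (within-group $\sigma = 0.3$,
typical of MS replicate spread) for three studies of 8/8/9 animals per
time point, with per-study baseline shifts (different vehicles or
platforms; SD 0.5 on the log scale) and left-censored missingness below
a per-study detection floor.

Passing tests on these generators demonstrate that the pipeline recovers
directions *when the liver model truly drives the changes and the noise
is multiplicative and independent*. They say nothing about metabolite
identification errors, correlated animals, batch effects within a
study, non-hepatic confounders, or the fidelity of any genome-scale
reconstruction — all of which matter on real data.

## Problem sizes and determinism

The bundled analyses run at desk scale by design: toy network scoring is
a few hundred LP solves of ~100-variable tableaus; direction-calling
simulations use $B = 10^4$ replicates for hundreds of metabolites
(inference defaults to $B = 10^5$, which simply scales linearly).
Everything downstream of a seed is deterministic, including LP pivoting
(fixed variable order, Bland's rule), so identical configs produce
byte-identical outputs.

## Known limitations

* The simplex is dense; genome-scale models (thousands of reactions)
  will be slow. The model I/O and scoring interfaces do not change if
  the LP backend is swapped.
* The z-transform population is whatever scored `"ok"`; on small
  networks the centring $\mu$ is sensitive to which metabolites are
  scoreable, which is why the toy network carries auxiliary anchors.
* The direction caller inherits the detection-floor assumption of
  minimum imputation; data missing for other reasons (e.g. at random
  across the intensity range) would need a different imputation.
* Fold changes are late/early; flip the labels if your design runs the
  other way.
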