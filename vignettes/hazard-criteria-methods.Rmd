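---
title: "Deriving quantitative hazard criteria for silver nanoforms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving quantitative hazard criteria for silver nanoforms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hazardbn` turns a flat table of in-vitro silver-nanoform exposures into
an expert-constrained discrete Bayesian network and, from its conditional
probability tables, into IF–THEN hazard criteria with certainty factors.
This vignette explains the model, every tunable that matters, the
numerical conventions, and what the synthetic study design does and does
not establish.

## The data model

One row is one exposure condition: a nanoform (identified by an ERM
registry code) characterized by *system-independent* descriptors — XPS
atomic concentrations (O 1s, Ag 3d, C 1s, Na 1s, N 1s, in %), TEM core
size (nm), the derived spherical surface area, XRD crystallinity (%) and
average crystallite size (nm), plus its coating (HEC, PVP, CUR or none) —
and *system-dependent* descriptors measured in cell-culture medium: DLS
hydrodynamic size and polydispersity index at exposure start (t0) and
after 24 h (t24). Biological attributes (organ, cell line, cell type,
multiwell, digestion pretreatment), the exposure dose (ppm) and the
viability assay complete the row; the outcome is cellular viability (%).

The surface area uses the spherical convention `A = 4·pi·s^2` with the
tabulated core-size value `s` inserted directly into the squared term.
That convention (rather than `s/2`) is adopted because it reproduces the
reference bin edges of the study design (17.8 nm to ~3981.5 nm², 20 nm to
~5026.5 nm²) to within 0.01%; rows inconsistent with it are flagged by
`validate_dataset()`, never silently repaired.

Viability maps to an ordered hazard class per ISO 10993-5: `safe`
(≥ 70%), `toxic` (30–70%), `very_toxic` (< 30%). Both thresholds are
left-closed: exactly 70 is safe (the definition is "≥ 70%") and exactly
30 is toxic. Viability above 100% — routine assay noise — is retained
unclipped and classifies as safe.

## Preprocessing

**Stratified dose interpolation.** A missing system-dependent value at
dose *d* is filled by linear interpolation between the nearest smaller
and larger doses at which it is known, strictly within the
(nanoform, cell line, pretreatment) stratum; outside the known dose range
it stays missing, and strata never exchange information (a digested
measurement at 50 ppm says nothing about the non-digested sample at
50 ppm). Replicates at one dose are averaged into a single anchor.

**Chained imputation.** Remaining gaps are filled by modelling each
incomplete column as a gradient-boosted-tree function of all other
features, with the ERM identifier kept (one-hot) as a predictor because
it is the only feature that cleanly fragments the table into
nanoform-specific groups. Columns are visited in ascending order of
missingness, initialized at column medians, cycling for at most 10 sweeps
or until the largest absolute change of any imputed cell falls to 1e-3 in
standardized (per-column SD) units. These choices — order, start, stop —
are fixed for reproducibility; they are defaults of convenience, not
claims of optimality. A column with nothing observed is an error: there
is nothing to learn from.

**Feature finalization.** The modeling view drops organ (encapsulated by
the cell line), multiwell (encapsulated by the assay), cell type, the
Na 1s / N 1s concentrations (zero-heavy, synthesis-related, no plausible
causal route to hazard), the constant 24 h duration, the pretreatment
label, and the ERM identifier, leaving 15 inputs plus viability.

**SMOTE.** Discretizing the outcome leaves `safe` heavily over-represented,
so minority classes in the *training split only* are oversampled to parity:
`x_new = x + u (x_nn - x)` with `u ~ Uniform(0,1)` and `x_nn` one of the
k = 5 nearest same-class neighbours, Euclidean on z-scored one-hot
features (standardization fitted on the training split). Originals are
preserved verbatim. An `"all"` mode that balances before splitting is
available because the pooled row count sometimes quoted for balanced
tables is only reproducible that way; it is not the default, since
balancing before splitting leaks synthetic copies of test neighbourhoods
into training.

**Discretization.** Numeric inputs are cut into three bins at the
33.33rd/66.67th percentiles, computed by linear interpolation between
order statistics (R quantile type 7) — the common default, adopted
because no convention is canonical here; realized numeric edges are
always reported next to the percentile ranks so the applicability domain
reads as ranges. Bins are left-closed/right-open with the high bin
open-ended, and values below the fitted minimum fall in `low`. Bins are
fitted on the SMOTE-balanced training numerics: balanced-table edges
(e.g. a dose edge at an interpolated value like 58.35 ppm rather than a
laboratory dose) are the signature of that order of operations, and the
fitted map is then applied unchanged to the test rows. A column with
fewer than three distinct values cannot support terciles and raises a
degenerate-column error.

For the Bayesian network the categorical inputs stay *single multi-state
nodes* rather than one-hot indicators: a k-state one-hot block would give
the network k near-deterministic binary nodes carrying the same
information with artificial arcs among them. One-hot encoding is used
where it belongs, in the numeric-matrix baselines and inside SMOTE.

## Association analysis

Numeric–numeric associations use Spearman's rank correlation (Pearson on
mid-ranks, ties averaged; a constant vector yields an undefined signal,
not 0). Categorical pairs use the classical Cramér's V,
`sqrt(chi2 / (n (min(r,c) - 1)))` with no continuity correction and *no*
small-sample bias correction — users comparing against toolkits that
apply the Bergsma correction will see slightly larger values here.
Numeric–categorical pairs use Cramér's V after tercile-binning the
numeric member, consistent with the discretization used everywhere else.
Skewness is the adjusted Fisher–Pearson coefficient, with |skew| ≤ 2
taken as the conventional band of acceptable asymmetry.

The Mapper summary covers the lens range (by default viability) with
overlapping intervals, single-linkage-clusters each preimage on min–max
scaled features at a fixed cut height, and joins clusters sharing rows.
With one wide interval it degenerates, as it should, to plain
single-linkage clustering. The low-dimensional UMAP-style embedding
sometimes shown next to such summaries is out of scope here.

## The Bayesian network

**Scores.** Structure quality is a decomposable score: BDeu with
equivalent sample size 1 (default) or BIC. The equivalent sample size is
deliberately small — the balanced table has ~1.3k rows and 3–4-state
nodes, so larger priors wash out real dependence.

**Exact search.** Per node, the best-scoring admissible parent set within
every predecessor subset is tabulated; dynamic programming over all 2^n
variable subsets then yields the globally optimal ordering
(Silander–Myllymäki style). This is exponential and refuses beyond 18
nodes; its parent cap defaults to 4 for tractability, with the outcome
node exemptible so that dose, assay and several descriptors can coexist
as its parents. Its role in this package is as the optimality oracle on
small problems and for the constrained-versus-unconstrained score
comparison; the 16-node production structure comes from hill climbing.

**Hill climbing.** Greedy add/delete/reverse from the constraint-seeded
graph (required arcs present), 6-parent cap, each accepted move strictly
improving the score; ties break lexicographically by (move type, parent,
child), so the search is fully deterministic and the `seed` argument is
interface decoration. The score trace is strictly increasing by
construction.

**Expert constraints.** `asina_constraints()` encodes the domain
reasoning: exposure dose and assay are independent experimental settings
— roots whose only outgoing arc feeds viability — and nothing measured
may "cause" them; coating determines surface area and the Ag 3d
concentration while core size cannot determine the coating; t24
dispersion features never parent their t0 counterparts; viability is the
unique terminal node. Because "the outcome is the only terminal point" is
a property of the whole graph rather than of any single arc, the learner
enforces it constructively: after convergence, any non-outcome node left
childless is given an arc into the outcome. This is the one place the
search accepts a (usually tiny) score sacrifice to honour the constraint
set's semantics.

**CPTs and inference.** Conditional probability tables use
`(count + a) / (total + a·k)` smoothing with pseudocount a = 0.5, so
unobserved parent configurations give uniform rows rather than zeros.
Inference is exact variable elimination under a greedy min-degree
ordering; posteriors are checked in the test suite against brute-force
joint enumeration to 1e-10, and are invariant to the elimination order.
Evidence with zero probability yields an explicit undefined signal,
deliberately distinct from a uniform answer. Class prediction is the
posterior argmax with ties broken toward the *more hazardous* class — the
precautionary choice appropriate for a screening tool.

## Rules and certainty factors

For each joint configuration of the evidence features (default: the
outcome's Markov blanket) with nonzero probability, each class's
posterior p becomes a rule with certainty factor `CF = p / (1 − p)`: the
odds for versus against the consequent given the antecedent. This
posterior-odds reading is adopted because it reproduces the reference
worked value exactly (p = 0.87 gives CF 6.69, printed as 6.7); an
alternative reading that divides out the prior odds (an
evidence-likelihood ratio) is available via the `prior` argument, since
the loose phrase "likelihood ratio for and against the outcome" admits
both. Configurations with p = 1 are discarded — odds with no
counterexamples are infinite and carry no usable gradation — and
zero-probability configurations are skipped before emission; both counts
are logged.

Merging over a free condition (typically dose) averages member
probabilities and member certainty factors *separately*. The mean of
odds grows much faster than the odds of the mean — members at
p = (0.99, 0.90, 0.72) merge to an average probability 0.87 but a CF
near 37 — which is exactly how a pooled "safe under any exposure range"
rule can carry a CF an order of magnitude above `0.87/0.13`. Whether such
pooling should weight by data support is genuinely open; the unweighted
mean is used, and per-rule support counts are attached so users can
reweight.

## The synthetic study design

The generator reproduces the *shape* of the measured study: six
ERM-identified nanoform fingerprints (two HEC-coated variants, uncoated
and PVP-coated references, a HEC-ratio variant, a curcumin variant) with
descriptor values fixed once per profile; A549 lung exposures under MTT
and Alamar blue across 0.1–100 ppm; HCT-116 intestinal exposures under
WST-1, digested and non-digested, across 1.25–100 ppm; triplicates —
900 rows; 47% missingness on the four DLS columns and 19% on surface
area, missing completely at random (an optional measured-dose-subset mode
instead blanks all non-anchor doses, to exercise interpolation
specifically).

What the measured data does *not* get from the generator: the
dose–response is a clean Hill curve `V = 100 / (1 + (dose/EC50)^h)` with
homoscedastic Gaussian replicate noise (default SD 8% viability, h = 1.5)
— a stand-in mechanism, not an estimated one; agglomeration is a
deterministic log-dose growth of hydrodynamic size
(`t24 = t0 (1 + 0.35 log10(1 + dose))`) with the polydispersity index
tracking relative growth; missingness is independent of values; and
per-profile EC50s (5–80 ppm at A549, scaled ×1.5 for HCT-116 and ×2.5
for digested samples, reflecting the attenuating gastrointestinal
passage) were chosen once so that all three hazard classes are populated
with a safe majority. Passing tests therefore demonstrate *parameter
recovery under the assumed mechanisms* — monotone dose–hazard structure,
profile-specific fingerprints, MCAR gaps — not performance on laboratory
data, where interference between nanoforms and assays, correlated
missingness and heteroscedastic noise all await.

One consequence is worth stating plainly: with tercile-binned dose (three
states spanning two orders of magnitude) and ~8% replicate noise, part of
the class signal is simply not representable, and the macro-recall
summary of the constrained network sits in the low 0.70s — at the
empirical ceiling of the binned representation (a majority vote over the
full binned configuration does no better), while the mean of per-class
balanced accuracies sits around 0.80. Both summaries are reported by
`classification_metrics()`: `balanced_accuracy` is the macro mean of
per-class recalls (the scikit-learn convention), and
`mean_class_balanced_accuracy` averages the per-class `(TPR + TNR)/2`
panel — the convention under which per-class validation panels are
usually summarized into a single "average accuracy across hazard
classes". Choose deliberately when comparing to other work.

## Problem sizes and runtime choices

The test suite and analysis scripts run the full design at its natural
size (900 rows, 16 network nodes); exact structure search is exercised on
3–5 node problems where exhaustive enumeration (all 543 four-node DAGs)
is available as the optimality oracle, and inference is verified on
networks small enough to enumerate joints. Baseline ensembles use 300
trees / 150 boosting rounds with library-default hyperparameters recorded
in the leaderboards; a broad AutoML sweep is represented
by one member per family (random forest, extremely randomized trees,
gradient boosting, linear / single tree), which suffices to reproduce the
qualitative ordering tree ensembles > linear.

## Known limitations

* The constraint vocabulary covers required/forbidden arcs, roots, a
  unique sink and tiers — not path constraints or latent confounders.
* Exact search is exponential; beyond ~14 nodes use hill climbing.
* Rules condition on bins; a nanoform falling outside every mined rule's
  ranges must be scored through posterior inference directly (the
  applicability-domain view of the discretization map tells you when).
* Multiple-imputation uncertainty is not propagated; the chained imputer
  returns point estimates.
* The pipeline models a single outcome node; multi-endpoint networks are
  out of scope.
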