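---
title: "Methods: expression-based brain connectomes and their comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-based brain connectomes and their comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iegnet)
```

## The model

`iegnet` treats the regional expression of an immediate-early gene as a
multivariate observation per animal: one vector of 33 normalized
relative-dpm values (one per region of interest, ROI) for each animal of a
treatment group. Functional coupling between two ROIs within a group is
the Pearson correlation of their expression across that group's animals.
A group's *connectome* is the 33×33 correlation matrix; its *network* is
the undirected graph that keeps the ROI pairs whose correlation is
significant at p < 0.05, weighted by the signed coefficient.

The assumptions inherited from this design are worth stating plainly:

* **Normality.** Pearson correlation p-values come from the exact
  transform $t = r\sqrt{(n-2)/(1-r^2)}$ at $n-2$ df, which assumes
  bivariate normal expression. The study design this mirrors gates its
  own data on normality tests, and the synthetic generator draws from a
  multivariate normal for the same reason.
* **Tiny n.** With $n = 5$ animals per group the correlation estimate is
  extremely noisy (at $\rho = 0$, $\mathrm{sd}(\hat r) \approx 0.5$).
  Only strong coupling is detectable; every inferential statement leans
  on the permutation machinery rather than asymptotics.
* **Exchangeability.** The permutation tests assume animals are
  exchangeable between the two groups under the null — true for
  randomized treatment assignment, and the reason the whole animal (not
  the section, not the ROI) is the reassignment unit.

## Stages and their parameters

**Section averaging.** Each (animal, ROI) cell is the arithmetic mean of
its adjacent-section replicates (canonically 3), reported with the sample
sd. The replicate count is data-driven; a deviation from 3 only warns.

**Reference normalization** (`normalize_by_reference()`). Each animal's
ROI values are divided by that animal's reference-channel value (`gcc`,
genu of the corpus callosum — white matter with no expected signal).
Ratio scaling is the default because normalized group means of
densitometry data of this kind sit near 0–1 with differences of
0.1–0.7, consistent with a ratio rather than a difference scale; a
`subtract` mode shares the interface. Normalization is per animal, not by
the group-mean reference: a per-animal reference removes
animal-level exposure differences, which is what a loading control is
for. A zero reference in ratio mode is a hard, named error; missing
cells are hard errors too — with 5 animals per group there is no
defensible imputation.

**ROI contrasts** (`contrast_groups()`). Classical two-sample *t* per
ROI, difference = first group − second group. The pooled (equal-variance)
variant with $n_A + n_B - 2$ df is the default; a Welch variant is one
flag away, because published reports of this design mix pooled df = 8
with fractional Welch-like df, and the text does not resolve which ROIs
used which. We surface both rather than silently pick per ROI. The 95%
CI uses the same variance estimate and df as the test, so CI-excludes-0
and p < 0.05 coincide exactly (asserted in the tests). Family-wise
control is Bonferroni at α/m with m = number of ROIs; at α = 0.05 and
m = 33 the threshold displays as 0.0015. Zero-variance degenerate inputs
are given defined results (t = 0, p = 1 for equal means; ±∞, p = 0,
flagged, otherwise) instead of errors, so screening loops never crash.

**Thresholded networks** (`build_network()`). Edges are retained at raw
p < 0.05 — deliberately *not* corrected across the 528 pair tests. This
is a sensitivity/specificity trade-off: at n = 5 per group, any
family-wise correction across 528 tests would empty the graph. The
consequence, quantified by the calibration tests, is ~5% false edges
under a null with no true coupling (≈ 26 of 528). Negative-weight edges
are retained; ROIs with no retained edge are dropped from the node list
(node counts below 33 are therefore informative).

**Graph metrics** (`network_metrics()` and friends).

* *Density* is $E/(N(N-1))$ — the ordered-pair convention, under which a
  complete undirected graph has density 0.5. This is not the common
  undirected convention, but it is the one internally consistent with the
  published node/edge/density triples this package reproduces
  (e.g. 128 edges on 32 nodes → 0.129, 34 on 28 → 0.045); it is asserted
  in the acceptance tests and recorded in every run manifest.
* *Characteristic path length*, *clustering*, *betweenness* and
  *components* are computed on the unweighted graph: a retained edge
  counts 1 whatever its weight, because negative correlations have no
  shortest-path semantics. Path length averages over connected pairs
  only, which keeps it finite on fragmented networks (published values
  are finite with 4 components, which forces this convention).
  Clustering is the mean local coefficient with degree < 2 nodes
  contributing 0; the global-transitivity variant is available since the
  published tables do not say which was used. Betweenness is
  unnormalized by default (normalized = divide by $(N-1)(N-2)/2$).
* *Global strength* is $\sum_{i<j} |r_{ij}|$ of the **full** correlation
  matrix, not the thresholded graph — the whole-network statistic the
  permutation comparison uses; a thresholded variant sits behind a flag.

**Permutation comparison** (`compare_groups()` and the individual
tests). The observed statistic is always "first group − second group":
$r_A - r_B$ per pair, $S_A - S_B$ for strength, per-node centrality
differences with isolated nodes carrying 0. The null reassigns pooled
animals to pseudo-groups of the original sizes and recomputes everything
per assignment. Numerical conventions:

* When $\binom{n_A+n_B}{n_A} \le B$ the assignments are enumerated
  exhaustively — true for the canonical 5+5 design (252 < 1000), where
  exhaustive enumeration is strictly better than 1000 random draws; a
  `force_monte_carlo` flag reproduces literal sampling. Exhaustive p is
  the plain proportion of $|{\rm null}| \ge |{\rm observed}|$ (the
  identity assignment is included, so p > 0 and a zero observed
  statistic gives p = 1). Monte-Carlo p uses the add-one estimator
  $(x+1)/(B+1)$, which cannot be 0 at finite B.
* Tie comparisons use a $10^{-12}$ absolute fuzz so that exact
  symmetries (e.g. the full group swap) count as ties deterministically.
* A column made constant by a permutation would leave a correlation
  undefined; the affected pair's permuted statistic is recorded as 0 and
  counted in `n_constant_flags` — dropping the assignment would bias the
  null.
* No correction across the 528 edge or 33 node tests, mirroring the
  thresholding decision above; the per-test α is reported so callers can
  apply `p.adjust` downstream if they want.
* `compare_groups()` runs all four statistics on one shared assignment
  set, so the edge, strength and centrality results of a single report
  are mutually consistent permutation-for-permutation.

## What the synthetic generator emulates — and what it does not

`study_template()` fixes the study conditions: 4 treatment arms
(VEH/VEH, VEH/ASE, KET/VEH, KET/ASE) × 5 animals × 33 ROIs × 3 sections.
Animal-level ROI vectors are drawn as $\mu + \sigma \cdot (Z R^{1/2})$
with $R^{1/2}$ the symmetric eigendecomposition square root of the
target correlation matrix; section values add independent Gaussian noise
(default sd 0, so the imposed correlation is observed undiluted — any
positive section noise attenuates it, which is documented rather than
corrected); the reference channel is drawn independently with mean 1 and
sd 0 by default, making ratio normalization exact. The generated raw
table is pushed through the real averaging and normalization stages, so
tests exercise the actual pipeline path.

Preset structure:

* `null` — identical configs, identity correlation. The identity is
  forced by its calibration role: the ~5%-of-528 false-edge rate check
  requires zero true coupling.
* `paper_like` — means 0.5, marginal sd 0.15; within-system coupling
  r = 0.8 on disjoint striatal (LSS, CPDM, CPDL, CPVL, CPVM, AcCo,
  AcSh), insular (GI, DI, AID, AIV, Cl) and limbic (Ig, Cg2, LSD, LSI,
  LSV, MS, Shi) blocks over a 0.2 background (a sum of PSD components,
  hence PSD by construction). The KET-like group sign-flips the Ig and
  Cg2 *variables* ($DRD$ with $D = \mathrm{diag}(\pm 1)$), which exactly
  preserves PSD and turns their rows negative — the qualitative
  signature described for acute NMDA-antagonist challenge; the KET/ASE
  arm restores the control structure, and the KET arm's means are
  lowered by 0.2. Coupling of 0.8 is a deliberate choice: at n = 5, only
  strong coupling is detectable at all, matching the dense blocks such
  matrices display in practice.
* `edge_difference` — two groups differing in exactly one pair's
  correlation; the minimal differential-edge scenario for power checks.

The generator does **not** emulate: section-count imbalance, optical
densitometry artifacts, left/right hemisphere structure, non-normal or
heavy-tailed expression, animal-level covariates, or the actual
(unpublished) dpm values of any study — presets are structural, not
numerical mimics. Passing tests therefore show the *machinery* is
correct and calibrated under the stated model, not that any particular
biological claim replicates.

## Test and calibration problem sizes

The suite sizes its simulations to what the statistics need, not more:
oracle equivalence runs 200 random instances of ≤ 8 nodes against
brute-force enumerations (min-plus shortest paths, simple-path
betweenness, union-find components, triangle-count clustering);
exhaustive-vs-Monte-Carlo agreement uses the 20-assignment 3+3 design
against B = 10,000 draws (a per-statistic two-standard-error check, i.e.
a ~95%-coverage criterion per continuous statistic); type-I calibration
uses 200 replicate null datasets at the study's own 5+5 with all 252
exhaustive relabelings; power uses 50 replicates of the single-edge
Δr = 0.9 scenario at 20 animals per group. Seeds are fixed throughout;
`generate_study()` refuses to draw without one.

## Known limitations

* Correlation matrices use animal-level means only; pooling section
  replicates into the correlation would pseudo-replicate animals.
* Negative edges are retained but play no role in topology metrics;
  signed-graph metrics are out of scope.
* No partial correlations, shrinkage, or regularized network estimation:
  with n = 5 the marginal Pearson matrix is already at the edge of what
  the data support.
* The density convention and the raw-p edge threshold are faithful to
  the reference tables rather than to common graph-theory defaults; both
  are flagged in the documentation and the run manifest because they are
  the two places a careless cross-package comparison would go wrong.
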