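---
title: "Quantitative phenomic interaction analysis with qhtcp"
author: "qhtcp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phenomic interaction analysis with qhtcp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtcp)
```

# The measurement model

Q-HTCP screens grow arrayed spot cultures on agar under time-lapse
imaging. The observable per culture is a background-subtracted pixel
density trajectory, which is well described by logistic growth

$$G(t) = b + \frac{K}{1 + e^{-r (t - L)}}$$

with baseline $b$, carrying capacity $K$ (above baseline, in intensity
units), maximum specific rate $r$ (1/h) and $L$ (h), the time at which the
culture reaches half of $K$. $L$ is the workhorse parameter downstream: it
is inversely related to fitness and responds most strongly to drug dose,
which is why interactions are quantified on the $L$ scale. The area under
the fitted curve over an observation window has the closed form
$A = (K/r)\,[\mathrm{softplus}(r(t_1 - L)) - \mathrm{softplus}(r(t_0 - L))]$,
computed with an overflow-safe softplus.

**Fitting.** `fitLogistic` minimizes least squares by Levenberg–Marquardt
(`minpack.lm::nls.lm`) with an analytic Jacobian. Starting values are
deterministic functions of the data: $K_0$ from the intensity range, $L_0$
from linear interpolation of the half-range crossing, $r_0 = 4 \cdot
\text{slope}(L_0)/K_0$ (the logistic's maximal slope is $rK/4$), baseline
from the minimum. The baseline is fitted by default because real plate
images have nonzero background; fixing it at the first observation is a
configuration switch. 95% confidence bounds are symmetric curvature
(observed-information) intervals, $\hat\theta \pm t_{0.975,\,n-p}\,
\mathrm{se}(\hat\theta)$ with $\mathrm{se}$ from
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum; profile-likelihood bounds
were deliberately not used, as the curvature form is cheap, standard, and
adequate for the well-conditioned fits these dense series produce.
Optimizer failure or hitting the iteration cap never raises — the culture
is returned as non-grown with `converged = FALSE`.

**No-growth detection.** The screen needs a reproducible stand-in for "no
measurable growth". A culture is non-grown when its fitted $K$ falls
strictly below a capacity threshold or the fit's $R^2$ falls strictly
below 0.7. At screen level (`fitScreen`) the capacity threshold is 5% of
the plate-wide median fitted $K$, so the rule adapts to the imaging scale;
both cuts are configuration-exposed (`fitConfig`). A value exactly at the
threshold counts as grown (the cut is exclusive below).

**Image front end.** `quantifyStack` measures each spot as the summed
pixel intensity in a square window of side $0.9 \times$ pitch centered on
its nominal grid position, minus the frame's background (median of all
inter-spot pixels) times the window area. There is no per-spot
re-centering or plate-warp correction: the synthetic plates this front end
is validated on are rigid, and registration of real plates is out of
scope. With a Gaussian spot of width $\sigma = \text{pitch}/6$ the window
captures about 99.3% of the mass, which is why quantification accuracy is
asserted at the 1% level.

# Interaction scoring

For each deletion strain, $Y_i$ is the fitted $L$ at dose $D_i$ of a
six-step drug ladder starting at zero. Against the per-dose central
tendency $RD_i$ of the replicated single-mutant reference:

1. $K_i = Y_i - RD_i$ removes the dose effect on the reference;
2. $K_0$ (the value of $K_i$ at $D = 0$, the "ORF effect") is the
   knockout's drug-independent growth effect;
3. $L_i = K_i - K_0$ removes it, so $L_0 = 0$ exactly, by construction —
   the package asserts this identity to $10^{-12}$;
4. a quadratic $L_i = A + B D_i + C D_i^2$ is fit by least squares over
   the grown doses (including the zero at $D = 0$);
5. $INT = A + B D_{\max} + C D_{\max}^2$ evaluates it at the highest dose
   with measurable growth.

Choices worth stating:

* **Central tendency is the median** of grown replicates (mean available
  by option). With hundreds of replicates and occasional censoring or
  outliers the median is the robust default, and it is the summary the
  neutrality function is defined on. The reference band is the empirical
  central 95% (2.5/97.5 percentiles), used for display and diagnostics.
* **The intercept $A$ is fitted freely** even though $L_0 = 0$ by
  construction. The quadratic is a smoother, not a structural model;
  constraining $A = 0$ would propagate the (noisy) zero-dose anchoring
  into every coefficient. On exactly-quadratic input the fitted $A$ is 0
  to numerical precision, and recovered $(A, B, C)$ match planted
  coefficients to $10^{-9}$.
* **Censored doses are excluded, never imputed.** A dose without
  measurable growth contributes no $L$; the count of such doses is the
  strain's tier, and $D_{\max}$ retreats to the highest grown dose.
  Strains with fewer than three grown doses get no quadratic ($INT$ is
  NA) but keep their tier, so they remain rankable; strains failing at
  every nonzero dose carry the maximal tier and rank above all scored
  enhancers. Doses are equally weighted in the fit.
* **Ranking** is tier-descending, then $INT$-descending; within a tier a
  non-computable $INT$ sorts first (those strains are censored harder than
  any scored one), and ties break lexicographically by strain id so the
  order is deterministic. Tiers are kept as a separate key rather than
  folded into a single numeric scale with $INT$.
* **Classification is strict-inequality**: enhancer when $INT$ exceeds the
  positive cut or the strain has any no-growth tier, suppressor below the
  negative cut. The defaults (10 / −16 for the sensitized screen, 10 / −12
  for the wild-type background) are the tails of the interaction-strength
  distributions of the two screens; values exactly at a cut are not
  called.
* **Gene-drug conditions** tested at too few concentrations for a
  quadratic use the single-condition difference-of-differences:
  $(L^{del}_{drug} - L^{ref}_{drug}) - (L^{del}_{ctrl} - L^{ref}_{ctrl})$.

**Quality flags** (`qcFlags`) automate the manual low-confidence review:
`large_zero_dose_effect` ($|K_0| > 10$ h), `wildtype_context_interaction`
(the companion screen already calls the gene at its own thresholds),
`poor_quadratic_fit` (quadratic $R^2 < 0.8$), `plateau_response` (fitted
slope $B + 2 C D_{\max}$ under 5 h·mL/µg in magnitude while $|INT| > 10$ h
— a response that saturates instead of accelerating), and `weak_effect`
($|INT| < 5$ h). All cuts are configuration defaults, not published
constants; a call is high-confidence when classified and unflagged.

**Reproducibility diagnostic.** Deletions of overlapping open reading
frames disrupt the same locus, so their interaction scores should agree.
`overlapOrfCorrelation` reports the Pearson correlation over such pairs;
on synthetic pairs sharing a planted effect (effect spread ≫ measurement
noise) it exceeds 0.8.

# Profile clustering and enrichment

Genes passing either screen's thresholds (union, plus tiered no-growth
enhancers) are assembled into 15-column profiles: both screens' $INT$,
the control-media growth defect, and twelve gene-drug conditions
(`profileSchema`). Missing entries are median-imputed per column with the
mask retained.

`remc` clusters recursively: at each round a diagonal-covariance Gaussian
mixture is fit for $k = 1..6$ with 10 seeded restarts each, $k$ chosen by
BIC ($-2\ell + p\log n$, $p = (k-1) + 2kd$), and each resulting cluster is
re-clustered until BIC prefers $k = 1$ or the cluster drops below 9
members. Numerical safeguards: responsibilities are computed in the log
domain; per-dimension variances are floored at 5% of the full data's
variance in that dimension (held fixed through the recursion), and
restarts in which a component collapses onto fewer than two effective
members are rejected — without these, near-singular components inflate
the likelihood and BIC over-splits. The log-likelihood is non-decreasing
across EM iterations within any fit (tested), the tree is a partition of
the genes, node names encode round and lineage, and the whole tree is
reproducible from one seed. Within each leaf, display order comes from
complete-linkage hierarchical clustering on Euclidean distances
(`stats::hclust`).

Per-cluster enrichment uses the exact upper-tail hypergeometric
probability of each term's overlap (`stats::phyper`, verified against
combinatorial enumeration on all universes up to 25 genes),
Benjamini–Hochberg adjusted across terms within a cluster. Overall
functional-information enrichment is summarized GOid_z-style: the summed
$-\log p$ mass is compared with its permutation distribution over random
same-size gene sets (200 draws by default) as a z-score. This is a
reconstruction of the aggregate-enrichment idea, not a reimplementation
of any specific published formula; outputs label it `goid_z`. No GO DAG
parsing or term propagation is attempted — annotations are flat
term-to-gene tables.

# The synthetic screen generator

`generateScreen` emulates the statistical structure the analysis assumes,
not any particular dataset:

* a six-dose ladder 0–0.25 µg/mL and 768 reference replicates per dose,
  the screen's stated design;
* a monotone reference dose response $RD(D) = 30 + 30 D + 80 D^2$ h,
  a growth delay rising from 30 h untreated to ≈ 42 h at the top dose —
  plausible spot-culture kinetics on respiratory media;
* per-gene effects composed as
  $L(D) = RD(D) + K_0 + B D + C D^2 + \varepsilon$, with $K_0 \sim
  N(0, 2^2)$ h for every gene and planted $INT$ at the top dose drawn
  uniformly in $[15, 40]$ h for enhancers and $[-40, -24]$ h for
  suppressors (10% each by default) — magnitudes at least 1.5× the
  classification cuts, so recovery rates measure the pipeline rather than
  threshold luck; the linear/quadratic split of each planted effect is
  randomized;
* noise at two levels, $L$ noise (sd 0.5 h) and pixel-density noise
  (sd 2 intensity units on $K \approx 100$), so both the fitting and the
  scoring stages see error;
* censoring: a culture whose deterministic composed $L$ exceeds a 72 h
  horizon is emitted as a flat no-growth series, exercising the detector
  path; because the deterministic response is monotone in dose for
  enhancers, censoring is monotone too;
* optional overlapping-ORF pairs sharing one planted effect, and a
  class-linked gene-drug block for the profile columns.

Everything is reproducible bit for bit from the seed. What the generator
does **not** emulate: plate spatial artifacts, edge and batch effects,
pinning variability, non-logistic growth, or the real screen's
(unpublished) noise magnitudes. Green tests on this generator therefore
demonstrate correctness of the computations and recoverability under the
stated noise model — not robustness to everything real plates do.

# Problem sizes and test design

The suite validates each operation against an independent oracle computed
in the tests themselves: an exhaustive $(K, r, L)$ grid search for noisy
fits, trapezoidal quadrature for the AUC, direct polynomial evaluation
for planted quadratics, a hand-written comparison sort for ranking,
combinatorial enumeration for hypergeometric p-values, planted labels
(and an independently implemented mixture model, `mclust`) for
clustering. Screen-scale checks use 500 genes with 768 reference
replicates and full time-series rendering (≈ 7,600 curve fits), where at
least 90% of planted non-null genes must be classified correctly with at
most 5% false calls among nulls; clustering recovery uses two planted
15-dimensional clusters 4 sd apart across 10 seeds (ARI ≥ 0.9). Pipeline
determinism is asserted byte-for-byte on the written files. These sizes
were chosen as the smallest that exercise the screen's stated design;
all complete in about a minute on one core.

# Known limitations

* The quadratic is a local smoother over a short dose ladder; responses
  that saturate are flagged (`plateau_response`), not modeled.
* Confidence bounds are curvature-based and symmetric; for poorly
  constrained fits (few points past $L$) they can under-cover.
* The mixture model assumes diagonal covariance; strongly correlated
  profile columns can split elongated clusters.
* No p-values are attached to individual interaction calls; thresholds
  and tiers are the inferential device.
* The image front end assumes a rigid grid and well-separated spots.
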