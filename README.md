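# qhtcp

Quantitative high-throughput cell array phenotyping (Q-HTCP) and
gene-interaction analysis for chemical-genomic screens of arrayed yeast
spot cultures.

Genome-wide deletion screens grown across a drug concentration ladder
produce, for every double-mutant culture, a spot-intensity time series.
`qhtcp` turns those series into interaction calls and functional modules:

1. **Image quantification** — background-subtracted pixel density per spot
   of a 384-position plate across time-lapse frames.
2. **Growth-curve fitting** — each culture is fit to the logistic equation

   `G(t) = baseline + K / (1 + exp(-r (t - L)))`

   with carrying capacity `K`, maximum specific rate `r`, and `L`, the time
   to half carrying capacity (an inverse fitness proxy), plus the area
   under the curve `A = (K/r) log((1 + e^{r(t1-L)})/(1 + e^{r(t0-L)}))`.
3. **Interaction scoring** — for each strain with observed parameter `Y_i`
   at drug dose `D_i`, against the per-dose summary `RD_i` of hundreds of
   replicated single-mutant reference cultures:
   `K_i = Y_i - RD_i` (dose effect removed), `L_i = K_i - K_0` (knockout
   main effect removed, so `L_0 = 0` by construction), quadratic fit
   `L_i = A + B D_i + C D_i^2`, and the interaction value
   `INT = A + B D_max + C D_max^2` at the highest dose with measurable
   growth. Strains failing to grow at high doses are ranked in tiers by
   the number of such doses.
4. **Classification and QC** — deletion enhancers (`INT` above a positive
   cut, or any no-growth tier) worsen drug sensitivity; deletion
   suppressors (`INT` below a negative cut) rescue it; automated flags
   reproduce the manual low-confidence exclusion criteria (large zero-dose
   effect, wild-type-context interaction, poor quadratic fit, plateau
   response, weak effect).
5. **Profile clustering and enrichment** — selected genes get a 15-column
   interaction profile (both screens, control growth, twelve gene-drug
   conditions) clustered by recursive EM (diagonal-covariance Gaussian
   mixtures, BIC-chosen k, recursed per cluster), ordered within clusters
   by complete-linkage hierarchical clustering, and scored for gene-set
   enrichment (exact hypergeometric per term, BH-adjusted, plus a
   permutation z for overall enrichment).

A fully seeded synthetic-screen generator (`generateScreen`,
`generateProfiles`, `renderPlateImages`) emulates the statistical
structure of such a screen — dose-dependent reference response, planted
knockout and quadratic interaction effects, censoring of strong enhancers
at high doses, replicated reference cultures, overlapping-ORF pairs —
with ground truth attached, so every stage is testable end to end.

## Worked example

```r
library(qhtcp)
set.seed(1)

## one culture: fit the logistic growth curve
t <- seq(0, 48, by = 2)
fit <- fitLogistic(CultureSeries("yfg1-d0.25", t,
  logisticCurve(t, 100, 0.4, 30) + rnorm(length(t), 0, 2)))
fit
#> GrowthFit 'yfg1-d0.25': K = 99.49, r = 0.4287 /h, L = 30.01 h, AUC = 1790, R2 = 0.9984

## reference model from 768 replicates per dose
doses <- c(0, 0.05, 0.1, 0.15, 0.2, 0.25)
ref <- buildReference(data.frame(
  dose = rep(doses, each = 768),
  L = rnorm(768 * 6, rep(30 + 30 * doses + 80 * doses^2, each = 768), 1.5)))

## score one strain's dose response
dr  <- DoseResponse("yfg1", doses, centralL(ref) + 2 + 50 * doses + 60 * doses^2)
res <- qcFlags(classifyInteraction(scoreInteraction(dr, ref), Thresholds(10, -16)))
res
#> InteractionResult 'yfg1': K0 = 2 h, INT = 16.2 h at D = 0.25, tier = 0, class = deletion_enhancer
```

The strain's deletion slows growth by 2 h on its own (`K0`, removed before
fitting), and its drug response diverges from the reference by 16.25 h at
the top dose (`50*0.25 + 60*0.25^2`), calling a high-confidence deletion
enhancer. `runPipeline(pipelineConfig(...))` chains all stages on a
simulated screen and writes provenance-stamped TSV tables
(screen layout, interaction layout, selected genes, clusters, cluster
summary) plus a run log.

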