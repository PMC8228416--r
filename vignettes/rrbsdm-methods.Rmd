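---
title: "Methods: overdispersion-corrected differential methylation for RRBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overdispersion-corrected differential methylation for RRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdm)
```

## The problem

Reduced representation bisulfite sequencing (RRBS) enriches CpG-rich genomic
regions by MspI digestion (cutting at CCGG), size selection, and bisulfite
conversion, yielding per-CpG counts of methylated and unmethylated reads.
Small-n animal studies — here the motivating design is three treatment
groups × three animals × two striatal hemispheres — need a per-CpG test that
is honest about two things: the counts are binomial only within one animal,
with extra-binomial scatter between animals; and with three animals per
group there is no room for a random-effects model, so a conservative
moment-based dispersion correction has to carry that burden.

## The per-CpG model and test

At one CpG, let sample $i$ in group $g(i)$ have $m_i$ methylated reads out
of $n_i$. The working model is a binomial logistic regression of the
methylated proportion on the group indicator. With a single binary
covariate the maximum-likelihood fitted proportions have closed form — the
coverage-weighted pooled proportions per group,
$\hat p_g = \sum_{i \in g} m_i / \sum_{i \in g} n_i$ — so `rrbsdm` fits the
model in closed form rather than by IRLS; the unit tests verify agreement
with an independently coded `stats::glm` fit to $10^{-6}$.

The statistic is the deviance difference between the intercept-only and
two-group fits, scaled by a dispersion factor estimated from the Pearson
residuals of the two-group fit:

$$X^2 = \frac{D_0 - D_1}{\varphi}, \qquad
\varphi = \max\!\left(1,\ \frac{\sum_i r_i^2}{n - 2}\right),$$

referred to $\chi^2_1$. Properties that matter:

* **Clamping at 1.** Under-dispersed sites are *not* rewarded: $\varphi < 1$
  is never applied, so the correction can only push p-values up. The
  acceptance suite asserts this at every site with raw dispersion above 1.
* **Boundary fits.** When a group is entirely unmethylated or entirely
  methylated the fitted proportion sits on the boundary; deviance terms are
  evaluated with fitted proportions clipped to $[10^{-8}, 1-10^{-8}]$ and
  the $0 \log 0 = 0$ convention, so the statistic is always finite.
* **Pseudo-replication.** When the six striata of a group (two hemispheres
  × three animals) enter as six samples, the hemispheres are not independent
  — the two sides of an animal have near-identical methylation. The test is
  run exactly as specified on six samples, and the dispersion correction
  absorbs part, not all, of the resulting correlation. This is a documented
  limitation, not a modelling choice we endorse: no animal-level random
  effect is fitted. The null simulations below quantify the consequence
  (the realized false-call rate at $q<0.01$ stays around 0.1–0.2%, i.e.
  within an order of magnitude of nominal but not exactly nominal).

Filtering precedes testing: a (site, sample) cell is used only with
coverage ≥ 10 reads (the standard RRBS convention of keeping cytosines with
more than 9 reads), and a site is testable when each group retains at least
`min_samples_per_group` cells — all samples by default, with the relaxed
4-of-6 rule available for pooled six-striata comparisons.

Multiple testing uses Benjamini–Hochberg across all tested sites of a
comparison, with DMS called at strictly $q < 0.01$ and **no**
minimum-difference filter. BH was chosen deliberately: the q-value variant
used by some methylation toolchains (e.g. SLIM) is less transparent and
harder to verify by hand arithmetic; absolute DMS counts are therefore not
comparable across q-value procedures, while all distributional and
relational results are.

The reported effect size is the pooled difference
$100(\hat p_b - \hat p_a)$ in percentage points — not a model coefficient —
because that is what the field reports and thresholds (e.g. the ≥20-point
screen) are defined on.

## Genomic context assignment

Two independent axes, each exhaustive and exclusive:

* **Gene axis** with precedence promoter > exon > intron > intergenic,
  evaluated across all overlapping genes (most specific label wins). The
  promoter window is ±1000 bp around the TSS (TSS = interval start on the
  plus strand, end − 1 on the minus strand). The window size is a
  convention, not an estimate; it is configurable.
* **CpG-density axis** with precedence island > shore > open sea. The shore
  is fixed at 2000 bp from an island edge (inclusive), matching the standard
  definition of shores as the 2 kb flanks of CGIs. Overlapping islands are
  merged before any distance computation.

Nearest-gene assignment breaks exact distance ties toward the
lexicographically smaller gene id so output is deterministic.

## Spatial and comparative analyses

* **Distance null.** The null distribution of DMS neighbor distances is the
  per-bin mean histogram over 100 draws of the same number of sites,
  uniformly without replacement from the background CpG set, genome-wide
  (per-chromosome stratification is available as an option; the genome-wide
  choice is the default because the background is itself genome-wide).
  Histogram bins are logarithmic, 30 bins from 1 bp to 10 Mb, plus an
  overflow bin; the bin layout is a display choice with no effect on any
  test.
* **Co-direction.** The same-direction fraction is computed over *pairs* of
  DMS within 100 bp on a chromosome (not over connected clusters; with
  clusters the quantity would depend on an arbitrary linkage rule). The
  median absolute amplitude difference among same-sign pairs summarizes how
  similar the change magnitudes are.
* **1-Mb bins** are anchored at coordinate 0 per chromosome and half-open,
  so positions 999,999 and 1,000,000 fall in different bins; the difference
  track conserves totals by construction.
* **Nested correlations** are Pearson product-moment coefficients of
  per-CpG methylation changes for three nested site sets: all shared CpGs,
  CpGs that are DMS in at least one comparison, and CpGs that are DMS in
  both. Coefficients are undefined (NA) below 3 points.
* **Delta screen**: CpGs that are DMS in ≥1 of the two comparisons with
  $|\Delta_1 - \Delta_2| \ge 20$ points, threshold inclusive.

## What the simulator emulates — and what it does not

`simulate_rrbs()` generates the full study: a miniature genome (genes with
exons and strand, CpG islands half-anchored at TSSs), CCGG positions whose
inter-site gaps mix short (50–1150 bp) and long (1300–4000 bp) fragments so
that a realistic fraction of CpGs survives the [50, 1200] bp size-selection
window, and counts built from latent regional methylation levels:

* Consecutive covered CpGs within 100 bp share one **latent region**;
  regions, not sites, carry baselines and effects. This is what produces
  the observed co-direction of close DMS pairs.
* Region baselines are Beta(mean·30, (1−mean)·30) draws with
  context-dependent means: 0.1 in CpG islands/promoters, 0.8 in open sea,
  and 0.5 in shores (the first two are the canonical bimodal methylation
  pattern of mammalian genomes; shores are intermediate in CpG density and
  methylation, hence 0.5).
* Animal-level levels are Beta-distributed around the group mean with
  intra-class correlation `dispersion` (default 0.02, a typical magnitude
  of between-animal scatter in bisulfite data; the original study reports
  no dispersion estimates, so this default is constrained only by the
  invariant tests, never tuned to match reported DMS counts). **Both
  hemispheres of an animal share the animal's latent level** — sides are
  exchangeable replicates, reproducing the near-identical side profiles of
  the motivating study. A `side_effect` knob exists and defaults to 0.
* Effects shift the latent level of the affected region in the target
  group(s) by `delta` percentage points; an effect spec can target several
  groups at the same sites, which models a shared treatment response. The
  default effect-table helper uses a 0.75 hypomethylation fraction,
  mirroring the >3:1 hypo:hyper asymmetry of chronic drug-treatment
  methylation responses, and places effects in open sea, where >80% of such
  changes are observed.

Not emulated: nucleotide sequence (CCGG positions are placed, not read from
sequence), bisulfite conversion errors, read-level artifacts, mappability,
chromosome-scale methylation domains, and any transcriptional coupling.
Passing tests on this generator therefore demonstrate the correctness and
calibration of the statistics under a plausible count-generating process —
they do not certify performance on real libraries with conversion bias or
alignment artifacts.

## Verification experiments and problem sizes

The test suite and the acceptance script verify, on freshly simulated data:

* **Oracle equivalence** on 100 random small instances (2–6 samples/group,
  coverage 10–50), against a separately coded IRLS fit.
* **Null calibration** on ≥20,000 tested CpGs (3 chromosomes × 3.5 Mb):
  DMS fraction ≤ 2% at $q<0.01$ (realized ≈ 0.1–0.2%).
* **Recovery**: 200 injected ±40-point effects at depth 30 are detected at
  ≥70% (realized ≈ 85–95%) with ≥95% correct sign (realized 100%).
* **Correlation nesting** over 50 replicates of a shared-effect study: the
  experiment injects mostly shared effects of heterogeneous magnitude into
  both treated groups (70 shared hypo, 15 shared hyper regions) plus a small
  group-specific component (6 per group), matching a setting where the two
  treatments act largely identically; $r_{all} < r_{any} < r_{both}$ must
  hold in ≥90% of replicates (realized 100%, with means ≈ 0.75/0.89/0.95).
  Note that $r_{all}$ is substantially positive even at null sites because
  both comparisons share the reference group's sampling noise — the same
  reason the analogous genome-wide coefficient is mid-range in real data.
* **Co-direction**: DMS pairs within 100 bp agree in sign in >85% of cases
  (realized ≈ 100%, since whole latent regions shift together).
* **Resampling-null sanity**: a uniformly drawn "DMS" set stays within 3
  null standard deviations per histogram bin.

These sizes (1–3 chromosomes of 1–3.5 Mb, ~2,000–25,000 covered CpGs) were
chosen as the smallest scale at which the asymptotic behaviors above are
stable across seeds; they are the package's reference conditions for
verification, and the generator defaults encode the study design itself
(3 groups × 3 animals × 2 hemispheres, mean depth 30).

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; all emitted files
  use the 1-based inclusive convention of the Bismark coverage format.
* The Bismark coverage format carries no strand, so file-derived sites get
  strand `"*"`; sites are keyed by (chrom, pos, strand) and opposite-strand
  CpGs are never merged (per-cytosine reporting, no destranding).
* Missingness is explicit (`NA`), distinct from zero coverage, which makes
  the 4-of-6 rule well-defined.
* A site where one group has zero total usable coverage is excluded and
  logged, not tested.
* A pooled difference of exactly 0 is never a DMS regardless of q; q exactly
  at the threshold is not a DMS (strict inequality).
* Ties in BH are handled by `stats::p.adjust`; ties in nearest-gene
  distances by gene id; RNG state is saved and restored around every seeded
  operation so package calls never perturb the caller's random stream.

## Known limitations

* No covariates, no paired within-animal model, no region-level (DMR)
  calling — single-CpG resolution only, as in the motivating analysis.
* The dispersion estimate has only $n-2$ degrees of freedom at $n=6$; its
  sampling noise makes individual p-values rough, which is why calling is
  done at a strict $q<0.01$ and why headline results should be read as
  distributional, not per-site, statements.
* Gene-set enrichment is out of scope; the annotation module exports
  ranked nearest-gene tables suitable for external enrichment tools.
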