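---
title: "Mapping interaction QTLs from donor-resolved HiChIP loops: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping interaction QTLs from donor-resolved HiChIP loops: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopqtl)
```

## The problem

H3K27ac HiChIP measures chromatin contacts anchored at active regulatory
elements. When the same loops are profiled across a genotyped cohort, loop
strength becomes a quantitative trait: an *interaction QTL* (iQTL) is a
variant whose genotype — and, in heterozygous donors, whose allele — is
associated with the contact count of a specific loop. loopqtl implements
this mapping for cohorts of the scale typical in such studies (~30 donors),
together with two extensions: *multi-loop iQTLs* (one SNP driving several
loops in the same direction) and *connectivity-QTLs* (a SNP associated with
the pooled contacts of a whole spatial cluster of loops), plus a
loop-matched resampling null for annotation-overlap enrichment.

Inputs are tabular: per-donor loop tables at 5 kb bin resolution (observed
and expected counts, per-donor significance flags), bi-allelic autosomal
genotypes from a VCF, and optionally per-donor read-pair records for
allele-specific counting. All coordinates are 0-based half-open internally;
VCF positions are converted at ingest.

## Candidate pairs and allele-specific reads

For a loop between bins $b_1$ and $b_2$ (width = resolution $r$ = 5000 bp),
the SNPs tested are those within $[b_1 - w,\, b_1 + r + w)$ or
$[b_2 - w,\, b_2 + r + w)$ with $w = 5000$ bp, i.e. two 15 kb windows (the
anchor bin plus one flanking bin each side). We treat the windows as
half-open on both flanks so the three bins are covered exactly once. A SNP
inside both windows of one loop is tested once (`side = "both"`), with
allele reads counted toward the anchor farther from the SNP; whether such a
SNP should contribute reads in both directions is not determined by the
source material, and the single-direction choice is ours.

Allele-specific reads for a (SNP, loop, donor) triple are the paired-end
cis contacts whose allele-tagged end overlaps the SNP and whose other end
falls inside the opposite 15 kb window, requiring MAPQ ≥ 10 on both ends
and a pair span inside 10 kb–3 Mb. Reads showing a third base at the SNP
are ignored (bi-allelic model) but tallied. Only heterozygous donors are
counted; donors with missing genotypes at a SNP are excluded from both the
trend test and the allele test (the original pipeline's behaviour for
missing calls is unknown; exclusion is our documented choice).

## Association statistics

The upstream reference pipeline fits a Bayesian negative-binomial model
(RASQUAL) jointly over population and allelic signals. loopqtl substitutes
defined, reproducible statistics whose thresholds play the same roles:

* **Genotype trend** (`p_geno`, feeding `FDR_Pop`): OLS of
  $\log_2(\text{CPM}+1)$ on dosage (0/1/2), with categorical donor
  covariates (sex, age group, race) as indicator columns. Sequencing depth
  enters through counts-per-million normalisation, not the regression. The
  p-value is the F-test for the dosage term.
* **Allele-paired test** (`p_as`): a one-sided paired t-test on per-donor
  `alt − ref` read counts over heterozygous donors with ≥ 1 assignable
  read; at least 3 usable donors are required, otherwise `p_as` is
  missing. The side is the sign of the genotype slope (falling back to the
  sign of the mean difference), mirroring the requirement that allelic and
  genotype trends agree.
* **Combined significance** (`p_comb`, feeding `FDR_Def`): Fisher's
  combination of `p_geno` and `p_as` when the latter exists, else `p_geno`
  alone. Benjamini–Hochberg step-up over all testable pairs genome-wide
  gives `fdr_def` and `fdr_pop`; BH was chosen because the source's FDR
  procedure is not stated.

Numerical choices: p-values are clamped at `1e-300` before taking logs; a
numerically perfect fit reports p = 0 (slope ≠ 0) or 1; a constant response
reports p = 1, slope = 0; fewer than 4 residual degrees of freedom marks
the pair untestable. For the degenerate paired test with zero variance we
use the $t \to \pm\infty$ limit — p = 0 when the mean difference points in
the tested direction and p = 1 when it opposes it — rather than an
unconditional 0, so a discordant degenerate case cannot slip through.

## The filtering cascade

A pair enters the call set iff all of the following hold
(`apply_filter_cascade()`):

1. `fdr_def` < 0.05;
2. each genotype class (0|0, 0|1, 1|1) present in ≥ 2 donors;
3. if `fdr_pop` ≥ 0.05: `p_as` must exist and be < 0.05, **and** the
   allelic direction must match the genotype direction (mean alt − ref
   reads vs mean normalized count at 1|1 − 0|0, both nonzero);
4. if `fdr_pop` < 0.05 and `p_as` is missing or ≥ 0.05: the per-genotype
   counts must be strictly monotone. We parse "either mean or median of the
   raw and normalized counts" as: **one** statistic (mean *or* median),
   strictly monotone in **both** the raw and normalized series, with the
   same orientation — the permissive "either" binds the statistic, the
   conjunction binds the two series. A pair significant in both branches
   passes without the auxiliary checks.

Reason codes name the first failed clause in the order `fdr_def`,
`presence`, then the branch clause, so decisions are reproducible from the
written statistics alone.

## Multi-loop and connectivity QTLs

An accepted SNP with > 1 loop is a *multi-loop iQTL* when all per-loop
genotype slopes share one nonzero sign and the pooled regression of
obs/exp ratios (stacked over loops × donors) on dosage has p < 1e-5.
Dosage (not genotype-class means) is the regressor; the source fits
"against the genotypes" without specifying, and dosage matches a linear
genotype coding.

For connectivity, each accepted (SNP, loop) seeds an iterative component
growth over the loops significant in ≥ 1 donor: with extrema
$r_1^s, r_1^e$ over member $b_1$'s and $r_2^s, r_2^e$ over $b_2$'s, any
loop with $b_1' \in [r_1^s - t, r_1^e + t]$ and
$b_2' \in [r_2^s - t, r_2^e + t]$ joins ($t$ = 10 kb, two bins; closed
bounds on bin starts), until a fixpoint. If the segments
$A = [r_1^s, r_1^e]$ and $B = [r_2^s, r_2^e]$ are disjoint, the final set
is every significant loop with one end in $A$ and the other in $B$;
otherwise every significant loop inside the span $[r_1^s, r_2^e]$.

One caveat we verified empirically: because candidates are compared against
the *box* of the current set while a fresh seed is only a point, this
growth is not seed-symmetric on arbitrarily dense loop configurations. With
$t$ = 10 kb, loops $(20000, 110000)$, $(30000, 115000)$, $(35000, 100000)$
grow to all three from the first loop but only to itself from the third.
On realistic loop calls — tight anchor clusters separated by much more than
the slack — any member of a final component reproduces the identical
component, and that is the regime our seed-invariance tests generate.
Duplicated (SNP, region) pairs reached from different seeds are evaluated
once.

A region is called a connectivity-QTL when (i) the pooled regression over
its loops has p < 1e-5, (ii) the Bonferroni-adjusted p (family = all
(SNP, region) pairs actually evaluated in the run, the source names no
family) is < 0.005, and (iii) the genotype-aggregated maps pass the
percentile step: per genotype class, each map cell (bin pair with a
positive contact) holds the mean obs/exp ratio over donors of that class
with a positive count; $y_g$ is the 95th percentile of the log2 map over
non-empty cells (linear interpolation between order statistics, R type 7 —
the interpolation rule is not specified upstream); the triple
$(y_{ref}, y_{het}, y_{alt})$ must be monotone with every step ≥ 0.1.
Cells with no positive contact in a class are excluded from that class's
percentile rather than treated as zero, because $\log_2 0$ is undefined;
this is a documented divergence risk. A genotype class with no donors
leaves $y$ undefined and the region uncalled.

## Enrichment with a loop-matched null

Overlap uses exact coordinates by default (a SNP inside a half-open
interval), with a configurable slack (5000 bp reproduces "within 5 kb"
proximity matching). The null set samples, for each iQTL-associated loop,
as many control SNPs as that loop has iQTLs, from the SNPs overlapping or
within ±20 kb of either anchor, excluding all iQTLs; we sample without
replacement *globally across loops* (the stricter reading — whether
controls may repeat across loops is not stated). A pool smaller than the
required count contributes all its SNPs and logs the shortfall; we never
resample with replacement. Significance is two-sided Fisher's exact; the
reported odds ratio is the cross-product $(ad)/(bc)$ with the 0/∞
conventions, not the conditional MLE.

## The synthetic cohort generator

`sim_config()` states the world the tests assume: 30 donors; Hardy–Weinberg
dosages at MAFs in [0.1, 0.5]; per-donor depths uniform in 1–3 × 10^5 valid
cis read pairs; per-loop expected counts
$\mu_{ld} = \text{baseline}_l \cdot (\text{depth}_d/10^5) \cdot
(\text{dist}_l/10^5)^{-1}$ with baselines uniform in [5, 50] (≈ 5–100
counts across the 20–350 kb distance range); observed counts
negative-binomial with dispersion 0.2 (variance $\mu + 0.2\mu^2$), the
faithful noise family for count data of this kind; planted pairs multiply
$\mu$ by $\text{effect}^{\text{dosage}}$ (default 1.5 per alt copy) with a
matching allelic ratio (alt fraction $\rho/(1+\rho)$ in heterozygotes,
0.5 at nulls); a `discordant` switch plants opposing allelic and genotype
directions to exercise the concordance filter. Connectivity loci are
chains of 8 loops whose anchors advance one bin at a time (one component
under the 10 kb slack) sharing a MAF-0.4 SNP whose effect spans the
cluster. Significance flags mark the top quartile of obs/exp within each
donor × distance stratum — a stand-in for per-donor loop calls whose only
downstream role is membership ("significant in ≥ 1 donor"). Read-pair
records are emitted consistently with the aggregate allele counts, plus
decoys (low MAPQ, off-window, third base) that the counting filters must
reject.

What the generator does *not* emulate: mappability and restriction-site
structure, reference bias in allele assignment, linkage disequilibrium
between SNPs, trans contacts, structural variation, and donor-level
correlation beyond depth. A green parameter-recovery test therefore
establishes that the pipeline recovers multiplicative genotype effects and
binomial allelic imbalance from NB counts at cohort scale — not that it
reproduces any study's specific call set, whose inputs are controlled
access.

## Scaling of the test suite

Acceptance-style properties run at desk scale: calibration uses 2000 null
fits, iQTL recovery averages 10 seeds of a 500-loop cohort, connectivity
recovery uses 20 planted and 20 matched-null replicates of an 8-loop
locus. These sizes keep the suite inside a few minutes; the statistical
thresholds tested (rejection rate in [0.03, 0.07], sensitivity ≥ 0.8,
FDP ≤ 0.10, recovery ≥ 90% with silent nulls) are the stated acceptance
bands, not tuned quantities.

## Known limitations

* The RASQUAL substitution ignores genotype uncertainty and reference
  bias; effect sizes are slopes on log2 CPM, not the original model's
  allelic fold changes.
* Expected counts estimated by `estimate_expected_counts()` (log-spaced
  distance strata, 8 per decade, stratum means, 0.5 pseudocount for empty
  strata) are coarser than a full loop-caller background model; supply the
  caller's expected column when available.
* Component growth inherits the seed asymmetry described above on
  pathological inputs.
* The enrichment module does not expand sets by linkage disequilibrium.
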