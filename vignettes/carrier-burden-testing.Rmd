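---
title: "Control-free carrier burden testing in disease-centralized cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-free carrier burden testing in disease-centralized cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecarrier)
```

## The problem

Small, disease-centralized sequencing cohorts — everyone in the study has the
condition, and there are no matched healthy controls — cannot be analyzed
with the usual case/control burden machinery. What such a cohort *can* ask
is: given public population allele frequencies, is any variant carried by
more of the cohort than chance would allow? `rarecarrier` implements that
question end to end for a whole-exome cohort: genotype/variant quality
control, rare-variant selection from functional annotation, a per-variant
binomial carrier test under dominant and recessive inheritance, and a
gene-level CAST collapse ranked by protein-length-normalized mutation
fraction. A synthetic cohort generator makes every stage testable at desk
scale without access to patient data.

## The carrier model

For a bi-allelic variant with resolved population minor allele frequency
$q$ (written `pmaf` throughout), Hardy-Weinberg proportions give the
probability that one unrelated individual carries the variant:

* dominant model (het or hom-alt): $p_{\mathrm{ind}} = 2q(1-q) + q^2$;
* recessive model (hom-alt only): $p_{\mathrm{ind}} = q^2$.

$q$ is resolved per variant as the larger of the two panel frequencies
(genomes and exomes columns of a gnomAD-style annotation); when both are
absent, a fixed default of 3e-6 is used — just below the smallest frequency
such panels deposit — so $p_{\mathrm{ind}}$ is never zero.

With $N$ cohort members and $k$ observed carriers, the reported statistic is
the binomial point mass

$$P(k; N, p_{\mathrm{ind}}) = \binom{N}{k} p_{\mathrm{ind}}^{\,k}
 (1 - p_{\mathrm{ind}})^{N-k},$$

adjusted across the scan by Bonferroni multiplication (the output column is
labelled `fdr` for continuity with common usage in such scans, but it is a
family-wise adjustment). Note the statistic is a *point* probability, not a
tail sum. We implement it exactly in this form because it reproduces the
published worked examples it is modelled on; it is anti-conservative in
principle as a test (a point mass can be small simply because many outcomes
are possible), so `burden_scan(..., tail = TRUE)` provides the proper
upper-tail probability $P(X \ge k)$ as a clearly-labelled alternative. In the
null simulations shipped with the package the two behave almost identically
at rare frequencies, because at small $p_{\mathrm{ind}}$ the point mass
dominates its own upper tail.

The dominant scan tests every rare variant, autosomal and X-linked; the
recessive scan first drops X-chromosome variants (hemizygous genotypes make
"homozygote" ill-defined there), restricts the *report* to variants with at
least one homozygous carrier, but keeps the full post-exclusion variant
count as the Bonferroni multiplier — the multiplier counts tests performed,
not results printed. Ties in raw probability are broken by (chrom, pos, alt)
so output order is stable.

Hemizygous or otherwise haploid genotypes are decoded as their alternate
allele count (a single-allele `GT` of `1` is dosage 1), and any individual
with dosage $\ge 1$ counts as a dominant-model carrier. Multi-allelic VCF
records are split per alternate allele before analysis, since all
probabilities are per-allele; at a split record an allele belonging to a
*different* alternate counts as non-carrier rather than missing — coding it
missing would zero the call rate at every multi-allelic site under the
default call-rate-1.0 filter — and `AD` keeps the reference count and that
alternate's count only.

## Quality control

The cascade runs masking → depth → Hardy-Weinberg → call rate; each stage's
removals are recorded in a `qc_report`. Defaults, all on "less than"
semantics (the boundary value is kept):

| parameter | default | meaning |
|---|---|---|
| `gq_min` | 20 | genotypes with GQ < 20 set missing |
| `ab_low`, `ab_high` | 0.2, 0.8 | het calls with allele balance outside the band set missing |
| `dp_min` | 10 | variants whose depth statistic < 10 excluded |
| `hwe_p_min` | 1e-6 | variants with HWE exact p < 1e-6 excluded |
| `call_rate_min` | 1.0 | variants with any missing genotype excluded |

Allele balance is `ad_alt / (ad_ref + ad_alt)`; a heterozygote without
usable AD fields is masked and counted separately by default
(`het_missing_ad = "keep"` retains them). The depth statistic defaults to
the *minimum* per-sample DP over calls with a non-missing dosage — the
strictest reading of a minimum-depth exclusion — with `depth_stat = "mean"`
as the lenient alternative. Whether depth filtering runs before or after
genotype masking is in principle a free choice; the package fixes the order
masking-first (so masked calls do not contribute their depth), which the
report makes auditable.

The Hardy-Weinberg test defaults to the exact test: conditional on the
total genotype count and the minor-allele count, the probability of each
possible heterozygote count has a closed hypergeometric-type form, and the
two-sided p-value sums all heterozygote counts whose probability does not
exceed the observed one's (no mid-p). The exact test is the right default at
rare-variant counts where the chi-square approximation fails;
`hwe_method = "chisq"` gives the asymptotic test for users who want it.
Internally the enumeration runs in log space with a `1 + 1e-7` relative
tolerance when comparing probabilities, so equal-probability configurations
are not lost to floating-point rounding. Because the cohort is all cases,
HWE here is a *technical artifact* filter, not a population-genetics test;
a true disease locus under strong selection could in principle be removed,
which is a known limitation of control-free designs.

## Rare-variant selection

A variant enters the scan when (i) its population MAF — maximum of the two
panel fields, with a variant absent from *both* panels treated as rare — is
strictly below `maf_cutoff` (default 0.05); (ii) its functional region is
not in the excluded list (UTRs, intronic, intergenic, up/downstream and
ncRNA categories; `splicing` and `exonic;splicing` are retained); (iii) it
is not a synonymous SNV; and (iv) it is not flagged as pseudogenic. The
exclusion list is data, not code. Note the asymmetry in missing-MAF
handling: absence from the panels keeps a variant in the rare set (it is, as
far as anyone knows, rare) but contributes the 3e-6 default only inside the
probability computation — the annotation itself is never edited. Pseudogene
status is supplied by the user (a flag column); the package does not attempt
to identify pseudogenes. Unknown functional-region categories are kept with
a warning rather than dropped, so a novel annotation vocabulary fails loudly
instead of silently shrinking the scan.

## Gene-level CAST collapse

For gene ranking, variants qualify either by type — frameshift
insertion/deletion, stopgain, stoploss, nonframeshift insertion/deletion
(category aliases like "stop gain" are canonicalized via a configurable
synonym table) — or, for nonsynonymous SNVs, by at least two damaging votes
among SIFT = D, PolyPhen2-HVAR = D, CADD phred > 15 (strictly), and
FATHMM-MKL = D. Missing predictor values cast no vote, and PolyPhen's "P"
(possibly damaging) does not count by default — the vote rule asks for
*damaging* calls — though `polyphen_damaging = c("D", "P")` relaxes that.

CAST then reduces each sample to a binary indicator per gene (carries at
least one qualifying variant or not); the gene's carrier count is the size
of the union of its variants' carrier sets, hence always at least the
largest variant-level count. Dividing by protein length (amino acids, from
a user-supplied UniProt-derived table) gives the mutation fraction, which
corrects the tendency of long genes to accumulate variants by chance; genes
missing from the length table are reported but excluded from ranking. The
top tier flags the genes in the top 0.1% of defined fractions: the cutoff is
the smallest fraction among the top `ceiling(percentile * n)` values and
ties at the cutoff are all flagged. Genes are keyed by annotated symbol with
no harmonization attempted; `damaging_filter = FALSE` collapses all rare
variants for users who want the unselected version. There is no gene-level
p-value by design — the ranking is descriptive.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not a sequencer: genotypes are drawn directly as Binomial(2, q)
alternate alleles per sample — Hardy-Weinberg at the variant's true MAF, so
the cohort carrier count is Binomial(n, p_ind(q)) under either model — and
the quality fields are decorations sufficient to exercise each QC filter.
Defaults describe a 93-sample whole-exome cohort: 2,000 variants, a
log-uniform MAF spectrum on [1e-5, 0.05) (rare variants span orders of
magnitude, so log-uniform is the natural desk-scale spectrum), 5% of
variants absent from both panels, 5% of variants on X, mean depth 85 with
Poisson per-call variation, GQ from a normal(70, 10) truncated to [0, 99],
and het AD drawn Binomial(DP, 0.5). Enrichment is injected by giving chosen
variants a per-sample carrier probability above their null (heterozygous
carriers for dominant injections, homozygous for recessive), while their
*annotated* MAF stays at the null value — which is exactly what an
overrepresented disease variant looks like. Three purpose-split random
streams (annotations / genotypes / quality) are derived from the master
seed, so switching quality decoration off, as the large simulation studies
do for speed, does not perturb the genotype draws; a given configuration is
byte-reproducible. `corrupt_for_qc()` plants low-GQ, low-depth, skewed-AB
and missing calls at known, mutually disjoint positions so QC removal
counts can be asserted exactly.

What the generator does *not* model: linkage disequilibrium between
variants, population structure or relatedness, read-level error processes,
batch effects, and annotation error. Passing tests therefore demonstrate the
pipeline's correctness under its own assumptions — independent carriers at
known frequencies — not robustness to the confounders of real cohorts.

## Numerical and design notes

* The binomial point mass is computed via `lchoose` + `log1p` in log space;
  it matches `dbinom` to better than 1e-10 relative error and sums to 1
  over outcomes to 1e-9. `p_ind = 0` with carriers observed returns 0 with a
  warning rather than an adjusted "significant" value.
* The test-suite simulation studies use 500 null cohorts and 200
  injected-variant cohorts of 93 samples × 1,000 variants; at those sizes
  the whole suite completes in well under a minute. Empirical family-wise
  error at adjusted 0.05 on null cohorts is ≈ 0.025 for both the point-mass
  and tail statistics.
* Degenerate inputs: a monomorphic variant has HWE p = 1; a variant with no
  informative calls passes depth/HWE vacuously and is removed by call rate;
  an empty scan returns a zero-row result with `n_tests = 0`.
* Coordinates are 1-based inclusive throughout (the annotation convention
  where an SNV has start = end); `chr` prefixes are stripped on ingestion.

## Limitations

Compound heterozygosity, X-linked recessive inheritance, polygenic models,
covariate or ancestry adjustment are out of scope. The per-variant statistic
inherits the biases of its population reference: panel allele frequencies
from a different ancestry composition than the cohort shift
$p_{\mathrm{ind}}$ and hence every probability. And because the design has
no controls, overrepresentation is evidence of enrichment relative to the
reference population, not of causality.
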