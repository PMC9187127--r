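---
title: "Testing sex differences in allele frequency on the X chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing sex differences in allele frequency on the X chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmafx)
```

## The problem

A sex difference in minor allele frequency (sdMAF) at an X-chromosome
variant is either a signal of genotyping artefacts (males are hemizygous
over most of the chromosome, so array intensities and sequencing depth are
halved relative to homozygous females) or a real consequence of
sex-linkage, particularly near the boundaries between the
non-pseudoautosomal region (NPR) and the pseudoautosomal regions PAR1 and
PAR2, and around the X-transposed region (PAR3/XTR). Downstream association
methods generally assume sdMAF is absent; screening for it is therefore a
quality-control and biology question at once.

`sdmafx` implements the full screening pipeline: region assignment,
sex-stratified genotype tallying with region-appropriate male ploidy,
HWD-adjusted Wald tests for sdMAF, chi-square and exact Hardy-Weinberg
tests, population-stratified and meta-analysis, sliding-window smoothing,
and a synthetic genotype generator used to validate every stage.

## Regions and male ploidy

Positions are 1-based inclusive, matching VCF `POS`. PAR1 and PAR2 default
to the Genome Reference Consortium spans (GRCh37: 60,001–2,699,520 and
154,931,044–155,260,560; GRCh38: 10,001–2,781,479 and
155,701,383–156,030,895). The PAR3/XTR span in Xq21.3 has no GRC-published
coordinates; the packaged default (GRCh37 88,400,001–92,310,000, GRCh38
89,145,001–93,055,000, both ~3.91 Mb) is an approximation chosen to match
the region's reported size and its centromeric boundary near 88.5 Mb
(GRCh37), and should be overridden via a BED file (`load_region_map(...,
override=)`) for replication work that depends on exact boundaries. Every
position outside the three PAR intervals is NPR. Males are treated as
hemizygous (one allele) in NPR and PAR3 and as diploid in PAR1 and PAR2.

## The sdMAF statistic

Let females have genotype counts $(f_0, f_1, f_2)$ for $0/1/2$ copies of
the designated allele $A$ (the minor allele in the sex- and
population-pooled sample), with $\hat p_f = (2f_2+f_1)/2f$ and HWD
coefficient $\hat\delta_f = f_2/f - \hat p_f^2$. With hemizygous males,
$\hat p_m = m_2/m$, and

$$T_X = \frac{(\hat p_f - \hat p_m)^2}
{\frac{1}{2f}\left(\hat p_f(1-\hat p_f)+\hat\delta_f\right)
 + \frac{1}{m}\,\hat p_m(1-\hat p_m)} \sim \chi^2_1 .$$

With diploid males (PAR1/PAR2) the male variance term mirrors the female
one, including $\hat\delta_m$, giving the statistic $T_A$. Both are Wald
tests; the score variant (sex-pooled variance estimates) is deliberately
out of scope, as the Wald form is the more conservative of the two.

Because the variance uses the *pooled* female HWD estimate, applying the
test to a mixture of populations with unequal allele frequencies inflates
$\hat\delta_f$ by the Wahlund effect. The bias factor is non-negative, so
the pooled test is conservative, never anticonservative — the package
verifies this by simulation in the acceptance suite (two HWE populations
at frequencies 0.1 and 0.5, rejection at or below nominal) and the
positive mean pooled delta is checked directly.

### Degenerate variants

If the genotype is fixed within each sex but differs between sexes, the
variance is zero while the numerator is not; the statistic is reported as
`Inf` with a `degenerate` flag. We do not substitute any finite plotting
constant in the data layer — that is a presentation choice, not a
statistical one.

## Hardy-Weinberg testing

Within a diploid stratum the 1-df chi-square test is implemented in two
algebraically identical forms (expected-count Pearson form and the
HWD-coefficient form $T = \hat\delta^2 n / (\hat p^2(1-\hat p)^2)$); their
numerical identity on random triples is a tested invariant. In NPR/PAR3
only females are tested (hemizygous males have no degree of freedom left
after estimating their allele frequency); in PAR1/PAR2 the test runs per
sex and sex-combined. Monomorphic strata report `NA` p-values.

The exact tests condition on the allele count. Within a stratum this is
the classical Levene-Haldane enumeration over heterozygote counts; for an
X-linked variant the joint test enumerates male A-carrier counts and
female heterozygote counts jointly, with males contributing single
alleles. The two-sided p-value is the sum of probabilities of all
configurations no more probable than the observed one, with the standard
relative tie slack of 1e-7; all combinatorics are evaluated in log space.
Note the joint test's null couples "no HWD" with "no sdMAF": a variant
with strong sdMAF but HWE females is emphatically rejected (the packaged
toy example yields p ≈ 6.4e-61), which is exactly why the per-sex tests
are the default in the pipeline.

## Log-space p-values

Scan statistics here routinely exceed 1,000, far past where survival
probabilities underflow doubles. All p-values are carried as
$-\log_{10}p$ computed from `pchisq(..., log.p = TRUE)`; report files
print values below 1e-300 as `"<1E-300"` while retaining the numeric
$-\log_{10}p$ in a separate column.

## Stratified analysis and meta-analysis

The minor allele is designated once, from the pooled sample, before
stratifying; stratified frequencies may then exceed 0.5, and the allele
designation can only change the sign of sdMAF, never the statistic (a
tested invariant). The meta-analysis combines per-stratum
$Z_i=\mathrm{sign}(\widehat{sdMAF}_i)\sqrt{T_i}$ with weights
$w_i=\sqrt{n_i}$ as $Z=\sum w_iZ_i/\sqrt{\sum w_i^2}$. Whether $n_i$
should count individuals or alleles is not settled; the default is the
allele count ($2f+m$ hemizygous, $2f+2m$ diploid) because that is the
information actually contributing to the comparison, and a custom vector
can be supplied. Strata with infinite statistics are *excluded* from the
weighted sum (flagged, with a warning) rather than propagated: a single
sex-fixed stratum would otherwise force the combined p-value to zero and
mask the remaining strata's evidence; the flag preserves the information
that the variant is degenerate somewhere.

## Minor-allele flips and Bland-Altman bounds

A flip means the within-female and within-male minor alleles differ
(frequencies straddle 0.5); exact 0.5 is reported as a tie, never a flip.
On a Bland-Altman plot of $y = \widehat{sdMAF}$ against the sex-combined
MAF $x$, flipped variants are confined to an analytic band. Writing $w$
for the fraction of pooled alleles contributed by females,
$p_f = x + (1-w)y$ and $p_m = x - wy$ for the allele with pooled
frequency $x \le 0.5$; requiring the frequencies to straddle 0.5 and stay
in $[0,1]$ gives (at $w = 1/2$) $1-2x < |y| \le 2x$. The bounds are
derived here from the frequency definitions alone and verified against a
dense grid over the frequency simplex in the tests.

## Sliding windows

Fixed windows of 50 consecutive SNPs advanced by 25, valued at the
arithmetic mean of member $-\log_{10}p$ and located at the leftmost SNP's
position. Trailing partial windows are dropped; infinite sentinels are
excluded from means and counted per window. Peak-calling thresholds are a
user decision, not hard-coded.

## The synthetic generator: what it emulates and what it does not

`sim_config()` describes independent biallelic variants: female genotypes
from the HWD-parameterized trinomial
$((1-p)^2+\delta,\; 2p(1-p)-2\delta,\; p^2+\delta)$, hemizygous males
Bernoulli($p_m$), diploid males the analogous trinomial. The default
panel mimics a 1000-Genomes-style cohort — five populations of 500 with
equal sex ratio, frequencies spread over 0.1–0.5, HWE, no sex difference
— i.e. a stratified null. Sex-differential missingness and a
hemizygote-miscall error (a hemizygous male called as a diploid
heterozygote, the signature artefact of low-coverage X data) can be
layered on. One seeded stream drives a run, with per-variant substreams
derived deterministically so variant order never changes draws; the VCF
writer expands the same drawn counts to individual genotypes (NPR/PAR3
males written haploid), so tallying a simulated VCF reproduces the drawn
counts exactly — a round-trip contract the tests enforce.

The generator deliberately has **no linkage disequilibrium, no coalescent
structure, no call-rate dependence on allele frequency, and no
reference-bias model**. A green simulation test therefore establishes the
correctness and calibration of the single-variant statistics under the
stated sampling model — not robustness to the correlated artefacts of
real sequencing pipelines.

## Numerical and design choices

* MAF retention is inclusive (`>= 0.05` by default).
* A pooled frequency of exactly 0.5 designates the ALT-side allele as
  minor with a `tie` flag; ties are reported, never silently broken.
* Multiallelic records are dropped, not decomposed; indels are dropped.
* Heterozygous male calls at hemizygous sites default to `set_missing`
  with a warning (phase-3-style data mixes haploid and diploid male
  encodings); a strict `error` policy is available. Diploid-homozygous
  male calls at hemizygous sites contribute a single allele.
* Exact-test sidedness is the standard "sum of probabilities ≤ observed"
  convention with 1e-7 relative tie slack; reference X-linked exact
  software agrees with the packaged toy value to all reported digits.
* Comparisons against published summary tables round frequency
  differences and HWD deltas to 3 decimals and p-values to 3 significant
  figures, matching their printed precision.

## Worked example

```{r example}
tab <- system.file("extdata", "gnomad_top8_counts.tsv", package = "sdmafx")
res <- run_pipeline(run_config(tab, mode = "count_table", build = "GRCh38",
                               out_dir = tempdir()))
res$results[, c("ID", "POPULATION", "REGION", "STAT_TYPE", "sdMAF", "P")]
```

## Known limitations

* No genotype-likelihood handling, phasing, or INFO-field allele-count
  fallback: sites-only summary data enters through the count-table path.
* No liftover; coordinates are taken at face value per build.
* No mid-p exact variants, continuity corrections, or Bayesian HWE.
* The meta-analysis offers sign-consistency flagging only, not formal
  heterogeneity statistics.
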