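---
title: "Mapping embryonic-lethal haplotypes by deficit of homozygotes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping embryonic-lethal haplotypes by deficit of homozygotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalscan)
```

## The problem and the population design

Dairy cattle breeds are effectively small populations: a handful of elite
artificial-insemination (AI) sires contribute a large share of each
generation's gene pool, inbreeding accumulates at roughly 1% per
generation, and recessive defects surface regularly. Defects that kill the
conceptus during gestation are the hardest to observe — there is no calf to
examine — yet they depress female fertility, a trait of major economic
concern. The screen implemented here turns the genomic-selection database
itself into the experiment: among tens of thousands of genotyped animals, a
haplotype carrying a recessive lethal will be carried by many heterozygotes
but (almost) never observed homozygous.

The family structure this package assumes is the AI design: every genotyped
animal has a genotyped **sire** and a genotyped **maternal grandsire**
(MGS), while the dam herself is usually not genotyped. The dam's genotype
is therefore inferred: she carries a given haplotype on her paternal
chromosome with the transmission probability of her sire (the MGS) and on
her maternal chromosome with the population frequency.

## The scan model

Phased genotypes are scanned in sliding windows of `window_size` markers
(default 20, about 1–1.5 Mb at 50k array density), sliding by
`slide_step` (default 1). A window haplotype is the **exact allele
string** over the window: identity is exact string match with no mismatch
tolerance, and recombination is ignored in the counting. Haplotype
frequencies are counted on the **maternal chromosomes of animals having at
least one progeny**; animals without progeny are excluded so that frequency
drift across generations does not bias the comparison between generations.
Only haplotypes with frequency strictly above `min_haplotype_freq`
(default 0.01) are tested.

For haplotype $k$ the expected number of homozygous progeny is accumulated
over mating groups (sire $i$ $\times$ MGS $j$, $n_{ij}$ progeny):

$$E(k) = \sum_{ij} n_{ij}\, p_{ik}\, \frac{q_{jk} + f_k}{2},$$

with $p_{ik}, q_{jk} \in \{0, \tfrac12, 1\}$ the transmission probabilities
implied by the sire's and MGS's diploid genotypes and $f_k$ the maternal
frequency. Only groups with $p_{ik} > 0$ enter the sum — restricting to
carrier sires makes $E(k)$ (and the matched observed count, taken over the
same progeny) robust to error in $\hat f_k$, since the dominant factor is
then the directly observed sire genotype. In the rarer situation where dams
are genotyped, the dam's own transmission probability $r_{jk}$ replaces the
inferred term, $E(k) = \sum_{ij} n_{ij} p_{ik} r_{jk}$, and the expectation
becomes invariant to $f_k$ (a property asserted by the test suite).

**Test statistic.** The observed count $O(k)$ is compared with $E(k)$ by
the one-cell chi-square $\chi^2 = (O-E)^2/E$ with 1 df and an upper-tail
p-value. Other chi-square flavours exist (two-cell goodness of fit, exact
binomial); the one-cell form was adopted because it reproduces, to the two
significant figures printed, the p-value column of the published reference
table of deficit regions in three dairy breeds — all 35 rows, spanning
p from $3.3\times10^{-3}$ to $2.5\times10^{-30}$ — which pins down the
statistic the field's published scans used. The statistic is symmetric, so
windows with an *excess* of homozygotes can reach small p-values too;
candidate reporting is one-sided (`deficit = O < E` required), because the
biological hypothesis is a deficit. The significance threshold
(`p_threshold`, default $10^{-4}$) is applied per haplotype test with **no
multiple-testing correction**, matching published practice; with roughly
$10^5$ windows per genome this is liberal, and users should treat reported
regions as candidates for confirmation (the fertility stage is that
confirmation).

**Region merging.** Within a chromosome, significant windows sharing the
chromosome-wide minimum $O$ are merged when consecutive, from the first
marker of the left-most window to the last marker of the right-most; each
run is reported with the E, O, frequency and p of its most significant
haplotype test. Separated runs yield separate regions, so two distinct
lethals on one chromosome are reported separately.

**Degenerate cases.** $E = 0$ makes the test undefined; such haplotypes are
skipped. Windows crossing a chromosome boundary are skipped, not errors.
Progeny whose sire or MGS is not genotyped are excluded with a reported
count. An empty cohort returns an empty result rather than an error.

## The fertility model

A fully penetrant lethal reduces conception in matings at risk (carrier
bull $\times$ daughter of a carrier sire): the bull transmits with
probability $\tfrac12$ and the dam carries the haplotype paternally with
probability $\tfrac12$ and maternally with probability $f$, so the
conceptus is homozygous with probability $(\tfrac12 + f)/4$ and the
conception rate drops by

$$\Delta = -\mu\,\frac{\tfrac12 + f_k}{4} \;\xrightarrow{f\to 0}\; -\frac{\mu}{8},$$

i.e. 5–7 percentage points at mean conception rates of 40–55%. Averaged
over *all* daughters of a carrier bull the loss is only
$-\tfrac12(\tfrac12+f_k)f_k\mu$ — an order of magnitude smaller for rare
haplotypes — which is why the analysis contrasts matings at risk rather
than daughter fertility. Heifers and lactating cows are analysed
separately: their mean conception rates differ (defaults
$\mu_h = 0.55$, $\mu_c = 0.45$), the lethal's absolute effect scales with
$\mu$, and the split yields two independent confirmations.

Two choices here were genuinely open. The **control group** defaults to
noncarrier bull $\times$ daughter of noncarrier sire (the cleanest null);
a flag allows "all non-at-risk matings" instead, which changes the control
rate only in the third decimal at realistic frequencies. The **test** is
Welch's unequal-variance t-test on the 0/1 outcomes; at the group sizes
involved (hundreds to hundreds of thousands) the choice between t-test
variants is immaterial. Losses are raw group differences, not
model-adjusted: the simulated data contain no herd or season effects, and
on real data the at-risk/control contrast within parity class already
removes the largest systematic terms. Haplotypes with zero at-risk matings
report n = 0 and loss 0 with no test.

## Marker quality control

Markers are dropped when their minor allele frequency, pooled over all
animals (breeds are pooled, matching the published filter wording; a
per-breed flag is not provided), is strictly below 3%, or when a 1-df
chi-square goodness-of-fit against Hardy–Weinberg proportions (expected
counts from the observed allele frequency, no continuity correction) gives
p strictly below $10^{-4}$. Both filters are per-marker predicates, so
their order does not matter — a property the tests assert. Monomorphic
markers have MAF 0 and are removed, not errored; fewer than two animals
makes the HWE test meaningless, so it is skipped with a warning.
Boundary conventions are strict on both filters ("lower than"), so a
marker at exactly 3% MAF or exactly $p = 10^{-4}$ is retained.

## The variant-filtering stage

Causative mutations need not lie inside the detected haplotype: the
mutation may have arisen on a frequent ancestral haplotype that is in
incomplete linkage disequilibrium with the detected one, placing it several
Mb away. The search region therefore extends the haplotype by a
`flank_mb` = 6 Mb flank on each side, clamped at the chromosome start
(intervals are half-open `[start, end)` in bp internally, printed in Mb to
one decimal). Within the region, a candidate variant must be heterozygous
in **every** sequenced carrier and homozygous reference in **every**
control — a live carrier cannot be homozygous for a lethal, so carrier
hom-alt sites are rejected by the same rule. Missing genotypes fail the
condition by default (strict mode); because moderate-coverage sequencing
leaves occasional missing calls, a `lenient` flag skips them instead. The
consequence filter keeps protein-truncating classes unconditionally and
missense only when flagged damaging by *both* external predictor columns;
deleteriousness is consumed as annotation, never computed, since the
predictors are external services. Unannotated candidates are retained as
"unknown" with a warning — silently dropping them would hide exactly the
variants most in need of manual review.

The association check mirrors how real candidates are confirmed or killed
on a key-ancestor panel: a variant exclusively associated with the detected
haplotype survives; association with several haplotypes plus a viable
homozygous-alternate animal eliminates it; and a haplotype homozygote that
is merely heterozygous for the variant reveals an ancestral version of the
haplotype without the mutation.

## What the simulator emulates — and what it does not

The generator (`simulate_population()`) is a founder-pool gene drop, not a
coalescent: the scan only needs haplotype identity-by-state over 20-marker
windows, and the "limited number of founders" structure of AI breeds is
exactly a small founder pool. Sires and MGS draw chromosomes from
`n_founder_haplotypes` founder strings (marker-wise allele frequencies
uniform on [0.1, 0.9]); dams are daughters of a random MGS and an anonymous
pool chromosome; progeny are gene-dropped with Poisson recombination at
`recombination_rate_per_bp` (default $10^{-8}$, about 1 Morgan / 100 Mb).

Each embedded lethal is one designated founder string over its window.
Carriers are **placed exactly**: `round(2fn)` distinct heterozygous
carriers per parental stratum, the carrier copies split evenly between the
paternal and maternal phase. This realizes the target frequency exactly on
the maternal chromosomes the scan counts, which is the appropriate model
for an *established* segregating haplotype whose frequency is a known
quantity (the alternative — binomial draws — adds between-replicate
frequency noise that real scans, whose frequencies rest on thousands of
chromosomes, do not exhibit at test scale); it also guarantees no live
homozygous founder, which complete lethality forbids. Homozygous progeny
die before genotype emission with probability `penetrance`; with
`fertility_effect` on, death occurs at conception and zeroes the mating's
outcome, while switching it off emulates defects where affected calves are
born (and hence conception is normal) but never enter the genotyped cohort,
as with syndactyly. Insemination outcomes are Bernoulli with success
probability $\mu_{\text{parity}}(1 - P(\text{homozygous})\cdot\text{penetrance})$,
where $P(\text{homozygous})$ comes from the parents' true diplotypes.

Features of real data deliberately **not** modelled: realistic linkage
disequilibrium decay (founder strings are exchangeable apart from the
lethal), selection across generations, genotyping and phasing error, herd
and season effects on conception, and multi-generation pedigrees (the drop
is two generations). Passing tests therefore demonstrate that the
statistics behave correctly under the design assumptions, not that the
pipeline is robust to phasing error or population stratification.

One consequence of test-scale genomes matters when interpreting test
configurations: compressing a chromosome to 100–150 markers makes a
20-marker window span 13–20% of the chromosome, so within-window crossover
rates are inflated roughly tenfold relative to real 50k density, eroding
intact haplotype strings across meioses. Counting-oriented tests therefore
set the recombination rate to zero (the expectation formula itself omits
recombination by design), while the demo analysis keeps recombination on so
that the deficit signal decays away from the lethal window and the merged
region localizes.

## Problem sizes and numerical conventions

The test suite exercises the scan at three scales, chosen to balance
statistical power against runtime: small populations (500–3,000 progeny)
for unit behaviour; a four-chromosome null genome yielding more than
$10^4$ haplotype tests for false-positive calibration (the one-cell
chi-square is an approximation, so the suite asserts the significant-deficit
fraction stays within ten times the nominal tail mass rather than equality);
and twenty replicates of a half-cohort-scale population — about 8,400
scanned progeny over 400 sires and 400 MGS, one lethal at $f = 0.05$ with
full penetrance — for parameter recovery, where the embedded window must be
reported with $O = 0$ and $p < 10^{-4}$ in at least 19 of 20 replicates and
the fertility stage must recover the analytic loss within two binomial
standard errors in both parity classes. The expectation formula is
validated against an independent Monte-Carlo transmission oracle
($10^6$ sampled conceptuses per pedigree, agreement within three standard
errors on twenty random pedigrees).

Formatting conventions are pinned to the field's reporting style: p-values
print in two-significant-figure scientific notation (`"2.6E-12"`), region
coordinates in Mb to one decimal, frequencies as percentages, significance
stars as \*p<0.05, \*\*p<0.01, \*\*\*p<0.001. All generator outputs are
reproducible bit-for-bit under a fixed seed; the pipeline's report bundle
is byte-identical across reruns of the same configuration.

## Known limitations

* The per-test $10^{-4}$ threshold with no multiplicity correction is a
  published convention, not a controlled error rate.
* Exact string matching cannot see a lethal allele on a recombined or
  genotype-error-bearing haplotype; real scans mitigate this with dense
  maps, and the incomplete-linkage-disequilibrium phenomenon (candidate
  mutations outside the detected interval) is handled only through the 6 Mb
  search flank.
* The fertility stage assumes the 0/1 conception outcome is exchangeable
  within parity class; confounding by herd, year or bull fertility is out
  of scope.
* The simulator's two-generation drop understates long-range haplotype
  breakup, so merged regions on simulated data are wider than on real
  multi-generation data.
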