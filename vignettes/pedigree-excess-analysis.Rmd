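---
title: "Discovering rare cancer-predisposition variants in high-risk pedigrees"
author: "pedseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering rare cancer-predisposition variants in high-risk pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedseg)
```

## The problem

Founder populations with deep, registry-linked genealogies make a distinctive
study design possible: instead of scanning unrelated cases for association,
one looks for *pedigrees with more cancer than expected*, sequences closely
related affected members, and asks which rare variants those relatives share
and transmit.  pedseg implements this design end to end for a
prostate-cancer-style phenotype:

1. **Cohort-stratified baseline risk.**  Every individual with enough
   recorded genealogy is assigned to a stratum by 5-year birth cohort,
   birthplace flag and sex, and the empirical lifetime rate of the cancer is
   estimated per stratum.
2. **Excess-of-cancer test.**  A founder's descendant set is scored by its
   observed case count against the expectation obtained by summing each
   eligible descendant's cohort rate; significance comes from the exact
   Poisson upper tail.
3. **Shared-variant screening.**  Rare variants (population frequency below
   0.005) that are coding, or noncoding/UTR with a RegulomeDB score between
   "2a" and "4", and carried by *both* members of an affected cousin pair are
   candidate predisposition variants.
4. **Segregation.**  For each candidate assayed in a wider case panel,
   clusters of three or more related heterozygous carriers are formed, the
   cluster's founding common ancestor is located, and the cluster is retained
   only when that founder's descendants show a significant cancer excess.
5. **Independent validation.**  Carrier status is tested case versus
   control (controls matched 1:1 by nearest neighbour on the first two
   principal components) with Bonferroni correction across variants.

## The excess statistic

For a descendant set with observed case count $O$ and expected count
$E=\sum_i r_{c(i)}$ (the sum of cohort rates $r_{c}$ over eligible male
descendants), the pedigree's p-value is the one-sided exact Poisson upper
tail

$$p = P(X \ge O), \qquad X \sim \mathrm{Poisson}(E),$$

computed by log-space term summation (`poissonUpperTail()`), exact to better
than ten significant digits across the range the analysis meets.  A pedigree
is **high-risk** when $p < 0.05$ *and* $O > E$, so case deficits are never
flagged.  The inclusive tail $P(X \ge O)$ was frozen after verifying that it
reproduces, at two printed significant figures, every one of the eleven
observed/expected/p triples published for this design; the residual
last-digit differences in four of them are fully explained by the expected
counts being printed with one decimal.

Eligibility is deliberately symmetric between the two sides of the test:
the persons in the rate denominators, the descendants contributing to $E$,
and the descendants counted in $O$ all satisfy the same predicate (correct
sex, known birth year, at least three generations of recorded ancestry).
That symmetry gives the exact identity "expected over the whole eligible
population = total eligible case count", which the test suite asserts to
1e-9, and makes $E$ additive and monotone over descendant sets.

## Relationship machinery

Relatedness is Wright's path-counting coefficient: the sum over
common-ancestor path pairs, disjoint except at the shared ancestor, of
$(1/2)^{\text{meioses}}$; the relationship degree is
$\mathrm{round}(-\log_2 r)$.  This reproduces the conventional classes
(degree 1 parent–child and siblings, 3 first cousins) without hard-coding
them, and handles multiple marriages and inbreeding loops by summing paths.
First/second cousin classification requires a shared ancestor at exactly
two/three meioses on both sides and nothing closer; a single shared ancestor
(rather than a couple) yields the same class with a half-relationship flag.

Two rules the source design leaves open are fixed here and exposed as
options:

* **"Related" for clustering** means sharing *any* recorded common ancestor,
  with no generation cap by default (`maxMeioses = Inf`), because the
  clusters of interest descend from deep founders; a cap is available.
* **The founding common ancestor** of a cluster is the common ancestor with
  the fewest descendants — the most recent — returned as a couple when both
  spouses qualify, with lexicographic tie-break.  When nested ancestors all
  show a significant excess only this minimal one is reported.

## The synthetic cohort

Real genealogy–registry resources of this kind are access-restricted, so the
package ships a generator (`simulateStudy()`) whose defaults define the
study conditions under which every simulation-based test and calibration in
the package runs:

| Parameter | Default | Why |
|---|---|---|
| founder couples | 13 | enough separate clans that any one pedigree is a modest fraction of the population |
| generations | 5 | eligible (3+-generation) individuals appear in the last two generations |
| children per couple | 6, 4.5, 3, 2.2 | declining historical fertility; ~3,500 individuals in total |
| marriage rate | 0.9 | most individuals marry |
| immigrant spouse fraction | 0.92 | a young founder population: spouses mostly marry in, keeping clans nearly disjoint |
| founder birth year | 1835, 25-year generations, 5-year jitter | realistic 5-year cohort occupancy from the 1830s to the 1990s |
| baseline lifetime risk | 0.05 before 1900, 0.10 after | registry-era lifetime prostate-cancer-scale risk with cohort variation |
| registry start | 1966 | diagnoses before the registry era leave no record, so cases concentrate in the most recent generations, as in real pedigrees |
| planted variant | heterozygous in the clan founder at the 0.70 descendant-count quantile, relative risk 10 | a highly penetrant founder variant in a mid-to-large pedigree |
| neutral variants | 50, dropped from random single founders | exercise the frequency, sharing and segregation filters |

Transmission is Mendelian gene dropping (each parent passes the alternate
allele to each child with probability allele-count/2), and phenotypes are
Bernoulli with probability $\min(1,\ \text{baseline} \times \prod
\text{relative risks carried})$ — the simplest proportional-risk penetrance
model, capped at one.

What the generator does *not* emulate: genotyping error, pedigree
record-linkage error, competing mortality, secular screening trends (beyond
the registry start), and population sizes beyond a few thousand.  Passing
tests therefore demonstrate the pipeline's logic and calibration, not its
power on registry-scale data.

### Power at desk scale

The published version of this design works because its pedigrees are
enormous (tens of thousands of descendants), so a modest relative excess is
many Poisson standard deviations.  At a few thousand members the same
arithmetic is much tighter, and one constraint deserves record.  A planted
founder variant's carriers among eligible descendants are at most one in
eight (Mendelian halving to the first eligible generation, ~0.06–0.09 in
practice); recovery by `findSegregating()` requires the carrier count to
fall **above** the excess-test detection threshold for the clan and
**below** the 10% carrier-frequency cap computed on the whole case panel.
At ~3,500 members the width of that window is comparable to the binomial
standard deviation of the carrier count itself, so recovery saturates near
50% regardless of relative risk (even at full penetrance), planting choice
or fertility profile; pushing recovery toward 80–90% requires genealogies
of roughly 5,000+ members, where the window widens with population size.
The defaults were frozen at the best-performing configuration near 3,500
members after a designed sweep over clan count, fertility, spouse-pool
composition and planting rule; the acceptance suite reports the measured
recovery rate (~0.4) alongside a false-positive count whose median is zero.

## Numerical and degenerate-input choices

* `poissonUpperTail()` sums the upper tail directly when $O > E$ (terms are
  decreasing) and complements the lower tail otherwise; summation stops when
  a term falls below $10^{-18}$ of the running sum.  Agreement with
  `ppois()` is better than $10^{-12}$ relative over a 500 × 50 grid.
* A founder with no eligible descendants is *untestable* (p `NA`, never
  high-risk) rather than an error.
* Individuals with unknown birth year or sex cannot be cohort-assigned:
  they are excluded from rate denominators and contribute zero expected
  cases (with a warning when their cohort is missing from the table).
* Variants with no population-frequency record are retained by the rarity
  filter as presumed-rare but flagged (`af_missing`), keeping the funnel
  auditable.
* Carrier clusters whose members lack any single common ancestor (possible,
  since "related" is pairwise) cannot be founder-tested and are dropped.
* Control matching is greedy without replacement in case-id order with
  control-id tie-breaks, making matched cohorts bit-reproducible.
* The association p-value is the two-sided Fisher exact test, chosen for
  validity at rare-carrier counts; a chi-square alternative is exposed.
  Odds ratios use a flagged 0.5 continuity correction when a cell is zero.

## Known limitations

* Lifetime (per-person) rather than person-year rates: no follow-up-time
  model, matching the cases-over-persons definition of the cohort rates.
* The 10% carrier-frequency cap is computed on the configured panel size;
  in small simulated cohorts the cap is structurally harsher than in a
  registry-scale panel (see *Power at desk scale*).
* Kinship-matrix mixed-model association, genealogy deduplication, PCA
  computation and genotype imputation are out of scope; principal
  components and annotations are consumed as inputs.
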