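---
title: "Mapping a recessive mutant locus by bulked-segregant sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive mutant locus by bulked-segregant sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
library(dplyr)
```

mutmapr implements the computational chain used to map a single recessive
mutant locus in a plant F2 population: segregation-ratio tests, a
MutMap-style delta(SNP-index) bulk-segregant genome scan with a
simulation-based null band, recessive-class fine mapping with codominant
markers, and candidate-gene interval intersection. A forward simulator of
an EMS-mutant x wild-type cross drives every stage, so the whole pipeline
is testable without sequencing data. This vignette is the package's
account of the underlying models, the tunable parameters, the numerical
choices, and what the simulation does and does not establish about real
data.

## The genetic model

The phenotype is assumed to be controlled by one fully penetrant nuclear
recessive allele. In an F2 between the mutant and a wild-type line,
genotypes at the causal locus segregate 1:2:1 and phenotypes 3:1
wild:mutant; F2:3 families from phenotypically wild F2 plants split 1:2
into non-segregating and segregating lines. These ratios are the first
testable predictions and the package tests them with a chi-square
goodness-of-fit statistic.

### Segregation tests

For two phenotypic classes (one degree of freedom) `yates_chisq()` applies
the continuity correction

$$\chi^2 = \sum_i \frac{(|O_i - E_i| - 0.5)^2}{E_i},$$

with one deliberate numerical choice: the corrected deviation is **not**
floored at zero. When the observation is closer than 0.5 to expectation
(e.g. counts (4, 9) against 1:2, where |O − E| = 1/3), the floored variant
returns exactly 0 (p = 1.00) while the unfloored variant returns a small
positive statistic (0.01, p = 0.92). Reference tabulations of this kind of
cross report the latter, so the unfloored form is the default and only
form. With more than two classes the ordinary uncorrected statistic is
used. Tail probabilities come from `stats::pchisq` and critical values
from `stats::qchisq`; two-decimal rounding is applied only when printing,
raw values are retained in the `seg_test` object.

## The delta(SNP-index) scan

Two bulks of F2 plants are pooled and sequenced: Pool A from
phenotypically wild plants, Pool B from mutant plants. At every SNP
distinguishing the mutant line from the reference, the **SNP-index** of a
pool is the fraction of its reads carrying the mutant allele, and

$$\Delta(\text{SNP-index}) = \text{index}_B - \text{index}_A.$$

Under the recessive model the expected values at the causal locus are 1
in Pool B (every mutant plant is homozygous) and 1/3 in Pool A (wild
plants are 1/3 homozygous wild, 2/3 heterozygous), so delta peaks at 2/3
and decays with recombination distance \(r\) as
\(\tfrac{2}{3}(1 - 2r)\); far from the locus both indices drift around
1/2 and delta around 0.

The scan proceeds in five steps:

1. **Filtering.** Keep SNPs with call quality >= 100 and read depth >= 10
   in *both* pools (both thresholds inclusive and exposed in
   `scan_config()`). A SNP with adequate depth in only one pool cannot
   yield a delta, hence the both-pool rule. A looser upstream
   variant-calling filter (depth 7, base quality 20) belongs to the
   caller, not to this analysis, and is not applied here.
2. **Per-SNP statistics.** Indices, delta, and a two-sided Fisher exact
   test of the 2x2 pool-by-allele count table. The two-sided p sums
   hypergeometric probabilities of all tables no more probable than the
   observed one (the minimum-likelihood convention, matching
   `stats::fisher.test`, which serves as an independent cross-check in
   the test suite).
3. **Null band.** Under "no locus anywhere", each pool's true mutant
   allele frequency is the mean of 40 fair coin flips (2 x 20
   chromosomes of an unselected bulk) and the read counts are binomial
   at the SNP's observed depth. `null_delta_ci()` simulates this
   (default 10,000 replicates; fewer than 1,000 is refused because
   empirical 2.5% quantiles become unstable) and returns the symmetric
   95% quantile band, memoised per distinct depth pair and fully seeded.
4. **Sliding windows.** Windows of 2 Mb advanced by 50 kb, anchored at
   bp 1 and spanning half-open `[start, start + window)` intervals of
   1-based positions (anchoring and openness are conventions the scan
   fixes explicitly; results are insensitive to them at these scales).
   Per window the arithmetic means of the indices, delta, Fisher p and
   the per-SNP band bounds are taken; the window band is the mean of the
   per-SNP bands, matching the per-depth definition of the null band (an
   alternative — the band recomputed at the window's mean depth — is
   available via `window_ci = "window-depth"`). Empty windows are
   reported with `n_snps = 0` and excluded from calling and plotting.
5. **Region calling.** A window is significant iff its mean delta
   exceeds its upper band bound *and* its mean Fisher p is below 0.05.
   Significant windows closer than one window size merge into a
   candidate region; regions are ranked by peak window delta with ties
   broken by genomic order. The merge radius equals the window size
   because the window mean is a 2-Mb-scale smoother: two significant
   stretches separated by less than the averaging scale are not resolved
   as distinct signals by this statistic.

## The cross simulator

`simulate_cross()` produces data with exactly the statistical structure
the scan assumes:

* **Founder SNPs** are a homogeneous Poisson process along each
  chromosome (default 5 SNPs/Mb, giving ~500 SNPs on the default
  2 x 50 Mb genome) with the causal locus always included. EMS induces
  almost exclusively G:C -> A:T transitions, so reference alleles are
  drawn from G/C with the corresponding transition; only biallelic SNPs
  are simulated, since EMS point mutations dominate real mutant lines.
* **Meiosis** follows the Haldane model: crossover counts per gamete and
  chromosome are Poisson with mean equal to the genetic length in
  Morgans under a uniform 2.5 cM/Mb map (a genome-average rate for a
  large legume genome), positions uniform in bp, no interference. Each
  F2 plant is two independent gametes of a uniformly heterozygous F1.
* **Phenotype** is mutant iff the plant is homozygous mutant at the
  causal locus; penetrance is a config scalar defaulting to 1 (real
  lesion-mimic phenotypes are environment-sensitive; that variability is
  deliberately outside the default model).
* **Bulks** are 20 + 20 plants drawn uniformly from the phenotypic
  classes; `phenotype_blind = TRUE` draws them without selection, which
  is the null configuration used to check false-positive behaviour.
* **Reads** are independent allele draws: depth ~ Poisson(30) per SNP
  per pool, and each read reports the mutant allele with probability
  \(q(1-\varepsilon) + (1-q)\varepsilon\), where \(q\) is the bulk's
  true allele frequency and \(\varepsilon\) = 0.003 the per-read error
  (a realistic post-filter short-read value). There is no mapping bias,
  GC bias, or contamination; each would be a config hook, all off by
  default. Call quality is a constant (228) because quality originates
  upstream of this pipeline; a constant makes the filter's behaviour
  testable.
* **Marker genotypes** are produced only for mutant-phenotype plants,
  mirroring recessive-class mapping practice, with codes A
  (wild-parent homozygote), H (heterozygote), B (mutant-parent
  homozygote) and an optional missing rate.

Determinism: every stochastic stage derives an independent seed stream
from the single config seed, so equal seeds give byte-identical outputs
across the whole pipeline.

## Fine mapping

Only phenotypically mutant plants are genotyped, so both of their
chromosomes carry the mutant allele at the causal locus and every marker
call exposes recombination directly: B contributes 0 recombinant
chromosomes, H one, A two; missing calls are dropped per marker (not per
plant). The recombination fraction estimate is
\(\hat r = \text{recombinants} / (2 n_\text{scored})\).

`delimit_interval()` places the locus inside the run of co-segregating
(zero-recombinant) markers and brackets it with the nearest flanking
marker on each side showing at least one recombinant. If no marker
co-segregates, the run of markers attaining the minimal recombinant
count plays the same role — the natural generalisation when marker
density outruns the population's recombination resolution. Recombinants
on only one side mean the locus is not bracketed, which is an error
rather than a guess. Marker positions are the forward-primer start
coordinates, and interval widths are start-to-start differences reported
in kb; with the packaged chromosome-04 soybean SSR panel this bracketing
reproduces a 76.23 kb interval. Two-point counting only: marker order is
taken from physical positions, and no multipoint likelihood ordering is
attempted.

## Candidate genes

`genes_in_interval()` uses any-overlap semantics against the closed
interval `[left, right]`: a gene overlapping an interval edge is a
candidate even if not contained — necessary because causal genes
routinely straddle the outermost marker. Coordinates are 1-based
inclusive internally; BED input/output converts to and from 0-based
half-open at the boundary (GFF3 via rtracklayer is 1-based already).

## Problem sizes used in the tests

The shipped test-and-verification suite runs the scan recovery sweep at
50 seeds of the default configuration (2 chromosomes x 50 Mb, 400 F2
plants, bulks 20 + 20, depth 30, ~500 SNPs), the null false-positive
check at 20 unselected genomes, the Fisher oracle comparison on all 2x2
tables with every cell <= 7 plus 500 random tables with totals up to 60,
and the type-I calibration of the corrected chi-square at 10,000
simulated 3:1 draws of n = 400. These sizes give Monte-Carlo standard
errors comfortably below the margins being tested while keeping the
suite quick on a laptop.

## Known limitations

* **Region-count fragility at desk-scale SNP density.** With ~10 SNPs
  per 2-Mb window, window means are noisy where the decaying delta
  crosses the null band. On a two-chromosome genome the causal
  chromosome is linked end to end (125 cM), expected delta at its
  telomeres is still 0.13–0.25 against a ~0.33 band, and joint
  fluctuations of the delta and mean-p criteria produce, on average,
  roughly half an extra "island" region per scan a few Mb from the main
  run. The planted locus falls inside the *top-ranked* region
  essentially always in our sweeps, but the scan returns exactly one
  region in only about two-thirds of seeds. Real crosses between
  divergent parents carry orders of magnitude more SNPs per window,
  which suppresses this noise; at EMS-only density, users should rank
  regions by peak delta rather than count them. Raising `merge_gap` or
  the CI level trades sensitivity for region-count stability.
* The simulator draws reads as independent Bernoulli alleles; real pools
  have mapping bias, indels, repeat regions and depth overdispersion.
  Passing tests show the statistics are implemented correctly, not that
  a particular real experiment will behave this way.
* Fully penetrant, environment-free phenotype by default; misclassified
  plants in the mutant bulk would depress the Pool B index below 1.
* Uniform recombination; real genomes have pericentromeric crossover
  deserts that widen physical intervals there.
* No multi-locus or duplicated-gene models, no structural variants, no
  lift-over between assembly versions.
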