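---
title: "Mapping a dominant wing-colour morph locus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant wing-colour morph locus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albamap)
```

## The problem

Alba is a dominant, female-limited wing-colour polymorphism of *Colias*
butterflies: females carrying at least one copy of the Alba allele `A`
are white, homozygous `aa` females are orange. Because the morph is
scored per individual but sequencing is cheapest in pools, the locus is
mapped by bulk segregant analysis (BSA): F1 females from informative
crosses are sorted by morph, pooled, and sequenced, and the genome is
scanned for sites whose pooled allele frequencies diverge between
morph pools exactly as Mendelian segregation of a dominant allele
predicts. albamap implements that inference chain — per-cross
allele-frequency filters, a contig-level intersection rule, a
case/control association scan with FDR control, read-depth genotyping
of a presence/absence insertion, and the morph-physiology statistics —
together with a forward cross simulator so that every stage can be
verified against known ground truth without any raw reads.

## Cross designs and their Mendelian expectations

Three cross designs are informative for a dominant allele:

* **Female informative** (`Aa` mother × `Aa` father). Alba F1 females
  are 1 `AA` : 2 `Aa`, so a marker fully linked to `A` sits at
  frequency 2/3 in the Alba pool and 0 in the orange pool: expected
  pool difference **2/3**. The filter accepts differences in
  [0.4, 0.8].
* **Male informative** (`Aa` father × `aa` mother, two independent
  crosses). Every Alba F1 female is `Aa`, so the linked-marker
  difference is exactly **1/2**; the filter band is [0.45, 0.55].

These two expectations are the backbone of the whole design: they are
what the simulator must reproduce (and does, see the acceptance tests)
and what the per-cross filter bands encode.

Beyond the depth windows and difference bands, each cross imposes the
segregation pattern its parents make possible: the female informative
cross requires the mother heterozygous (allele frequency within
[0.4, 0.6]), the orange pool fixed, and the changed allele present in
the mother; the male crosses require mother (where sequenced) and
orange pool homozygous. A contig is called associated only when it
carries at least 3 passing SNPs in *all three* crosses — requiring
independent support from three segregating families is what drives the
false-positive rate of unlinked contigs to essentially zero, since an
unlinked site must fall inside a narrow band in three independent
experiments simultaneously.

## What the simulator emulates — and what it does not

`simulate_cross()` draws offspring gamete by gamete: the transmitted
causal allele is Bernoulli(1/2) in each heterozygous parent, and each
marker copies the allele in phase with it with probability $1-r$.
Offspring are drawn until both morph quotas are filled, mirroring the
fixed pool sizes of morph-sorted sequencing. `simulate_pool_counts()`
then models pooled sequencing: Poisson depth per site, uniform
chromosome sampling within the pool, and a uniform substitution error
to the three other bases.

Defaults are the study conditions: pool sizes 21/21, 26/24 and 26/28;
pooled depths 50 (female cross, window 20–90) and 60 (male crosses,
windows 30–300 and 20–300); mother depths 40 and 15 (windows 15–60 and
5–30); error-free reads for the design-arithmetic checks. The default
marker landscape is 10 contigs × 40 sites with the causal contig fully
linked ($r = 0$) and all other contigs unlinked ($r = 0.5$): the real
recombination landscape of the crosses is unknown, and contig-complete
linkage is the resolution at which the ≥3-SNP intersection rule
operates, so the landscape is deliberately contig-grained. A site
segregates in a given cross with probability 0.3 — a typical
heterozygosity for crosses from an outbred wild population — and every
`Aa` parent carries the alternate allele in phase with `A`.

Deliberately **not** modelled: read-level artefacts (mapping bias, GC
bias, duplicates), depth overdispersion beyond Poisson, interference in
recombination, and Z/W sex-linked inheritance (the locus is autosomal;
offspring sex is a label). Passing tests therefore demonstrate that the
inference rules are correct under clean Mendelian segregation and
binomial read sampling — they do not certify robustness to alignment
artefacts in real pool-seq data, which is exactly what the published
depth windows and indel masking are there to absorb.

## Association on the re-sequencing panel

The panel simulator draws 15 Alba and 15 orange females from a
population where `A` segregates at frequency 0.2 (roughly the Alba
phenotype frequency seen in wild catches); Alba individuals are `AA` or
`Aa` with Hardy–Weinberg probabilities conditioned on phenotype, orange
are `aa`. Sites pass to testing only with ≤50% missing genotypes, mean
depth within [15, 50] and quality ≥30 (all bounds inclusive).

The per-site test is Fisher's exact test on the 2×2 allele-count table
(two alleles per non-missing individual), two-sided by summation of
table probabilities at most the observed one. The original analysis
used PLINK without stating the model; PLINK's basic allelic test is a
1-df chi-square, which with 30 individuals can misbehave at sparse
cells, so the exact test is the default and the chi-square is available
behind `method = "chisq"`. Benjamini–Hochberg step-up q-values are
computed with `stats::p.adjust`; sites with q < 0.05 are called.

One behaviour worth understanding: with ~40 perfectly tagging sites on
the causal contig, BH becomes adaptive and a handful of null sites with
modest p-values can slip under the threshold. The pipeline therefore
checks that significant sites *concentrate* on BSA-associated contigs
(≥90%) rather than demanding universal containment — the same pattern
as the original study's 70-of-72 SNPs at the locus.

## Insertion genotyping by depth ratio

The causal haplotype carries a transposable-element insertion absent
from the orange haplotype, so read depth inside the insertion scales
with insertion copy number: expected inside/flanking ratios 1, 0.5 and
0 for `AA`, `Aa`, `aa`. Classification thresholds 0.2 and 0.75 sit
between those expectations with margin for Poisson noise at the default
baseline depth 30 over a 3 kb window; individuals with flanking depth
below 5 are reported unclassifiable rather than guessed. The
spanning-read model captures the complementary check: a read pair
crossing the insertion junction maps as a proper pair only if its
apparent fragment length on the mapping haplotype stays within the
aligner's maximum insert (1000 bp), so fragments from the insertion-free
haplotype cannot span the junction on the insertion haplotype once the
insertion dwarfs that limit.

## Morph-physiology statistics

All group comparisons use the Welch two-sample t-test
(Welch–Satterthwaite df, 95% CI), computed through `stats::t.test` and
cross-checked in the tests against a closed form with the two-sided p
evaluated via the regularized incomplete beta function. Lipid classes
are quantified against a standard
($\mathrm{pmol} = A_\mathrm{sample}/A_\mathrm{standard} \times
\mathrm{pmol}_\mathrm{standard}$), totals are summed over the four
neutral lipid classes, regressed on abdomen mass, and standardized
residuals (residual / residual SD) serve as the mass-corrected trait.
Simple standardization is the default — published wording does not
distinguish it from internal studentization, so the latter is available
behind a flag. Granule counting averages the (typically three) 4 μm²
squares placed per individual.

`welch_groups_from_summary()` inverts a reported tuple (n, means, t,
df) into the unique compatible pair of group variances and emits
deterministic moment-matched samples; running `welch_t()` on them
reproduces the full tuple including p and CI. This gives a round-trip
check of published summary statistics. It also detects inconsistent
tuples: a df larger than $n_1+n_2-2$ is impossible for any variance
pair and is rejected — one published granule-count comparison
(t = 2.93 with df 5.97 at n = 3 vs 3) fails exactly this way and is
therefore reproduced only up to its t statistic under an
equal-variance assumption.

## Numerical conventions

* All band and depth-window memberships are closed intervals
  ("between x and y" read inclusively); 0.45 and 0.55 pass the male
  band.
* "Homozygous" means minor-allele frequency ≤ `hom_tol`, default 0
  (major allele at literally 100%); a small positive tolerance is
  available for error-prone high-depth data.
* "Minimum minor allele frequency of 3" is a minor-allele *count* ≥ 3,
  the standard pool-seq min-count semantics, evaluated on the combined
  morph pools.
* Bi-allelic state is assessed jointly across all sequenced columns of
  a cross (pools plus mother where present) after removing `N` and
  indel counts; indel neighbourhoods are masked with a default 5 bp
  radius.
* Ties for the major allele break deterministically in base order
  A < C < G < T.
* Sites with zero usable depth in either pool are skipped, never
  called.
* Every generator takes a single integer seed; sub-generators derive
  child seeds deterministically (`derive_seed()`), so a pipeline run is
  bit-reproducible and each stage can be re-run standalone.

## Problem sizes used in the checks

The package's own verification runs at desk scale, chosen to keep the
Monte-Carlo error well below the decision margins: 200 replicate
crosses per design for the band arithmetic (Monte-Carlo SE of the mean
difference ≈ 0.005), 100 pipeline seeds for unique-contig recovery
(observed rate 0.98 against the 0.9 requirement), 200 null panels for
FDR control (observed q < 0.05 rate ≈ 4 × 10⁻⁴), 500–600 simulated
individuals for depth-ratio classification (observed accuracy 1.00
against the 0.99 requirement), and exhaustive enumeration for every
2×2 table oracle with margins ≤ 30.

## Known limitations

The genome-scale numbers of the original study (a ~3.7 Mbp locus over
19 contigs, fine-mapped to a ~430 kb contig) depend on its deposited
read data and assembly and are not reproducible from simulation; the
package verifies the *rules* that produced them, at simulation scale.
The simulator's clean error model means filter robustness to systematic
artefacts is untested here; the LD model of the panel is a single
phase-copy weight per site ($w = 1 - 2r$), adequate for the perfect-
tagging and unlinked endpoints the design uses but not a population-
genetic LD decay; and the depth-ratio genotyper assumes the insertion
is the only copy-number difference between haplotypes in its window.
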