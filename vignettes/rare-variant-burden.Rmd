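---
title: "Rare-variant collapsing burden analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing burden analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The analysis

`rvburden` implements the classical case-control collapsing burden test for
rare variants, the framework popularised by tools such as TRAPD. The premise
is the common disease-rare variant hypothesis: individually rare alleles in
a gene (or pathway) may jointly shift disease risk even when no single
variant reaches significance. The procedure is:

1. **Qualifying variants.** Keep variant sites that are *rare* (population
   allele frequency below a cutoff, 5% by default) and of a tested
   consequence class — missense, or loss-of-function (frameshift, stop-gain,
   canonical splice donor/acceptor). Genotype calls must additionally pass
   per-genotype QC: site quality strictly over 20 and read depth strictly
   over 10 by default.
2. **Collapsing.** Per gene, each individual is reduced to one carrier
   category: HOM (any homozygous qualifying site), CH (two or more distinct
   heterozygous qualifying sites — a putative compound heterozygote), HET
   (exactly one), or non-carrier.
3. **Testing.** A 2x2 table of carriers vs non-carriers across cohorts is
   tested with the exact hypergeometric (Fisher) test, under a dominant
   model (HET + CH + HOM are carriers) and a recessive model (CH + HOM).
4. **Multiplicity.** Benjamini-Hochberg adjustment, applied separately per
   variant class and inheritance model, with the family size equal to the
   number of genes tested in that family.
5. **Gene sets.** The same carrier-collapsing test applied across all genes
   of a panel at once, which pools sparse per-gene signal at the pathway
   level.

## Design decisions

**Strictness of thresholds.** "Below 5%", "over 20" and "over 10" are all
implemented as strict inequalities; a variant at exactly AF = 0.05 is not
rare. A missing population frequency counts as rare: absence from a large
reference database is itself evidence of rarity. Both conventions are
configurable in `burden_config()`.

**Per-genotype QC.** Depth varies per sample, so QC is applied to genotype
calls, not sites: a failing call is treated as dosage 0 for collapsing
rather than discarding the whole site. Site quality is a site-level
quantity and enters every genotype of the site identically.

**Category precedence HOM > CH > HET.** Published carrier tables report each
individual in exactly one column. An individual with a homozygous site plus
additional heterozygous sites is counted once, as HOM. Compound-het calling
is phase-naive — any two heterozygous qualifying sites in a gene — because
unphased exome data cannot establish a trans configuration.

**Sidedness of the exact test.** The field's collapsing tools compute a
one-sided (enrichment-in-cases) exact p-value, and reference carrier tables
produced by such tools are only reproducible under that convention, even
where they are described as two-sided; `burden_config()` therefore defaults
to `alternative = "greater"`. The two-sided minimum-likelihood rule (sum of
all tables with the fixed margins whose point probability does not exceed
the observed one, with a relative tie tolerance of 1e-7) is implemented and
selectable, and is the convention checked exhaustively against enumeration
in the test suite.

**Gene inclusion.** A gene is tested only when *both* cohorts contain at
least three distinct qualifying variant sites in it, so that no association
rests on a single variant. "Qualifying variants" is read as distinct sites
(not allele counts); sites with no observed qualifying allele in a cohort do
not count for that cohort.

**Total allele count.** `total_ac` is the plain sum of qualifying allele
dosages over individuals. Published tables of this kind are not always
internally consistent with any single AC definition; carrier counts, which
drive every p-value here, are unaffected by that ambiguity.

**Gene-set statistic.** Carrier status is collapsed at the individual level
across the set (an individual counts once however many member genes they
carry in), then the same exact test is applied. The alternative — summing
allele counts — weights multi-carrier individuals more heavily and is not
the default. Panel results are reported nominally; BH across panels is
available behind the `adjust` flag.

## The synthetic cohort generator

`simulate_cohorts()` emulates the data structure the analysis assumes, not
real exomes. Per gene, control site allele frequencies are drawn uniformly
from a rare range (defaults: 5 sites per gene, AFs on (5e-4, 0.01)), and
genotype dosages are drawn independently per individual and site as
Binomial(2, AF) — Hardy-Weinberg proportions. Case frequencies are the
control frequencies times a per-gene enrichment factor (1 = null), acting
multiplicatively on AF rather than on carrier relative risk; in the rare
regime the two are nearly equivalent. Default cohort sizes are 247 cases vs
1622 controls, the design of the retrospective exome study this package
models; the default class mix (80% missense, 10% LoF, 10% other) reflects
the dominance of missense sites in such data. Each gene has its own seeded
substream, so extending a simulation with more genes does not perturb
existing ones, and a fixed seed reproduces the cohorts byte-identically
through VCF round trips.

What the generator does *not* emulate: linkage disequilibrium between sites,
realistic site-frequency spectra, population stratification, relatedness,
batch effects of capture kits, or genotyping error beyond a uniform
QC-failure rate. Passing calibration tests on this generator therefore
demonstrates correctness of the collapsing and testing machinery under the
model's own assumptions — not robustness to confounding in real cohorts,
which this framework (like any unadjusted exact test) does not address.

`make_table1_fixture()` is the deterministic counterpart: it constructs
cohorts whose collapsed counts equal prescribed HET/CH/HOM values exactly,
spreading carriers round-robin over three sites per gene so genes with at
least three carriers per cohort pass the inclusion rule. It is used to
regression-test the whole pipeline against published carrier-count
configurations end to end.

## Numerical choices

* Hypergeometric point probabilities are computed in log space
  (`lchoose`), so tables at cohort scale (N near 2000) neither overflow
  nor lose the tail.
* Two-sided ties are compared with relative tolerance 1e-7.
* Degenerate margins (no carriers anywhere, or an empty cohort side) give
  p = 1 — the only admissible table is the observed one.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`, with the
  family size `m` allowed to exceed the number of supplied p-values.
* Report TSVs round display p-values to 4 decimals and keep full precision
  in `*_full` columns; all ordering is deterministic (dominant p, then gene
  symbol).

## Validation problem sizes

The test suite validates the exact test against brute-force enumeration of
every 2x2 table up to total N = 60; collapsing against an exhaustive
classifier over all dosage vectors of up to three sites; type-I error on
200 null simulated cohorts at the 247/1622 design (50 genes, 5 missense
sites each, AFs uniform on (5e-4, 0.01)); and enrichment recovery on 100
replicates with five genes enriched five-fold. The acceptance script
re-runs the pipeline end to end on the fixture cohorts and reports the
recomputed p-values together with the simulation operating
characteristics.

## Known limitations

* No covariate adjustment, population-structure correction, or
  regression-based burden tests (SKAT and relatives are out of scope).
* No X-chromosome hemizygote handling; male X genotypes are treated like
  autosomal ones.
* Phase-naive CH calling overcounts true biallelic individuals when two
  variants sit in cis.
* Panels are consumed as plain symbol lists; no identifier harmonisation
  is attempted, so symbols must match the VCF annotation's vocabulary.
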