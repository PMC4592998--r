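---
title: "Polymorphism, divergence and the efficacy of selection in nonrecombining genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymorphism, divergence and the efficacy of selection in nonrecombining genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydiv)
```

## The scientific problem

A nonrecombining genome -- the animal mitochondrial genome is the canonical
case -- transmits as a single linked block. Its effective population size is
reduced by uniparental haploid inheritance and by selection on linked sites,
and a long-standing expectation is that purifying selection should therefore
be less effective at purging weakly deleterious amino-acid variants from
mtDNA than from the recombining nuclear genome. The classical instrument for
this question is the McDonald-Kreitman (MK) contrast: within-species
polymorphism and between-species fixed differences are each split into
nonsynonymous and synonymous counts, giving a 2x2 table per gene
(P_N, P_S, D_N, D_S). Under neutrality the two ratios agree; an excess of
nonsynonymous polymorphism (weak purifying selection keeping deleterious
variants segregating but not fixing) inflates P_N/P_S relative to D_N/D_S.

`polydiv` implements the complete analytical toolkit around that contrast
for haploid population samples with one or two outgroups:

* codon-aware MK counting with mutational-pathway averaging,
* the neutrality-index family of summary statistics,
* site-frequency-spectrum (SFS) diversity statistics with
  coalescent-simulation null distributions,
* linkage-disequilibrium and four-gamete recombination tests, and
* a fully seeded synthetic-data generator with exact truth records, so that
  every stage is testable without any external data.

## Codon counting

Variable codon columns are decomposed into single-base changes. For a codon
pair differing at k positions there are k! mutational pathways; each step is
classified synonymous or nonsynonymous by translating before and after.
Two counting modes are provided:

* **more-inclusive** -- codons with partial missing data are kept
  (classification over the non-missing sequences) and divergence steps are
  *averaged* over pathways, which is what produces fractional counts such as
  D_N = 55.833;
* **less-inclusive** -- codons with any missing data are dropped, designated
  high-missing sequences can be removed first, and the divergence pathway
  *minimising* D_N is used (ties broken toward maximal D_S, then by the
  lexicographically first position order, for reproducibility).

Polymorphism counting is identical under both modes, so on complete data the
modes differ only in divergence. Fractional counts in this package arise
from pathway averaging only; no site-frequency weighting is applied.

A polymorphic position only contributes a fixed difference when the outgroup
allele is absent from the ingroup; when the outgroup allele segregates in
the ingroup the position is a polymorphism only. With two outgroups,
divergence is restricted to positions where both outgroups agree and differ
from the fixed ingroup state (substitutions assigned to the ingroup branch);
discordant positions are excluded from divergence.

Decisions the counting rules leave open, resolved here once:

* *Pathways through stop codons* are excluded from averages; if every
  pathway is blocked, all pathways are used and a warning is raised.
* *Codon columns with three or more ingroup states* are counted per variable
  nucleotide position against the majority codon background, ties broken
  lexicographically. Such columns are rare at mitochondrial diversity
  levels, but the rule must be fixed for reproducibility.
* *Internal stop codons* in an annotated frame are tolerated with a warning,
  because real mitochondrial annotations contain incomplete stop codons.
* The hypervariable (A+T-rich) control region is expected to be excluded by
  the user's annotation; the package analyses exactly the annotated
  intervals and applies no coverage heuristics of its own.

Per-codon synonymous/nonsynonymous *site totals* (the fractional "bp" that
accompany per-gene diversity tables) count, at each codon position, the
fraction of non-stop single-base changes that are synonymous, so a codon
contributes 3 sites split between the classes.

## Neutrality-index statistics

For a single gene table the package computes

* **NI** = (D_S P_N)/(D_N P_S), with the zero-cell rule: if any cell is 0, a
  count of 1 is added to *all four* cells first;
* **Z\*** = log10(((D_N+1)(P_S+1))/((D_S+1)(P_N+1))), whose +1 is part of
  the definition (negative values mirror NI > 1);
* **Z** = log10((D_N P_S)/(D_S P_N)) on raw counts, undefined when a cell is
  zero, and equal to -log10(NI) whenever no pseudocount fires;
* a two-sided Fisher exact p-value (point-probability method), with
  fractional counts rounded half-away-from-zero for the exact test only.

The pseudocount scope matters and is deliberately asymmetric: per-gene NI
uses the all-cells +1 rule; gene-*set* statistics (summed counts, Z) use raw
sums with **no** pseudocount. This asymmetry is what makes the set-level
statistics internally consistent (e.g. a summed table with no zero cells
must not be perturbed).

Across genes the package avoids averaging per-gene ratios (which is biased
by low-divergence genes) and uses the combined estimator

$$NI_{TG} = \frac{\sum_i D_{Si} P_{Ni}/(P_{Si}+D_{Si})}
                 {\sum_i P_{Si} D_{Ni}/(P_{Si}+D_{Si})},$$

with a percentile bootstrap interval over genes (default 5000 resamples,
seeded). A resample whose denominator is zero leaves the estimator
undefined; by default *any* undefined resample voids the interval, which is
the behaviour required to reproduce an undefined interval for a two-gene
complex containing a zero-denominator gene, while leaving large gene sets
unaffected (the tolerated fraction is an exposed argument). Heterogeneity of
gene-level odds ratios is tested with Woolf's weighted chi-square on
Haldane-Anscombe (+0.5) corrected cells. Distribution-level comparisons
between genomes use Mann-Whitney rank-sum tests and the effect size
|mean difference| / RMS(SD).

## Diversity statistics and their nulls

Per gene and per site class the package reports S, pi (unbiased expected
heterozygosity, count units by default, per-site on request), Watterson's
theta_W = S/a_{n-1}, Tajima's D, Fu & Li's polarized D (plus the
outgroup-free D*), and Fay & Wu's H. Missing data are handled per column
(frequencies use the per-column non-missing sample size), while the
normalising constants of D use the full sample size, matching how per-gene
tables are conventionally computed at fixed n. Unfolded spectra omit a site
when the outgroup carries neither ingroup allele -- such sites cannot be
polarized -- and both SFS modes skip sites with more than two ingroup
alleles.

Significance comes from neutral Kingman coalescent simulation without
recombination, conditioned on the observed S (mutations are dropped on the
genealogy after it is drawn, Hudson-style). The p-value convention is
(r+1)/(m+1), so p is never zero; lower, upper and doubled two-sided tails
are available. The heterogeneity test for a difference in Tajima's D
between synonymous and nonsynonymous polymorphisms simulates, per
replicate, *one* genealogy, drops S_syn + S_nonsyn mutations on it and
labels them at random -- the reading of "simulated genealogies" that keeps
both classes on a shared tree, which is the appropriate null for a
nonrecombining molecule. An independent-genealogies variant is exposed as a
flag (`shared_genealogy = FALSE`); it produces a wider null and is provided
for sensitivity analysis only. Because placements are i.i.d. given the
tree, random labelling is implemented as sequential dropping, which is
distributionally identical.

The simulation kernel is written in C++ (via Rcpp) and works directly on
the derived-count spectrum -- no haplotype matrices are built -- so
calibration studies with hundreds of thousands of genealogies run in
seconds. It draws from R's RNG, so everything is reproducible under
`set.seed()`. A deliberately naive, independent R simulator (explicit node
lists, recursive descendant sets) serves as its cross-check in the test
suite.

## Recombination tests

Pairwise |D'| and r^2 are computed for biallelic sites passing a
minor-allele-frequency cutoff (a list of cutoffs is the intended usage),
on the sequences non-missing at both sites. The classic signature of
recombination is a negative correlation between LD and inter-site
distance; the package uses Spearman correlation (the LD measures are
bounded and far from normal) with a one-sided permutation p-value obtained
by permuting site *positions* and recomputing all pairwise distances, which
respects the non-independence of pairs sharing a site. Because site
positions are exchangeable under no recombination, this permutation test is
exact at its nominal level -- a property the test suite verifies by
simulation. The four-gamete test counts site pairs exhibiting all four
haplotypes; on a single genealogy under infinite sites this count is
provably zero, and that invariant is asserted across a thousand simulated
datasets. Distances are linear alignment distances by default; circular
(min-arc) distances are available by flag for circular genomes, off by
default so that results are directly comparable with linear-coordinate
analyses.

## What the synthetic generator emulates

`sim_config()` defaults describe the study conditions the package is
validated against: 38 haploid ingroup sequences, a single outgroup at
moderate divergence (Poisson-distributed substitutions on an unbroken
outgroup branch, expected 20 synonymous and 8 nonsynonymous), AT-rich codon
composition (ancestral G+C weight 0.3, as in insect mtDNA), per-gene
population mutation rates theta_syn = 5 and theta_nonsyn = 2 in count
units, and 300 codons -- a mid-sized mitochondrial gene. The partial-sweep
scenario builds a constrained genealogy: 95% of tips coalesce in a
star-like burst by time 0.05, and 2 deeply divergent lineages join near the
root -- the genealogical shape of a recent cytoplasmic sweep with remnant
ancestral haplotypes, which produces the characteristic joint excess of
rare alleles (negative Tajima's D, singleton-heavy Fu & Li's D) and
high-frequency derived alleles (negative Fay & Wu's H).

Mutations are planted class-first: a synonymous mutation is placed only at
a codon position where the change is synonymous on the current background,
stops are avoided, and an optional G/C-to-A/T bias constrains the base
change. Every mutation occupies its own codon (infinite sites across
codons), so the truth record is exact and pipeline counts must match it
*exactly* on noiseless data -- the strongest end-to-end test available.
Features of real data the generator does not emulate: recurrent mutation
within a codon, indels, alignment error, sequencing-error singletons, and
selection acting during the sweep (the sweep is genealogical, not a
forward simulation). Passing tests therefore demonstrate correctness of
the counting and inference machinery, not robustness to upstream
assembly artefacts.

## Validation scale and numerical conventions

The test suite validates: pathway averaging against a brute-force
enumeration oracle over all 64x64 codon pairs under genetic codes 1, 2
and 5; diversity statistics against a naive double-loop oracle to 10
significant digits; LD against a per-pair contingency oracle; p-value
uniformity by Kolmogorov-Smirnov over 500 null draws (1000 simulations
each); heterogeneity-test type-I error over 400 replicates; four-gamete
cleanliness over 1000 nonrecombining datasets; LD-distance test level over
1200 datasets; Watterson recovery within 5% over 500 generator replicates;
and bootstrap interval coverage over 500 replicates of 80-gene sets. These
sizes were chosen so Monte-Carlo error is several times smaller than each
tolerance while the whole suite completes in minutes.

Numerical conventions worth knowing: statistics on S = 0 genes are
undefined (NA), not zero; Fisher tests round fractional counts
half-away-from-zero while the ratio statistics never round; bootstrap
intervals are percentile intervals (simple, transformation-respecting, and
adequate at gene-set sizes); Monte-Carlo p-values use the +1 convention;
and all tie-breaks (majority codons, pathway choice) are lexicographic so
reruns are byte-identical.

## Limitations

NI-family statistics are upwardly biased for short genes with little
divergence (the motivation for NI_TG); per-gene values should be read
alongside the combined estimator. The less-inclusive mode discards a lot
of data at realistic missing-data rates -- with 38 sequences, even 0.5%
random per-base missingness removes most codons -- so it is best used with
the per-sequence drop list it was designed around. The coalescent null is
a constant-size equilibrium model; demographic alternatives belong to the
generator's scenarios, not the null. And the heterogeneity test, like the
statistics it compares, conditions on observed class totals, so it has no
power when either class has no segregating sites.
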