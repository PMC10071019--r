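---
title: "Methods: EM phasing, phenotype translation and cohort simulation in the CYP2C cluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EM phasing, phenotype translation and cohort simulation in the CYP2C cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp2cphase)
```

## The inference problem

Genotyping assays return unphased genotypes: at each SNP we observe an
unordered allele pair, not which alleles sit together on one chromosome. The
quantities of pharmacogenetic interest — CYP2C haplotypes such as TG,
star alleles such as *2, and their combinations — are properties of
*haplotypes*, so phase must be inferred. The panel here is small (at most
six biallelic SNPs in the CYP2C cluster: rs2860840 and rs11188059 in
*CYP2C18*; rs4244285 (*2), rs4986893 (*3), rs17884712 (*9) and rs12248560
(*17) in *CYP2C19*), which makes exact EM over all compatible phase
configurations cheap and removes any need for PHASE-style Bayesian samplers
or reference-panel imputation.

## The EM model

Let $f_h$ be the population frequency of haplotype $h$. Under random mating,
an individual's two haplotypes are independent draws from $f$, so an
unordered pair $\{a, b\}$ has probability $f_a^2$ if $a = b$ and $2 f_a f_b$
otherwise. A genotype $g$ with $k$ heterozygous sites is compatible with
$2^{k-1}$ unordered configurations ($1$ when $k = 0$), and its likelihood is
the sum of the pair probabilities over those configurations. The EM
iteration is the classic one for multilocus haplotype frequencies:

* **E step**: weight each configuration of individual $i$ by
  $f_a f_b (2 - [a = b])$, normalized within the individual;
* **M step**: set each $f_h$ to its expected share of the $2n$ chromosomes.

The log-likelihood is non-decreasing along this iteration (a property-style
test asserts it on every run, with $10^{-10}$ slack), and on small instances
the fixed point matches a direct simplex search of the likelihood within
$10^{-6}$ log-units (tested against a coarse-grid-plus-Nelder-Mead oracle
that never touches the EM code path).

Per-individual diplotype posteriors follow from the same model:
$P(\{a,b\} \mid g) \propto f_a f_b (2 - [a=b])$ over the compatible
configurations. An individual enters downstream diplotype and phenotype
tables only when its best configuration reaches a posterior of 0.95 — an
*inclusive* boundary, since the threshold is phrased as a minimal value for
inclusion. The haplotype sets observed in these cohorts make phase almost
always certain: only double heterozygotes at the two CYP2C sites are
ambiguous, and the alternative configuration requires the CA haplotype,
which is absent, so posteriors are overwhelmingly 1.

### Numerical choices

* **Initialization** is uniform over the haplotypes compatible with at least
  one sample, not over all $2^L$ strings; a seed-controlled random-restart
  option (`n_restarts`) guards against the rare local optimum, and the small
  acceptance instances use 5 restarts.
* **Convergence**: $|\Delta \log L| < 10^{-10}$ or 500 iterations,
  conservative for panels of this size.
* **Discreteness**: estimated frequencies below $10^{-6}$ are treated as
  numerical zeros; the "identified haplotypes" list uses a 0.01 report
  threshold, which is what turns a continuous frequency estimate into the
  discrete haplotype count a study reports.
* **Ties** in the posterior argmax are broken by lexicographic order on the
  haplotype strings and flagged `ambiguous`.
* **Frequency estimation uses all complete samples**; the 0.95 cutoff
  governs only which individuals enter diplotype/phenotype tables. The
  source method statement applies the threshold to inclusion of individuals
  in the analyses, not to the frequency estimation itself; both readings are
  possible, and this package keeps estimation on the full sample (the
  discrepancy between the two reported Kaingang TA-type frequencies, 0.471
  vs 0.481, is consistent with the subtler reading but cannot be resolved
  from the printed tables).
* **Missing data**: a sample missing a call at any panel locus is excluded
  from the analysis that needs that locus, and counted. With at most six
  SNPs, exclusion is cheaper and more transparent than marginalizing over
  the missing locus.

## Naming and the linkage constraint

Star alleles are defined by a *data* table (rsid, variant allele, star tag),
not code, because the nomenclature must be swappable: the default follows
the methods definition *9 = rs17884712 A, but the same source elsewhere
lists rs28399504 for *9 and mentions *4 — an internal inconsistency we do
not try to resolve. *1 is assigned by default when no defining variant is
present on a haplotype; a haplotype carrying two defining variants is a
flagged conflict, excluded from phenotype tables and counted, rather than
silently collapsed. The TG haplotype is never observed linked to the *2 or
*17 variants; a `*2TG`-type label is therefore rendered but flagged as a
linkage violation, and the simulator can generate such haplotypes only when
explicitly asked to (the flag's test path).

## Phenotype translation

Both schemes are expressed as activity classes plus one ladder (see
`?phenotype_scheme`) instead of a literal lookup of the eight published
diplotype rows. The ladder reproduces every published row exactly (a
table-driven regression test asserts all eight), while also giving
principled assignments to unobserved diplotypes such as *2CG/*2CG (PM) and
*17CG/*17CG (UM). The only genuinely undefined cell is decreased-with-
increased (*9 with *17): no published rule covers it in this allele set, the
ladder assigns NM, and the result carries an `extrapolated` flag. Percent
reporting rounds half away from zero (0.556 → 56%, 0.204 → 20%), which is
what the published whole-percent figures use; base R's round-half-even would
disagree at exact halves.

## Statistics

Hardy-Weinberg goodness-of-fit compares observed genotype counts with
$p^2 n, 2pqn, q^2 n$ at the counted allele frequency, $\chi^2$ with one
degree of freedom (three classes, one estimated parameter); `chisq.test`
does not provide this df, so the statistic is computed directly and the
p-value taken from `pchisq`. A monomorphic locus returns statistic 0 and
p = 1 by convention. Haplotype-frequency comparisons are plain 2×2 Pearson
chi-squares on *chromosome* counts (2n), phenotype comparisons r×2
chi-squares on *individual* counts, both via `chisq.test(correct = FALSE)`:
no Yates correction anywhere, matching the plain chi-square tests reported,
and no multiple-testing adjustment, with $\alpha = 0.05$. Comparing the two
assignment procedures on the same cohort treats them as independent samples
(a plain contingency test) even though the individuals are paired; this
mirrors the reported analysis rather than a marginal-homogeneity test, a
deliberate fidelity-over-orthodoxy choice. When a haplotype is absent from
both cohorts the 2×2 test is undefined and returned as a flagged result,
not an exception. External-population comparisons reconstruct counts as
round(frequency × 2n), since only frequencies are printed.

## What the simulator emulates — and what it does not

`generate_cohort()` draws, for each individual, two haplotypes
independently from the configured frequency table (random mating, hence
Hardy-Weinberg proportions at the haplotype level), expands labels to full
allele strings so star-site/CYP2C-site linkage holds by construction,
collapses pairs to unphased genotypes, and optionally injects per-call
missingness. It is seeded and byte-reproducible. The presets transcribe the
reported frequency columns of the four study cohorts at their reported sizes
(68/61/54/33); columns that do not sum to 1 as printed (the 1KG_NAT and
Kaingang 2-SNP columns at 1.001/0.999, the Kaingang combined column at
0.999, and the Guarani combined column at 0.839) are shipped verbatim plus
an explicitly renormalized `_norm` variant — printed data are never silently
altered, and simulation refuses a non-normalized table.

The simulator deliberately omits: mutation, recombination (the CYP2C SNPs
are treated as one non-recombining block, consistent with the strong
observed linkage), admixture and ancestry structure, genotyping error, and
inbreeding (no F parameter). Consequently, passing tests demonstrate that
the *inference chain* is correct under the stated population model; they do
not validate the model against real Native American genotypes, where
substructure, relatedness or assay artifacts could perturb both HWE and
phasing confidence.

## Problem sizes

The test suite and acceptance script use the study's own cohort sizes
(n = 33–68) with 200 seeded replicates for the Monte-Carlo recovery checks,
2000 replicates of n = 100 for the HWE type-I calibration, n = 500 for the
consistency check, and n ≤ 8 instances for the likelihood-oracle
equivalence; the full suite runs in about a minute on one CPU.

## Known limitations

* Only biallelic SNVs, one genome build (GRCh38), no liftover, no
  genotype-quality filtering.
* The star nomenclature is the five-allele subset used here, not the full
  PharmVar table; sub-alleles (e.g. *1.002 via c.991A>G) are out of scope.
* Frequencies for external comparison populations enter only as
  user-supplied tables; no retrieval from public archives is performed.
* The EM reports a point estimate; no standard errors or Bayesian
  uncertainty on haplotype frequencies beyond the per-individual posteriors.
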