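---
title: "Methods: rare-variant screening, association and LD in candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant screening, association and LD in candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarescreen)
library(dplyr)
```

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` do not
themselves compute.

## The analysis problem

A small cohort is whole-genome sequenced; variants falling in the
functional space of one or a few candidate genes are prioritised against a
public reference panel; the survivors are genotyped in a large case–control
sample and tested for allelic association, carrier burden and haplotype
structure. Each stage is statistically elementary — the value of the
package is doing all of them correctly, reproducibly and testably on
standard file formats, with the rare-variant edge cases (zero cells,
monomorphic loci, phase ambiguity, discrete exact tests) handled
deliberately.

## Coordinates and gene models

All internal coordinates are **1-based, fully closed**, the native
convention of VCF, GFF3 and the R/Bioconductor interval stack; BED input
and output (0-based, half-open) is converted at the boundary. A transcript
model is an ordered exon table with strand and an optional CDS span;
isoforms are rows of a tibble.

Region windows are defined in transcription direction:

* **Promoter**: the `window` bases (default **1,000 bp**) immediately
  upstream of the transcription start — the 5′ end of the first exon, not
  the first coding base. The choice matters for genes with long 5′ UTRs;
  the transcription start is the standard promoter anchor and is what a
  transcript-level definition implies. `window` is configurable for users
  who prefer a CDS-anchored or wider promoter.
* **Splice donor**: last 5 exonic + first 6 intronic bases (11 bp);
  **acceptor**: last 20 intronic + first 3 exonic bases (23 bp). These
  widths cover the canonical donor/acceptor consensus including the branch
  proximal polypyrimidine tract side. No windows are emitted at transcript
  termini.
* **UTRs**: exonic sequence outside the CDS, 5′ or 3′ by strand.
* **Coding consequence**: the affected codon is translated before and
  after substitution with the standard genetic code (alternate allele
  complemented on minus-strand transcripts). In-CDS indels are marked
  unsupported rather than guessed at.

Labels are computed per isoform and **unioned** across isoforms, since a
variant regulatory in one isoform context and transcribed in another is
interesting in both. Membership tests use the variant's affected reference
span `[pos, pos + nchar(ref) - 1]`; insertions use the VCF anchor base, so
an insertion recorded as `-/T` at a junction is attributed to the base to
its left.

## The frequency screen

The screen's 2×2 allele table (cohort alt/ref vs panel alt/ref) is tested
with Fisher's exact test, **one-sided toward cohort enrichment** by
default: the screening rule itself demands case-direction excess, so the
lower tail carries no information for it. Two-sided is a flag. The
significance threshold is `alpha = 0.05` with **strict** inequality. The
default panel size is 372 diploid samples (744 alleles), the size of the
European reference panel the screen is calibrated against; it is
configurable because public panels vary by release.

Exclusion rules: a variant whose anchor base sits in a reference
homopolymer run of `min_run` bases (default **5**, a conventional cutoff —
no published value exists for this rule) is excluded as a likely
sequencing artefact; an **insertion** overlapping a repeat interval is
excluded (SNVs in repeats are not — the rule exists because short
insertions in repeats are enriched for alignment artefacts). Target-intron
variants pass a conjunction: inside the target interval, overlapping a
regulatory (ENCODE-marked) element, conserved (interval track **or** GERP
score ≥ threshold, default **2.0**), and not in a repeat.

A variant missing from the panel is treated as unseen there (0 alternate
alleles out of `2 × panel_size`) and reported, rather than dropped: absence
from a public panel is exactly what makes a rare variant interesting.

## Association statistics

**MAF** is `(2·hom_alt + het) / 2n` with `n` the *sum of the genotype
counts*, folded to the minor allele with a flag. The genotype-sum
denominator, not a separately printed sample-size column, is the only
definition under which published tables of this design reproduce their own
MAF columns.

**Exact HWE** uses the conditional (Levene) distribution of the
heterozygote count given `n` and the minor-allele count, computed in log
space; the p-value sums all configurations whose point probability does
not exceed the observed one (a `1 + 1e-9` factor guards ties against
floating-point loss). No mid-p, no continuity correction: zero cells are
handled natively by the exact formulation.

**Allelic association** is Fisher's exact test on the 2×2 allele table,
**one-sided toward case enrichment** by default. This is a deliberate
reproduction decision: recomputing from the published genotype counts of
the study design this workflow targets, the printed headline p-value
(0.015) is obtained only under the one-sided tail (the two-sided value is
0.028). Two-sided is available by flag. One published value (0.042)
recomputes to ≈ 0.040 by exact enumeration under every sidedness and
denominator choice the package exposes; the discrepancy is documented
(the source may have used a slightly different test variant) rather than
absorbed, and the acceptance check admits the printed value.

One published MAF cell is internally inconsistent with its own genotype
counts (a control stratum with 1 heterozygote among 1,026 samples printed
as 0.0010, twice the allele-scale value, while the identical count shape
elsewhere prints 0.0005); the package asserts the recomputed value for
that cell.

`expected_homozygotes()` returns `n·q²` with `q` the *alternate*-allele
frequency — the expectation quoted when judging an excess of rare-allele
homozygotes (3 observed vs 1.5 expected in the motivating case, an excess
the exact HWE test finds unremarkable at p = 0.18).

## Carrier burden

A sample is a **carrier** if it has ≥ 1 alternate allele at ≥ 1 called
locus of the gene; a **non-carrier** must be homozygous reference at every
called locus. Samples with no call at any locus are excluded. Partial
missingness therefore can never create a carrier, and a hom-ref call at
the remaining loci is accepted as non-carrier evidence — the alternative
(excluding any sample with any missing call) discards most of a realistic
genotyping experiment. The rule is declared here because published
descriptions of this design do not state one.

The test is the plain Pearson χ² on the 2×2 carrier table, 1 df, **no
continuity correction** by default (Yates by flag); zero margins error out
with advice to use an exact test rather than silently degenerating.

## Two-locus EM, LD statistics, blocks

With unphased genotypes only the double-heterozygote cell is
phase-ambiguous. The EM iteration splits it between coupling (AB/ab) and
repulsion (Ab/aB) in proportion to their current expected frequency;
everything else is direct counting. Numerical choices:

* **Initialisation at linkage equilibrium**, deterministically — the
  two-locus likelihood is well behaved, and degenerate flat cases (e.g. a
  lone double heterozygote) then resolve to the LE point instead of an
  arbitrary phase.
* **Convergence** when the observed-data log-likelihood changes by less
  than `tol = 1e-10`, capped at 1,000 iterations (both configurable); the
  monotonicity of the trace is asserted in the tests.
* Estimated haplotype frequencies conserve the table's allele frequencies
  exactly (a property of the M-step, asserted as an invariant).

`D = p_AB − p_A p_B`; `D′ = |D| / D_max` with
`D_max = min(p_A p_b, p_a p_B)` for positive `D` and
`min(p_A p_B, p_a p_b)` otherwise; `r² = D² / (p_A p_a p_B p_b)`. At a
monomorphic locus `D = 0` and the normalised measures are `NA`, not 0 —
"no disequilibrium" and "disequilibrium undefined" are different answers.
The LOD is the base-10 likelihood ratio of the fitted frequencies against
linkage equilibrium at the same allele frequencies, floored at 0.

Missing genotypes drop the sample for that marker pair only, so a sparse
genotyping experiment keeps its information pair by pair.

**Solid-spine blocks**: a block `[i, j]` requires `D′ ≥` threshold
(default **1**) between the first marker and every later block member and
between the last marker and every earlier one. Pairs with undefined `D′`
**break** the spine — an undefined pair is not evidence of strong LD.
Blocks are selected longest-first, leftmost among equals, non-overlapping;
the implementation is checked against an exhaustive interval search.

Reproducing any published pairwise `D′`/`r²`/LOD table numerically is out
of scope — that requires the study's individual-level genotypes. What the
package reproduces, and tests, is the machinery and the qualitative
signature of a rare allele riding one common background: `D′ = 1` with
`r² ≈ 0`.

## The synthetic-data module

Generators are pure functions of (parameters, seed); the global seed
expands into per-component substreams so adding a generator never perturbs
another's output. Defaults mirror the study design the workflow targets:
1,510 cases, 1,095 controls, a 372-diploid reference panel, rare variants
(control MAF ≤ 0.05). Case allele frequencies derive from an allelic odds
ratio, `q_case = OR·q / (1 − q + OR·q)`, matching the 2×2 allelic test.
Genotypes are drawn under HWE *within* each stratum; the reference panel
is binomial at the panel frequency; two-locus genotypes are formed from
2n i.i.d. haplotypes.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: genotyping error and plate effects,
population stratification within strata, linkage between the simulated
variants (they are independent except in the explicit two-locus module),
sequencing depth and call uncertainty, and ascertainment of cases. The
planted-truth genome (`synth_genome_context()`) is a geometric miniature:
its gene models and tracks exercise every classification and filter branch
(both strands, multi-isoform promoters/UTRs, donor/acceptor windows, a
target interval with regulatory/conserved/repeat geometry, homopolymer
flanks), not genomic realism.

A deterministic fixture carries the published genotype counts of the
twelve genotyped variants, expandable to individual-level records and back
— the association, burden and pipeline stages are tested against it.

## Calibration checks and problem sizes

The test suite runs its stochastic checks at sizes chosen to finish in
minutes on one CPU while keeping Monte-Carlo error meaningful: null
calibration uses 500 replicate variants at full cohort size
(1,510 / 1,095) and a common control MAF of 0.2 (allele counts large
enough that the discrete exact-test p-value distribution is
near-continuous); EM recovery uses n = 2,000 samples over 20 seeds against
truth (0.5, 0.2, 0.2, 0.1), with a 0.02 bound on the maximum absolute
error; oracle-equivalence sweeps cover all 2×2 tables with row totals
≤ 10–12 exhaustively plus seeded samples up to margin 30, and all HWE
configurations with n ≤ 10.

Exact tests are **conservative**: their p-values are discrete and
stochastically larger than uniform, so a two-sided uniformity test will
correctly reject their null distribution given enough replicates. The
calibration check therefore (a) bounds the empirical rejection rate at
α = 0.05 from above and (b) applies a *one-sided* Kolmogorov–Smirnov test
that rejects only anti-conservative deviations (empirical CDF above the
uniform). That is the property a valid test must have; demanding exact
uniformity from an exact test would be testing the wrong thing.

## Known limitations

* Single-nucleotide substitutions only for coding consequence; in-CDS
  indels are flagged unsupported.
* The screen treats variants independently; no LD-aware prioritisation.
* The burden test is the plain carrier χ² — no weighting by frequency or
  predicted function, no dispersion-style alternatives.
* Two-locus LD only; no multi-locus haplotype phasing.
* The pipeline assumes biallelic records; multiallelic VCF rows are split
  at input and analysed per alternate allele.
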