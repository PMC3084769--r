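---
title: "Methods: locus assignment and molecular diversity of HERV-W env amplicon clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus assignment and molecular diversity of HERV-W env amplicon clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervclone)
```

## The problem

The human genome carries HERV-W envelope (*env*) sequences at many
chromosomal loci. Only the ERVWE1 provirus at 7q21.2 encodes the
complete Syncytin-1 open reading frame; the paralogs at other loci
(chromosome 14, 15, X and others) are more than 90% identical to it
but defective. RT-PCR of *env* transcripts from tissue therefore
amplifies a mixture of near-identical paralogs, and every cloned
amplicon must be traced to its chromosomal encoding locus before
transcript diversity or abundance can be interpreted. `hervclone`
implements that tracing and the analyses built on it, plus a
synthetic-data module that generates panels, clone libraries and
tag-count matrices with recorded truth so every stage can be validated
without any external data.

## In-silico nested PCR and trimming

`in_silico_pcr()` anneals the published outer and inner SU-TM primer
pairs on the plus strand of a template (the antisense primer as its
reverse complement, downstream). A primer site may carry at most
`max_mismatches` (default 2) substitutions, and its 3'-terminal
`three_prime_exact` bases (default 3) must match exactly, mimicking the
3'-end sensitivity of polymerase extension while keeping the search
deterministic. Products longer than 2000 bp are discarded as
implausible; the target amplicon is ~650 bp. Absence of a site yields
an empty product table — the "none detected" (ND) outcome — rather
than an error. Coordinates are 1-based and inclusive throughout, the
R/Bioconductor convention; this keeps slicing and reporting in one
system.

`trim_to_region()` aligns each clone to the prototype amplicon
(semi-global, free end gaps) and keeps the clone bases that fall within
the insert, removing both primer footprints (including the BamHI/XhoI
linker bases, which are part of the printed primers) and vector tails.
A clone covering less than 50% of the amplicon fails with a diagnostic
and is flagged rather than sinking its sample. Trimming is idempotent.

## The locus match rule

`assign_locus()` aligns a trimmed clone against every panel locus using
`Biostrings::pairwiseAlignment` (overlap type, match +1, mismatch −1,
gap open 5, gap extend 2 — an approximation of megablast-like scoring).
Identity is matches over aligned columns, counting internal gap columns
as mismatches and excluding end gaps: the closest deterministic
analogue of a BLAST "Max identity". The match rule is read literally:
a call requires identity strictly greater than 0.97 over at least 580
aligned bp. Hits are ranked by identity, then alignment score, then
lexicographic locus id, so panel order can never change a call. Two
passing hits within `tie_margin` (default 0.002) give the distinct
`AMBIGUOUS` class, because near-ties between paralogs are not honestly
resolvable at this identity resolution. The search space is a curated
panel FASTA rather than a whole-genome database: the package is
self-contained and desk-scale, while the decision rule itself is
preserved exactly. Raising `min_identity` can only shrink the called
set (monotonicity, enforced by test).

## Diversity statistics

For each sample of aligned clones, `count_variant_sites()` counts
alignment columns with more than one base among clones; columns
containing a gap or ambiguity in any clone are excluded from both the
variant count S and the compared length L. The normalised number of
variant sites is `theta_watterson()`:

$$\hat\theta = \frac{S}{L \cdot a_n}, \qquad a_n = \sum_{i=1}^{n-1} \frac 1 i .$$

"Correcting for the sample size" is implemented as this harmonic
normalisation — the standard Watterson form in the molecular-evolution
framework the method descends from; plain division by n is exposed as
`correction = "n"` for comparison. Percent diversity relative to the
prototype is the mean over clones of 100 × mismatches / compared
columns against the ERVWE1 insert; because the per-patient figure
could equally be read as pooled over sites, `diversity_summary()`
reports both (`pct_div_vs_prototype`, `pct_div_pooled`).

## Ka/Ks by LWL85

`kaks_lwl()` implements the Li–Wu–Luo (1985) counting estimator. Each
codon position is classified by its degeneracy (0 synonymous
alternatives → nondegenerate; 1 or 2 → twofold, the usual convention
for three-codon families; 3 → fourfold), and the class totals L0, L2,
L4 are averaged over the two sequences. Differences are resolved by
enumerating all minimal mutational pathways between the two codons of
a pair; pathways passing through a stop codon are excluded whenever a
stop-free pathway exists. Each step contributes half to the class of
the changed position in the "from" codon and half in the "to" codon,
averaged over pathways. Per class, transitions and transversions give
K2P components

$$A_i = \tfrac12\ln\frac{1}{1-2P_i-Q_i} - \tfrac14\ln\frac{1}{1-2Q_i},
\qquad B_i = \tfrac12\ln\frac{1}{1-2Q_i},$$

and

$$K_s = \frac{L_2 A_2 + L_4 (A_4+B_4)}{L_2/3 + L_4}, \qquad
  K_a = \frac{L_2 B_2 + L_0 (A_0+B_0)}{2L_2/3 + L_0}.$$

Counting noise can push a class's A component slightly negative
(transversions without transitions), so the final Ka and Ks are floored
at zero. Saturated classes (log argument ≤ 0) flag the result rather
than silently dropping it, and Ks = 0 yields a flagged NaN ratio. The
"modified" weighting used by some Ka/Ks software is exposed as
`weighting = "mlwl"`: the 1/3 : 2/3 split of twofold sites is replaced
by κ/(κ+2) : 2/(κ+2) with κ estimated from the fourfold class. The
software variant's exact formulas are not published alongside the
analyses this package follows, so this kappa-aware reading is this
package's own, and LWL85 remains the default. Any stop codon in the
input is rejected (trim terminal stops first): pathway bookkeeping
through stops is not meaningful for these colinear amplicons.

## Distances and trees

`k2p_distance()` is the closed-form Kimura two-parameter distance over
pairwise-complete ACGT columns, with saturation an explicit error.
Neighbor joining is delegated to `ape::nj` (Saitou–Nei with the
Studier–Keppler criterion); on additive matrices it reproduces the
generating tree exactly, which the tests verify against a tree-metric
oracle on 500 random cases. When an outgroup (e.g. an MSRV prototype
*env* sequence) is given, the root is placed at the midpoint of the
outgroup's pendant edge; because no rooted position on that edge is
identifiable from distances alone, the midpoint is the symmetric
choice. Negative NJ branch lengths are retained and flagged, not
clamped, so additivity checks stay exact. The exact outgroup sequence
used for rooting is a user input; the simulator provides a diverged
"MSRV" copy (15% per-site) for self-contained runs.

## Tag counting and normalisation

`count_tags()` matches each fixed-length read ungapped, over its full
length, against both strands of every reference feature, tolerating at
most `max_mismatch` substitutions (default 1 for 36 bp tags — the
mapping tolerance is otherwise unstated, so it is configurable). A
read is credited to the unique feature achieving its minimal mismatch
count; ties across features go to an `ambiguous` bucket — conservative
and reproducible, rather than fractional or arbitrary assignment — and
everything else is `unmatched`, with
counted + ambiguous + unmatched = total enforced per sample. The
implementation uses Biostrings `PDict` dictionaries; tests require
exact equality with a naive all-pairs Hamming scan. `filter_min_tags()`
applies the "at least 2 tags detected per sample" rule; since that
phrase is ambiguous between *each* sample and *some* sample, the
default scope is `"every"` with `"any"` exposed.
`normalize_to_housekeeping()` divides by the GAPDH count of the same
sample, so the housekeeping feature normalises to 1 everywhere and a
zero housekeeping count is an error naming the sample.

## Co-expression selection and group statistics

`select_correlated_genes()` computes Pearson r of each gene's
normalised abundance against the target (HERV-W *env*) across samples
and selects genes with r² ≥ 0.75 (inclusive, following the stated
filtering criterion). Correlations are computed on fold-change-to-GAPDH
abundances, matching the analysis the selection feeds; zero-variance
genes are flagged undefined and excluded. No multiple-testing
correction is applied by default because the downstream use is a
descriptive screen with unadjusted thresholds; `stats::p.adjust` can be
applied to the reported table if desired. One caveat the tests make
explicit: dividing two noisy counts by the same housekeeping count
couples the ratios (the classic spurious-ratio-correlation artifact),
so the null calibration of the selection rule is tested on
unnormalised independent counts, where the permutation null is exact.
Group contrasts use the exact Mann–Whitney U for min(n₁,n₂) ≤ 8
without ties and the tie-corrected normal approximation otherwise;
Spearman correlations use exact p-values for n ≤ 10 without ties.
Heatmap standardisation (`expression_matrix_for_heatmap()`) z-scores
each gene with the sample (n−1) standard deviation — a convention that
must be stated because either sd convention is defensible — and emits
constant rows as zeros with a flag.

## The synthetic-data generators

`simulate_panel()` builds a random ancestral locus with the four primer
footprints embedded intact and derives each panel locus as an
independently mutated copy: substitutions only (the real amplicons
align colinearly), transition:transversion 2:1 (so distances have K2P
structure), primer footprints shielded so in-silico PCR always succeeds
on simulated panels — PCR-failure testing is thereby separated from
assignment testing. The default ancestor length (838 bp) makes the
nested product exactly 650 bp. Default per-locus divergence 0.03 keeps
all pairwise identities above 90%, the similarity regime of the real
paralog family; if a configuration drives identities below the
configured floor the generator fails loudly. `simulate_clones()` draws
6–27 clones per sample (uniformly), assigns each an origin locus from
the sample's mixture weights, and applies independent per-base errors
at `clone_error_rate`; a rate of 2×10⁻⁴ reproduces the ~0.02%
artifactual diversity of a plasmid PCR control, while 3×10⁻³ is used
as a conservative bound on combined polymerase and sequencing error in
clinical material. `simulate_tag_counts()` draws negative-binomial
counts (variance μ + φμ², default φ = 0.1) with *env* the most
abundant HERV feature in expectation, "tracking" genes affine in env
abundance and "independent" genes unrelated to it. All randomness
flows through one explicitly seeded generator: a fixed seed gives
byte-identical FASTA and TSV output, and the caller's RNG state is
left untouched.

What the simulations do *not* emulate: indels and recombination
between paralogs, coalescent structure within loci, chromatogram or
base-quality error profiles, and amplification bias between loci.
Passing tests therefore demonstrate the correctness of the decision
rules and estimators under the stated error model, not robustness to
every artifact of real capillary or short-read data.

## Problem sizes and numerical choices

The validation suite uses 12-locus panels, 200-clone assignment runs,
1000-replicate coalescent calibrations, 100 random 100-codon Ka/Ks
pairs, 500 random additive matrices on 6–10 taxa, and 10,000-read tag
counting — sizes at which every oracle (quadratic alignment DP,
pathway enumeration, all-pairs Hamming scan, exhaustive permutation)
is itself exact and fast. Ties in assignment are broken by documented
rule, never input order; alignment scoring is fixed; identity
comparisons use strict/inclusive bounds exactly as stated above;
degenerate inputs (empty panels, constant vectors, all-tied groups,
zero housekeeping counts) raise typed conditions rather than NA
propagation.

## Known limitations

Assignment restricted to a curated panel cannot discover novel
integration loci; a clone from an unrepresented locus will surface as
ND or as a near-threshold call on its closest panel relative. The
LWL85 estimator saturates on distant pairs (flagged, not imputed).
NJ with midpoint-of-pendant rooting conveys no support values —
bootstrap support is out of scope. The ratio-correlation caveat above
applies to any housekeeping-normalised co-expression screen, including
the r² ≥ 0.75 selection.
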