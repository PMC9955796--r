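---
title: "Characterizing ABC transporter families with abcfam: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing ABC transporter families with abcfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcfam)
```

# Scope

`abcfam` implements the desk half of a genome-scale ABC-transporter family
characterization: motif-level detection of nucleotide-binding domains
(NBDs), structural typing from conserved-domain arrangements, consensus
derivation from aligned motif blocks, promoter cis-element censuses,
RPKM-based expression screening with hierarchical clustering, and
2^-ddCt relative quantification of qPCR time courses. Everything upstream
of these steps — read alignment, multiple sequence alignment, homology
modelling, phylogenies — is out of scope; those inputs enter as plain
files (FASTA, GFF3, TSV, CSV).

Because the real assembly and transcriptomes behind such a study are not
desk-reproducible, the package ships seeded generators
(`genCohortRegistry()`, `genProteins()`, `genPromoters()`, `genCounts()`,
`genCt()`) that emulate the study conditions and keep an exact ground-truth
ledger, so every stage is testable end to end without downloads.

# The motif model

## Pattern language

Patterns are extended PROSITE-style: ordered position elements that are an
exact residue, a residue class (`[GA]`), or a wildcard `X`, with
fixed-count repeats `X(3)` and a hydrophobic-class symbol Φ usable alone or
inside brackets (`[ΦHY]` is the union of the hydrophobic set with H and Y).
Every compiled pattern has a fixed span; variable-length repeats `X(n,m)`
are parsed and rejected, because none of the NBD motifs need them and a
fixed span keeps match semantics and block extraction trivial.

The literature does not enumerate "hydrophobic", so Φ defaults to the
classical strongly hydrophobic set {A, C, F, I, L, M, V, W} and is an
argument everywhere it is expanded. Letters outside the 20-letter alphabet
(B, Z, J, X-as-residue) never satisfy an exact or class element; by default
they are tolerated but fail wildcards too (`unknown = "never-match"`),
which is the conservative choice for identification work.

The shipped pattern set (`nbdPatterns()`) contains the generalized fungal
consensi

* Walker A `G-XX-[GA]-X-G-K-[ST]`
* ATP-binding (C-loop)
  `[LIVMFYC]-S-[SGQDEVAHL]-G-X(3)-[RKALV]-[LIVMYATC]-X-[LIVMF]-[AGCT]`
* Walker B `[ΦHY]-[ΦCY]-[ΦC]-[ΦCT]-[D]-[DEI]`

plus the three classical motifs they generalize (`G-X(4)-G-K-[ST]`,
`[LIVMFY]-S-[SG]-G-X(3)-[RKA]-[LIVMYA]-X-[LIVMF]-[AG]`, `[Φ](4)-[D]`).
The classical ATP-binding motif is sometimes printed with a line-break
hyphen inside the `[LIVMF]` class; the shipped form removes it.

## NBD assembly

An NBD is a Walker A → C-loop → Walker B triplet in N-to-C order.
Spacing windows are not stated anywhere authoritative, so they are
configuration (`nbdSpacing()`): the C-loop must start 30–200 residues
after the Walker A end and Walker B 5–80 residues after the C-loop end,
which brackets typical ABC NBD geometry while keeping accidental
assemblies rare. Assembly is greedy left-to-right with
earliest-compatible pairing — deterministic, and matching how one reads
an alignment figure by eye. Only complete triplets count as NBDs;
position indices (B1, B2, …) follow Walker A order along the chain.

Sequence classes are diagnosed from the variable positions of Walker A
and the C-loop. The published description indexes alignment columns
("eighth and ninth" of Walker A, "…thirteenth" of the ATP-binding motif)
that run past the printed motif spans (8 and 12), so the shipped rule
clamps to within-span positions (Walker A 7–8; C-loop 6, 8, 11, 12) and
the residue-to-class map is editable data seeded with heuristic
exemplars (Class1 ≈ Protein White/Rim protein, Class2 ≈ Uup, Class3 ≈
efflux families). Classification is exact lookup, then nearest exemplar
by Hamming distance, with inter-class ties mapped to `unassigned` rather
than guessed.

# Structural typing

Conserved-domain arrangement strings over the five-letter alphabet
(A = ABC-membrane, B = ABC-ATPase, C = ABC2-membrane, D = ABC-tran-2,
E = acyl-transfer-3) map deterministically to six structural types;
types 1–4 are transmembrane transporters, 5–6 translational regulators.
The `A-B` arrangement is genuinely ambiguous between a full transporter
(type 1, ATM1) and a half transporter (type 2, ATM1/MdlB/3a0123). The
resolution here: `A-B` defaults to type 2, and a per-record
full-transporter flag promotes ATM1 members to type 1. This preserves
both published rows of the type table while staying a function.

# Consensus derivation and information content

`deriveConsensus()` generalizes an aligned, fixed-span motif block column
by column: a column with a single observed residue becomes an exact
element; a column whose residues at or above `freq_floor` number at most
`class_threshold` becomes a bracket class; anything more diverse becomes a
wildcard. The class is widened to include every residue actually observed
in a non-wildcard column, which makes the derived pattern match 100% of
its source rows by construction — the invariant the test suite checks.
Defaults `freq_floor = 0.05` and `class_threshold = 10` reproduce bracket
sizes of the same order as the published motifs (e.g. the 9-residue
`[SGQDEVAHL]` class); they are tunable, and derived patterns should be
read as targets of form, not bit-exact reproductions.

Per-column information content is `log2(20)` minus the Shannon entropy of
the column frequencies — 0 bits for a uniform column, ≈4.3219 bits for an
invariant one. The pseudocount defaults to 0 and the small-sample
correction used by logo software is deliberately omitted; the numbers are
meant for ranking column conservation, not publication-grade logos.

# Promoter census

Cis-element dictionaries are IUPAC consensus strings with a stress flag;
the default stress set is {GCR1, GCN4, ADR1, STRE, HSTF, PHO4, GC/FAR,
ABF1}. The shipped dictionary (`inst/extdata/scpd_motifs.tsv`) carries
published yeast consensus strings as clearly-labelled external defaults —
the underlying study names its motifs but not their consensus strings, so
the file is reference data the user is expected to edit.

Matching expands the consensus over {A, C, G, T} only: an `N` in a
promoter never matches, every overlapping occurrence counts, and with
`both_strands` the reverse-complement consensus is also scanned, so a
palindromic consensus (e.g. `GAANNTTC`) counts once per strand at the
same position — a documented convention, since the original prediction
server's behaviour is unspecified. Promoters longer than the configured
1000 bp are truncated keeping the gene-proximal (3') end, with a warning.

# Expression screen

RPKM is the textbook quantity `C * 1e9 / (N * L)` with the per-library
mapped-read total `N` an explicit input (which denominator the original
pipeline used is not recoverable, so nothing is inferred). Heatmap values
are `log2(RPKM + 1)`; the published caption writes `log2(RPKM)`, but real
count data contain zeros, so the offset defaults to 1 and is an argument.
Clustering is the standard Euclidean-distance, complete-linkage
agglomeration (`stats::dist` + `stats::hclust`, the same calls the
original analysis names); the suite verifies it against a brute-force
O(n³) oracle. "Highly expressed" has no published definition, so the
default rule flags a gene whose RPKM is at or above the condition's upper
quartile, with an absolute-cutoff alternative.

# qPCR relative quantification

Ct tables are long-format records over condition × timepoint ×
replicate with designated reference genes (defaults: actin, α-tubulin,
β-tubulin). ΔCt subtracts the arithmetic mean of the reference Ct values
within the same sample — equivalent to normalizing by the geometric mean
of reference quantities, a standard choice the source protocol leaves
unstated. The calibrator defaults to the same condition's 0-h sample, so
each condition gets its own trajectory and the treatment-minus-control
difference is formed afterwards on the log2 scale; calibrating against
control-at-same-time instead is supported by re-basing the table.

Significance uses a pooled-variance two-sample t-test (Welch optional).
The test is computed on the replicate ΔCt values of the two conditions at
the timepoint, not on ΔΔCt replicates: all ΔΔCt replicates within a
condition share one noisy calibrator mean, so testing them directly is
anticonservative, while ΔCt replicates are independent between conditions
and test the same contrast. With zero variance in both groups the
convention is p = 1 for equal means and p = 0 otherwise. Stars follow
p < 0.05 = `*`, p < 0.01 = `**`.

# What the generators emulate — and what they do not

`genCohortRegistry()` pins the cohort marginals (44 genes; family counts
MRP 9, MDR 8, CFTR 6, MdlB 5, Uup 5, ATM1 4, Protein White 4,
Rim protein 2, 3a0123 1; type counts 27/6/2/4/2/3; intron bins
5/5/13/4/17 over 0–15; pI spanning [5.48, 9.87] with 27 acidic and 17
basic; MW spanning [55.33, 187.56] kDa; 17 scaffolds, at most 7 genes on
one). The per-record family/type split consistent with those sums is one
fixed, non-authoritative choice; the seed only jitters continuous values
within the pinned marginals. The per-type arrangement strings give 79
ABC-ATPase (B) domains in total, so the planted proteome carries exactly
79 NBD triplets (35 two-NBD and 9 one-NBD proteins).

`genProteins()` plants motif instances sampled uniformly from the pattern
element sets on an i.i.d. residue background and regenerates any protein
where detection does not recover the plant exactly — accidental motifs
are screened out, which is what makes planted-truth tests exact.
`genPromoters()` works the same way at nucleotide level: planted sites
become IUPAC constraints, the rest is i.i.d. background, and accidental
dictionary matches are removed by resampling their footprints; the
per-gene plant budget (9–32 expected census counts, palindromes counting
double) mirrors the published per-promoter range. `genCounts()` draws
negative-binomial counts around a design in which two genes are pinned to
exact published RPKM values (ABC31: 8537 in MM, 59214 in PdPap; ABC42:
3957 in MM, 11790 in N-hungry) and 17 transport plus 4
translation-regulating genes are high in at least one condition under the
upper-quartile rule. `genCt()` plants log2-effect trajectories whose
peaks are the published fold-change magnitudes (3.13, 2.54, 4.92, 5.09,
−1.83) with replicate noise SD 0.2 cycles and n = 3, rounding Ct to three
decimals for cross-platform determinism.

What the generators do *not* emulate: real residue composition and
homology structure (backgrounds are i.i.d., so there are no paralogous
near-motifs), promoter GC structure and motif clustering, overdispersion
heterogeneity across genes, amplification-efficiency drift in qPCR, and
any linkage between a protein's sequence and its registry pI/MW (those
are registry values, not recomputed from the synthetic sequences).
Passing planted-truth tests therefore demonstrates correctness of the
computations, not robustness to the messiness of real genomes.

# Numerical choices and degenerate inputs

* pI is found by bisection of the Henderson–Hasselbalch net charge on
  [0, 14] to 1e-4 pH units; the net-charge function is strictly
  decreasing, so the root is unique. The pKa table is a common
  Bjellqvist-style set shipped as editable data; different servers use
  slightly different tables, so absolute pI values carry that caveat.
* Molecular weight uses average residue masses plus one water.
* Intron count is exon count − 1 on the longest transcript when a gene
  model has several; zero-exon genes are an error, not a zero.
* Empty patterns cannot scan; empty blocks cannot profile; ragged blocks
  and mixed motif spans are errors. Ties in NBD class distance give
  `unassigned`; `hclust` tie behaviour is inherited and immaterial on
  continuous data.
* Simulation sizes in the test suite (cohorts of 44 proteins, 1000
  random 200-mers for the regex-oracle comparison, 100 random 8-gene
  clustering instances, 500 qPCR simulations) were chosen as the
  smallest sizes that exercise the pinned worked examples and give the
  calibration checks useful power.

# Known limitations

* NBD detection is purely motif-based; degenerate NBDs that fail one of
  the three motifs are invisible, and the 79-NBD count convention counts
  complete triplets only.
* The shipped class exemplars and promoter dictionary are heuristic /
  external defaults, not assertions about any particular genome.
* No amplification-efficiency correction (Pfaffl) is implemented; 2^-ddCt
  assumes near-100% efficiency.
* The expression screen performs no differential-expression inference —
  flags are descriptive thresholds, by design.
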