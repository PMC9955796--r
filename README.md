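# abcfam

Characterization of ATP-binding cassette (ABC) transporter gene families
in R.

ABC transporters move toxins, ions and metabolites across membranes at
the cost of ATP, and in filamentous fungi they are front-line equipment
for surviving competitor and pathogen toxins. Characterizing a genome's
ABC complement is a standard multi-stage desk analysis, and `abcfam`
implements its computational core as a tested, reusable pipeline:

* **Motif engine** — extended PROSITE-style patterns (exact residues,
  `[classes]`, wildcards, `X(n)` repeats, and a hydrophobic-class symbol
  Φ), with overlapping-match scanning over protein sequences.
* **NBD detection** — nucleotide-binding domains assembled as ordered
  Walker A → ATP-binding (C-loop) → Walker B motif triplets
  (`G-XX-[GA]-X-G-K-[ST]`,
  `[LIVMFYC]-S-[SGQDEVAHL]-G-X(3)-[RKALV]-[LIVMYATC]-X-[LIVMF]-[AGCT]`,
  `[ΦHY]-[ΦCY]-[ΦC]-[ΦCT]-[D]-[DEI]`), indexed by chain position and
  assigned sequence classes from diagnostic positions.
* **Structural typing** — conserved-domain arrangement strings
  (`A-B-A-B`, `B-C-B`, …) mapped to six structural types;
  types 1–4 transport, types 5–6 translational regulation.
* **Consensus derivation** — generalized patterns and per-column
  information content (`log2 20 − H`) from aligned motif blocks.
* **Promoter census** — IUPAC consensus dictionaries (GCN4, STRE, HSTF,
  …) counted over 1000-bp upstream regions, both strands, with
  stress-subset and per-family rollups.
* **Expression screen** — RPKM (`C·10⁹ / (N·L)`), `log2(RPKM + 1)`,
  Euclidean/complete-linkage gene clustering, high-expression flagging.
* **qPCR** — 2^−ΔΔCt relative quantification against multiple reference
  genes with an independent-samples t-test per timepoint.
* **Synthetic cohorts** — seeded generators with exact ground-truth
  ledgers for every input (registry + GFF3, planted-motif proteomes,
  planted-site promoters, count matrices, Ct tables), so the whole
  pipeline is testable offline.

## Worked example

```r
library(abcfam)

## a 44-gene cohort with pinned marginals, and its planted proteome
reg  <- genCohortRegistry(seed = 1)$registry
prot <- genProteins(reg, seed = 1)

cohortSummary(reg)$family_counts
#>        3a0123          ATM1          CFTR          MdlB           MDR
#>             1             4             6             5             8
#>           MRP Protein White   Rim protein           Uup
#>             9             4             2             5

hits <- classifyNbdSet(findNbdsSet(prot$sequences))
nrow(hits)
#> [1] 79
head(hits[, c("protein_id", "nbd_index", "walkerA_start",
              "cloop_start", "walkerB_start", "class")], 3)
#>   protein_id nbd_index walkerA_start cloop_start walkerB_start      class
#> 1      ABC01         1           121         184           245     Class1
#> 2      ABC01         2           471         624           674     Class2
#> 3      ABC02         1           121         171           198 unassigned

## derive a consensus back from the detected Walker A block
renderPattern(deriveConsensus(extractMotifBlock(hits, "walkerA")))
#> [1] "G-X(2)-[AG]-X-G-K-[ST]"

## expression screen with pinned reference genes
cnt <- genCounts(reg, seed = 1)
r   <- rpkmMatrix(cnt$counts, cnt$lengths, cnt$mapped)
r[c("ABC31", "ABC42"), ]
#>         MM C-hungry N-hungry PdPap
#> ABC31 8537    30000    25000 59214
#> ABC42 3957     8000    11790  9000

## 2^-ddCt on a planted toxin-response time course
ct <- genCt(seed = 1)
foldChange(ct$table, "ABC31", 6)
#>    gene condition timepoint minus_ddct     sd  fold p_vs_other stars
#> 1 ABC31 treatment         6      5.065 0.1318 33.47  1.623e-06    **
```

The 79 detected NBDs sit exactly at the generator's planted coordinates;
the derived Walker A consensus recovers the planted pattern's shape; the
two pinned genes carry their exact designed RPKM values; and the
recovered log2 fold change at 6 h (5.065 here) estimates the planted
effect of 5.09, i.e. a ≈34-fold induction, significant against the
control series.

A thin command-line dispatcher over the same functions is installed at
`inst/scripts/abcfam.R` (`scan-motif`, `scan-nbd`, `classify`,
`consensus`, `census`, `rpkm`, `ddct`, `simulate`).

See `vignettes/abc-transporter-characterization.Rmd` for the methods:
the pattern language and its semantics, NBD spacing windows and class
rules, the `A-B` typing ambiguity, census strand conventions, the qPCR
model and its t-test, and exactly what the synthetic cohorts do and do
not emulate.

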