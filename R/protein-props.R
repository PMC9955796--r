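.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

#' Protein molecular weight
#'
#' Sum of average (isotope-abundance-weighted) residue masses plus one
#' water, in daltons.
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @return Molecular weight in Da.
#' @examples
#' molecularWeight("GG")  # 132.1191
#' @export
molecularWeight <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, names(.AA_AVG_MASS))
  if (length(bad))
    stop(sprintf("invalid residue letter '%s'", bad[1]))
  sum(.AA_AVG_MASS[chars]) + .WATER_MASS
}

#' Ionizable-group pKa table
#'
#' Bjellqvist-style pKa values for the protein termini and ionizable side
#' chains, shipped as editable data (different prediction servers use
#' slightly different tables; this one is a common default).
#'
#' @return Named numeric vector with entries \code{Nterm}, \code{Cterm},
#'   \code{K}, \code{R}, \code{H} (basic) and \code{D}, \code{E},
#'   \code{C}, \code{Y} (acidic).
#' @export
bjellqvistPka <- function() {
  c(Nterm = 7.50, Cterm = 3.55,
    K = 10.00, R = 12.00, H = 5.98,
    D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
}

#' Net protein charge at a given pH
#'
#' Henderson--Hasselbalch net charge: each basic group contributes
#' \code{+1 / (1 + 10^(pH - pKa))}, each acidic group
#' \code{-1 / (1 + 10^(pKa - pH))}; side-chain contributions are counted
#' per residue occurrence, termini once each.
#'
#' @param sequence amino-acid string.
#' @param pH pH value (vectorized).
#' @param pka pKa table from [bjellqvistPka()].
#' @return Net charge (same length as \code{pH}).
#' @export
netCharge <- function(sequence, pH, pka = bjellqvistPka()) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, names(.AA_AVG_MASS))
  if (length(bad)) stop(sprintf("invalid residue letter '%s'", bad[1]))
  n_basic <- c(Nterm = 1, K = sum(chars == "K"), R = sum(chars == "R"),
               H = sum(chars == "H"))
  n_acid <- c(Cterm = 1, D = sum(chars == "D"), E = sum(chars == "E"),
              C = sum(chars == "C"), Y = sum(chars == "Y"))
  vapply(pH, function(ph) {
    pos <- sum(n_basic / (1 + 10^(ph - pka[names(n_basic)])))
    neg <- sum(n_acid / (1 + 10^(pka[names(n_acid)] - ph)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' The pH at which [netCharge()] crosses zero, found by bisection on
#' \[0, 14\] to the requested tolerance. The net-charge function is
#' strictly decreasing in pH, so the root is unique.
#'
#' @param sequence amino-acid string.
#' @param pka pKa table from [bjellqvistPka()].
#' @param tol bisection tolerance on pH (default 1e-4).
#' @return Estimated pI.
#' @export
isoelectricPoint <- function(sequence, pka = bjellqvistPka(), tol = 1e-4) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (netCharge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Acid/base classification of an isoelectric point
#'
#' pI > 7 is basic, pI < 7 acidic, exactly 7 neutral.
#'
#' @param pI finite numeric pI.
#' @return \code{"acidic"}, \code{"basic"} or \code{"neutral"}.
#' @export
classifyPI <- function(pI) {
  stopifnot(is.finite(pI))
  if (pI > 7) "basic" else if (pI < 7) "acidic" else "neutral"
}

#' Count introns per gene from a GFF3 file
#'
#' Introns per gene = exon count of the canonical transcript minus one.
#' With multiple transcripts per gene the longest transcript (largest
#' summed exon width) is used. Coordinates are GFF3 1-based inclusive;
#' strand affects exon ordering only, not the count. A gene whose chosen
#' transcript has no exon rows is an error.
#'
#' @param gff path to a GFF3 file, or a \code{GRanges} as returned by
#'   \code{rtracklayer::import}.
#' @return Named integer vector: gene ID -> intron count.
#' @export
countIntrons <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3")
        else gff
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- vapply(md$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  gene_idx <- which(types == "gene")
  if (length(gene_idx) == 0) stop("no gene features in GFF3 input")
  out <- integer(0)
  for (gi in gene_idx) {
    gid <- ids[gi]
    tx_idx <- which(types %in% c("mRNA", "transcript") & parents == gid)
    if (length(tx_idx) == 0) {
      # exons directly under the gene
      ex <- which(types == "exon" & parents == gid)
      if (length(ex) == 0)
        stop(sprintf("gene '%s' has no exons", gid))
      out[gid] <- length(ex) - 1L
      next
    }
    tx_ids <- ids[tx_idx]
    exon_sets <- lapply(tx_ids, function(tid)
      which(types == "exon" & parents == tid))
    lens <- vapply(exon_sets, function(ii)
      sum(GenomicRanges::width(gr[ii])), numeric(1))
    if (all(lengths(exon_sets) == 0))
      stop(sprintf("gene '%s' has no exons", gid))
    best <- exon_sets[[which.max(lens)]]
    out[gid] <- length(best) - 1L
  }
  out
}

#' Per-protein property table
#'
#' Convenience wrapper: molecular weight (kDa), isoelectric point and its
#' acid/base class for a set of protein sequences.
#'
#' @param sequences named character vector or
#'   \code{Biostrings::AAStringSet}.
#' @param pka pKa table from [bjellqvistPka()].
#' @return \code{data.frame}: protein_id, mw_kda, pI, pi_class.
#' @export
proteinProperties <- function(sequences, pka = bjellqvistPka()) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  stopifnot(!is.null(names(sequences)))
  data.frame(
    protein_id = names(sequences),
    mw_kda = vapply(sequences, molecularWeight, numeric(1)) / 1000,
    pI = vapply(sequences, isoelectricPoint, numeric(1), pka = pka),
    pi_class = vapply(sequences, function(s)
      classifyPI(isoelectricPoint(s, pka)), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
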