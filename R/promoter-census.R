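.IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Compile an IUPAC DNA consensus into a matcher
#'
#' Expands a consensus string over the 15-letter IUPAC nucleotide alphabet
#' into a positional matcher that accepts exactly the ACGT sequences in the
#' consensus's expansion. An \code{N} in a scanned sequence never matches:
#' expansions are over \{A, C, G, T\} only, so ambiguous subject bases fail
#' every position.
#'
#' @param consensus IUPAC string, e.g. \code{"TGACTC"} or \code{"WWT"}.
#' @return List matcher with fields \code{consensus}, \code{length},
#'   \code{regex} (a lookahead regex reporting overlapping hits).
#' @export
compileIupac <- function(consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1)
  if (nchar(consensus) == 0) stop("empty consensus")
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, names(.IUPAC_DNA))
  if (length(bad))
    stop(sprintf("illegal IUPAC letter '%s' in consensus '%s'",
                 bad[1], consensus))
  body <- paste(vapply(chars, function(cc) {
    ex <- .IUPAC_DNA[[cc]]
    if (length(ex) == 1) ex else paste0("[", paste(ex, collapse = ""), "]")
  }, character(1)), collapse = "")
  list(consensus = toupper(consensus),
       length = length(chars),
       regex = paste0("(?=", body, ")"))
}

#' All (overlapping) match starts of a compiled IUPAC matcher
#'
#' @param sequence DNA string over ACGTN.
#' @param matcher from [compileIupac()].
#' @return Integer vector of 1-based start positions, ascending.
#' @export
iupacMatchStarts <- function(sequence, matcher) {
  m <- gregexpr(matcher$regex, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Load a cis-regulatory motif dictionary
#'
#' Reads a tab-separated dictionary (columns \code{name}, \code{consensus},
#' \code{stress} as 0/1). With no path, loads the shipped default: a set of
#' published yeast promoter-element consensus strings (SCPD-style names).
#' The defaults are external reference data, editable and clearly labelled
#' as such; the stress subset defaults to \{GCR1, GCN4, ADR1, STRE, HSTF,
#' PHO4, GC/FAR, ABF1\}.
#'
#' @param path optional TSV path.
#' @return \code{data.frame} with columns \code{name}, \code{consensus},
#'   \code{stress} (logical); names unique.
#' @export
motifDictionary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scpd_motifs.tsv", package = "abcfam")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer"))
  stopifnot(all(c("name", "consensus", "stress") %in% names(tab)))
  if (anyDuplicated(tab$name)) stop("duplicate motif names in dictionary")
  if (any(nchar(tab$consensus) == 0)) stop("empty consensus in dictionary")
  tab$stress <- as.logical(tab$stress)
  # compile early so illegal letters fail at load time
  invisible(lapply(tab$consensus, compileIupac))
  tab
}

.check_dna <- function(seqs) {
  for (id in names(seqs)) {
    chars <- unique(strsplit(seqs[[id]], "")[[1]])
    bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop(sprintf("record '%s' contains non-DNA letter '%s'", id, bad[1]))
  }
}

#' Census of cis-regulatory motifs over promoter regions
#'
#' Scans each promoter (1000-bp upstream region by default) against every
#' dictionary entry and counts all, possibly overlapping, occurrences.
#' With \code{both_strands}, occurrences of the reverse complement of each
#' consensus on the given strand are added (equivalently: hits on the
#' reverse strand); a palindromic consensus therefore counts once per
#' strand at each position. Promoters longer than \code{promoter_length}
#' are truncated keeping the 3' end (the gene-proximal side), with a
#' warning.
#'
#' @param promoters named character vector or
#'   \code{Biostrings::DNAStringSet} of upstream regions (ACGTN only).
#' @param dict dictionary \code{data.frame} from [motifDictionary()].
#' @param both_strands logical; scan both strands (default TRUE).
#' @param promoter_length expected region length in bp (default 1000).
#' @return List census table: \code{counts} (gene x motif integer matrix),
#'   \code{per_gene} (data.frame: gene, total, distinct_types,
#'   stress_total), \code{total}, \code{stress_total},
#'   \code{per_motif_total}, \code{n_types_seen}, \code{both_strands}.
#' @export
promoterCensus <- function(promoters, dict, both_strands = TRUE,
                           promoter_length = 1000L) {
  if (is(promoters, "DNAStringSet")) promoters <- as.character(promoters)
  stopifnot(is.character(promoters), !is.null(names(promoters)))
  .check_dna(promoters)
  too_long <- nchar(promoters) > promoter_length
  if (any(too_long)) {
    warning(sprintf("%d promoter(s) longer than %d bp truncated 3'-anchored",
                    sum(too_long), promoter_length))
    promoters[too_long] <- substring(
      promoters[too_long],
      nchar(promoters[too_long]) - promoter_length + 1L)
  }
  fwd <- lapply(dict$consensus, compileIupac)
  rev <- lapply(dict$consensus, function(cs)
    compileIupac(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cs)))))
  counts <- matrix(0L, nrow = length(promoters), ncol = nrow(dict),
                   dimnames = list(names(promoters), dict$name))
  for (g in names(promoters)) {
    s <- promoters[[g]]
    for (j in seq_len(nrow(dict))) {
      k <- length(iupacMatchStarts(s, fwd[[j]]))
      if (both_strands)
        k <- k + length(iupacMatchStarts(s, rev[[j]]))
      counts[g, j] <- k
    }
  }
  per_gene <- data.frame(
    gene = rownames(counts),
    total = as.integer(rowSums(counts)),
    distinct_types = as.integer(rowSums(counts > 0)),
    stress_total = as.integer(rowSums(counts[, dict$stress, drop = FALSE])),
    stringsAsFactors = FALSE)
  list(counts = counts,
       per_gene = per_gene,
       total = sum(counts),
       stress_total = sum(counts[, dict$stress, drop = FALSE]),
       per_motif_total = colSums(counts),
       n_types_seen = sum(colSums(counts) > 0),
       both_strands = both_strands)
}

#' Per-family promoter census summary
#'
#' Arithmetic mean motif count and mean number of distinct motif types per
#' family, with integer-rounded columns matching the conventional
#' whole-number reporting of per-family averages.
#'
#' @param census census list from [promoterCensus()].
#' @param family_map named character vector: gene id -> family label; every
#'   censused gene must be mapped.
#' @return \code{data.frame}: family, n_genes, mean_motifs,
#'   mean_distinct_types, plus integer-rounded versions.
#' @export
summarizeByFamily <- function(census, family_map) {
  pg <- census$per_gene
  unmapped <- setdiff(pg$gene, names(family_map))
  if (length(unmapped))
    stop(sprintf("gene '%s' has no family mapping", unmapped[1]))
  fam <- family_map[pg$gene]
  agg <- lapply(split(seq_len(nrow(pg)), fam), function(ii) {
    data.frame(n_genes = length(ii),
               mean_motifs = mean(pg$total[ii]),
               mean_distinct_types = mean(pg$distinct_types[ii]))
  })
  out <- do.call(rbind, agg)
  out <- cbind(data.frame(family = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out$mean_motifs_rounded <- as.integer(round(out$mean_motifs))
  out$mean_types_rounded <- as.integer(round(out$mean_distinct_types))
  out
}
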