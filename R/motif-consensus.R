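#' Per-column residue profiles of an aligned motif block
#'
#' Counts residues column-by-column over a rectangular block (as produced
#' by [extractMotifBlock()]). Each profile carries integer counts over the
#' 20-letter alphabet, the block depth, and the relative frequencies.
#'
#' @param block character matrix of single residues, or character vector of
#'   equal-length strings.
#' @return List of profiles, one per column; each a list with
#'   \code{counts} (named integer, length 20), \code{depth},
#'   \code{freq} (named numeric, sums to 1).
#' @export
columnProfiles <- function(block) {
  if (is.character(block) && is.null(dim(block))) {
    if (length(unique(nchar(block))) > 1)
      stop("ragged block: rows differ in length")
    block <- do.call(rbind, strsplit(block, ""))
  }
  stopifnot(is.matrix(block))
  if (nrow(block) == 0 || ncol(block) == 0)
    stop("empty block")
  aa <- aminoAcids()
  if (!all(block %in% aa))
    stop("block contains letters outside the 20-letter alphabet")
  lapply(seq_len(ncol(block)), function(j) {
    cnt <- table(factor(block[, j], levels = aa))
    cnt <- stats::setNames(as.integer(cnt), aa)
    depth <- nrow(block)
    list(counts = cnt, depth = depth, freq = cnt / depth)
  })
}

#' Information content of a column profile
#'
#' Shannon information in bits: \code{log2(20)} minus the entropy of the
#' (optionally pseudocounted) residue frequencies. An invariant column
#' scores \code{log2(20) ~ 4.3219} bits; a uniform column scores 0. The
#' small-sample correction used by sequence-logo software is deliberately
#' omitted (pseudocount defaults to 0).
#'
#' @param profile one profile from [columnProfiles()].
#' @param pseudocount value added to every residue count before
#'   normalizing.
#' @return Information content in bits, in \[0, log2(20)\].
#' @export
informationContent <- function(profile, pseudocount = 0) {
  if (is.null(profile$depth) || profile$depth < 1)
    stop("profile depth must be >= 1")
  stopifnot(pseudocount >= 0)
  cnt <- profile$counts + pseudocount
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  log2(20) - ent
}

#' Derive a generalized consensus pattern from a motif block
#'
#' Reproduces, per column, the generalization that turns an aligned motif
#' block into an extended PROSITE-style pattern: a single residue carrying
#' more than \code{1 - freq_floor} of the column becomes an exact element;
#' otherwise, if at most \code{class_threshold} residues each reach
#' \code{freq_floor}, those residues form a bracketed class; otherwise the
#' column is a wildcard. Residues below \code{freq_floor} are treated as
#' noise but the derived class is widened to include every residue actually
#' observed in the column whenever the column is not a wildcard, so the
#' derived pattern always matches 100% of its source rows.
#'
#' @param block character matrix or equal-length string vector.
#' @param class_threshold maximum number of residues for a bracket class.
#' @param freq_floor minimum per-residue frequency to count as a class
#'   member.
#' @return A [MotifPattern-class].
#' @export
deriveConsensus <- function(block, class_threshold = 10, freq_floor = 0.05) {
  profiles <- columnProfiles(block)
  elements <- lapply(profiles, function(pr) {
    f <- pr$freq
    observed <- names(f)[f > 0]
    dominant <- names(f)[f > 1 - freq_floor]
    members <- names(f)[f >= freq_floor]
    if (length(dominant) == 1 && length(observed) == 1) {
      list(kind = "exact", residues = dominant)
    } else if (length(members) <= class_threshold) {
      set <- sort(unique(c(members, observed)))
      if (length(set) == 20) list(kind = "wildcard", residues = character(0))
      else list(kind = "class", residues = set)
    } else {
      list(kind = "wildcard", residues = character(0))
    }
  })
  src <- sprintf("derived from %d x %d block", profiles[[1]]$depth,
                 length(profiles))
  new("MotifPattern", elements = elements, source = src)
}
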