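#' Spacing configuration for NBD triplet assembly
#'
#' An NBD is assembled from a Walker A match, an ATP-binding (C-loop) match
#' and a Walker B match in that N-to-C order. The gaps between consecutive
#' motifs in real ABC nucleotide-binding domains are loosely constrained by
#' NBD geometry; the defaults (C-loop starts 30--200 residues after the
#' Walker A end, Walker B starts 5--80 residues after the C-loop end) keep
#' false assemblies rare while accepting typical fungal NBDs.
#'
#' @param cloop_gap integer length-2: min/max allowed
#'   \code{cloop_start - walkerA_end}.
#' @param walkerb_gap integer length-2: min/max allowed
#'   \code{walkerB_start - cloop_end}.
#' @return List with the two gap windows.
#' @export
nbdSpacing <- function(cloop_gap = c(30L, 200L), walkerb_gap = c(5L, 80L)) {
  stopifnot(length(cloop_gap) == 2, length(walkerb_gap) == 2,
            cloop_gap[1] <= cloop_gap[2], walkerb_gap[1] <= walkerb_gap[2])
  list(cloop_gap = as.integer(cloop_gap),
       walkerb_gap = as.integer(walkerb_gap))
}

.emptyNbdFrame <- function() {
  data.frame(
    nbd_index = integer(0),
    walkerA_start = integer(0), walkerA_end = integer(0),
    walkerA_match = character(0),
    cloop_start = integer(0), cloop_end = integer(0),
    cloop_match = character(0),
    walkerB_start = integer(0), walkerB_end = integer(0),
    walkerB_match = character(0),
    class = character(0),
    stringsAsFactors = FALSE)
}

#' Locate nucleotide-binding domains in one protein
#'
#' Scans for the Walker A, ATP-binding (C-loop) and Walker B motifs and
#' assembles them greedily left-to-right into non-overlapping ordered
#' triplets subject to the spacing windows: walking along the chain, the
#' earliest unused Walker A hit is paired with the earliest compatible
#' C-loop hit, then the earliest compatible Walker B hit; a Walker A hit
#' with no compatible completion is skipped. Triplets are indexed 1, 2, ...
#' in N-to-C order (the first NBD along the chain is index 1).
#'
#' @param sequence amino-acid string.
#' @param patterns named list with [MotifPattern-class] entries
#'   \code{walkerA}, \code{cLoop}, \code{walkerB} (default: the generalized
#'   consensus set of [nbdPatterns()]).
#' @param spacing spacing windows from [nbdSpacing()].
#' @return \code{data.frame} with one row per NBD: \code{nbd_index}, the
#'   start/end/matched subsequence of each of the three motifs, and a
#'   \code{class} column initialised to \code{"unassigned"}.
#' @export
findNbds <- function(sequence, patterns = nbdPatterns("novel"),
                     spacing = nbdSpacing()) {
  stopifnot(all(c("walkerA", "cLoop", "walkerB") %in% names(patterns)))
  a_hits <- scanMotif(sequence, patterns$walkerA)
  c_hits <- scanMotif(sequence, patterns$cLoop)
  b_hits <- scanMotif(sequence, patterns$walkerB)
  out <- .emptyNbdFrame()
  if (nrow(a_hits) == 0 || nrow(c_hits) == 0 || nrow(b_hits) == 0) return(out)
  cursor <- 0L  # last residue consumed by a completed triplet
  idx <- 0L
  for (ai in seq_len(nrow(a_hits))) {
    a <- a_hits[ai, ]
    if (a$start <= cursor) next
    cg <- c_hits$start - a$end
    ci <- which(c_hits$start > cursor & cg >= spacing$cloop_gap[1] &
                  cg <= spacing$cloop_gap[2])
    if (length(ci) == 0) next
    cc <- c_hits[ci[1], ]
    bg <- b_hits$start - cc$end
    bi <- which(b_hits$start > cursor & bg >= spacing$walkerb_gap[1] &
                  bg <= spacing$walkerb_gap[2])
    if (length(bi) == 0) next
    bb <- b_hits[bi[1], ]
    idx <- idx + 1L
    out <- rbind(out, data.frame(
      nbd_index = idx,
      walkerA_start = a$start, walkerA_end = a$end, walkerA_match = a$match,
      cloop_start = cc$start, cloop_end = cc$end, cloop_match = cc$match,
      walkerB_start = bb$start, walkerB_end = bb$end, walkerB_match = bb$match,
      class = "unassigned",
      stringsAsFactors = FALSE))
    cursor <- bb$end
  }
  out
}

#' Locate NBDs across a set of proteins
#'
#' @param sequences named character vector or \code{Biostrings::AAStringSet}.
#' @param ... passed to [findNbds()].
#' @return \code{data.frame} as [findNbds()] with a leading
#'   \code{protein_id} column; rows ordered by (protein, chain position).
#' @export
findNbdsSet <- function(sequences, ...) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  res <- lapply(names(sequences), function(id) {
    hits <- findNbds(sequences[[id]], ...)
    if (nrow(hits) == 0) return(NULL)
    cbind(data.frame(protein_id = id, stringsAsFactors = FALSE), hits)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    return(cbind(data.frame(protein_id = character(0)), .emptyNbdFrame()))
  do.call(rbind, res)
}

#' Default NBD sequence-class rule
#'
#' NBD sequence classes are diagnosed from the variable positions of the
#' Walker A and ATP-binding motifs. The shipped rule reads Walker A
#' elements 7--8 and C-loop elements 6, 8, 11, 12 (the positions inside the
#' motif spans where fungal ABC NBD alignments vary), concatenates the
#' residues found there, and maps the resulting string to a class: first by
#' exact lookup, then by nearest labelled exemplar under Hamming distance
#' (ties between classes give \code{"unassigned"}). The exemplar strings
#' shipped here are heuristic seeds for the three broad NBD classes
#' (Class1: Protein White / Rim protein; Class2: Uup; Class3: efflux
#' families) and are plain editable data, not an asserted ground truth.
#'
#' @param diagnostic data.frame with columns \code{motif} (one of
#'   \code{"walkerA"}, \code{"cLoop"}, \code{"walkerB"}) and \code{index}
#'   (1-based element index within that motif).
#' @param table named character vector: exact diagnostic string -> class.
#' @param exemplars data.frame with columns \code{string}, \code{class}.
#' @return List rule object consumed by [classifyNbd()].
#' @export
nbdClassRule <- function(
    diagnostic = data.frame(
      motif = c("walkerA", "walkerA", "cLoop", "cLoop", "cLoop", "cLoop"),
      index = c(7L, 8L, 6L, 8L, 11L, 12L),
      stringsAsFactors = FALSE),
    table = character(0),
    exemplars = data.frame(
      string = c("KTERLG", "KSQKIA", "KSDRVC"),
      class = c("Class1", "Class2", "Class3"),
      stringsAsFactors = FALSE)) {
  stopifnot(all(c("motif", "index") %in% names(diagnostic)))
  stopifnot(all(c("string", "class") %in% names(exemplars)))
  list(diagnostic = diagnostic, table = table, exemplars = exemplars)
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Assign a sequence class to one NBD hit
#'
#' Extracts the residues at the rule's diagnostic positions from the hit's
#' matched motif subsequences, concatenates them, and assigns the class by
#' exact table lookup, falling back to the nearest exemplar under Hamming
#' distance. A tie between exemplars of different classes yields
#' \code{"unassigned"}.
#'
#' @param hit one-row \code{data.frame} as produced by [findNbds()].
#' @param rule rule object from [nbdClassRule()].
#' @return Class label string.
#' @export
classifyNbd <- function(hit, rule = nbdClassRule()) {
  stopifnot(nrow(hit) == 1)
  motif_col <- c(walkerA = "walkerA_match", cLoop = "cloop_match",
                 walkerB = "walkerB_match")
  res <- character(nrow(rule$diagnostic))
  for (i in seq_len(nrow(rule$diagnostic))) {
    m <- rule$diagnostic$motif[i]
    idx <- rule$diagnostic$index[i]
    sub <- hit[[motif_col[[m]]]]
    if (idx < 1 || idx > nchar(sub))
      stop(sprintf("diagnostic index %d out of range for motif '%s' (span %d)",
                   idx, m, nchar(sub)))
    res[i] <- substr(sub, idx, idx)
  }
  key <- paste(res, collapse = "")
  if (length(rule$table) && key %in% names(rule$table))
    return(unname(rule$table[[key]]))
  if (nrow(rule$exemplars) == 0) return("unassigned")
  d <- vapply(rule$exemplars$string, .hamming, numeric(1), b = key)
  best <- which(d == min(d))
  cls <- unique(rule$exemplars$class[best])
  if (length(cls) == 1) cls else "unassigned"
}

#' Classify every NBD in a hit table
#'
#' @param hits \code{data.frame} from [findNbdsSet()] (or [findNbds()]).
#' @param rule rule object from [nbdClassRule()].
#' @return The hit table with its \code{class} column filled in.
#' @export
classifyNbdSet <- function(hits, rule = nbdClassRule()) {
  if (nrow(hits) == 0) return(hits)
  hits$class <- vapply(seq_len(nrow(hits)),
                       function(i) classifyNbd(hits[i, ], rule), character(1))
  hits
}

#' Extract an aligned motif block from NBD hits
#'
#' Collects the matched subsequences of one motif over many hits into a
#' rectangular character matrix (one row per NBD, one column per motif
#' position), ordered by (protein id, chain position index). All hits must
#' come from the same fixed-span pattern.
#'
#' @param hits \code{data.frame} from [findNbdsSet()]; needs columns
#'   \code{protein_id}, \code{nbd_index} and the requested match column.
#' @param motif one of \code{"walkerA"}, \code{"cLoop"}, \code{"walkerB"}.
#' @return Character matrix of single residues; row names
#'   \code{"<protein>|B<index>"}. A zero-row matrix for an empty hit list.
#' @export
extractMotifBlock <- function(hits, motif = c("walkerA", "cLoop", "walkerB")) {
  motif <- match.arg(motif)
  col <- c(walkerA = "walkerA_match", cLoop = "cloop_match",
           walkerB = "walkerB_match")[[motif]]
  if (nrow(hits) == 0)
    return(matrix(character(0), nrow = 0, ncol = 0))
  seqs <- hits[[col]]
  spans <- nchar(seqs)
  if (length(unique(spans)) != 1)
    stop("mixed motif spans in block: all hits must share one pattern")
  ord <- order(hits$protein_id, hits$nbd_index)
  seqs <- seqs[ord]
  block <- do.call(rbind, strsplit(seqs, ""))
  rownames(block) <- sprintf("%s|B%d", hits$protein_id[ord],
                             hits$nbd_index[ord])
  block
}
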