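#' @import methods
NULL

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes, alphabetical order. This is the alphabet every
#' pattern element is defined over; non-standard letters (B, J, O, U, Z, X
#' used as a residue) are never members of a residue class.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Hydrophobic residue class (Phi)
#'
#' The residue set the pattern language substitutes for the Phi symbol.
#' Defaults to the eight classically strongly hydrophobic residues
#' \{A, C, F, I, L, M, V, W\}. ABC-transporter Walker B consensus motifs are
#' written over this class, but the literature does not pin down one set, so
#' it is an argument everywhere Phi is expanded.
#'
#' @return Character vector of hydrophobic one-letter codes.
#' @export
hydrophobicResidues <- function() {
  c("A", "C", "F", "I", "L", "M", "V", "W")
}

.PHI <- "Φ"

#' MotifPattern: a compiled extended PROSITE-style pattern
#'
#' A compiled positional protein motif pattern. Each position element is
#' exactly one of: an exact residue, a residue class (a non-empty subset of
#' the 20-letter alphabet), or a wildcard. The pattern language extends
#' classic PROSITE syntax with the Phi hydrophobic-class symbol, usable on
#' its own or inside brackets, and fixed-count repeats \code{(n)} after any
#' element. Variable-length repeats \code{X(n,m)} are rejected: every
#' compiled pattern has a fixed span.
#'
#' @slot elements list of position elements; each is a list with fields
#'   \code{kind} (one of \code{"exact"}, \code{"class"}, \code{"wildcard"})
#'   and \code{residues} (allowed residues; empty for wildcards).
#' @slot source the original pattern text.
#'
#' @seealso [parsePattern()], [scanMotif()], [minSpan()]
#' @export
setClass("MotifPattern",
  representation(elements = "list", source = "character"))

setValidity("MotifPattern", function(object) {
  aa <- aminoAcids()
  for (i in seq_along(object@elements)) {
    el <- object@elements[[i]]
    if (!is.list(el) || !all(c("kind", "residues") %in% names(el)))
      return(sprintf("element %d is malformed", i))
    if (!el$kind %in% c("exact", "class", "wildcard"))
      return(sprintf("element %d has unknown kind '%s'", i, el$kind))
    if (el$kind == "wildcard") next
    if (length(el$residues) == 0)
      return(sprintf("element %d has an empty residue set", i))
    if (el$kind == "exact" && length(el$residues) != 1)
      return(sprintf("element %d: exact elements hold one residue", i))
    if (!all(el$residues %in% aa))
      return(sprintf("element %d has residues outside the 20-letter alphabet", i))
  }
  TRUE
})

.element <- function(kind, residues = character(0)) {
  list(kind = kind, residues = residues)
}

#' Parse an extended PROSITE-style pattern
#'
#' Compiles pattern text into a [MotifPattern-class]. Legal tokens: a single
#' residue letter; \code{X} (wildcard); the Phi symbol (hydrophobic class);
#' a bracketed class such as \code{[GA]} or \code{[ΦHY]} (Phi inside
#' brackets unions the hydrophobic set with the listed residues); any of
#' these followed by a fixed repeat count \code{(n)}. Hyphens separate
#' tokens but are optional: \code{"XX"} and \code{"X-X"} are equivalent.
#'
#' @param text pattern string, e.g. \code{"G-XX-[GA]-X-G-K-[ST]"}.
#' @param phi residues the Phi symbol expands to.
#' @return A [MotifPattern-class] object.
#' @examples
#' p <- parsePattern("G-XX-[GA]-X-G-K-[ST]")
#' minSpan(p)  # 8
#' @export
parsePattern <- function(text, phi = hydrophobicResidues()) {
  stopifnot(is.character(text), length(text) == 1)
  stopifnot(all(phi %in% aminoAcids()))
  src <- text
  chars <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
  aa <- aminoAcids()
  elements <- list()
  i <- 1L
  n <- length(chars)

  read_repeat <- function(i) {
    # returns list(count, next_i); count = 1 if no "(n)" follows position i-1
    if (i > n || chars[i] != "(") return(list(count = 1L, next_i = i))
    close <- NA_integer_
    for (j in seq(i + 1L, length.out = n - i)) {
      if (chars[j] == ")") { close <- j; break }
    }
    if (is.na(close))
      stop(sprintf("unbalanced repeat parenthesis at position %d", i))
    inner <- paste(chars[seq(i + 1L, close - 1L)], collapse = "")
    if (grepl(",", inner, fixed = TRUE))
      stop(sprintf(
        "variable-length repeat '(%s)' at position %d is not supported",
        inner, i))
    if (!grepl("^[0-9]+$", inner))
      stop(sprintf("malformed repeat count '(%s)' at position %d", inner, i))
    cnt <- as.integer(inner)
    if (cnt < 1L)
      stop(sprintf("repeat count must be >= 1, got '(%s)' at position %d",
                   inner, i))
    list(count = cnt, next_i = close + 1L)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") { i <- i + 1L; next }
    if (ch == "[") {
      close <- NA_integer_
      for (j in seq(i + 1L, length.out = n - i)) {
        if (chars[j] == "]") { close <- j; break }
      }
      if (is.na(close))
        stop(sprintf("unbalanced bracket at position %d", i))
      inner <- chars[seq(i + 1L, length.out = close - i - 1L)]
      if (length(inner) == 0)
        stop(sprintf("empty residue class at position %d", i))
      set <- character(0)
      for (cc in inner) {
        if (cc == .PHI) set <- c(set, phi)
        else if (cc %in% aa) set <- c(set, cc)
        else stop(sprintf("unknown character '%s' in class at position %d",
                          cc, i))
      }
      set <- sort(unique(set))
      rep_info <- read_repeat(close + 1L)
      el <- .element("class", set)
      elements <- c(elements, rep(list(el), rep_info$count))
      i <- rep_info$next_i
      next
    }
    if (ch == "]")
      stop(sprintf("unbalanced bracket at position %d", i))
    if (ch == "X") {
      rep_info <- read_repeat(i + 1L)
      elements <- c(elements, rep(list(.element("wildcard")), rep_info$count))
      i <- rep_info$next_i
      next
    }
    if (ch == .PHI) {
      rep_info <- read_repeat(i + 1L)
      el <- .element("class", sort(phi))
      elements <- c(elements, rep(list(el), rep_info$count))
      i <- rep_info$next_i
      next
    }
    if (ch %in% aa) {
      rep_info <- read_repeat(i + 1L)
      el <- .element("exact", ch)
      elements <- c(elements, rep(list(el), rep_info$count))
      i <- rep_info$next_i
      next
    }
    stop(sprintf("unknown character '%s' at position %d", ch, i))
  }

  new("MotifPattern", elements = elements, source = src)
}

#' Span of a compiled pattern
#'
#' Number of residues any match occupies (repeats already expanded).
#'
#' @param pattern a [MotifPattern-class].
#' @return Integer span; 0 for an empty pattern.
#' @export
setGeneric("minSpan", function(pattern) standardGeneric("minSpan"))

#' @rdname minSpan
#' @export
setMethod("minSpan", "MotifPattern", function(pattern) {
  length(pattern@elements)
})

#' Render a compiled pattern back to text
#'
#' Produces canonical pattern text: exact residues as letters, classes as
#' sorted brackets, wildcards as \code{X} with runs collapsed to
#' \code{X(n)}, hyphen-joined. Compiling the rendered text yields a pattern
#' matching the same sequence set as the original.
#'
#' @param pattern a [MotifPattern-class].
#' @return Pattern text string.
#' @export
renderPattern <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  els <- pattern@elements
  if (length(els) == 0) return("")
  toks <- character(0)
  i <- 1L
  while (i <= length(els)) {
    el <- els[[i]]
    if (el$kind == "wildcard") {
      run <- 1L
      while (i + run <= length(els) && els[[i + run]]$kind == "wildcard")
        run <- run + 1L
      toks <- c(toks, if (run == 1L) "X" else sprintf("X(%d)", run))
      i <- i + run
    } else if (el$kind == "exact") {
      toks <- c(toks, el$residues)
      i <- i + 1L
    } else {
      toks <- c(toks, paste0("[", paste(sort(el$residues), collapse = ""), "]"))
      i <- i + 1L
    }
  }
  paste(toks, collapse = "-")
}

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern of span %d: %s\n",
              minSpan(object), renderPattern(object)))
})

#' Scan a protein sequence for a motif pattern
#'
#' Reports every (possibly overlapping) occurrence of a fixed-span pattern,
#' in ascending start order. Matching is positional: residue \code{s[i+j-1]}
#' must be allowed by pattern element \code{j}. Letters outside the 20-letter
#' alphabet never satisfy an exact or class element; whether they satisfy a
#' wildcard, and whether they are an error at all, is controlled by
#' \code{unknown}.
#'
#' @param sequence amino-acid string.
#' @param pattern a [MotifPattern-class]; must be non-empty.
#' @param unknown \code{"never-match"} (default): non-standard letters are
#'   tolerated but fail every class/exact element; \code{"error"}: reject the
#'   sequence; \code{"wildcard"}: non-standard letters additionally satisfy
#'   wildcard elements.
#' @return \code{data.frame} with columns \code{start}, \code{end} (1-based,
#'   inclusive) and \code{match} (the matched subsequence). Zero rows when
#'   nothing matches.
#' @examples
#' wa <- parsePattern("G-XX-[GA]-X-G-K-[ST]")
#' scanMotif("GPSGAGKST", wa)
#' @export
scanMotif <- function(sequence, pattern,
                      unknown = c("never-match", "error", "wildcard")) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  stopifnot(is(pattern, "MotifPattern"))
  unknown <- match.arg(unknown)
  k <- minSpan(pattern)
  if (k == 0L) stop("cannot scan with an empty pattern")
  empty <- data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < k) return(empty)
  known <- chars %in% aminoAcids()
  if (unknown == "error" && !all(known))
    stop(sprintf("sequence contains non-standard letter '%s'",
                 chars[which(!known)[1]]))
  cand <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    el <- pattern@elements[[j]]
    okj <- if (el$kind == "wildcard") {
      if (unknown == "wildcard") rep(TRUE, n) else known
    } else {
      chars %in% el$residues
    }
    cand <- cand & okj[j:(j + n - k)]
    if (!any(cand)) return(empty)
  }
  starts <- which(cand)
  data.frame(
    start = starts,
    end = starts + k - 1L,
    match = vapply(starts, function(s)
      paste(chars[s:(s + k - 1L)], collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}

#' Does a sequence match a pattern exactly end-to-end?
#'
#' @param sequence amino-acid string whose length equals the pattern span.
#' @param pattern a [MotifPattern-class].
#' @return Logical scalar.
#' @export
matchesPattern <- function(sequence, pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  if (nchar(sequence) != minSpan(pattern)) return(FALSE)
  hits <- scanMotif(sequence, pattern)
  nrow(hits) == 1 && hits$start[1] == 1L
}

#' Built-in NBD motif pattern set
#'
#' The six shipped nucleotide-binding-domain patterns: the generalized
#' Walker A, ATP-binding (C-loop/signature) and Walker B consensi derived
#' from fungal ABC-transporter NBD alignments, plus the three classical
#' literature motifs they generalize. Phi denotes the hydrophobic class
#' (see [hydrophobicResidues()]).
#'
#' @param which \code{"novel"}, \code{"classic"} or \code{"all"}.
#' @param phi hydrophobic set used when compiling.
#' @return Named list of [MotifPattern-class] objects.
#' @export
nbdPatterns <- function(which = c("novel", "classic", "all"),
                        phi = hydrophobicResidues()) {
  which <- match.arg(which)
  novel <- c(
    walkerA = "G-XX-[GA]-X-G-K-[ST]",
    cLoop   = paste0("[LIVMFYC]-S-[SGQDEVAHL]-G-X(3)-[RKALV]-",
                     "[LIVMYATC]-X-[LIVMF]-[AGCT]"),
    walkerB = paste0("[", .PHI, "HY]-[", .PHI, "CY]-[", .PHI, "C]-[",
                     .PHI, "CT]-[D]-[DEI]"))
  classic <- c(
    walkerA_classic = "G-X(4)-G-K-[ST]",
    cLoop_classic   = "[LIVMFY]-S-[SG]-G-X(3)-[RKA]-[LIVMYA]-X-[LIVMF]-[AG]",
    walkerB_classic = paste0("[", .PHI, "](4)-[D]"))
  sel <- switch(which, novel = novel, classic = classic,
                all = c(novel, classic))
  lapply(sel, parsePattern, phi = phi)
}

#' Read a motif pattern TSV
#'
#' Two-column tab-separated file: \code{motif_name}, \code{pattern_text}.
#'
#' @param path file path.
#' @param phi hydrophobic set used when compiling.
#' @return Named list of [MotifPattern-class] objects.
#' @export
readPatternTable <- function(path, phi = hydrophobicResidues()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("motif_name", "pattern_text") %in% names(tab)))
  pats <- lapply(tab$pattern_text, parsePattern, phi = phi)
  names(pats) <- tab$motif_name
  pats
}
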