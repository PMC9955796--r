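#' Conserved-domain arrangement string
#'
#' Joins ordered conserved-domain superfamily labels into the hyphenated
#' arrangement string used for structural typing. Labels are restricted to
#' the five-letter alphabet A--E: A = ABC-membrane, B = ABC-ATPase,
#' C = ABC2-membrane, D = ABC-tran-2, E = acyl-transfer-3 superfamily.
#'
#' @param labels character vector of domain labels in N-to-C order.
#' @return Hyphen-joined arrangement string, e.g. \code{"A-B-A-B"}.
#' @export
arrangementString <- function(labels) {
  if (length(labels) == 0) stop("empty domain label list")
  if (!all(labels %in% c("A", "B", "C", "D", "E")))
    stop("domain labels must be in the A-E alphabet")
  paste(labels, collapse = "-")
}

#' Default structural-type rule set
#'
#' Maps conserved-domain arrangement strings (with an optional multidomain
#' family constraint) to the six structural types, and types to functional
#' roles. Types 1--4 are transmembrane transporters; types 5--6 regulate
#' translation. The \code{"A-B"} arrangement is ambiguous between a full
#' transporter half (type 1, ATM1) and a half-size transporter (type 2,
#' ATM1/MdlB/3a0123): by default it resolves to type 2, and a per-record
#' full-transporter flag promotes ATM1 members to type 1.
#'
#' @return List with \code{rules} (data.frame: arrangement, family or NA,
#'   type) applied top-down first-match, and \code{roles} (type -> role).
#' @export
arrangementRules <- function() {
  rules <- data.frame(
    arrangement = c("A-B-A-B",
                    "A-B",
                    "B-C-B", "B-E-B",
                    "B-C-B-C", "B-C",
                    "B-B", "B-B-B",
                    "B-D-B", "B-B-D-B"),
    family = NA_character_,
    type = c(1L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L),
    stringsAsFactors = FALSE)
  roles <- c(`1` = "transport", `2` = "transport", `3` = "transport",
             `4` = "transport", `5` = "translation", `6` = "translation")
  list(rules = rules, roles = roles)
}

#' Assign a structural type from an arrangement string
#'
#' Deterministic first-match application of the rule set. Unknown
#' arrangements give \code{NA} (unclassified).
#'
#' @param arrangement arrangement string over the A--E alphabet.
#' @param family optional multidomain family label.
#' @param full_transporter logical; when TRUE and \code{family == "ATM1"},
#'   an \code{"A-B"} arrangement is promoted from type 2 to type 1.
#' @param rules rule set from [arrangementRules()].
#' @return Integer type in 1..6, or \code{NA} if unclassified.
#' @examples
#' assignStructuralType("A-B-A-B", "MRP")   # 1
#' assignStructuralType("B-B", "Uup")       # 5
#' @export
assignStructuralType <- function(arrangement, family = NA_character_,
                                 full_transporter = FALSE,
                                 rules = arrangementRules()) {
  stopifnot(length(arrangement) == 1)
  if (arrangement == "A-B" && isTRUE(full_transporter) &&
      !is.na(family) && family == "ATM1")
    return(1L)
  tab <- rules$rules
  for (i in seq_len(nrow(tab))) {
    if (tab$arrangement[i] != arrangement) next
    if (!is.na(tab$family[i]) && (is.na(family) || tab$family[i] != family))
      next
    return(tab$type[i])
  }
  NA_integer_
}

#' Functional role of a structural type
#'
#' Types 1--4 are involved in transmembrane transport; types 5--6 in
#' translational regulation.
#'
#' @param type integer structural type.
#' @param rules rule set from [arrangementRules()].
#' @return \code{"transport"} or \code{"translation"}.
#' @export
functionalCategory <- function(type, rules = arrangementRules()) {
  if (is.na(type) || !as.character(type) %in% names(rules$roles))
    stop(sprintf("no functional role for type '%s'", type))
  unname(rules$roles[[as.character(type)]])
}

#' Summarize an ABC cohort registry
#'
#' Produces the family-level descriptors of a cohort: per-family counts,
#' per-structural-type counts, the percentage of proteins in types 1--2,
#' the intron-count distribution (with the conventional 0/1/2/3/">4"
#' binning and percentages), and the acidic/basic isoelectric-point split
#' (acidic pI < 7, basic pI > 7, pI = 7 neutral).
#'
#' @param records \code{data.frame} with columns \code{family},
#'   \code{structural_type}, \code{intron_count}, \code{pI} (extra columns
#'   ignored). Zero rows allowed.
#' @return List with \code{n}, \code{family_counts}, \code{type_counts},
#'   \code{type12_share_pct}, \code{intron_distribution} (data.frame bin /
#'   count / pct), \code{pi_counts} (acidic/basic/neutral).
#' @export
cohortSummary <- function(records) {
  needed <- c("family", "structural_type", "intron_count", "pI")
  stopifnot(all(needed %in% names(records)))
  n <- nrow(records)
  fam <- if (n) table(records$family) else table(character(0))
  typ <- if (n) table(factor(records$structural_type, levels = 1:6))
         else table(factor(integer(0), levels = 1:6))
  share <- if (n) 100 * sum(records$structural_type %in% c(1L, 2L)) / n else 0
  bins <- c("0", "1", "2", "3", ">4")
  ic <- records$intron_count
  cnt <- c(sum(ic == 0), sum(ic == 1), sum(ic == 2), sum(ic == 3),
           sum(ic > 4))
  intron <- data.frame(
    bin = bins, count = cnt,
    pct = if (n) round(100 * cnt / n) else rep(0, 5),
    stringsAsFactors = FALSE)
  pic <- c(acidic = sum(records$pI < 7), basic = sum(records$pI > 7),
           neutral = sum(records$pI == 7))
  list(n = n,
       family_counts = fam,
       type_counts = typ,
       type12_share_pct = share,
       intron_distribution = intron,
       pi_counts = pic)
}
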