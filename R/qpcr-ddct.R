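#' CtTable: qPCR cycle-threshold records with reference genes
#'
#' Holds raw Ct values for a control-vs-treatment time-course experiment
#' together with the designated reference genes and the calibrator
#' timepoint. Ct records are long-format: one row per (gene, condition,
#' timepoint, replicate).
#'
#' @slot data \code{data.frame} with columns \code{gene}, \code{condition}
#'   (\code{"control"} / \code{"treatment"}), \code{timepoint} (hours),
#'   \code{replicate}, \code{ct} (> 0).
#' @slot refGenes character; reference (housekeeping) genes, e.g. actin,
#'   alpha-tubulin, beta-tubulin. Must be measured in every sample.
#' @slot calibratorTimepoint timepoint used as the within-condition
#'   calibrator (default 0 h).
#' @export
setClass("CtTable",
  representation(data = "data.frame", refGenes = "character",
                 calibratorTimepoint = "numeric"))

setValidity("CtTable", function(object) {
  d <- object@data
  needed <- c("gene", "condition", "timepoint", "replicate", "ct")
  if (!all(needed %in% names(d)))
    return(paste("data must have columns:", paste(needed, collapse = ", ")))
  if (any(d$ct <= 0)) return("all Ct values must be > 0")
  if (length(object@refGenes) == 0) return("at least one reference gene")
  if (!all(object@refGenes %in% d$gene))
    return("every reference gene must appear in the data")
  samples <- unique(d[, c("condition", "timepoint", "replicate")])
  for (i in seq_len(nrow(samples))) {
    sel <- d$condition == samples$condition[i] &
      d$timepoint == samples$timepoint[i] &
      d$replicate == samples$replicate[i]
    if (!all(object@refGenes %in% d$gene[sel]))
      return(sprintf(
        "missing reference gene in sample condition=%s, timepoint=%s, replicate=%s",
        samples$condition[i], samples$timepoint[i], samples$replicate[i]))
  }
  TRUE
})

#' Construct a CtTable
#'
#' @param data long-format Ct \code{data.frame} (see [CtTable-class]).
#' @param ref_genes reference gene names.
#' @param calibrator_timepoint within-condition calibrator timepoint
#'   (default 0 h).
#' @return A [CtTable-class] object.
#' @export
ctTable <- function(data, ref_genes, calibrator_timepoint = 0) {
  new("CtTable", data = as.data.frame(data), refGenes = ref_genes,
      calibratorTimepoint = calibrator_timepoint)
}

#' @describeIn ctTable Ct records accessor.
#' @param x a [CtTable-class].
#' @export
ctData <- function(x) x@data

#' @describeIn ctTable reference-gene accessor.
#' @export
refGenes <- function(x) x@refGenes

setMethod("show", "CtTable", function(object) {
  d <- object@data
  cat(sprintf(
    "CtTable: %d records, %d target gene(s), %d reference gene(s)\n",
    nrow(d), length(setdiff(unique(d$gene), object@refGenes)),
    length(object@refGenes)))
  cat(sprintf("  conditions: %s; timepoints (h): %s; calibrator: %s h\n",
              paste(unique(d$condition), collapse = ", "),
              paste(sort(unique(d$timepoint)), collapse = ", "),
              object@calibratorTimepoint))
})

#' Per-sample delta-Ct normalization
#'
#' For every sample (condition, timepoint, replicate), subtracts the
#' arithmetic mean of the reference-gene Ct values in that same sample from
#' each target gene's Ct. Averaging reference Ct values arithmetically is
#' equivalent to normalizing by the geometric mean of the reference
#' quantities. Adding a constant to every Ct in a sample leaves the result
#' unchanged.
#'
#' @param table a [CtTable-class].
#' @return \code{data.frame}: gene, condition, timepoint, replicate,
#'   delta_ct (target genes only).
#' @export
normalizeCt <- function(table) {
  stopifnot(is(table, "CtTable"))
  d <- table@data
  refs <- table@refGenes
  key <- interaction(d$condition, d$timepoint, d$replicate, drop = TRUE)
  out <- lapply(split(seq_len(nrow(d)), key), function(ii) {
    sub <- d[ii, ]
    ref_ct <- sub$ct[sub$gene %in% refs]
    ref_mean <- mean(ref_ct)
    tgt <- sub[!sub$gene %in% refs, ]
    data.frame(gene = tgt$gene, condition = tgt$condition,
               timepoint = tgt$timepoint, replicate = tgt$replicate,
               delta_ct = tgt$ct - ref_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene, out$condition, out$timepoint, out$replicate), ]
}

.ddct_replicates <- function(dct, gene, condition, timepoint, calib_tp) {
  here <- dct$gene == gene & dct$condition == condition &
    dct$timepoint == timepoint
  cal <- dct$gene == gene & dct$condition == condition &
    dct$timepoint == calib_tp
  if (!any(cal))
    stop(sprintf("no calibrator sample (timepoint %s h) for gene '%s', %s",
                 calib_tp, gene, condition))
  if (!any(here))
    stop(sprintf("no Ct records for gene '%s', %s at %s h",
                 gene, condition, timepoint))
  dct$delta_ct[here] - mean(dct$delta_ct[cal])
}

#' Relative quantification by the 2^-ddCt method
#'
#' Computes per-replicate ddCt = delta-Ct(sample) minus the mean delta-Ct
#' of the calibrator (by default, the same condition at the calibrator
#' timepoint, i.e. each condition's own 0-h sample), and reports the mean
#' -ddCt (a log2 fold change), its replicate SD, the fold change
#' \code{2^-ddCt}, and a two-sided p value for the contrast against the
#' other condition at the same timepoint (NA when only one condition is
#' present). The p value is computed on the replicate delta-Ct values of
#' the two conditions, not on ddCt replicates: within a condition every
#' ddCt replicate shares the same noisy calibrator mean, so testing ddCt
#' replicates would be anticonservative, while delta-Ct replicates are
#' independent between conditions and test the same contrast.
#'
#' @param table a [CtTable-class].
#' @param gene target gene.
#' @param timepoint timepoint (hours).
#' @param condition condition to quantify (default \code{"treatment"}).
#' @param var_equal pooled-variance t-test if TRUE (default), Welch
#'   otherwise.
#' @return One-row \code{data.frame}: gene, condition, timepoint,
#'   minus_ddct (mean log2 fold change), sd, fold, p_vs_other, stars.
#' @export
foldChange <- function(table, gene, timepoint, condition = "treatment",
                       var_equal = TRUE) {
  stopifnot(is(table, "CtTable"))
  dct <- normalizeCt(table)
  calib_tp <- table@calibratorTimepoint
  mdd <- -.ddct_replicates(dct, gene, condition, timepoint, calib_tp)
  other <- setdiff(unique(dct$condition), condition)
  p <- NA_real_
  if (length(other) == 1) {
    a <- dct$delta_ct[dct$gene == gene & dct$condition == condition &
                        dct$timepoint == timepoint]
    b <- dct$delta_ct[dct$gene == gene & dct$condition == other &
                        dct$timepoint == timepoint]
    if (length(a) >= 2 && length(b) >= 2)
      p <- ctTTest(-a, -b, var_equal = var_equal)$p.value
  }
  data.frame(gene = gene, condition = condition, timepoint = timepoint,
             minus_ddct = mean(mdd), sd = stats::sd(mdd),
             fold = 2^mean(mdd), p_vs_other = p,
             stars = significanceStars(p), stringsAsFactors = FALSE)
}

#' Fold changes for every target gene, condition and timepoint
#'
#' @param table a [CtTable-class].
#' @param var_equal see [foldChange()].
#' @return \code{data.frame} with one [foldChange()] row per combination.
#' @export
foldChangeTable <- function(table, var_equal = TRUE) {
  d <- table@data
  targets <- setdiff(unique(d$gene), table@refGenes)
  combos <- unique(d[d$gene %in% targets,
                     c("gene", "condition", "timepoint")])
  rows <- lapply(seq_len(nrow(combos)), function(i)
    foldChange(table, combos$gene[i], combos$timepoint[i],
               combos$condition[i], var_equal = var_equal))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene, out$condition, out$timepoint), ]
}

#' Treatment-minus-control differential expression
#'
#' Differential log2 expression per gene and timepoint: the treatment
#' mean -ddCt minus the control mean -ddCt (both against their own
#' condition's calibrator), with the treatment-vs-control p value.
#'
#' @param table a [CtTable-class].
#' @param var_equal see [foldChange()].
#' @return \code{data.frame}: gene, timepoint, diff_log2, p, stars.
#' @export
diffExpression <- function(table, var_equal = TRUE) {
  fc <- foldChangeTable(table, var_equal = var_equal)
  tr <- fc[fc$condition == "treatment", ]
  co <- fc[fc$condition == "control", ]
  merged <- merge(tr, co, by = c("gene", "timepoint"),
                  suffixes = c("_treat", "_ctrl"))
  out <- data.frame(gene = merged$gene, timepoint = merged$timepoint,
                    diff_log2 = merged$minus_ddct_treat -
                      merged$minus_ddct_ctrl,
                    p = merged$p_vs_other_treat,
                    stars = merged$stars_treat, stringsAsFactors = FALSE)
  out[order(out$gene, out$timepoint), ]
}

#' Independent two-sample t-test with degenerate-data convention
#'
#' Pooled-variance two-sample t-test (Welch with
#' \code{var_equal = FALSE}). When both groups have zero variance and
#' equal means the statistic is defined as 0 with p = 1; zero variance
#' with different means gives p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return List with \code{statistic} and \code{p.value}.
#' @export
ctTTest <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p.value = 1))
    return(list(statistic = Inf * sign(mean(a) - mean(b)), p.value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Significance stars
#'
#' \code{p < 0.01} gives \code{"**"}, \code{p < 0.05} gives \code{"*"},
#' otherwise an empty string (NA p gives \code{NA}).
#'
#' @param p p value (vectorized).
#' @return Character vector of star strings.
#' @export
significanceStars <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  out
}
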