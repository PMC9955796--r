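#' RPKM from raw read counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \code{RPKM[g, s] = C[g, s] * 1e9 / (N[s] * L[g])}. The mapped-read
#' totals \code{N} are an explicit input (total mapped reads of each
#' library), never recomputed from the column sums.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param lengths per-gene transcript length in bp (> 0), in row order.
#' @param mapped per-sample total mapped reads (> 0), in column order.
#' @return Numeric matrix of RPKM values, same dimnames as \code{counts}.
#' @examples
#' rpkmMatrix(matrix(10), lengths = 1000, mapped = 1e6)  # 10
#' @export
rpkmMatrix <- function(counts, lengths, mapped) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts),
            length(mapped) == ncol(counts))
  if (any(counts < 0)) stop("negative counts")
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (any(mapped <= 0)) stop("mapped-read totals must be > 0")
  r <- counts * 1e9 / outer(lengths, mapped)
  dimnames(r) <- dimnames(counts)
  r
}

#' Log2 transform of an expression matrix
#'
#' \code{log2(x + offset)}. The offset defaults to 1 because real count
#' data contain zeros; an offset of 0 is only legal when the matrix is
#' strictly positive.
#'
#' @param expr non-negative numeric matrix (e.g. RPKM).
#' @param offset added before taking logs.
#' @return Matrix of \code{log2(expr + offset)}.
#' @export
log2Matrix <- function(expr, offset = 1) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression values must be >= 0")
  if (offset <= 0 && any(expr == 0))
    stop("offset must be > 0 when zero expression values are present")
  log2(expr + offset)
}

#' Hierarchical clustering of genes by expression profile
#'
#' Agglomerative clustering of gene rows with Euclidean distance and
#' complete linkage -- the standard \code{dist} + \code{hclust} procedure
#' behind expression heatmaps. Under complete linkage, merge heights are
#' non-decreasing and each merge height equals the maximum pairwise
#' distance between the two merged clusters.
#'
#' @param mat genes x conditions numeric matrix; >= 2 rows, no missing
#'   values.
#' @return An \code{stats::hclust} object (merge list, heights, leaf
#'   order).
#' @export
clusterGenes <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least two genes to cluster")
  if (any(!is.finite(mat))) stop("matrix contains missing/non-finite values")
  stats::hclust(stats::dist(mat, method = "euclidean"), method = "complete")
}

#' Flag highly expressed genes
#'
#' Marks each gene, per condition, as highly expressed under one of two
#' rules: \code{quantile} (expression at or above the given quantile of
#' that condition's values; default upper quartile) or \code{absolute}
#' (expression at or above a fixed cutoff). A gene is "high overall" when
#' flagged in at least one condition; the rollup counts high-overall genes
#' within each functional category when a category map is supplied.
#'
#' @param expr genes x conditions expression matrix (RPKM scale).
#' @param rule list: \code{type} = \code{"quantile"} with \code{q} in
#'   (0, 1), or \code{"absolute"} with \code{cutoff}.
#' @param category optional named character vector gene -> functional
#'   category (e.g. transport / translation).
#' @return List: \code{flags} (logical matrix), \code{high_any} (named
#'   logical), \code{rollup} (per-category data.frame: n high / n total,
#'   NULL without a category map).
#' @export
flagHigh <- function(expr, rule = list(type = "quantile", q = 0.75),
                     category = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rule$type)) stop("rule must carry a 'type'")
  flags <- switch(rule$type,
    quantile = {
      if (is.null(rule$q) || rule$q <= 0 || rule$q >= 1)
        stop("quantile rule needs q in (0, 1)")
      thr <- apply(expr, 2, stats::quantile, probs = rule$q)
      sweep(expr, 2, thr, ">=")
    },
    absolute = {
      if (is.null(rule$cutoff)) stop("absolute rule needs a cutoff")
      expr >= rule$cutoff
    },
    stop(sprintf("unknown flagging rule '%s'", rule$type)))
  high_any <- apply(flags, 1, any)
  rollup <- NULL
  if (!is.null(category)) {
    missing <- setdiff(rownames(expr), names(category))
    if (length(missing))
      stop(sprintf("gene '%s' has no functional category", missing[1]))
    cat_vec <- category[rownames(expr)]
    rollup <- do.call(rbind, lapply(split(names(cat_vec), cat_vec),
      function(gg) data.frame(n_high = sum(high_any[gg]),
                              n_total = length(gg))))
    rollup <- cbind(data.frame(category = rownames(rollup),
                               stringsAsFactors = FALSE), rollup)
    rownames(rollup) <- NULL
  }
  list(flags = flags, high_any = high_any, rollup = rollup)
}
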