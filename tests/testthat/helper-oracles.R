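# Independent oracles used across the suite. These deliberately do NOT
# share code with the package: the regex oracle translates pattern TEXT
# straight to a PCRE, and the clustering oracle is a brute-force O(n^3)
# agglomerator.

PHI_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")
AA_STR <- "ACDEFGHIKLMNPQRSTVWY"

# the six shipped NBD pattern texts (Phi written as Φ)
nbd_pattern_texts <- c(
  walkerA = "G-XX-[GA]-X-G-K-[ST]",
  cLoop = "[LIVMFYC]-S-[SGQDEVAHL]-G-X(3)-[RKALV]-[LIVMYATC]-X-[LIVMF]-[AGCT]",
  walkerB = "[ΦHY]-[ΦCY]-[ΦC]-[ΦCT]-[D]-[DEI]",
  walkerA_classic = "G-X(4)-G-K-[ST]",
  cLoop_classic = "[LIVMFY]-S-[SG]-G-X(3)-[RKA]-[LIVMYA]-X-[LIVMF]-[AG]",
  walkerB_classic = "[Φ](4)-[D]")

# translate pattern text to an overlapping-match PCRE, independently of
# the package's compiler
oracle_regex <- function(text, phi = PHI_SET) {
  tok_re <- paste0("\\[[^]]+\\]|\\([0-9]+\\)|X|", "Φ", "|[A-Z]|-")
  toks <- regmatches(text, gregexpr(tok_re, text))[[1]]
  pieces <- character(0)
  for (tk in toks) {
    if (tk == "-") next
    if (grepl("^\\(", tk)) {
      n <- as.integer(sub("^\\(([0-9]+)\\)$", "\\1", tk))
      pieces <- c(pieces, rep(pieces[length(pieces)], n - 1))
    } else if (tk == "X") {
      pieces <- c(pieces, paste0("[", AA_STR, "]"))
    } else if (tk == "Φ") {
      pieces <- c(pieces, paste0("[", paste(phi, collapse = ""), "]"))
    } else if (grepl("^\\[", tk)) {
      inner <- strsplit(substr(tk, 2, nchar(tk) - 1), "")[[1]]
      set <- unique(unlist(lapply(inner, function(cc)
        if (cc == "Φ") phi else cc)))
      pieces <- c(pieces, paste0("[", paste(set, collapse = ""), "]"))
    } else {
      pieces <- c(pieces, tk)
    }
  }
  paste0("(?=", paste(pieces, collapse = ""), ")")
}

oracle_scan_starts <- function(sequence, regex) {
  m <- gregexpr(regex, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

random_aa <- function(n) {
  paste(sample(strsplit(AA_STR, "")[[1]], n, replace = TRUE), collapse = "")
}

# brute-force complete-linkage agglomeration; returns merge heights and
# the partition (set of sorted index vectors) after every merge
oracle_complete_linkage <- function(mat) {
  D <- as.matrix(dist(mat))
  n <- nrow(mat)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best_h <- Inf; best <- c(NA, NA)
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_h)
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

hclust_partitions <- function(h, n) {
  lapply(seq_len(n - 1), function(step) {
    memb <- stats::cutree(h, k = n - step)
    unname(split(seq_len(n), memb))
  })
}
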