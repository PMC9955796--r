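#' @importFrom stats rnorm runif rnbinom setNames quantile sd
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  force(expr)
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

# One concrete instance of a compiled pattern (uniform over element sets).
.sample_pattern_instance <- function(pattern) {
  aa <- aminoAcids()
  paste(vapply(pattern@elements, function(el) {
    if (el$kind == "wildcard") .sample1(aa) else .sample1(el$residues)
  }, character(1)), collapse = "")
}

.random_protein <- function(n) {
  paste(sample(aminoAcids(), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic ABC-protein cohort with planted NBD triplets
#'
#' Builds one protein per cohort record, planting as many Walker A /
#' C-loop / Walker B triplets as the record's arrangement has ABC-ATPase
#' (B) domains; with the default registry the cohort carries 79 NBDs over
#' 44 proteins (35 proteins with two triplets, 9 with one). Motif
#' instances are sampled uniformly from the pattern element sets, gaps are
#' drawn inside the spacing windows, and the background is i.i.d. over the
#' 20-letter alphabet. Each protein is screened: it is regenerated until
#' [findNbds()] recovers exactly the planted triplets at the planted
#' coordinates, so accidental motif assemblies never survive.
#'
#' @param registry cohort registry \code{data.frame} (default:
#'   [genCohortRegistry()] at the same seed); needs columns \code{id},
#'   \code{arrangement}.
#' @param seed RNG seed.
#' @param patterns motif patterns as in [findNbds()].
#' @param spacing spacing windows from [nbdSpacing()].
#' @param protein_length optional forced protein length; an error if
#'   shorter than the planted layout requires.
#' @param max_retries per-protein regeneration cap.
#' @return List: \code{sequences} (named character vector) and
#'   \code{ledger} (\code{data.frame}: protein_id, nbd_index, the three
#'   planted motif starts and instances).
#' @export
genProteins <- function(registry = NULL, seed = 1,
                        patterns = nbdPatterns("novel"),
                        spacing = nbdSpacing(),
                        protein_length = NULL, max_retries = 100) {
  if (is.null(registry)) registry <- genCohortRegistry(seed)$registry
  n_trip <- vapply(strsplit(registry$arrangement, "-"),
                   function(x) sum(x == "B"), integer(1))
  .with_seed(seed, {
    seqs <- character(0)
    ledger <- NULL
    for (i in seq_len(nrow(registry))) {
      id <- registry$id[i]
      k <- n_trip[i]
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        parts <- .random_protein(120L)
        rows <- NULL
        for (t in seq_len(k)) {
          a_inst <- .sample_pattern_instance(patterns$walkerA)
          c_inst <- .sample_pattern_instance(patterns$cLoop)
          b_inst <- .sample_pattern_instance(patterns$walkerB)
          gap1 <- sample(seq(spacing$cloop_gap[1] + 10L,
                             spacing$cloop_gap[2] - 50L), 1L)
          gap2 <- sample(seq(spacing$walkerb_gap[1] + 5L,
                             spacing$walkerb_gap[2] - 20L), 1L)
          a_start <- nchar(parts) + 1L
          c_start <- a_start + nchar(a_inst) + gap1
          b_start <- c_start + nchar(c_inst) + gap2
          parts <- paste0(parts, a_inst, .random_protein(gap1), c_inst,
                          .random_protein(gap2), b_inst,
                          .random_protein(220L))
          rows <- rbind(rows, data.frame(
            protein_id = id, nbd_index = t,
            walkerA_start = a_start, walkerA_inst = a_inst,
            cloop_start = c_start, cloop_inst = c_inst,
            walkerB_start = b_start, walkerB_inst = b_inst,
            stringsAsFactors = FALSE))
        }
        parts <- paste0(parts, .random_protein(50L))
        if (!is.null(protein_length)) {
          if (nchar(parts) > protein_length)
            stop(sprintf(
              "protein '%s' too short for %d planted triplet(s): need %d, have %d",
              id, k, nchar(parts), protein_length))
          parts <- paste0(parts,
                          .random_protein(protein_length - nchar(parts)))
        }
        hits <- findNbds(parts, patterns, spacing)
        if (nrow(hits) == k &&
            all(hits$walkerA_start == rows$walkerA_start) &&
            all(hits$cloop_start == rows$cloop_start) &&
            all(hits$walkerB_start == rows$walkerB_start)) {
          ok <- TRUE
          seqs[id] <- parts
          ledger <- rbind(ledger, rows)
          break
        }
      }
      if (!ok)
        stop(sprintf("could not place clean triplets in '%s' after %d tries",
                     id, max_retries))
    }
    list(sequences = seqs, ledger = ledger)
  })
}

.instantiate_constraints <- function(constraint) {
  vapply(constraint, function(cc) .sample1(.IUPAC_DNA[[cc]]), character(1),
         USE.NAMES = FALSE)
}

#' Generate synthetic promoters with planted cis-regulatory sites
#'
#' Builds fixed-length upstream regions with i.i.d. ACGT background and a
#' per-gene number of planted, non-overlapping motif sites drawn from the
#' dictionary (weighted sampling; each site on the forward strand with
#' probability \code{1 - rev_prob}). Every promoter is screened by local
#' resampling: any match of any dictionary consensus, on either scan
#' direction, that is not one of the planted sites has its footprint
#' redrawn (respecting planted-site constraints) until the census equals
#' the plant exactly; a gene that cannot be cleaned is re-placed from
#' scratch, and exceeding the restart cap is an error.
#'
#' @param dict motif dictionary from [motifDictionary()].
#' @param genes gene identifiers (default ABC01..ABC44).
#' @param sites_range inclusive range of planted sites per gene.
#' @param rev_prob probability a site is planted on the reverse strand.
#' @param weights optional per-motif sampling weights (named, defaults to
#'   favouring GCN4, GCR1 and ADR1 where present).
#' @param length promoter length in bp.
#' @param seed RNG seed.
#' @param max_iter screening iterations per attempt.
#' @param max_restarts per-gene re-placement cap.
#' @return List: \code{promoters} (named character), \code{sites}
#'   (\code{data.frame}: gene, name, offset, strand), \code{expected_both}
#'   and \code{expected_forward} (gene x motif expected-count matrices for
#'   double- and single-strand censuses).
#' @export
genPromoters <- function(dict = motifDictionary(),
                         genes = sprintf("ABC%02d", 1:44),
                         sites_range = c(9L, 32L), rev_prob = 0.3,
                         weights = NULL, length = 1000L, seed = 1,
                         max_iter = 400, max_restarts = 25) {
  max_len <- max(nchar(dict$consensus))
  if (length < max_len) stop("promoter length shorter than longest consensus")
  if (is.null(weights)) {
    weights <- setNames(rep(1, nrow(dict)), dict$name)
    for (nm in intersect(c("GCN4", "GCR1", "ADR1"), dict$name))
      weights[nm] <- c(GCN4 = 8, GCR1 = 5, ADR1 = 4)[[nm]]
  }
  fwd <- lapply(dict$consensus, compileIupac)
  rc_str <- vapply(dict$consensus, function(cs)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cs))),
    character(1), USE.NAMES = FALSE)
  rev <- lapply(rc_str, compileIupac)
  # a self-reverse-complement consensus (e.g. GAANNTTC) matches both scan
  # directions at every planted site; the ledger must expect that
  self_rc <- toupper(dict$consensus) == rc_str
  .with_seed(seed, {
    promoters <- character(0)
    all_sites <- NULL
    for (g in genes) {
      # target double-strand census total; palindromic sites contribute 2
      n_target <- sample(seq(sites_range[1], sites_range[2]), 1L)
      done <- FALSE
      for (restart in seq_len(max_restarts)) {
        # lay out non-overlapping planted sites as IUPAC constraints
        constraint <- rep("N", length)
        occupied <- rep(FALSE, length)
        sites <- NULL
        feasible <- TRUE
        contrib <- 0L
        while (contrib < n_target) {
          placed <- FALSE
          for (att in 1:200) {
            j <- sample.int(nrow(dict), 1L, prob = weights[dict$name])
            if (self_rc[j] && contrib + 2L > n_target) next
            w <- nchar(dict$consensus[j])
            pos <- sample.int(length - w + 1L, 1L)
            span <- pos:(pos + w - 1L)
            if (any(occupied[span])) next
            strand <- if (runif(1) < rev_prob) "-" else "+"
            cons <- dict$consensus[j]
            if (strand == "-")
              cons <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(cons)))
            constraint[span] <- strsplit(cons, "")[[1]]
            occupied[span] <- TRUE
            sites <- rbind(sites, data.frame(
              gene = g, name = dict$name[j], offset = pos, strand = strand,
              width = w, stringsAsFactors = FALSE))
            contrib <- contrib + (if (self_rc[j]) 2L else 1L)
            placed <- TRUE
            break
          }
          if (!placed) { feasible <- FALSE; break }
        }
        if (!feasible) next
        if (is.null(sites))
          sites <- data.frame(gene = character(0), name = character(0),
                              offset = integer(0), strand = character(0),
                              width = integer(0), stringsAsFactors = FALSE)
        chars <- .instantiate_constraints(constraint)
        seq_str <- paste(chars, collapse = "")
        # screen: remove accidental matches by local resampling
        clean <- FALSE
        for (it in seq_len(max_iter)) {
          extras <- NULL
          for (j in seq_len(nrow(dict))) {
            pos_f <- sites$offset[sites$name == dict$name[j] &
                                    sites$strand == "+"]
            pos_r <- sites$offset[sites$name == dict$name[j] &
                                    sites$strand == "-"]
            exp_f <- sort(if (self_rc[j]) c(pos_f, pos_r) else pos_f)
            exp_r <- sort(if (self_rc[j]) c(pos_f, pos_r) else pos_r)
            got_f <- iupacMatchStarts(seq_str, fwd[[j]])
            got_r <- iupacMatchStarts(seq_str, rev[[j]])
            w <- nchar(dict$consensus[j])
            if (!identical(got_f, exp_f) || !identical(got_r, exp_r)) {
              bad <- c(setdiff(got_f, exp_f), setdiff(got_r, exp_r))
              for (p in bad) extras <- rbind(extras, c(p, w))
            }
          }
          if (is.null(extras)) { clean <- TRUE; break }
          for (r in seq_len(nrow(extras))) {
            span <- extras[r, 1]:(extras[r, 1] + extras[r, 2] - 1L)
            chars[span] <- .instantiate_constraints(constraint[span])
          }
          seq_str <- paste(chars, collapse = "")
        }
        if (clean) {
          promoters[g] <- seq_str
          all_sites <- rbind(all_sites, sites)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop(sprintf(
          "site collision beyond retry limit for promoter '%s'", g))
    }
    expected_both <- matrix(0L, nrow = base::length(genes),
                            ncol = nrow(dict),
                            dimnames = list(genes, dict$name))
    expected_fwd <- expected_both
    if (is.null(all_sites))
      all_sites <- data.frame(gene = character(0), name = character(0),
                              offset = integer(0), strand = character(0),
                              width = integer(0), stringsAsFactors = FALSE)
    rc_of <- setNames(self_rc, dict$name)
    for (r in seq_len(nrow(all_sites))) {
      g <- all_sites$gene[r]; nm <- all_sites$name[r]
      # palindromic consensi count once per strand position
      expected_both[g, nm] <- expected_both[g, nm] +
        (if (rc_of[[nm]]) 2L else 1L)
      if (all_sites$strand[r] == "+" || rc_of[[nm]])
        expected_fwd[g, nm] <- expected_fwd[g, nm] + 1L
    }
    list(promoters = promoters,
         sites = all_sites[, c("gene", "name", "offset", "strand")],
         expected_both = expected_both,
         expected_forward = expected_fwd)
  })
}

#' Generate a synthetic read-count matrix for the expression screen
#'
#' Emulates a four-condition transcriptome screen over the cohort: counts
#' are drawn from a negative-binomial model whose per-gene, per-condition
#' mean encodes the design. Two pinned reference genes (ABC31 and ABC42,
#' gene length 1000 bp against 1e9 mapped reads) carry exact RPKM values
#' (ABC31: 8537 in MM and 59214 in PdPap; ABC42: 3957 in MM and 11790 in
#' N-hungry); 17 transport genes and 4 translation-regulating genes
#' (including the pinned pair) are designed to be highly expressed in at
#' least one condition under the upper-quartile rule, and the remaining
#' genes stay low everywhere. Draws are re-taken until the realized matrix
#' honours the design exactly, so the ledger is a strict ground truth.
#'
#' @param registry cohort registry (default [genCohortRegistry()] at the
#'   same seed).
#' @param seed RNG seed.
#' @param conditions condition (column) names.
#' @param mapped total mapped reads per condition library.
#' @param dispersion negative-binomial size parameter.
#' @param max_retries redraw cap for the design check.
#' @return List: \code{counts} (gene x condition integer matrix),
#'   \code{lengths}, \code{mapped}, and \code{ledger} with
#'   \code{high_by_condition} (designed flagged genes per condition),
#'   \code{high_any}, \code{category} (gene -> transport/translation),
#'   \code{pinned_rpkm} (the exact pinned values).
#' @export
genCounts <- function(registry = NULL, seed = 1,
                      conditions = c("MM", "C-hungry", "N-hungry", "PdPap"),
                      mapped = 1e9, dispersion = 50, max_retries = 100) {
  if (is.null(registry)) registry <- genCohortRegistry(seed)$registry
  genes <- registry$id
  category <- setNames(
    vapply(registry$structural_type, functionalCategory, character(1)),
    genes)
  pinned <- list(
    ABC31 = setNames(c(8537, 30000, 25000, 59214), conditions),
    ABC42 = setNames(c(3957, 8000, 11790, 9000), conditions))
  stopifnot(all(names(pinned) %in% genes))
  .with_seed(seed, {
    transport <- genes[category == "transport"]
    translation <- genes[category == "translation"]
    named_high <- intersect(
      c("ABC37", "ABC32", "ABC38", "ABC04", "ABC11", "ABC34", "ABC21",
        "ABC23", "ABC01", "ABC05", "ABC15", "ABC19", "ABC30"), transport)
    extra <- sample(setdiff(transport, named_high),
                    17L - length(named_high))
    high_transport <- c(named_high, extra)
    high_translation <- intersect(c("ABC29", "ABC31", "ABC35", "ABC42"),
                                  translation)
    high_all <- c(high_transport, high_translation)
    # per-condition slots: 11 flagged = 2 pinned + 9 rotating others
    others <- setdiff(high_all, names(pinned))
    slots <- lapply(conditions, function(cc) names(pinned))
    names(slots) <- conditions
    oi <- 0L
    for (ci in seq_along(conditions)) {
      for (s in 1:9) {
        oi <- oi %% length(others) + 1L
        slots[[ci]] <- c(slots[[ci]], others[oi])
      }
    }
    # ensure every high gene got at least one slot
    missing <- setdiff(high_all, unique(unlist(slots)))
    stopifnot(length(missing) == 0)
    lengths <- setNames(sample(1500:6000, length(genes), replace = TRUE),
                        genes)
    lengths[names(pinned)] <- 1000L
    design <- matrix(runif(length(genes) * length(conditions), 5, 200),
                     nrow = length(genes),
                     dimnames = list(genes, conditions))
    for (cc in conditions) {
      hi <- setdiff(slots[[cc]], names(pinned))
      design[hi, cc] <- runif(length(hi), 2000, 3400)
    }
    for (g in names(pinned)) design[g, ] <- pinned[[g]]
    mapped_vec <- setNames(rep(mapped, length(conditions)), conditions)
    mu <- design * outer(lengths, mapped_vec) / 1e9
    for (try in seq_len(max_retries)) {
      counts <- matrix(rnbinom(length(mu), mu = mu, size = dispersion),
                       nrow = nrow(mu), dimnames = dimnames(mu))
      for (g in names(pinned))
        counts[g, ] <- round(pinned[[g]] * mapped_vec * lengths[g] / 1e9)
      r <- rpkmMatrix(counts, lengths, mapped_vec)
      fl <- flagHigh(r, rule = list(type = "quantile", q = 0.75))
      ok <- all(vapply(conditions, function(cc)
        setequal(rownames(r)[fl$flags[, cc]], slots[[cc]]), logical(1)))
      overall <- sort(rowMeans(log2(r + 1)), decreasing = TRUE)
      ok <- ok && setequal(names(overall)[1:2], names(pinned))
      if (ok) break
      if (try == max_retries)
        stop("could not realize the designed high-expression sets")
    }
    list(counts = counts, lengths = lengths, mapped = mapped_vec,
         ledger = list(high_by_condition = slots,
                       high_any = sort(high_all),
                       category = category,
                       pinned_rpkm = pinned))
  })
}

#' Default planted log2-effect trajectories for the toxin-response assay
#'
#' Treatment-side -ddCt trajectories for the six assayed genes over the
#' 0/6/24/48-h series, with the peak magnitudes 3.13 (ABC01, 48 h), -0.80
#' and 0.29 (ABC02), 2.54 (ABC04, 6 h), 4.92 (ABC05, 6 h), 0.59 and
#' -1.83 (ABC30) and 5.09 (ABC31, 6 h). Control effects are 0 throughout.
#'
#' @return \code{data.frame}: gene, timepoint, effect (log2 scale,
#'   treatment condition).
#' @export
defaultCtEffects <- function() {
  tp <- c(6, 24, 48)
  data.frame(
    gene = rep(c("ABC01", "ABC02", "ABC04", "ABC05", "ABC30", "ABC31"),
               each = 3),
    timepoint = rep(tp, 6),
    effect = c(0.5, 1.5, 3.13,
               -0.80, 0.10, 0.29,
               2.54, 1.00, 0.50,
               4.92, 2.00, 1.00,
               0.59, -1.00, -1.83,
               5.09, 2.50, 1.20),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic Ct table with planted log2 effects
#'
#' Emulates a control-vs-treatment qPCR time course: reference genes sit
#' at stable baseline Ct values plus replicate noise; target genes sit at
#' a baseline minus the planted treatment effect (log2 scale, so that the
#' recovered -ddCt against the 0-h calibrator equals the planted effect
#' in expectation). Control-side effects are zero. Ct values are rounded
#' to 3 decimals for cross-platform determinism.
#'
#' @param effects planted treatment trajectories as [defaultCtEffects()];
#'   timepoint 0 is implicitly effect 0.
#' @param timepoints assay timepoints in hours (must include the 0-h
#'   calibrator).
#' @param n_reps replicates per sample.
#' @param noise_sd replicate Ct noise SD in cycles.
#' @param ref_genes reference gene names.
#' @param ref_ct baseline Ct of each reference gene.
#' @param target_base baseline Ct of target genes.
#' @param seed RNG seed.
#' @return List: \code{table} (a [CtTable-class]) and \code{ledger}
#'   (the planted effects).
#' @export
genCt <- function(effects = defaultCtEffects(),
                  timepoints = c(0, 6, 24, 48), n_reps = 3,
                  noise_sd = 0.2,
                  ref_genes = c("actin", "a-tubulin", "b-tubulin"),
                  ref_ct = c(18, 19, 20), target_base = 26, seed = 1) {
  stopifnot(0 %in% timepoints, length(ref_ct) == length(ref_genes))
  genes <- unique(effects$gene)
  .with_seed(seed, {
    rows <- list()
    for (cond in c("control", "treatment")) {
      for (tp in timepoints) {
        for (rep_i in seq_len(n_reps)) {
          ct_ref <- round(ref_ct + rnorm(length(ref_genes), 0, noise_sd), 3)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = ref_genes, condition = cond, timepoint = tp,
            replicate = rep_i, ct = ct_ref, stringsAsFactors = FALSE)
          eff <- vapply(genes, function(g) {
            if (cond != "treatment" || tp == 0) return(0)
            e <- effects$effect[effects$gene == g & effects$timepoint == tp]
            if (length(e)) e[1] else 0
          }, numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = genes, condition = cond, timepoint = tp,
            replicate = rep_i,
            ct = round(target_base - eff + rnorm(length(genes), 0, noise_sd),
                       3),
            stringsAsFactors = FALSE)
        }
      }
    }
    d <- do.call(rbind, rows)
    list(table = ctTable(d, ref_genes = ref_genes,
                         calibrator_timepoint = 0),
         ledger = effects)
  })
}

#' Generate the pinned 44-gene cohort registry
#'
#' Produces a 44-record ABC-transporter cohort whose marginals are the
#' study conditions of the package's worked examples: family counts
#' \{MRP 9, MDR 8, CFTR 6, MdlB 5, Uup 5, ATM1 4, Protein White 4,
#' Rim protein 2, 3a0123 1\}; Table-2-consistent arrangement strings
#' giving structural-type counts \{1: 27, 2: 6, 3: 2, 4: 4, 5: 2, 6: 3\}
#' (27 + 6 = 75% in types 1--2, and the two type-5 records carry only
#' ABC-ATPase domains); intron distribution \{0: 5, 1: 5, 2: 13, 3: 4,
#' more-than-4: 17\} over the range 0--15; isoelectric points spanning
#' exactly [5.48, 9.87] with 27 acidic and 17 basic; molecular weights
#' spanning exactly [55.33, 187.56] kDa; genes spread over 17 scaffolds
#' with at most 7 per scaffold. The family and type assignment of
#' individual records is one fixed consistent split (non-authoritative);
#' the seed only jitters the continuous values and orderings within the
#' pinned marginals.
#'
#' @param seed RNG seed.
#' @return List with \code{registry}: \code{data.frame} of id, family,
#'   arrangement, full_transporter, structural_type, role, intron_count,
#'   pI, mw_kda, scaffold.
#' @export
genCohortRegistry <- function(seed = 1) {
  ids <- sprintf("ABC%02d", 1:44)
  fam <- setNames(character(44), ids)
  fam[sprintf("ABC%02d", c(1, 5, 15, 3, 7, 8, 9, 10, 12))] <- "MRP"
  fam[sprintf("ABC%02d", c(4, 11, 13, 14, 16, 17))] <- "CFTR"
  fam[sprintf("ABC%02d", c(21, 23, 25, 18, 20, 22, 24, 26))] <- "MDR"
  fam[sprintf("ABC%02d", c(6, 34, 27, 28, 33))] <- "MdlB"
  fam[sprintf("ABC%02d", c(32, 38, 36, 39))] <- "ATM1"
  fam[sprintf("ABC%02d", c(19, 30, 40, 41))] <- "Protein White"
  fam[sprintf("ABC%02d", c(2, 44))] <- "Rim protein"
  fam[sprintf("ABC%02d", c(29, 31, 35, 42, 43))] <- "Uup"
  fam["ABC37"] <- "3a0123"
  arr <- setNames(character(44), ids)
  full_flag <- setNames(rep(FALSE, 44), ids)
  arr[fam %in% c("MRP", "CFTR", "MDR")] <- "A-B-A-B"
  arr[sprintf("ABC%02d", c(6, 34, 27))] <- "A-B-A-B"   # MdlB full
  arr[sprintf("ABC%02d", c(28, 33))] <- "A-B"          # MdlB half
  arr["ABC32"] <- "A-B"; full_flag["ABC32"] <- TRUE    # ATM1 full-evidence
  arr[sprintf("ABC%02d", c(38, 36, 39))] <- "A-B"      # ATM1 half
  arr["ABC37"] <- "A-B"                                # 3a0123 half
  arr["ABC02"] <- "B-C-B"; arr["ABC44"] <- "B-E-B"     # Rim protein
  arr[c("ABC19", "ABC30")] <- "B-C-B-C"                # Protein White
  arr[c("ABC40", "ABC41")] <- "B-C"
  arr[c("ABC31", "ABC29")] <- "B-B"                    # Uup, NBD-only
  arr[c("ABC35", "ABC42", "ABC43")] <- "B-D-B"
  stype <- vapply(ids, function(g)
    assignStructuralType(arr[g], fam[g], full_flag[g]), integer(1))
  role <- vapply(stype, functionalCategory, character(1))
  .with_seed(seed, {
    introns <- c(rep(0L, 5), rep(1L, 5), rep(2L, 13), rep(3L, 4),
                 15L, sample(5:15, 16, replace = TRUE))
    introns <- sample(introns)  # shuffle assignment over genes
    acid_idx <- sample(44, 27)
    pI <- numeric(44)
    pI[acid_idx] <- runif(27, 5.50, 6.95)
    pI[-acid_idx] <- runif(17, 7.05, 9.85)
    pI[acid_idx[1]] <- 5.48
    pI[setdiff(seq_len(44), acid_idx)[1]] <- 9.87
    mw <- runif(44, 55.5, 187.3)
    mw[sample(44, 2)] <- c(55.33, 187.56)
    scaff_sizes <- c(2, 3, 2, 3, 2, 7, 3, 2, 3, 2, 3, 2, 3, 2, 2, 2, 1)
    scaffold <- sample(rep(seq_along(scaff_sizes), scaff_sizes))
    registry <- data.frame(
      id = ids, family = unname(fam), arrangement = unname(arr),
      full_transporter = unname(full_flag),
      structural_type = unname(stype), role = unname(role),
      intron_count = introns, pI = round(pI, 2), mw_kda = round(mw, 2),
      scaffold = sprintf("scaffold_%d", scaffold),
      stringsAsFactors = FALSE)
    list(registry = registry)
  })
}

#' Render a cohort registry as GFF3 gene models
#'
#' Emits one gene / mRNA / exon feature set per registry record, with
#' exon count equal to intron count + 1, plausible exon (100--500 bp) and
#' intron (50--200 bp) lengths, genes laid out sequentially per scaffold,
#' and alternating strands. Round-tripping through [countIntrons()]
#' recovers the registry's intron counts.
#'
#' @param registry registry \code{data.frame} from [genCohortRegistry()].
#' @param seed RNG seed for exon/intron lengths.
#' @return Character vector of GFF3 lines (including the version pragma).
#' @export
registryToGff3 <- function(registry, seed = 1) {
  .with_seed(seed, {
    lines <- "##gff-version 3"
    cursor <- setNames(rep(1000L, length(unique(registry$scaffold))),
                       unique(registry$scaffold))
    for (i in seq_len(nrow(registry))) {
      g <- registry$id[i]
      sc <- registry$scaffold[i]
      n_ex <- registry$intron_count[i] + 1L
      ex_len <- sample(100:500, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(50:200, n_ex - 1, replace = TRUE)
                else integer(0)
      start <- cursor[sc]
      strand <- if (i %% 2 == 0) "-" else "+"
      ex_start <- integer(n_ex); ex_end <- integer(n_ex)
      pos <- start
      for (e in seq_len(n_ex)) {
        ex_start[e] <- pos
        ex_end[e] <- pos + ex_len[e] - 1L
        pos <- ex_end[e] + if (e < n_ex) in_len[e] else 0L
        if (e < n_ex) pos <- pos + 1L
      }
      gend <- ex_end[n_ex]
      lines <- c(lines,
        sprintf("%s\tabcfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                sc, start, gend, strand, g),
        sprintf("%s\tabcfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                sc, start, gend, strand, g, g),
        sprintf("%s\tabcfam\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                sc, ex_start, ex_end, strand, g, seq_len(n_ex), g))
      cursor[sc] <- gend + 2000L
    }
    lines
  })
}
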