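test_that("IUPAC compilation accepts exactly the consensus expansion", {
  m <- compileIupac("TGACTC")
  expect_equal(iupacMatchStarts("TGACTC", m), 1L)
  expect_equal(iupacMatchStarts("TGACTA", m), integer(0))
  w <- compileIupac("WWT")
  accepted <- vapply(c("AAT", "ATT", "TAT", "TTT", "GAT", "ACT"),
                     function(s) length(iupacMatchStarts(s, w)) == 1,
                     logical(1))
  expect_equal(unname(accepted), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  n8 <- compileIupac("NNNNNNNN")
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
               collapse = "")
    expect_equal(iupacMatchStarts(s, n8), 1L)
  }
  expect_error(compileIupac("ACGU"), "illegal IUPAC letter")
  # subject N never matches a non-N consensus letter
  expect_equal(iupacMatchStarts("TGNCTC", m), integer(0))
})

test_that("IUPAC matching agrees with Biostrings on random DNA", {
  set.seed(71)
  for (cs in c("TGACTC", "WWT", "CACGTK", "RTCRYNNNNNACG", "GAANNTTC")) {
    m <- compileIupac(cs)
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
      theirs <- Biostrings::matchPattern(cs, Biostrings::DNAString(s),
                                         fixed = FALSE)
      expect_identical(iupacMatchStarts(s, m),
                       as.integer(Biostrings::start(theirs)))
    }
  }
})

test_that("census counts planted sites exactly and respects strandedness", {
  dict <- data.frame(name = c("GCN4", "LONG"),
                     consensus = c("TGACTC", "AAGGTTCCAT"),
                     stress = c(TRUE, FALSE))
  bg <- strrep("A", 100)
  prom <- paste0(substr(bg, 1, 10), "TGACTC", substr(bg, 1, 20), "TGACTC",
                 substr(bg, 1, 20), "GAGTCA",  # reverse-strand GCN4
                 substr(bg, 1, 30))
  cen_both <- promoterCensus(c(g1 = prom), dict, both_strands = TRUE)
  expect_equal(unname(cen_both$counts["g1", "GCN4"]), 3L)
  cen_fwd <- promoterCensus(c(g1 = prom), dict, both_strands = FALSE)
  expect_equal(unname(cen_fwd$counts["g1", "GCN4"]), 2L)
  expect_equal(cen_both$per_gene$stress_total, 3L)
  expect_equal(cen_both$per_gene$distinct_types, 1L)
  # poly-A promoter has no hits for a non-poly-A dictionary
  cen0 <- promoterCensus(c(g2 = bg), dict)
  expect_equal(sum(cen0$counts), 0)
  # invalid letters are rejected by record name
  expect_error(promoterCensus(c(bad = "ACGX"), dict), "bad")
})

test_that("generated promoter cohorts reproduce their plant ledger", {
  dict <- motifDictionary()
  gp <- genPromoters(dict, genes = sprintf("g%02d", 1:8), seed = 17)
  cen <- promoterCensus(gp$promoters, dict, both_strands = TRUE)
  expect_identical(cen$counts, gp$expected_both)
  cen_f <- promoterCensus(gp$promoters, dict, both_strands = FALSE)
  expect_identical(cen_f$counts, gp$expected_forward)
  # per-gene totals follow the configured planting bounds
  expect_true(all(cen$per_gene$total >= 9 & cen$per_gene$total <= 32))
})

test_that("census is symmetric under reverse complement with both strands", {
  dict <- motifDictionary()
  gp <- genPromoters(dict, genes = sprintf("g%02d", 1:5), seed = 23)
  rc <- vapply(gp$promoters, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  cen1 <- promoterCensus(gp$promoters, dict, both_strands = TRUE)
  cen2 <- promoterCensus(rc, dict, both_strands = TRUE)
  expect_identical(cen1$counts, cen2$counts)
})

test_that("family summaries average per-gene counts arithmetically", {
  census <- list(per_gene = data.frame(
    gene = c("a1", "a2", "a3", "a4", "b1"),
    total = c(20L, 21L, 21L, 22L, 13L),
    distinct_types = c(7L, 8L, 7L, 8L, 7L),
    stress_total = c(10L, 10L, 11L, 11L, 6L)))
  fam <- c(a1 = "ATM1", a2 = "ATM1", a3 = "ATM1", a4 = "ATM1",
           b1 = "Rim protein")
  s <- summarizeByFamily(census, fam)
  expect_equal(s$mean_motifs[s$family == "ATM1"], 21)
  expect_equal(s$mean_motifs_rounded[s$family == "ATM1"], 21L)
  expect_equal(s$mean_motifs[s$family == "Rim protein"], 13)
  expect_error(summarizeByFamily(census, fam[-1]), "no family mapping")
})

test_that("overlong promoters are truncated 3'-anchored with a warning", {
  dict <- data.frame(name = "M", consensus = "TGACTC", stress = FALSE)
  long <- paste0("TGACTC", strrep("A", 1000))  # site falls off the 5' end
  expect_warning(cen <- promoterCensus(c(g = long), dict), "truncated")
  expect_equal(sum(cen$counts), 0)
})
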