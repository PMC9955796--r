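test_that("generators are deterministic under a fixed seed", {
  reg1 <- genCohortRegistry(101)$registry
  reg2 <- genCohortRegistry(101)$registry
  expect_identical(reg1, reg2)
  small <- reg1[1:4, ]
  expect_identical(genProteins(small, seed = 101)$sequences,
                   genProteins(small, seed = 101)$sequences)
  dict <- motifDictionary()
  expect_identical(genPromoters(dict, genes = c("a", "b"), seed = 101),
                   genPromoters(dict, genes = c("a", "b"), seed = 101))
  expect_identical(ctData(genCt(seed = 101)$table),
                   ctData(genCt(seed = 101)$table))
  expect_identical(genCounts(seed = 101)$counts,
                   genCounts(seed = 101)$counts)
  # generators restore the caller's RNG stream
  set.seed(55); x1 <- runif(1)
  set.seed(55); invisible(genCohortRegistry(7)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("registry reproduces the pinned cohort marginals", {
  reg <- genCohortRegistry(77)$registry
  expect_equal(nrow(reg), 44)
  fc <- table(reg$family)
  expect_equal(unname(fc[c("ATM1", "CFTR", "MdlB", "MDR", "MRP",
                           "Protein White", "Rim protein", "Uup",
                           "3a0123")]),
               c(4L, 6L, 5L, 8L, 9L, 4L, 2L, 5L, 1L),
               ignore_attr = TRUE)
  expect_equal(as.integer(table(factor(reg$structural_type, 1:6))),
               c(27L, 6L, 2L, 4L, 2L, 3L))
  expect_equal(range(reg$pI), c(5.48, 9.87))
  expect_equal(range(reg$mw_kda), c(55.33, 187.56))
  expect_equal(range(reg$intron_count), c(0L, 15L))
  # the two NBD-only records are the type-5 members
  only_b <- reg$arrangement %in% c("B-B", "B-B-B")
  expect_equal(sum(only_b), 2)
  expect_true(all(reg$structural_type[only_b] == 5))
  # arrangements agree with the typing rules record by record
  for (i in seq_len(nrow(reg)))
    expect_equal(assignStructuralType(reg$arrangement[i], reg$family[i],
                                      reg$full_transporter[i]),
                 reg$structural_type[i])
  # at most seven genes per scaffold, spread over 17 scaffolds
  expect_equal(length(unique(reg$scaffold)), 17)
  expect_equal(max(table(reg$scaffold)), 7)
})

test_that("planted protein ledgers re-match their patterns", {
  reg <- genCohortRegistry(31)$registry
  pr <- genProteins(reg[1:8, ], seed = 31)
  pats <- nbdPatterns("novel")
  for (i in seq_len(nrow(pr$ledger))) {
    expect_true(matchesPattern(pr$ledger$walkerA_inst[i], pats$walkerA))
    expect_true(matchesPattern(pr$ledger$cloop_inst[i], pats$cLoop))
    expect_true(matchesPattern(pr$ledger$walkerB_inst[i], pats$walkerB))
  }
  # triplet count per protein equals the arrangement's B-domain count
  n_b <- vapply(strsplit(reg$arrangement[1:8], "-"),
                function(x) sum(x == "B"), integer(1))
  expect_equal(as.integer(table(pr$ledger$protein_id)[reg$id[1:8]]), n_b)
})

test_that("protein generation fails cleanly when the protein is too short", {
  reg <- genCohortRegistry(1)$registry
  expect_error(genProteins(reg[1, ], seed = 1, protein_length = 300),
               "too short")
})

test_that("promoter generation with zero planted sites censuses to zero", {
  dict <- motifDictionary()
  gp <- genPromoters(dict, genes = "g1", sites_range = c(0L, 0L), seed = 3)
  expect_equal(nrow(gp$sites), 0)
  cen <- promoterCensus(gp$promoters, dict)
  expect_equal(sum(cen$counts), 0)
})

test_that("null count model keeps conditions exchangeable for unpinned genes", {
  # with all condition effects equal, per-gene RPKM differs across
  # conditions only by sampling noise
  reg <- genCohortRegistry(2)$registry
  gc <- genCounts(reg, seed = 2)
  r <- rpkmMatrix(gc$counts, gc$lengths, gc$mapped)
  low <- setdiff(rownames(r), gc$ledger$high_any)
  cv <- apply(r[low, ], 1, function(x) sd(x) / mean(x))
  # low genes were designed with independent uniform draws per condition,
  # so their spread is bounded well away from the pinned dynamic range
  expect_true(all(r[low, ] < 1000))
})

test_that("Ct generator recovers a planted single effect", {
  eff <- data.frame(gene = "gX", timepoint = 6, effect = 5.09)
  gen <- genCt(effects = eff, timepoints = c(0, 6), seed = 9,
               noise_sd = 0.05)
  fc <- foldChange(gen$table, "gX", 6)
  expect_equal(fc$minus_ddct, 5.09, tolerance = 0.2)
  expect_equal(fc$fold, 2^5.09, tolerance = 0.2 * 2^5.09)
})
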