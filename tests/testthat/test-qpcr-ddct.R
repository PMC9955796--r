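make_ct <- function(target_ct, ref_ct = list(actin = 20), gene = "g") {
  # two conditions x two timepoints x 2 reps, deterministic Ct values
  rows <- list()
  for (cond in c("control", "treatment")) {
    for (tp in c(0, 6)) {
      for (r in 1:2) {
        for (rg in names(ref_ct))
          rows[[length(rows) + 1]] <- data.frame(
            gene = rg, condition = cond, timepoint = tp, replicate = r,
            ct = ref_ct[[rg]])
        rows[[length(rows) + 1]] <- data.frame(
          gene = gene, condition = cond, timepoint = tp, replicate = r,
          ct = target_ct[[cond]][[as.character(tp)]])
      }
    }
  }
  ctTable(do.call(rbind, rows), ref_genes = names(ref_ct))
}

test_that("delta-Ct normalizes against the mean reference Ct per sample", {
  tab <- make_ct(list(control = list(`0` = 25, `6` = 25),
                      treatment = list(`0` = 25, `6` = 25)),
                 ref_ct = list(actin = 20, atub = 21, btub = 22))
  d <- normalizeCt(tab)
  expect_true(all(d$delta_ct == 25 - 21))  # reference mean 21
  # shifting every Ct in one sample leaves delta-Ct unchanged
  raw <- ctData(tab)
  sel <- raw$condition == "control" & raw$timepoint == 0 & raw$replicate == 1
  raw$ct[sel] <- raw$ct[sel] + 2
  d2 <- normalizeCt(ctTable(raw, ref_genes = refGenes(tab)))
  expect_equal(d2$delta_ct, d$delta_ct)
})

test_that("CtTable validity catches missing references and bad Ct", {
  raw <- ctData(make_ct(list(control = list(`0` = 25, `6` = 25),
                             treatment = list(`0` = 25, `6` = 24))))
  expect_error(ctTable(raw[-1, ], ref_genes = "actin"),
               "missing reference")
  raw2 <- raw; raw2$ct[1] <- -1
  expect_error(ctTable(raw2, ref_genes = "actin"), "> 0")
})

test_that("fold changes recover planted ddCt offsets exactly", {
  # treatment drops 5.09 cycles below its own 0-h calibrator at 6 h
  tab <- make_ct(list(control = list(`0` = 25, `6` = 25),
                      treatment = list(`0` = 25, `6` = 25 - 5.09)))
  fc <- foldChange(tab, "g", 6, "treatment")
  expect_equal(fc$minus_ddct, 5.09)
  expect_equal(fc$fold, 2^5.09, tolerance = 1e-12)
  expect_equal(fc$fold, 34.06, tolerance = 1e-3)
  # the calibrator sample itself has fold exactly 1
  fc0 <- foldChange(tab, "g", 0, "treatment")
  expect_equal(fc0$fold, 1)
  expect_equal(fc0$minus_ddct, 0)
  # symmetric planted offsets give folds 2 and 0.5
  tab2 <- make_ct(list(control = list(`0` = 25, `6` = 26),
                       treatment = list(`0` = 25, `6` = 24)))
  expect_equal(foldChange(tab2, "g", 6, "treatment")$fold, 2)
  expect_equal(foldChange(tab2, "g", 6, "control")$fold, 0.5)
  # absent calibrator errors
  raw <- ctData(tab)
  expect_error(
    foldChange(ctTable(raw[raw$timepoint != 0, ], ref_genes = "actin"),
               "g", 6), "calibrator")
})

test_that("adding a constant to every Ct in a sample changes nothing downstream", {
  gen <- genCt(seed = 41)
  raw <- ctData(gen$table)
  before <- foldChangeTable(gen$table)
  sel <- raw$condition == "treatment" & raw$timepoint == 6 &
    raw$replicate == 2
  raw$ct[sel] <- raw$ct[sel] + 3.7
  after <- foldChangeTable(ctTable(raw, ref_genes = refGenes(gen$table)))
  expect_equal(after$minus_ddct, before$minus_ddct, tolerance = 1e-10)
  expect_equal(after$p_vs_other, before$p_vs_other, tolerance = 1e-10)
})

test_that("t-test matches a hand-computed pooled-t oracle", {
  a <- c(5.1, 4.8, 5.3, 5.0)
  b <- c(3.9, 4.2, 4.0)
  res <- ctTTest(a, b)
  # independent pooled-variance computation
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_manual <- 2 * pt(-abs(t_manual), df = length(a) + length(b) - 2)
  expect_equal(res$statistic, t_manual, tolerance = 1e-6)
  expect_equal(res$p.value, p_manual, tolerance = 1e-6)
  # identical groups: t = 0, p = 1 (degenerate-variance convention)
  expect_equal(ctTTest(c(1, 1), c(1, 1)), list(statistic = 0, p.value = 1))
  # strong shift is detected
  expect_lt(ctTTest(c(1, 2, 3), c(11, 12, 13))$p.value, 0.001)
})

test_that("significance stars follow the p thresholds", {
  expect_equal(significanceStars(c(0.004, 0.03, 0.2, NA)),
               c("**", "*", "", NA))
})

test_that("treatment-minus-control differential series is reported", {
  gen <- genCt(seed = 43)
  de <- diffExpression(gen$table)
  expect_true(all(c("ABC01", "ABC31") %in% de$gene))
  led <- gen$ledger
  # planted treatment effects minus zero control effects, within noise
  for (i in seq_len(nrow(led))) {
    row <- de[de$gene == led$gene[i] & de$timepoint == led$timepoint[i], ]
    expect_equal(row$diff_log2, led$effect[i], tolerance = 1.0)
  }
})
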