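test_that("RPKM follows its defining formula and invariances", {
  expect_equal(rpkmMatrix(matrix(10), 1000, 1e6)[1, 1], 10)
  expect_equal(rpkmMatrix(matrix(0), 1000, 1e6)[1, 1], 0)
  # joint doubling of counts and depth leaves RPKM unchanged
  C <- matrix(c(5, 20, 7, 3), 2)
  expect_equal(rpkmMatrix(2 * C, c(500, 2000), 2 * c(1e6, 2e6)),
               rpkmMatrix(C, c(500, 2000), c(1e6, 2e6)))
  # linear in counts, inversely proportional to length and depth
  set.seed(3)
  C <- matrix(rpois(12, 50), 3)
  L <- c(800, 1500, 3000); N <- c(1e6, 2e6, 5e6, 1e7)
  r <- rpkmMatrix(C, L, N)
  expect_equal(rpkmMatrix(3 * C, L, N), 3 * r)
  expect_equal(rpkmMatrix(C, 2 * L, N), r / 2)
  expect_equal(rpkmMatrix(C, L, 4 * N), r / 4)
  expect_error(rpkmMatrix(matrix(1), 0, 1e6), "length")
  expect_error(rpkmMatrix(matrix(1), 100, 0), "mapped")
})

test_that("RPKM agrees with the edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  C <- matrix(rpois(40, 200), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  L <- sample(500:5000, 10)
  N <- c(2e6, 3e6, 1e6, 4e6)
  ours <- rpkmMatrix(C, L, N)
  theirs <- edgeR::rpkm(C, gene.length = L, lib.size = N)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("log2 transform applies the offset and preserves order", {
  expect_equal(log2Matrix(matrix(8), offset = 0)[1, 1], 3)
  expect_equal(log2Matrix(matrix(0), offset = 1)[1, 1], 0)
  expect_error(log2Matrix(matrix(0), offset = 0), "offset")
  x <- matrix(c(1, 5, 2, 9), 2)
  expect_equal(order(log2Matrix(x)), order(x))
})

test_that("identical expression rows merge first at height zero", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  h <- clusterGenes(m)
  expect_equal(h$height[1], 0)
  expect_setequal(-h$merge[1, ], c(1, 2))
  expect_error(clusterGenes(m[1, , drop = FALSE]), "two genes")
  m[1, 1] <- NA
  expect_error(clusterGenes(m), "missing")
})

test_that("clustering matches the brute-force complete-linkage oracle", {
  set.seed(31)
  for (rep_i in 1:100) {
    m <- matrix(rnorm(8 * 4), nrow = 8)
    h <- clusterGenes(m)
    oracle <- oracle_complete_linkage(m)
    expect_equal(h$height, oracle$heights, tolerance = 1e-10)
    got <- hclust_partitions(h, 8)
    for (s in seq_along(oracle$partitions)) {
      expect_identical(canonical_partition(got[[s]]),
                       canonical_partition(oracle$partitions[[s]]))
    }
  }
})

test_that("complete-linkage merge heights equal max inter-cluster distance", {
  set.seed(33)
  m <- matrix(rnorm(6 * 3), nrow = 6)
  h <- clusterGenes(m)
  D <- as.matrix(dist(m))
  # members of the cluster formed at each merge step
  members <- list()
  child <- function(x, step) if (x < 0) -x else members[[x]]
  for (step in seq_len(nrow(h$merge))) {
    a <- child(h$merge[step, 1], step)
    b <- child(h$merge[step, 2], step)
    expect_equal(h$height[step], max(D[a, b]), tolerance = 1e-10)
    members[[step]] <- c(a, b)
  }
  expect_true(all(diff(h$height) >= -1e-10))
})

test_that("high-expression flagging applies absolute and quantile rules", {
  expr <- rbind(g1 = c(99.9, 50), g2 = c(100, 10), g3 = c(0, 0))
  fl <- flagHigh(expr, rule = list(type = "absolute", cutoff = 100))
  expect_equal(unname(fl$high_any), c(FALSE, TRUE, FALSE))
  expect_equal(sum(flagHigh(matrix(0, 3, 2),
                            rule = list(type = "absolute",
                                        cutoff = 100))$high_any), 0)
  expect_error(flagHigh(expr, rule = list(type = "nope")), "unknown")
  fl2 <- flagHigh(expr, category = c(g1 = "t", g2 = "t", g3 = "u"))
  expect_equal(fl2$rollup$n_total, c(2, 1))
})

test_that("the generated count cohort realizes its designed screen", {
  gc <- genCounts(seed = 7)
  r <- rpkmMatrix(gc$counts, gc$lengths, gc$mapped)
  expect_equal(unname(r["ABC31", c("MM", "PdPap")]), c(8537, 59214))
  expect_equal(unname(r["ABC42", c("MM", "N-hungry")]), c(3957, 11790))
  fl <- flagHigh(r, category = gc$ledger$category)
  expect_setequal(names(fl$high_any)[fl$high_any], gc$ledger$high_any)
  roll <- fl$rollup
  expect_equal(roll$n_high[roll$category == "transport"], 17)
  expect_equal(roll$n_total[roll$category == "transport"], 39)
  expect_equal(roll$n_high[roll$category == "translation"], 4)
  expect_equal(roll$n_total[roll$category == "translation"], 5)
})
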