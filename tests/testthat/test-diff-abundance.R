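test_that("log2/median normalization centers every sample at zero", {
  q <- quant_row(paste0("p", 1:3), "prot", "s1", "Ctrl", c(2, 4, 8))
  norm <- log2_median_normalize(q)
  expect_equal(norm$value, c(-1, 0, 1))

  q_const <- quant_row(paste0("p", 1:3), "prot", "s1", "Ctrl", c(4, 4, 4))
  expect_equal(log2_median_normalize(q_const)$value, c(0, 0, 0))

  # scale invariance: multiplying one sample by 10 changes nothing
  q2 <- rbind(quant_row(paste0("p", 1:3), "prot", "s1", "Ctrl", c(2, 4, 8)),
              quant_row(paste0("p", 1:3), "prot", "s2", "Ctrl",
                        10 * c(2, 4, 8)))
  norm2 <- log2_median_normalize(q2)
  expect_equal(norm2$value[norm2$sample == "s1"],
               norm2$value[norm2$sample == "s2"])

  # property: per-sample medians are 0 on random tables
  set.seed(5)
  qr <- quant_row(paste0("p", 1:60), rep(paste0("pr", 1:20), 3),
                  rep(paste0("s", 1:4), each = 15),
                  "Ctrl", 2^rnorm(60, 5, 2))
  nr <- log2_median_normalize(qr)
  meds <- tapply(nr$value, nr$sample, median)
  expect_true(all(abs(meds) < 1e-12))
})

test_that("non-positive areas are treated as missing", {
  q <- quant_row(paste0("p", 1:3), "prot", "s1", "Ctrl", c(2, 0, -1))
  expect_message(norm <- log2_median_normalize(q), "missing")
  expect_identical(nrow(norm), 1L)
})

test_that("two-peptide filter drops under-supported proteins at the boundary", {
  q <- rbind(quant_row("p1", "one_pep", "s1", "Ctrl", 2),
             quant_row(c("p2", "p3"), "two_pep", "s1", "Ctrl", c(2, 4)))
  q$value <- log2(q$area)
  out <- two_peptide_filter(q)
  expect_setequal(unique(out$protein), "two_pep")
  expect_identical(nrow(two_peptide_filter(q[0, ])), 0L)
})

test_that("protein summaries are per-sample peptide medians", {
  q <- quant_row(paste0("p", 1:3), "prot", "s1", "Ctrl", 1)
  q$value <- c(-1, 0, 3)
  s <- summarize_protein(q)
  expect_equal(s$value, 0)
  # single peptide: identity
  q1 <- quant_row("p1", "prot", "s1", "Ctrl", 1)
  q1$value <- 2.5
  expect_equal(summarize_protein(q1)$value, 2.5)
  # absent in a sample: no row
  q2 <- rbind(q, within(quant_row(paste0("p", 1:3), "other", "s2", "Ctrl", 1),
                        value <- 1))
  s2 <- summarize_protein(q2)
  expect_identical(nrow(s2), 2L)
  expect_identical(attr(s2, "n_peptides")[["prot"]], 3L)
})

test_that("differential tests match stats::t.test and handle degeneracy", {
  set.seed(21)
  samples <- c(paste0("c", 1:4), paste0("t", 1:4))
  conditions <- rep(c("Ctrl", "Trt"), each = 4)
  vals <- list(
    pA = matrix(rnorm(16), 2),        # 2 peptides x 8 samples
    pB = matrix(rnorm(16, 2), 2),
    pC = matrix(rnorm(16, -1, 2), 2))
  q <- quant_from_values(vals, samples, conditions)
  norm <- log2_median_normalize(q)
  s <- summarize_protein(norm)
  st <- test_differential(s, c("Trt", "Ctrl"))
  # oracle: per-protein Welch t-test on the summarized values
  for (prot in st$protein) {
    x <- s$value[s$protein == prot & s$condition == "Trt"]
    y <- s$value[s$protein == prot & s$condition == "Ctrl"]
    tt <- t.test(x, y)
    row <- st[st$protein == prot, ]
    expect_equal(row$log2fc, mean(x) - mean(y), tolerance = 1e-12)
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  }
  expect_true(all(st$p_adj >= st$p))

  # identical groups: log2fc 0, p 1
  sm <- data.frame(protein = "x", sample = samples,
                   condition = conditions,
                   value = rep(c(1, 1), each = 4), stringsAsFactors = FALSE)
  st0 <- test_differential(sm, c("Trt", "Ctrl"))
  expect_equal(st0$log2fc, 0)
  expect_equal(st0$p, 1)

  # group means 3 vs 1: log2fc +2
  sm2 <- data.frame(protein = "x", sample = samples, condition = conditions,
                    value = c(1, 1.2, 0.8, 1, 3, 3.2, 2.8, 3),
                    stringsAsFactors = FALSE)
  expect_equal(test_differential(sm2, c("Trt", "Ctrl"))$log2fc, 2)
})

test_that("proteins with under-sampled groups are skipped with a warning", {
  sm <- data.frame(protein = c(rep("full", 4), rep("thin", 3)),
                   sample = c("c1", "c2", "t1", "t2", "c1", "c2", "t1"),
                   condition = c("Ctrl", "Ctrl", "Trt", "Trt",
                                 "Ctrl", "Ctrl", "Trt"),
                   value = rnorm(7), stringsAsFactors = FALSE)
  expect_warning(st <- test_differential(sm, c("Trt", "Ctrl")), "skipped")
  expect_identical(st$protein, "full")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  res <- data.frame(p = c(0.01, 0.02, 0.04))
  expect_equal(gsea_fdr(res)$fdr, c(0.03, 0.03, 0.04))
  expect_equal(gsea_fdr(data.frame(p = 0.2))$fdr, 0.2)
  expect_equal(gsea_fdr(data.frame(p = c(1, 1, 1)))$fdr, c(1, 1, 1))
})

test_that("significant/unique/shared protein sets follow set arithmetic", {
  mk <- function(ids, padj) data.frame(protein = ids, p_adj = padj,
                                       stringsAsFactors = FALSE)
  out <- significant_sets(mk(c("A", "B", "C"), c(0.01, 0.04, 0.9)),
                          mk(c("B", "C", "D"), c(0.01, 0.9, 0.02)))
  expect_identical(out$unique1, "A")
  expect_identical(out$unique2, "D")
  expect_identical(out$shared, "B")
  disj <- significant_sets(mk("A", 0.01), mk("B", 0.01))
  expect_identical(disj$shared, character(0))
  same <- significant_sets(mk("A", 0.01), mk("A", 0.01))
  expect_identical(same$unique1, character(0))
  expect_identical(same$unique2, character(0))
})

test_that("ranking sorts by fold change with lexicographic tie-break", {
  st <- data.frame(protein = c("A", "B", "C"), log2fc = c(2, -1, 0))
  expect_identical(make_ranking(st)$gene, c("A", "C", "B"))
  ties <- data.frame(protein = c("b", "a", "c"), log2fc = c(0, 0, 0))
  expect_identical(make_ranking(ties)$gene, c("a", "b", "c"))
  single <- data.frame(protein = "only", log2fc = 1)
  expect_identical(nrow(make_ranking(single)), 1L)
  dup <- data.frame(protein = c("A", "A"), log2fc = c(1, 2))
  expect_error(make_ranking(dup), "duplicate")
})

test_that("raw p-values are calibrated under a global null", {
  # no planted effect, 5 vs 5, vectorized across replicates
  set.seed(31)
  frac <- replicate(20, {
    vals <- matrix(rnorm(500 * 10, 0, 0.5), nrow = 500)
    sm <- data.frame(
      protein = rep(sprintf("P%03d", 1:500), 10),
      sample = rep(paste0("s", 1:10), each = 500),
      condition = rep(rep(c("Ctrl", "Trt"), each = 5), each = 500),
      value = as.vector(vals), stringsAsFactors = FALSE)
    st <- test_differential(sm, c("Trt", "Ctrl"))
    mean(st$p < 0.05)
  })
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})
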