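test_that("low-count filter applies the strict more-than rule", {
  m <- rbind(keep3 = c(11, 12, 13, 0),
             border = c(10, 10, 10, 10),
             keep4 = c(50, 60, 70, 80),
             two = c(11, 11, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  got <- filter_low_counts(m)
  expect_identical(rownames(got), c("keep3", "keep4"))
  expect_identical(filter_low_counts(got), got)   # idempotent
  expect_error(filter_low_counts(m, min_samples = 5), "exceeds")
  expect_error(filter_low_counts(m - 20), "non-negative")
})

test_that("upper-quartile normalization equalizes sample scales", {
  m <- cbind(a = c(5, 20, 100, 0, 7), b = c(5, 20, 100, 0, 7))
  eq <- upper_quartile_normalize(m)
  expect_equal(unname(eq$factors), c(1, 1))
  expect_equal(eq$normalized, m)

  m2 <- cbind(a = c(5, 20, 100, 0, 7), b = 2 * c(5, 20, 100, 0, 7))
  eq2 <- upper_quartile_normalize(m2)
  expect_equal(unname(eq2$normalized[, "a"]), unname(eq2$normalized[, "b"]))

  cnt <- simulate_counts(400, 5, seed = 2)
  norm <- upper_quartile_normalize(cnt)
  expressed <- rowSums(cnt) > 0
  uqs <- apply(norm$normalized[expressed, ], 2, quantile, probs = 0.75,
               names = FALSE)
  expect_lt(max(uqs) - min(uqs), 1e-9)
  # recompute the factors by the definition
  uq_raw <- apply(cnt[expressed, ], 2, quantile, probs = 0.75,
                  names = FALSE)
  expect_equal(unname(norm$factors),
               unname(uq_raw / exp(mean(log(uq_raw)))))

  bad <- cbind(a = c(1, 2), b = c(0, 0))
  expect_error(upper_quartile_normalize(bad), "all-zero")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(3, {
    for (i in 1:10) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    }
    p_sorted <- sort(runif(25))
    expect_false(is.unsorted(bh_fdr(p_sorted)))
  })
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("hypergeometric upper tail agrees with integer binomials", {
  expect_equal(hypergeometric_test(20, 5, 5, 0), 1)
  expect_equal(hypergeometric_test(20, 5, 5, 3), 1126 / 15504,
               tolerance = 1e-12)
  p_by_k <- vapply(0:5, function(k) hypergeometric_test(20, 5, 5, k),
                   numeric(1))
  expect_true(all(diff(p_by_k) < 0))
  expect_error(hypergeometric_test(10, 11, 5, 2), "inconsistent")
  # spot grid against the exact-summation oracle
  for (N in c(5, 12, 23)) for (K in c(0, 2, N %/% 2)) for (n in c(1, N %/% 3 + 1)) {
    for (k in 0:min(K, n))
      expect_equal(hypergeometric_test(N, K, n, k), hyper_oracle(N, K, n, k),
                   tolerance = 1e-12, info = paste(N, K, n, k))
  }
})

test_that("gene-set overrepresentation reports the paper-style fractions", {
  de <- data.frame(gene = sprintf("g%d", 1:200),
                   log2fc = rep(c(2, -1), 100),
                   fdr = rep(c(0.01, 0.5), 100),
                   stringsAsFactors = FALSE)
  set_hit <- sprintf("g%d", seq(1, 40, by = 2))  # 20 upregulated members
  res <- enrich_gene_set(de, set_hit)
  expect_equal(res$N, 200L)
  expect_equal(res$K, 20L)
  expect_equal(res$n, 100L)
  expect_equal(res$k, 20L)
  expect_equal(res$background_pct, 10.0)
  expect_equal(res$selected_pct, 20.0)
  expect_equal(res$p_value, hyper_oracle(200, 20, 100, 20),
               tolerance = 1e-12)

  none <- enrich_gene_set(de, c("absent1", "absent2"))
  expect_equal(none$K, 0L)
  expect_equal(none$k, 0L)
  expect_equal(none$p_value, 1)
  expect_error(enrich_gene_set(de[0, ], set_hit), "empty")
})

test_that("planted set enrichment lowers the overrepresentation p-value", {
  p_null <- p_enr <- numeric(40)
  for (s in 1:40) {
    null <- simulate_de_results(1500, 60, 150, enrichment_odds = 1,
                                seed = s)
    enr <- simulate_de_results(1500, 60, 150, enrichment_odds = 3,
                               seed = 1000 + s)
    p_null[s] <- enrich_gene_set(null$de_table, null$gene_set)$p_value
    p_enr[s] <- enrich_gene_set(enr$de_table, enr$gene_set)$p_value
  }
  expect_lt(median(p_enr), median(p_null))
})

test_that("gene sets read from plain and GMT dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1", "G2", "G2", ""), f)
  gs <- read_gene_set(f, name = "demo")
  expect_equal(gs$members, c("G1", "G2"))
  g <- withr::local_tempfile(fileext = ".gmt")
  writeLines("idin\tcurated\tG1\tG3", g)
  gm <- read_gene_set(g)
  expect_equal(gm$name, "idin")
  expect_equal(gm$members, c("G1", "G3"))
})
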