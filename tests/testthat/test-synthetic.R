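test_that("generators are pure functions of their seed", {
  expect_identical(make_hairpin_with_variant(8, 4, "stem", seed = 5),
                   make_hairpin_with_variant(8, 4, "stem", seed = 5))
  expect_identical(simulate_locus_set(6, 10, 0.5, seed = 9),
                   simulate_locus_set(6, 10, 0.5, seed = 9))
  expect_identical(simulate_ct_experiment(2, 3, seed = 4),
                   simulate_ct_experiment(2, 3, seed = 4))
  expect_identical(simulate_counts(50, 4, seed = 3),
                   simulate_counts(50, 4, seed = 3))
  expect_identical(simulate_de_results(200, 20, 30, 2, seed = 8),
                   simulate_de_results(200, 20, 30, 2, seed = 8))
})

test_that("hairpin construction plants the promised variant", {
  for (s in 1:10) {
    hp <- make_hairpin_with_variant(8, 4, "stem", seed = s)
    expect_equal(nchar(hp$sequence), 20L)
    b <- strsplit(hp$sequence, "")[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    # 3' arm is the exact reverse complement of the 5' arm
    expect_identical(b[13:20], rev(unname(comp[b[1:8]])))
    expect_true(hp$truth$disruptive)
    expect_identical(b[hp$variant$pos], hp$variant$ref)
    partner <- b[21 - hp$variant$pos]
    canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
    expect_false(paste0(hp$variant$alt, partner) %in% canon)

    lp <- make_hairpin_with_variant(8, 4, "loop", seed = s)
    expect_false(lp$truth$disruptive)
    expect_identical(lp$variant$ref, "A")
    expect_identical(lp$variant$alt, "C")
    expect_true(lp$variant$pos %in% 9:12)
  }
  expect_error(make_hairpin_with_variant(3, 4, "stem"), "stem_len")
  expect_error(make_hairpin_with_variant(8, 2, "loop"), "loop_len")
})

test_that("locus sets honor the planted overlap fractions", {
  sim0 <- simulate_locus_set(8, 12, exonic_fraction = 0, seed = 2)
  expect_false(any(sim0$truth$region == "exonic"))
  sim_none <- simulate_locus_set(5, 0, 0.5, seed = 2)
  expect_equal(nrow(sim_none$truth), 0L)
  sim <- simulate_locus_set(10, 20, 0.5, seed = 6)
  expect_equal(sum(sim$truth$region == "exonic"), 10L)
  expect_error(simulate_locus_set(5, 5, 1.5, seed = 1), "exonic_fraction")
})

test_that("locus-set FASTA alleles are consistent with the annotation", {
  sim <- simulate_locus_set(10, 24, 0.6, seed = 13)
  ex <- sim$truth[sim$truth$region == "exonic", ]
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(ex))) {
    tx <- sim$transcripts[[ex$transcript_id[i]]]
    v <- sim$variants[sim$variants$id == ex$variant_id[i], ]
    base_tx <- substr(sim$sequences[[tx$id]], ex$spliced_pos[i],
                      ex$spliced_pos[i])
    expected_ref <- if (tx$strand == "+") base_tx else flip[[base_tx]]
    expect_identical(v$ref, expected_ref)
    # genomic position maps back to the recorded spliced position
    expect_identical(genomic_to_spliced(tx, v$pos), ex$spliced_pos[i])
  }
})

test_that("count simulation matches its declared moments", {
  cnt <- simulate_counts(200, 4, seed = 5)
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  # dispersion zero reduces to Poisson: conditional variance equals the
  # mean, so the marginal variance is mu*E[L] + mu^2*Var(L) over the
  # library-size mixture
  pois <- simulate_counts(1, 10000, seed = 6, dispersion = 0)
  lib <- attr(pois, "lib_factors")
  mu <- attr(pois, "gene_means")[1]
  x <- as.numeric(pois[1, ])
  expect_equal(mean(x), mu * mean(lib), tolerance = 0.05)
  v_expected <- mu * mean(lib) + mu^2 * var(lib)
  expect_lt(abs(var(x) / v_expected - 1), 0.1)
})

test_that("DE simulation encodes selection consistently with its truth", {
  sim <- simulate_de_results(500, 50, 80, enrichment_odds = 5, seed = 7)
  de <- sim$de_table
  selected <- de$fdr < 0.05 & de$log2fc > 0
  expect_equal(sum(selected), 80L)
  expect_true(all(de$pvalue <= de$fdr))
  expect_equal(sum(selected & de$gene %in% sim$gene_set$members),
               sim$truth$k_selected_members)
  # K = 0: nothing to enrich
  empty <- simulate_de_results(100, 0, 20, 1, seed = 3)
  expect_equal(enrich_gene_set(empty$de_table, empty$gene_set)$p_value, 1)
  expect_error(simulate_de_results(10, 20, 5, 1, 1), "set_size")
})
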