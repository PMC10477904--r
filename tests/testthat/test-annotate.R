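test_that("generic and GWAS-catalog variant tables parse with skip tally", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tchrom\tpos\tref\talt\ttrait",
               "rs1\t13\t10\tA\tG\tt1d",
               "rs2\tchrX\t55\t\t\tt1d",
               "rs3\t2\tNA\tC\tT\tt1d"), f)
  v <- read_variant_table(f, dialect = "generic")
  expect_equal(nrow(v), 2L)
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(v$id, c("rs1", "rs2"))
  expect_equal(v$chrom, c("13", "X"))
  expect_equal(v$pos, c(10L, 55L))
  expect_equal(v$ref, c("A", NA))

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNPS\tCHR_ID\tCHR_POS\tDISEASE/TRAIT",
               "rs9585056\t13\t42343795\tType 1 diabetes",
               "rsX\t1\tNA\tType 1 diabetes"), g)
  gv <- read_variant_table(g, dialect = "gwas_catalog")
  expect_equal(nrow(gv), 1L)
  expect_equal(attr(gv, "n_skipped"), 1L)
  expect_true(is.na(gv$ref))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNPS\tCHR_ID", "rs1\t1"), bad)
  expect_error(read_variant_table(bad, "gwas_catalog"), "CHR_POS")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tchrom\tpos", empty)
  expect_error(read_variant_table(empty, "generic"), "empty")
})

test_that("BED12 and GTF exon coordinates are read into 1-based models", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr7\t100\t250\tTXA\t0\t+\t100\t250\t0\t2\t50,50,\t0,100,",
             bed)
  tx <- read_transcripts(bed, "bed12")[["TXA"]]
  expect_equal(IRanges::start(tx$exons), c(101L, 201L))
  expect_equal(IRanges::end(tx$exons), c(150L, 250L))
  expect_equal(tx$chrom, "7")
  expect_equal(spliced_length(tx), 100L)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0(
    'chr1\tsrc\texon\t101\t150\t.\t+\t.\t',
    'gene_id "G1"; transcript_id "T1";'), gtf)
  tg <- read_transcripts(gtf, "gtf")[["T1"]]
  expect_equal(IRanges::start(tg$exons), 101L)
  expect_equal(IRanges::end(tg$exons), 150L)

  dup <- withr::local_tempfile(fileext = ".bed")
  writeLines(rep("chr1\t0\t100\tSAME\t0\t+\t0\t100\t0\t1\t100,\t0,", 2), dup)
  expect_error(read_transcripts(dup, "bed12"), "duplicate")
  expect_error(transcript_model("T", "G", "1", "+", c(1, 50), c(60, 100)),
               "overlapping")
})

test_that("BED12 round-trip preserves exon structure bit-exactly", {
  sim <- simulate_locus_set(8, 0, 0, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_transcripts_bed12(sim$transcripts, f1)
  back <- read_transcripts(f1, "bed12")
  write_transcripts_bed12(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  for (tid in names(sim$transcripts)) {
    expect_identical(IRanges::start(back[[tid]]$exons),
                     IRanges::start(sim$transcripts[[tid]]$exons))
    expect_identical(IRanges::end(back[[tid]]$exons),
                     IRanges::end(sim$transcripts[[tid]]$exons))
    expect_identical(back[[tid]]$strand, sim$transcripts[[tid]]$strand)
  }
})

test_that("intersection matches the naive all-pairs oracle", {
  for (seed in 1:30) {
    shape <- random_locus(seed)
    sim <- simulate_locus_set(shape$n_tx, shape$n_v, shape$frac,
                              seed = seed)
    got <- intersect_variants(sim$variants, sim$transcripts)
    expect_equal(got, naive_intersect(sim$variants, sim$transcripts),
                 info = paste("seed", seed))
  }
})

test_that("intersection classifies exonic vs intronic positions", {
  tx <- transcript_model("TX1", "G1", "13", "+", c(101, 201), c(150, 250))
  v <- data.frame(id = c("v_ex", "v_in", "v_out"), chrom = "13",
                  pos = c(120L, 160L, 500L), ref = "A", alt = "G",
                  trait = "t", stringsAsFactors = FALSE)
  got <- intersect_variants(v, list(TX1 = tx))
  expect_equal(got$region[got$variant_id == "v_ex"], "exonic")
  expect_equal(got$region[got$variant_id == "v_in"], "intronic")
  expect_false("v_out" %in% got$variant_id)
  expect_equal(nrow(intersect_variants(v[0, ], list(TX1 = tx))), 0L)
})

test_that("genomic/spliced mapping matches explicit sequence construction", {
  plus <- transcript_model("P", "G", "1", "+", c(101, 201), c(150, 250))
  minus <- transcript_model("M", "G", "1", "-", c(101, 201), c(150, 250))
  expect_equal(genomic_to_spliced(plus, 201), 51L)
  expect_equal(genomic_to_spliced(minus, 211),
               spliced_pos_oracle(minus, 211))
  expect_equal(spliced_to_genomic(plus, 51), 201L)
  expect_error(genomic_to_spliced(plus, 160), "not exonic")
  expect_error(spliced_to_genomic(plus, 101), "out of range")
  expect_error(spliced_to_genomic(plus, 0), "out of range")

  for (seed in 1:25) {
    sim <- simulate_locus_set(2, 0, 0, seed = 100 + seed)
    for (tx in sim$transcripts) {
      coords <- mature_coordinates(tx)
      for (sp in seq_len(spliced_length(tx))) {
        g <- spliced_to_genomic(tx, sp)
        expect_identical(g, coords[sp])
        expect_identical(genomic_to_spliced(tx, g), sp)
      }
    }
  }
})

test_that("funnel report counts distinct transcripts per stage", {
  txs <- lapply(1:5, function(i)
    transcript_model(sprintf("T%d", i), sprintf("G%d", i), "1", "+",
                     1000 * i, 1000 * i + 199))
  names(txs) <- vapply(txs, `[[`, character(1), "id")
  # T1/T2/T3 overlapped; T1, T2 exonic (single-exon); T3 gets no variant
  v <- data.frame(id = c("v1", "v2", "v3"), chrom = "1",
                  pos = c(1010L, 2010L, 3010L), ref = "A", alt = "G",
                  trait = "t", stringsAsFactors = FALSE)
  ov <- intersect_variants(v, txs)
  ov$region[ov$transcript_id == "T3"] <- "intronic"  # forced stage split
  ov$spliced_pos[ov$transcript_id == "T3"] <- NA_integer_
  calls <- data.frame(variant_id = c("v1", "v2"),
                      transcript_id = c("T1", "T2"),
                      score = c(0.5, 0.1), empirical_p = c(0.01, 0.8),
                      disruptive = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  rep <- funnel_report(v, txs, ov, calls)
  expect_equal(rep$n_with_any_overlap, 3L)
  expect_equal(rep$n_with_exonic_overlap, 2L)
  expect_equal(rep$n_structure_disrupted, 1L)
  expect_true(rep$n_with_any_overlap >= rep$n_with_exonic_overlap)
  expect_true(rep$n_with_exonic_overlap >= rep$n_structure_disrupted)

  empty <- funnel_report(v[0, ], txs)
  expect_equal(empty$n_with_any_overlap, 0L)
  expect_equal(empty$n_structure_disrupted, 0L)

  bad_calls <- data.frame(variant_id = "vX", transcript_id = "T9",
                          score = 1, empirical_p = 0.1, disruptive = TRUE,
                          stringsAsFactors = FALSE)
  expect_error(funnel_report(v, txs, ov, bad_calls), "unknown")
})

test_that("allele orientation complements on the minus strand", {
  expect_equal(orient_alleles("G", "A", "+"), list(ref = "G", alt = "A"))
  expect_equal(orient_alleles("G", "A", "-"), list(ref = "C", alt = "U"))
  expect_equal(orient_alleles("T", "C", "-"), list(ref = "A", alt = "G"))
  expect_error(orient_alleles("N", "A", "+"), "single DNA bases")
})
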