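# Seeded generators for every input the pipeline consumes, each shipping
# a ground-truth record so pipeline outputs are checked against planted
# truth rather than against other pipeline outputs. All generators are
# pure functions of their parameters and seed.

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

rna_revcomp <- function(bases) rev(unname(RNA_COMPLEMENT[bases]))

# bases that can form a canonical pair (incl. G.U wobble) with `b`
pairs_with <- function(b) {
  switch(b,
         A = "U", C = "G",
         G = c("C", "U"), U = c("A", "G"))
}

#' Generate a hairpin sequence with a planted variant
#'
#' Builds a perfect hairpin -- a random 5' stem arm, an all-A loop, and
#' the exact reverse-complement 3' arm -- and plants one substitution.
#' A `"stem"` site substitutes the arm base adjacent to the loop (the
#' innermost stem position, emulating a variant at the boundary of a
#' loop) to a base that cannot pair with its partner: truth is
#' disruptive. A `"loop"` site substitutes a loop A to C, which pairs
#' with nothing in the loop: truth is non-disruptive.
#'
#' @param stem_len Stem length in pairs (>= 4).
#' @param loop_len Loop length (>= 3).
#' @param site `"stem"` or `"loop"`.
#' @param seed Integer seed; same seed, same output.
#' @return List with `sequence` (RNA), `variant` (list `pos`, `ref`,
#'   `alt`, 1-based transcript coordinates), and `truth` (generator name,
#'   seed, parameters, `disruptive` flag).
#' @export
make_hairpin_with_variant <- function(stem_len = 8L, loop_len = 4L,
                                      site = c("stem", "loop"),
                                      seed = 1L) {
  site <- match.arg(site)
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (stem_len < 4L) stop("stem_len must be >= 4")
  if (loop_len < 3L) stop("loop_len must be >= 3")

  withr::with_seed(seed, {
    arm <- sample(RNA_BASES, stem_len, replace = TRUE)
    seq_bases <- c(arm, rep("A", loop_len), rna_revcomp(arm))
    if (site == "stem") {
      pos <- stem_len                              # innermost 5' arm base
      ref <- seq_bases[pos]
      partner <- seq_bases[2L * stem_len + loop_len + 1L - pos]
      choices <- setdiff(RNA_BASES, c(ref, pairs_with(partner)))
      alt <- if (length(choices) == 1L) choices else sample(choices, 1L)
      disruptive <- TRUE
    } else {
      pos <- stem_len + (loop_len + 1L) %/% 2L     # a middle loop base
      ref <- "A"
      alt <- "C"
      disruptive <- FALSE
    }
    list(sequence = paste(seq_bases, collapse = ""),
         variant = list(pos = pos, ref = ref, alt = alt),
         truth = list(generator = "make_hairpin_with_variant", seed = seed,
                      stem_len = stem_len, loop_len = loop_len,
                      site = site, disruptive = disruptive))
  })
}

#' Simulate a set of transcripts and variants with known overlaps
#'
#' Places non-overlapping multi-exon transcripts on synthetic
#' chromosomes, then plants variants that are exonic, intronic, or
#' intergenic in stated proportions. Mature transcript sequences are
#' generated alongside, and exonic variant alleles are made consistent
#' with them (plus-strand genomic alleles; minus-strand transcripts carry
#' the complement). The returned truth table lists every expected
#' overlap annotation.
#'
#' @param n_transcripts,n_variants Sizes.
#' @param exonic_fraction Fraction of variants planted in exons; half of
#'   the remainder is intronic (where introns exist), half intergenic.
#' @param seed Integer seed.
#' @return List with `variants` (data.frame in the generic dialect),
#'   `transcripts` (list of [transcript_model()]), `sequences` (named
#'   character vector of mature DNA sequences), and `truth` (data.frame
#'   `variant_id`, `transcript_id`, `region`, `spliced_pos`).
#' @export
simulate_locus_set <- function(n_transcripts = 10L, n_variants = 20L,
                               exonic_fraction = 0.5, seed = 1L) {
  if (exonic_fraction < 0 || exonic_fraction > 1)
    stop("exonic_fraction must lie in [0, 1]")
  n_transcripts <- as.integer(n_transcripts)
  n_variants <- as.integer(n_variants)
  if (n_transcripts < 0L || n_variants < 0L) stop("sizes must be >= 0")

  withr::with_seed(seed, {
    chroms <- c("1", "2", "X")
    cursor <- setNames(rep(1000L, length(chroms)), chroms)
    transcripts <- list()
    for (i in seq_len(n_transcripts)) {
      chrom <- sample(chroms, 1L)
      n_ex <- sample(1:4, 1L)
      widths <- sample(60:200, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE)
              else integer()
      starts <- cursor[[chrom]] + cumsum(c(0L, widths[-n_ex] + gaps))
      ends <- starts + widths - 1L
      cursor[[chrom]] <- max(ends) + sample(2000:5000, 1L)
      tid <- sprintf("TX%03d", i)
      transcripts[[tid]] <- transcript_model(
        tid, sprintf("GENE%03d", i), chrom,
        sample(c("+", "-"), 1L), starts, ends)
    }

    sequences <- vapply(transcripts, function(tx)
      paste(sample(c("A", "C", "G", "T"), spliced_length(tx),
                   replace = TRUE), collapse = ""),
      character(1))

    n_exonic <- round(n_variants * exonic_fraction)
    n_rest <- n_variants - n_exonic
    n_intronic <- n_rest %/% 2L
    n_intergenic <- n_rest - n_intronic

    with_introns <- which(vapply(transcripts, function(tx)
      length(tx$exons) > 1L, logical(1)))
    if (length(with_introns) == 0L) {
      n_intergenic <- n_intergenic + n_intronic
      n_intronic <- 0L
    }
    if (n_transcripts == 0L) {
      n_intergenic <- n_variants
      n_exonic <- n_intronic <- 0L
    }

    dna_flip <- c(A = "T", C = "G", G = "C", T = "A")
    variants <- list(); truth <- list()
    vid <- 0L
    add_variant <- function(chrom, pos, ref, alt) {
      vid <<- vid + 1L
      variants[[vid]] <<- data.frame(
        id = sprintf("rs%04d", vid), chrom = chrom, pos = pos,
        ref = ref, alt = alt, trait = "t1d", stringsAsFactors = FALSE)
      sprintf("rs%04d", vid)
    }

    for (i in seq_len(n_exonic)) {
      ti <- sample(length(transcripts), 1L)
      tx <- transcripts[[ti]]
      sp <- sample(spliced_length(tx), 1L)
      gpos <- spliced_to_genomic(tx, sp)
      base <- substr(sequences[[tx$id]], sp, sp)     # transcript-oriented
      ref <- if (tx$strand == "+") base else dna_flip[[base]]
      alt_tx <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      alt <- if (tx$strand == "+") alt_tx else dna_flip[[alt_tx]]
      id <- add_variant(tx$chrom, gpos, ref, alt)
      truth[[length(truth) + 1L]] <- data.frame(
        variant_id = id, transcript_id = tx$id, region = "exonic",
        spliced_pos = sp, stringsAsFactors = FALSE)
    }

    for (i in seq_len(n_intronic)) {
      ti <- if (length(with_introns) == 1L) with_introns else
        sample(with_introns, 1L)
      tx <- transcripts[[ti]]
      s <- IRanges::start(tx$exons); e <- IRanges::end(tx$exons)
      gap <- sample(length(s) - 1L, 1L)
      gpos <- sample((e[gap] + 1L):(s[gap + 1L] - 1L), 1L)
      alleles <- sample(c("A", "C", "G", "T"), 2L)
      id <- add_variant(tx$chrom, gpos, alleles[1], alleles[2])
      truth[[length(truth) + 1L]] <- data.frame(
        variant_id = id, transcript_id = tx$id, region = "intronic",
        spliced_pos = NA_integer_, stringsAsFactors = FALSE)
    }

    for (i in seq_len(n_intergenic)) {
      chrom <- sample(chroms, 1L)
      gpos <- cursor[[chrom]] + sample(1000:100000, 1L)
      cursor[[chrom]] <- gpos                        # keep them distinct
      alleles <- sample(c("A", "C", "G", "T"), 2L)
      add_variant(chrom, gpos, alleles[1], alleles[2])
    }

    variants <- if (vid > 0L) do.call(rbind, variants) else
      data.frame(id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(), trait = character(),
                 stringsAsFactors = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(variant_id = character(), transcript_id = character(),
                 region = character(), spliced_pos = integer(),
                 stringsAsFactors = FALSE)
    truth <- truth[order(truth$variant_id, truth$transcript_id), ,
                   drop = FALSE]
    rownames(truth) <- NULL

    list(variants = variants, transcripts = transcripts,
         sequences = sequences, truth = truth,
         truth_record = list(generator = "simulate_locus_set", seed = seed,
                             n_transcripts = n_transcripts,
                             n_variants = n_variants,
                             exonic_fraction = exonic_fraction,
                             n_exonic = n_exonic, n_intronic = n_intronic,
                             n_intergenic = n_intergenic))
  })
}

#' Write a simulated locus set to disk in the pipeline's input dialects
#'
#' @param sim Result of [simulate_locus_set()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written (`variants`,
#'   `annotation`, `fasta`, `truth`).
#' @export
write_locus_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             annotation = file.path(dir, "transcripts.bed"),
             fasta = file.path(dir, "transcripts.fa"),
             truth = file.path(dir, "truth.json"))
  write.table(sim$variants, paths[["variants"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_transcripts_bed12(sim$transcripts, paths[["annotation"]])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$sequences), paths[["fasta"]])
  jsonlite::write_json(
    list(truth = sim$truth, truth_record = sim$truth_record),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' Simulate a qPCR Ct experiment with a planted fold change
#'
#' Reference-gene Cts are drawn around 20 cycles and target-gene baseline
#' Cts around 24, each with independent Gaussian noise; in the treated
#' condition the target Ct is shifted by `-log2(true_fold)`.
#'
#' @param true_fold Planted fold change (> 0).
#' @param n_reps Biological replicates per condition.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed Integer seed.
#' @return List with `ct_table` (columns `sample`, `condition`, `gene`,
#'   `replicate`, `ct`) and `truth`.
#' @export
simulate_ct_experiment <- function(true_fold, n_reps = 3L, noise_sd = 0.2,
                                   seed = 1L) {
  if (!is.finite(true_fold) || true_fold <= 0)
    stop("true_fold must be > 0")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  withr::with_seed(seed, {
    shift <- -log2(true_fold)
    grid <- expand.grid(replicate = seq_len(n_reps),
                        condition = c("baseline", "treated"),
                        gene = c("target", "reference"),
                        stringsAsFactors = FALSE)
    mu <- ifelse(grid$gene == "reference", 20,
                 ifelse(grid$condition == "treated", 24 + shift, 24))
    ct_table <- data.frame(
      sample = sprintf("S%02d", grid$replicate),
      condition = grid$condition, gene = grid$gene,
      replicate = grid$replicate,
      ct = rnorm(nrow(grid), mean = mu, sd = noise_sd),
      stringsAsFactors = FALSE)
    list(ct_table = ct_table,
         truth = list(generator = "simulate_ct_experiment", seed = seed,
                      true_fold = true_fold, n_reps = n_reps,
                      noise_sd = noise_sd))
  })
}

#' Simulate an RNA-seq count matrix (gamma-Poisson)
#'
#' Gene means are log-normal (log-mean 4, log-sd 1.5 on the natural
#' scale), per-sample library-size multipliers are log-uniform in
#' \[0.5, 2\], and counts are drawn negative-binomially with the stated
#' dispersion (`dispersion = 0` reduces to Poisson).
#'
#' @param n_genes,n_samples Matrix dimensions (>= 1).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @return Integer count matrix with gene/sample dimnames and attributes
#'   `gene_means`, `lib_factors`.
#' @export
simulate_counts <- function(n_genes = 1000L, n_samples = 6L, seed = 1L,
                            dispersion = 0.1) {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  if (n_genes < 1L || n_samples < 1L) stop("sizes must be >= 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  withr::with_seed(seed, {
    mu_g <- rlnorm(n_genes, meanlog = 4, sdlog = 1.5)
    lib <- exp(runif(n_samples, log(0.5), log(2)))
    mu <- outer(mu_g, lib)
    counts <- if (dispersion > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, n_samples)
    else matrix(rpois(length(mu), lambda = mu), n_genes, n_samples)
    dimnames(counts) <- list(sprintf("G%05d", seq_len(n_genes)),
                             sprintf("S%02d", seq_len(n_samples)))
    attr(counts, "gene_means") <- mu_g
    attr(counts, "lib_factors") <- lib
    counts
  })
}

#' Simulate a differential-expression table with planted set enrichment
#'
#' Selection ("significantly upregulated": FDR below 0.05 and positive
#' log2 fold change) is assigned by weighted sampling without
#' replacement, gene-set members carrying `enrichment_odds` times the
#' weight of non-members; `enrichment_odds = 1` is the exact
#' hypergeometric null. The table's `fdr`, `pvalue`, and `log2fc` columns
#' are populated consistently with the selection.
#'
#' @param n_genes Detected genes (N).
#' @param set_size Gene-set members among them (K).
#' @param n_selected Selected genes (n).
#' @param enrichment_odds Selection odds ratio for set members (>= 1).
#' @param seed Integer seed.
#' @return List with `de_table`, `gene_set` (list `name`, `members`), and
#'   `truth`.
#' @export
simulate_de_results <- function(n_genes, set_size, n_selected,
                                enrichment_odds = 1, seed = 1L) {
  n_genes <- as.integer(n_genes); set_size <- as.integer(set_size)
  n_selected <- as.integer(n_selected)
  if (set_size > n_genes) stop("set_size must be <= n_genes")
  if (n_selected > n_genes) stop("n_selected must be <= n_genes")
  if (enrichment_odds < 1) stop("enrichment_odds must be >= 1")
  withr::with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    members <- sample(genes, set_size)
    sel_idx <- if (enrichment_odds == 1) sample.int(n_genes, n_selected)
    else sample.int(n_genes, n_selected,
                    prob = ifelse(genes %in% members, enrichment_odds, 1))
    selected <- logical(n_genes); selected[sel_idx] <- TRUE

    fdr <- ifelse(selected, runif(n_genes, 0, 0.049),
                  runif(n_genes, 0.051, 1))
    de <- data.frame(
      gene = genes,
      log2fc = ifelse(selected, abs(rnorm(n_genes, 1.5, 0.5)),
                      rnorm(n_genes, 0, 1)),
      pvalue = fdr * runif(n_genes),
      fdr = fdr, stringsAsFactors = FALSE)
    list(de_table = de,
         gene_set = list(name = "planted_set", members = members),
         truth = list(generator = "simulate_de_results", seed = seed,
                      n_genes = n_genes, set_size = set_size,
                      n_selected = n_selected,
                      enrichment_odds = enrichment_odds,
                      k_selected_members = sum(selected &
                                               genes %in% members)))
  })
}
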