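# Variant tables, transcript models, and their intersection: the front of
# the prioritization funnel. Coordinates are 1-based closed intervals
# internally (the IRanges convention); BED12's 0-based half-open records
# are converted on read and restored on write.

normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  special <- toupper(x) %in% c("X", "Y", "MT", "M")
  x[special] <- toupper(x[special])
  x[x == "M"] <- "MT"
  x
}

#' Read a variant association table
#'
#' Two dialects are supported: `"generic"` (TSV with columns `id`,
#' `chrom`, `pos`, and optional `ref`, `alt`, `trait`) and
#' `"gwas_catalog"` (columns `SNPS`, `CHR_ID`, `CHR_POS`, optionally
#' `DISEASE/TRAIT`). Positions are 1-based. Chromosome names are
#' normalized (leading "chr" stripped, X/Y/MT upper-cased) so variant and
#' annotation sources that disagree on naming still intersect. Rows whose
#' position is not numeric are skipped and counted.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect `"generic"` or `"gwas_catalog"`.
#' @return A data.frame with columns `id`, `chrom`, `pos` (1-based
#'   integer), `ref`, `alt` (NA when absent), `trait`, and an attribute
#'   `n_skipped` giving the skipped-row tally.
#' @export
read_variant_table <- function(path, dialect = c("generic", "gwas_catalog")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) stop("variant table is empty: ", path)

  if (dialect == "gwas_catalog") {
    required <- c("SNPS", "CHR_ID", "CHR_POS")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("gwas_catalog table lacks required column(s): ",
           paste(missing, collapse = ", "))
    out <- data.frame(
      id = df$SNPS, chrom = df$CHR_ID, pos_raw = df$CHR_POS,
      ref = NA_character_, alt = NA_character_,
      trait = if ("DISEASE/TRAIT" %in% names(df)) df[["DISEASE/TRAIT"]]
              else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    required <- c("id", "chrom", "pos")
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("generic variant table lacks required column(s): ",
           paste(missing, collapse = ", "))
    out <- data.frame(
      id = df$id, chrom = df$chrom, pos_raw = df$pos,
      ref = if ("ref" %in% names(df)) toupper(df$ref) else NA_character_,
      alt = if ("alt" %in% names(df)) toupper(df$alt) else NA_character_,
      trait = if ("trait" %in% names(df)) df$trait else NA_character_,
      stringsAsFactors = FALSE)
  }

  pos <- suppressWarnings(as.integer(out$pos_raw))
  keep <- !is.na(pos) & pos >= 1L
  n_skipped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out$pos <- pos[keep]
  out$pos_raw <- NULL
  out$chrom <- normalize_chrom(out$chrom)
  out$ref[out$ref %in% c("", "NA", ".")] <- NA_character_
  out$alt[out$alt %in% c("", "NA", ".")] <- NA_character_
  bad_alleles <- !is.na(out$ref) & !is.na(out$alt) &
    (!out$ref %in% c("A", "C", "G", "T") |
     !out$alt %in% c("A", "C", "G", "T") | out$ref == out$alt)
  if (any(bad_alleles))
    stop("invalid ref/alt alleles for variant(s): ",
         paste(head(out$id[bad_alleles], 5), collapse = ", "))
  rownames(out) <- NULL
  out <- out[, c("id", "chrom", "pos", "ref", "alt", "trait")]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Construct a transcript model
#'
#' @param id,gene_id Transcript and gene identifiers.
#' @param chrom Chromosome (normalized with the same rules as variants).
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends 1-based closed exon coordinates.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, gene_id, chrom, strand, exon_starts,
                             exon_ends) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) < 1L || length(exon_starts) != length(exon_ends))
    stop("need matching, non-empty exon start/end vectors")
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (any(exon_ends < exon_starts))
    stop("transcript ", id, ": exon end before start")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1] <= exon_ends[-length(exon_ends)]))
    stop("transcript ", id, ": overlapping exons")
  structure(
    list(id = as.character(id), gene_id = as.character(gene_id),
         chrom = normalize_chrom(chrom), strand = strand,
         exons = IRanges::IRanges(start = exon_starts, end = exon_ends)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript %s (gene %s) %s:%s [%s], %d exon(s), %d nt spliced\n",
              x$id, x$gene_id, x$chrom,
              paste0(min(IRanges::start(x$exons)), "-",
                     max(IRanges::end(x$exons))),
              x$strand, length(x$exons), spliced_length(x)))
  invisible(x)
}

#' Spliced (mature) length of a transcript model
#' @param tx A `transcript_model`.
#' @return Integer number of exonic bases.
#' @export
spliced_length <- function(tx) sum(IRanges::width(tx$exons))

#' Read transcript annotation (BED12 or GTF)
#'
#' BED12 files are read with \pkg{rtracklayer}; blocks become exons. GTF
#' exon features are grouped by their `transcript_id` attribute (1-based
#' closed coordinates, per the Ensembl convention). Duplicate transcript
#' ids and overlapping exons within a transcript are errors.
#'
#' @param path Annotation file.
#' @param format `"bed12"` or `"gtf"`.
#' @return Named list of [transcript_model()] objects.
#' @export
read_transcripts <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "bed12") {
    g <- rtracklayer::import(path, format = "bed")
    ids <- g$name
    if (anyDuplicated(ids))
      stop("duplicate transcript id(s) in BED12: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    bl <- rtracklayer::blocks(g)
    txs <- lapply(seq_along(g), function(i) {
      ex <- bl[[i]]
      gene <- if (!is.null(g$gene_id)) g$gene_id[i] else ids[i]
      transcript_model(ids[i], gene,
                       as.character(GenomicRanges::seqnames(g)[i]),
                       as.character(GenomicRanges::strand(g)[i]),
                       GenomicRanges::start(ex), GenomicRanges::end(ex))
    })
  } else {
    g <- rtracklayer::import(path, format = "gtf")
    g <- g[!is.na(g$type) & g$type == "exon"]
    if (length(g) == 0L) stop("no exon features in GTF: ", path)
    if (is.null(g$transcript_id) || anyNA(g$transcript_id))
      stop("GTF exon features must carry a transcript_id attribute")
    split_idx <- split(seq_along(g), g$transcript_id)
    txs <- lapply(names(split_idx), function(tid) {
      gi <- g[split_idx[[tid]]]
      chroms <- unique(as.character(GenomicRanges::seqnames(gi)))
      if (length(chroms) > 1L)
        stop("transcript ", tid, " spans multiple chromosomes")
      gene <- if (!is.null(gi$gene_id)) gi$gene_id[1] else tid
      transcript_model(tid, gene, chroms[1],
                       as.character(GenomicRanges::strand(gi)[1]),
                       GenomicRanges::start(gi), GenomicRanges::end(gi))
    })
  }
  names(txs) <- vapply(txs, `[[`, character(1), "id")
  txs
}

#' Write transcript models as BED12
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output file.
#' @param chrom_prefix Optional prefix (e.g. `"chr"`) restored on output.
#' @return `path`, invisibly.
#' @export
write_transcripts_bed12 <- function(transcripts, path, chrom_prefix = "") {
  lines <- vapply(transcripts, function(tx) {
    s <- IRanges::start(tx$exons); e <- IRanges::end(tx$exons)
    chrom_start <- min(s) - 1L
    paste(paste0(chrom_prefix, tx$chrom), chrom_start, max(e), tx$id, 0L,
          tx$strand, chrom_start, max(e), 0L, length(s),
          paste0(paste(e - s + 1L, collapse = ","), ","),
          paste0(paste(s - 1L - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

as_granges <- function(transcripts, what = c("span", "exons"),
                       seqlevels = NULL) {
  what <- match.arg(what)
  chroms <- vapply(transcripts, `[[`, character(1), "chrom")
  if (is.null(seqlevels)) seqlevels <- unique(chroms)
  if (what == "span") {
    GenomicRanges::GRanges(
      seqnames = factor(chroms, levels = seqlevels),
      ranges = IRanges::IRanges(
        start = vapply(transcripts,
                       function(tx) min(IRanges::start(tx$exons)), integer(1)),
        end = vapply(transcripts,
                     function(tx) max(IRanges::end(tx$exons)), integer(1))),
      tx_id = vapply(transcripts, `[[`, character(1), "id"))
  } else {
    parts <- lapply(transcripts, function(tx)
      GenomicRanges::GRanges(tx$chrom, tx$exons, tx_id = tx$id))
    do.call(c, unname(parts))
  }
}

#' Intersect variants with transcript models
#'
#' A variant is reported against every transcript whose genomic span
#' (first exon start to last exon end, strand ignored) contains its
#' position; the hit is `exonic` if the position falls inside an exon and
#' `intronic` otherwise. Exonic rows carry the 1-based position of the
#' variant on the mature spliced transcript (strand-aware; see
#' [genomic_to_spliced()]). Variants outside every transcript yield no
#' row. Output is ordered by variant id, then transcript id.
#'
#' @param variants Data.frame as returned by [read_variant_table()].
#' @param transcripts List of [transcript_model()] objects.
#' @return Data.frame with columns `variant_id`, `transcript_id`,
#'   `region` (`"exonic"`/`"intronic"`), `spliced_pos` (NA for intronic).
#' @export
intersect_variants <- function(variants, transcripts) {
  empty <- data.frame(variant_id = character(), transcript_id = character(),
                      region = character(), spliced_pos = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0L || length(transcripts) == 0L) return(empty)

  lv <- union(unique(variants$chrom),
              vapply(transcripts, `[[`, character(1), "chrom"))
  vg <- GenomicRanges::GRanges(factor(variants$chrom, levels = lv),
                               IRanges::IRanges(variants$pos, variants$pos))
  spans <- as_granges(transcripts, "span", seqlevels = lv)
  hits <- GenomicRanges::findOverlaps(vg, spans, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)

  vi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(vi), function(h) {
    tx <- transcripts[[ti[h]]]
    pos <- variants$pos[vi[h]]
    exonic <- any(pos >= IRanges::start(tx$exons) &
                  pos <= IRanges::end(tx$exons))
    data.frame(variant_id = variants$id[vi[h]],
               transcript_id = tx$id,
               region = if (exonic) "exonic" else "intronic",
               spliced_pos = if (exonic) genomic_to_spliced(tx, pos)
                             else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$variant_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a genomic position to the mature transcript coordinate
#'
#' Returns the 1-based offset of a genomic position along the spliced
#' transcript read 5' to 3'. For minus-strand transcripts the mature
#' sequence runs from the highest genomic coordinate downward.
#'
#' @param tx A [transcript_model()].
#' @param pos 1-based genomic position; must be exonic.
#' @return 1-based integer position on the mature transcript.
#' @export
genomic_to_spliced <- function(tx, pos) {
  pos <- as.integer(pos)
  s <- IRanges::start(tx$exons); e <- IRanges::end(tx$exons)
  hit <- which(pos >= s & pos <= e)
  if (length(hit) != 1L)
    stop("position ", pos, " is not exonic on transcript ", tx$id)
  plus_offset <- sum(IRanges::width(tx$exons)[seq_len(hit - 1L)]) +
    (pos - s[hit] + 1L)
  if (tx$strand == "+") plus_offset
  else spliced_length(tx) - plus_offset + 1L
}

#' Map a mature transcript coordinate back to the genome
#'
#' Exact inverse of [genomic_to_spliced()].
#'
#' @param tx A [transcript_model()].
#' @param spliced_pos 1-based position on the mature transcript.
#' @return 1-based genomic position.
#' @export
spliced_to_genomic <- function(tx, spliced_pos) {
  spliced_pos <- as.integer(spliced_pos)
  n <- spliced_length(tx)
  if (is.na(spliced_pos) || spliced_pos < 1L || spliced_pos > n)
    stop("spliced_pos out of range 1..", n, " on transcript ", tx$id)
  plus_offset <- if (tx$strand == "+") spliced_pos else n - spliced_pos + 1L
  w <- IRanges::width(tx$exons)
  cum <- cumsum(w)
  ex <- which(plus_offset <= cum)[1]
  within <- plus_offset - (if (ex > 1L) cum[ex - 1L] else 0L)
  IRanges::start(tx$exons)[ex] + within - 1L
}

#' Orient genomic alleles into transcript space
#'
#' GWAS-style tables report alleles on the plus genomic strand; for a
#' minus-strand transcript the mature sequence carries their complements.
#'
#' @param ref,alt Plus-strand DNA alleles.
#' @param strand Transcript strand.
#' @return List with `ref` and `alt` as RNA bases in transcript
#'   orientation.
#' @export
orient_alleles <- function(ref, alt, strand) {
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% names(flip) || !alt %in% names(flip))
    stop("alleles must be single DNA bases (A/C/G/T)")
  if (strand == "-") { ref <- flip[[ref]]; alt <- flip[[alt]] }
  list(ref = chartr("T", "U", ref), alt = chartr("T", "U", alt))
}

#' Summarize the prioritization funnel
#'
#' Counts distinct transcripts at each stage -- overlapped by any variant,
#' carrying an exonic variant, and carrying at least one
#' structure-disruptive variant -- plus a gene-level rollup, and attaches
#' the per-candidate table.
#'
#' @param variants Variant data.frame.
#' @param transcripts List of [transcript_model()] objects.
#' @param overlaps Result of [intersect_variants()]; recomputed when
#'   omitted.
#' @param calls Optional data.frame of disruption calls with columns
#'   `variant_id`, `transcript_id`, `score`, `empirical_p`, `disruptive`.
#'   Every (variant, transcript) pair must appear in `overlaps`.
#' @return A `funnel_report`: list of stage counts and the candidate
#'   table.
#' @export
funnel_report <- function(variants, transcripts, overlaps = NULL,
                          calls = NULL) {
  if (is.null(overlaps)) overlaps <- intersect_variants(variants, transcripts)
  gene_of <- vapply(transcripts, `[[`, character(1), "gene_id")

  if (!is.null(calls) && nrow(calls)) {
    key <- paste(calls$variant_id, calls$transcript_id)
    known <- paste(overlaps$variant_id, overlaps$transcript_id)
    if (!all(key %in% known))
      stop("disruption call(s) reference unknown variant/transcript pair(s): ",
           paste(head(setdiff(key, known), 5), collapse = "; "))
  }

  exonic <- overlaps[overlaps$region == "exonic", , drop = FALSE]
  disrupted_tx <- if (!is.null(calls) && nrow(calls))
    unique(calls$transcript_id[calls$disruptive]) else character()

  candidates <- exonic
  if (!is.null(calls) && nrow(calls)) {
    candidates <- merge(exonic, calls, by = c("variant_id", "transcript_id"),
                        all.x = TRUE, sort = FALSE)
  } else {
    candidates$score <- rep(NA_real_, nrow(candidates))
    candidates$empirical_p <- rep(NA_real_, nrow(candidates))
    candidates$disruptive <- rep(NA, nrow(candidates))
  }
  candidates <- candidates[order(candidates$variant_id,
                                 candidates$transcript_id), , drop = FALSE]
  rownames(candidates) <- NULL

  tx_overlap <- unique(overlaps$transcript_id)
  tx_exonic <- unique(exonic$transcript_id)
  structure(list(
    n_variants = nrow(variants),
    n_transcripts = length(transcripts),
    n_with_any_overlap = length(tx_overlap),
    n_with_exonic_overlap = length(tx_exonic),
    n_structure_disrupted = length(disrupted_tx),
    n_genes_any_overlap = length(unique(gene_of[tx_overlap])),
    n_genes_exonic = length(unique(gene_of[tx_exonic])),
    n_genes_disrupted = length(unique(gene_of[disrupted_tx])),
    candidates = candidates),
    class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Variant prioritization funnel\n")
  cat(sprintf("  %d variants vs %d transcripts\n",
              x$n_variants, x$n_transcripts))
  cat(sprintf("  transcripts with any overlap:    %d (genes: %d)\n",
              x$n_with_any_overlap, x$n_genes_any_overlap))
  cat(sprintf("  ... with an exonic variant:      %d (genes: %d)\n",
              x$n_with_exonic_overlap, x$n_genes_exonic))
  cat(sprintf("  ... with structure disruption:   %d (genes: %d)\n",
              x$n_structure_disrupted, x$n_genes_disrupted))
  invisible(x)
}
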