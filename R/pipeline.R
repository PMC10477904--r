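# Orchestration of the prioritization funnel: read variant table,
# annotation, and transcript sequences; intersect; map exonic hits onto
# mature transcripts; orient alleles; score structure disruption; and
# summarize the funnel. Outputs are deterministic under a fixed seed and
# every output file names the run-manifest hash.

#' Build a run configuration for the prioritization pipeline
#'
#' @param variants,annotation,fasta Input paths (variant TSV, BED12/GTF
#'   annotation, mature transcript FASTA keyed by transcript id).
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @param seed Master seed; each scored variant derives its own seed from
#'   it deterministically.
#' @param variant_dialect,annotation_format Passed to the readers.
#' @param window,b,alpha,metric,l_min Structure-scoring parameters (see
#'   [score_variant()]).
#' @param e_gc,e_au,e_gu,temperature,min_hairpin Energy-model parameters
#'   (see [pair_energy_model()]).
#' @return A `run_config` list.
#' @export
run_config <- function(variants, annotation, fasta, out_dir = NULL,
                       seed = 1L, variant_dialect = "generic",
                       annotation_format = "bed12", window = 200L,
                       b = 200L, alpha = 0.1, metric = "d_local",
                       l_min = 10L, e_gc = -3, e_au = -2, e_gu = -1,
                       temperature = 310.15, min_hairpin = 3L) {
  cfg <- list(variants = variants, annotation = annotation, fasta = fasta,
              out_dir = out_dir, seed = as.integer(seed),
              variant_dialect = variant_dialect,
              annotation_format = annotation_format,
              window = as.integer(window), b = as.integer(b),
              alpha = alpha, metric = metric, l_min = as.integer(l_min),
              e_gc = e_gc, e_au = e_au, e_gu = e_gu,
              temperature = temperature,
              min_hairpin = as.integer(min_hairpin))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; anything omitted keeps
#' its default. Command-line overrides can be supplied through `...`.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

read_transcript_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Run the variant prioritization funnel
#'
#' Executes read, intersect, spliced mapping, allele orientation, and
#' structure-disruption scoring for every exonic, allele-bearing variant,
#' then summarizes the funnel. Variants lacking alleles are counted in
#' the overlap and exonic stages but excluded (and tallied) from the
#' structure stage, since disruption scoring needs both alleles. When
#' `config$out_dir` is set, writes `manifest.json`, `candidates.tsv`, and
#' `funnel.json`, each stamped with the manifest MD5 hash.
#'
#' @param config A [run_config()].
#' @return List of class `prioritize_result` with `funnel`
#'   ([funnel_report()]), `calls` (per-pair data.frame), `overlaps`,
#'   `n_unscoreable` (exonic pairs lacking alleles), `manifest`, and
#'   `files` (paths written, or `NULL`).
#' @export
run_prioritize <- function(config) {
  stopifnot(inherits(config, "run_config"))
  variants <- read_variant_table(config$variants,
                                 dialect = config$variant_dialect)
  transcripts <- read_transcripts(config$annotation,
                                  format = config$annotation_format)
  sequences <- read_transcript_fasta(config$fasta)

  missing_seq <- setdiff(names(transcripts), names(sequences))
  if (length(missing_seq))
    stop("transcript id(s) in annotation but absent from FASTA: ",
         paste(missing_seq, collapse = ", "))
  bad_len <- names(transcripts)[vapply(names(transcripts), function(tid)
    nchar(sequences[[tid]]) != spliced_length(transcripts[[tid]]),
    logical(1))]
  if (length(bad_len))
    stop("FASTA length disagrees with spliced length for: ",
         paste(bad_len, collapse = ", "))

  model <- pair_energy_model(config$e_gc, config$e_au, config$e_gu,
                             config$temperature, config$min_hairpin)
  overlaps <- intersect_variants(variants, transcripts)
  exonic <- overlaps[overlaps$region == "exonic", , drop = FALSE]

  calls <- list()
  n_unscoreable <- 0L
  for (i in seq_len(nrow(exonic))) {
    v <- variants[match(exonic$variant_id[i], variants$id), ]
    if (is.na(v$ref) || is.na(v$alt)) {
      n_unscoreable <- n_unscoreable + 1L
      next
    }
    tx <- transcripts[[exonic$transcript_id[i]]]
    al <- orient_alleles(v$ref, v$alt, tx$strand)
    seq <- chartr("T", "U", sequences[[tx$id]])
    call <- score_variant(seq, exonic$spliced_pos[i], al$ref, al$alt,
                          window = config$window, model = model,
                          metric = config$metric, b = config$b,
                          alpha = config$alpha,
                          seed = config$seed + i, l_min = config$l_min)
    calls[[length(calls) + 1L]] <- data.frame(
      variant_id = exonic$variant_id[i], transcript_id = tx$id,
      spliced_pos = exonic$spliced_pos[i],
      metric = config$metric, score = call$observed,
      empirical_p = call$empirical_p, disruptive = call$disruptive,
      b = call$b, seed = config$seed + i,
      window_start = call$window[["start"]],
      window_end = call$window[["end"]], stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(variant_id = character(), transcript_id = character(),
               spliced_pos = integer(), metric = character(),
               score = numeric(), empirical_p = numeric(),
               disruptive = logical(), b = integer(), seed = integer(),
               window_start = integer(), window_end = integer(),
               stringsAsFactors = FALSE)

  funnel <- funnel_report(variants, transcripts, overlaps, calls)

  manifest <- list(
    inputs = list(variants = config$variants,
                  annotation = config$annotation, fasta = config$fasta),
    parameters = config[c("seed", "variant_dialect", "annotation_format",
                          "window", "b", "alpha", "metric", "l_min",
                          "e_gc", "e_au", "e_gu", "temperature",
                          "min_hairpin")],
    n_variants_skipped = attr(variants, "n_skipped"),
    n_unscoreable = n_unscoreable)

  files <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    hash <- unname(tools::md5sum(manifest_path))

    cand_path <- file.path(config$out_dir, "candidates.tsv")
    con <- file(cand_path, "w")
    writeLines(paste0("# manifest: ", hash), con)
    write.table(funnel$candidates, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)

    funnel_path <- file.path(config$out_dir, "funnel.json")
    jsonlite::write_json(
      c(list(manifest_hash = hash),
        unclass(funnel)[c("n_variants", "n_transcripts",
                          "n_with_any_overlap", "n_with_exonic_overlap",
                          "n_structure_disrupted", "n_genes_any_overlap",
                          "n_genes_exonic", "n_genes_disrupted")]),
      funnel_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(manifest = manifest_path, candidates = cand_path,
               funnel = funnel_path)
    manifest$hash <- hash
  }

  structure(list(funnel = funnel, calls = calls, overlaps = overlaps,
                 n_unscoreable = n_unscoreable, manifest = manifest,
                 files = files),
            class = "prioritize_result")
}

#' @export
print.prioritize_result <- function(x, ...) {
  print(x$funnel)
  if (x$n_unscoreable > 0)
    cat(sprintf("  (%d exonic pair(s) lacked alleles and were not scored)\n",
                x$n_unscoreable))
  invisible(x)
}
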