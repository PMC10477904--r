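# RNA-seq post-processing arithmetic: low-count filtering, upper-quartile
# normalization, BH adjustment, and hypergeometric overrepresentation of a
# gene set among upregulated genes.

#' Filter genes by a minimum count in a minimum number of samples
#'
#' A gene is kept when strictly more than `min_count` reads are observed
#' in at least `min_samples` samples. Gene order is preserved; the filter
#' is idempotent.
#'
#' @param counts Integer matrix (genes x samples) with rownames.
#' @param min_count Count a sample must strictly exceed.
#' @param min_samples Minimum number of qualifying samples.
#' @return The filtered count matrix.
#' @examples
#' m <- rbind(keep = c(11, 12, 13, 0), drop = c(10, 10, 10, 10))
#' rownames(filter_low_counts(m, min_samples = 3))
#' @export
filter_low_counts <- function(counts, min_count = 10, min_samples = 3) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (min_samples > ncol(counts))
    stop("min_samples (", min_samples, ") exceeds the sample count (",
         ncol(counts), ")")
  keep <- rowSums(counts > min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Upper-quartile normalization
#'
#' For each sample, the 75th percentile (linear interpolation between
#' order statistics) of the counts of genes that are nonzero in at least
#' one sample defines the scale `UQ_j`; size factors are
#' `f_j = UQ_j / geometric-mean(UQ)` and normalized counts are
#' `count / f_j`. Centering by the geometric mean keeps the overall count
#' scale while equalizing the upper quartiles across samples.
#'
#' @param counts Count matrix (genes x samples), usually after
#'   [filter_low_counts()].
#' @return List with `normalized` (matrix) and `factors` (per-sample size
#'   factors).
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L || nrow(counts) < 1L)
    stop("count matrix must be non-empty")
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  expressed <- rowSums(counts) > 0
  uq <- apply(counts[expressed, , drop = FALSE], 2, quantile,
              probs = 0.75, names = FALSE, type = 7)
  if (any(uq <= 0))
    stop("upper quartile is zero for sample(s): ",
         paste(colnames(counts)[uq <= 0], collapse = ", "))
  f <- uq / exp(mean(log(uq)))
  list(normalized = sweep(counts, 2, f, `/`), factors = f)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Upper-tail hypergeometric test
#'
#' Probability of observing at least `k` gene-set members among `n` genes
#' drawn without replacement from `N` genes of which `K` belong to the
#' set. Computed through the hypergeometric distribution function (log
#' space internally), so it stays accurate for large `N`.
#'
#' @param N Total genes. @param K Set members among them.
#' @param n Selected genes. @param k Set members among the selection.
#' @return Upper-tail p-value, `P(X >= k)`.
#' @examples
#' hypergeometric_test(20, 5, 5, 3) # 1126/15504
#' @export
hypergeometric_test <- function(N, K, n, k) {
  vals <- c(N, K, n, k)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("N, K, n, k must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need K <= N, n <= N, k <= min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a gene set (one id per line, or single-set GMT)
#'
#' @param path Newline-delimited ids, or a GMT line
#'   (`name <TAB> description <TAB> gene1 <TAB> ...`).
#' @param name Set name for the plain dialect.
#' @return List with `name` and unique `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("gene set file is empty: ", path)
  if (length(lines) == 1L && grepl("\t", lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line in ", path)
    return(list(name = parts[1], members = unique(parts[-(1:2)])))
  }
  list(name = if (is.null(name)) basename(path) else name,
       members = unique(trimws(lines)))
}

#' Gene-set overrepresentation among selected genes
#'
#' Tests whether a gene set is overrepresented among the significantly
#' regulated genes of a differential-expression table: `N` detected
#' genes, `K` detected set members, `n` selected genes (FDR below the
#' threshold and fold change in the requested direction), `k` selected
#' set members, with an upper-tail hypergeometric p-value. Fractions are
#' reported as percentages rounded to one decimal.
#'
#' @param de_table Data.frame with columns `gene`, `log2fc`, and `fdr`
#'   (or `pvalue`, from which FDR is derived by [bh_fdr()]); one row per
#'   detected gene.
#' @param gene_set Character vector of member ids, or the list returned
#'   by [read_gene_set()].
#' @param fdr_threshold Selection threshold on FDR.
#' @param direction `"up"` (log2fc > 0) or `"down"` (log2fc < 0).
#' @return An `enrichment_result`: list with `N`, `K`, `n`, `k`,
#'   `background_pct`, `selected_pct`, `p_value`, `set_name`.
#' @export
enrich_gene_set <- function(de_table, gene_set, fdr_threshold = 0.05,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.list(gene_set)) {
    set_name <- gene_set$name
    members <- gene_set$members
  } else {
    set_name <- "gene_set"
    members <- gene_set
  }
  members <- unique(members)
  if (nrow(de_table) == 0L) stop("differential-expression table is empty")
  required <- c("gene", "log2fc")
  missing <- setdiff(required, names(de_table))
  if (length(missing))
    stop("DE table lacks column(s): ", paste(missing, collapse = ", "))
  if (!"fdr" %in% names(de_table)) {
    if (!"pvalue" %in% names(de_table))
      stop("DE table needs an 'fdr' or 'pvalue' column")
    de_table$fdr <- bh_fdr(de_table$pvalue)
  }
  if (anyDuplicated(de_table$gene))
    stop("DE table has duplicated gene ids")

  in_set <- de_table$gene %in% members
  selected <- de_table$fdr < fdr_threshold &
    (if (direction == "up") de_table$log2fc > 0 else de_table$log2fc < 0)
  N <- nrow(de_table)
  K <- sum(in_set)
  n <- sum(selected)
  k <- sum(selected & in_set)
  structure(list(
    N = N, K = K, n = n, k = k,
    background_pct = round(100 * K / N, 1),
    selected_pct = if (n > 0) round(100 * k / n, 1) else NA_real_,
    p_value = if (K == 0 || n == 0) 1 else hypergeometric_test(N, K, n, k),
    set_name = set_name,
    fdr_threshold = fdr_threshold, direction = direction),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Gene-set overrepresentation: %s\n", x$set_name))
  cat(sprintf("  detected: %d genes, %d in set (%.1f%%)\n",
              x$N, x$K, x$background_pct))
  cat(sprintf("  selected (%s, FDR < %g): %d genes, %d in set (%s%%)\n",
              x$direction, x$fdr_threshold, x$n, x$k,
              ifelse(is.na(x$selected_pct), "NA",
                     sprintf("%.1f", x$selected_pct))))
  cat(sprintf("  upper-tail hypergeometric p = %.4g\n", x$p_value))
  invisible(x)
}

#' Read a count matrix from TSV
#' @param path Genes-by-samples TSV with gene ids in the first column.
#' @return Integer matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE, comment.char = "#")
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  if (any(m < 0) || any(m != round(m)))
    stop("count matrix must contain non-negative integers")
  m
}

#' Read a differential-expression table from TSV
#' @param path TSV with columns `gene`, `log2fc`, `pvalue` and/or `fdr`.
#' @return Data.frame.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "log2fc") %in% names(df)))
    stop("DE table needs at least 'gene' and 'log2fc' columns")
  df
}
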