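# qPCR relative-expression arithmetic and the significance tests used
# alongside it: 2^-ddCt fold changes, per-replicate max-normalization,
# nuclear/whole-cell localization ratios, and induction screening.

#' Relative expression by the 2^-ddCt method
#'
#' Computes `dCt = Ct(target) - Ct(reference)` in the condition and the
#' baseline, and the fold change `2^-(dCt_condition - dCt_baseline)`.
#' Technical replicate Cts should be averaged before calling (see
#' [average_technical_replicates()]).
#'
#' @param ct_target_cond,ct_ref_cond Target and reference-gene Ct in the
#'   condition of interest.
#' @param ct_target_base,ct_ref_base Same in the baseline condition.
#' @return List of class `relative_expression` with `delta_ct_condition`,
#'   `delta_ct_baseline`, `ddct`, `fold_change`. All arguments may be
#'   vectors of equal length.
#' @examples
#' fold_change_ddct(24, 20, 25, 20)$fold_change # 2
#' @export
fold_change_ddct <- function(ct_target_cond, ct_ref_cond,
                             ct_target_base, ct_ref_base) {
  vals <- c(ct_target_cond, ct_ref_cond, ct_target_base, ct_ref_base)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  if (any(vals < 5 | vals > 40))
    warning("Ct value(s) outside the typical 5-40 cycle range")
  d_cond <- ct_target_cond - ct_ref_cond
  d_base <- ct_target_base - ct_ref_base
  ddct <- d_cond - d_base
  structure(list(delta_ct_condition = d_cond, delta_ct_baseline = d_base,
                 ddct = ddct, fold_change = 2^(-ddct)),
            class = "relative_expression")
}

#' Average technical qPCR replicates
#'
#' Technical duplicates of the same (sample, condition, gene) are averaged
#' before any delta-Ct arithmetic.
#'
#' @param ct_table Data.frame with columns `sample`, `condition`, `gene`,
#'   `replicate`, `ct`.
#' @return Data.frame with one row per (sample, condition, gene,
#'   replicate) and the mean `ct`.
#' @export
average_technical_replicates <- function(ct_table) {
  required <- c("sample", "condition", "gene", "replicate", "ct")
  missing <- setdiff(required, names(ct_table))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  agg <- stats::aggregate(ct ~ sample + condition + gene + replicate,
                          data = ct_table, FUN = mean)
  agg[order(agg$gene, agg$condition, agg$replicate), , drop = FALSE]
}

#' Per-replicate relative expression from a long Ct table
#'
#' Builds the gene-by-condition-by-replicate fold-change table that
#' [induction_screen()] consumes: for each replicate and condition,
#' `dCt = Ct(target) - Ct(reference)`; the fold change is
#' `2^-(dCt - mean baseline dCt)`, so baseline replicates scatter around
#' 1. Technical replicates are averaged first.
#'
#' @param ct_table Data.frame with columns `sample`, `condition`, `gene`,
#'   `replicate`, `ct`.
#' @param target_gene,reference_gene Gene labels in `ct_table`.
#' @param baseline Baseline condition label.
#' @return Data.frame with columns `gene`, `condition`, `replicate`,
#'   `value`.
#' @export
relative_expression_table <- function(ct_table, target_gene,
                                      reference_gene, baseline) {
  ct <- average_technical_replicates(ct_table)
  if (!baseline %in% ct$condition)
    stop("baseline condition '", baseline, "' not present")
  tgt <- ct[ct$gene == target_gene, ]
  ref <- ct[ct$gene == reference_gene, ]
  if (nrow(tgt) == 0L) stop("target gene not found: ", target_gene)
  if (nrow(ref) == 0L) stop("reference gene not found: ", reference_gene)
  m <- merge(tgt, ref, by = c("sample", "condition", "replicate"),
             suffixes = c("_target", "_ref"))
  m$delta <- m$ct_target - m$ct_ref
  base_mean <- mean(m$delta[m$condition == baseline])
  data.frame(gene = target_gene, condition = m$condition,
             replicate = m$replicate,
             value = 2^(-(m$delta - base_mean)),
             stringsAsFactors = FALSE)
}

#' Normalize values by the maximum within each replicate group
#'
#' Divides every value by the largest value of its experimental replicate,
#' so each replicate's maximum becomes exactly 1. Invariant to rescaling a
#' whole replicate by any positive constant.
#'
#' @param values Numeric vector.
#' @param groups Replicate labels, same length as `values` (a single
#'   group when omitted).
#' @return Numeric vector of normalized values in (0, 1].
#' @examples
#' max_normalize(c(2, 4, 8)) # 0.25 0.50 1.00
#' @export
max_normalize <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  if (length(groups) != length(values))
    stop("groups must match values in length")
  if (length(values) == 0L) stop("values must be non-empty")
  out <- values
  for (g in unique(groups)) {
    idx <- which(groups == g)
    m <- max(values[idx])
    if (!is.finite(m) || m <= 0)
      stop("replicate group ", g, " has non-positive maximum")
    out[idx] <- values[idx] / m
  }
  out
}

#' Nuclear versus whole-cell log ratio
#'
#' Subcellular localization read-out: the logarithm of relative transcript
#' amount in the nuclear fraction over the whole-cell extract (each
#' already normalized to its fraction-specific control).
#'
#' @param nuclear_rel,whole_rel Strictly positive relative amounts.
#' @param base Logarithm base (default 10).
#' @return List of class `fractionation_result` with `log_ratio` and
#'   `base`.
#' @examples
#' fractionation_log_ratio(10, 1)$log_ratio # 1
#' @export
fractionation_log_ratio <- function(nuclear_rel, whole_rel, base = 10) {
  if (!all(is.finite(c(nuclear_rel, whole_rel))) ||
      any(nuclear_rel <= 0) || any(whole_rel <= 0))
    stop("nuclear and whole-cell amounts must be strictly positive")
  structure(list(log_ratio = log(nuclear_rel / whole_rel, base = base),
                 base = base),
            class = "fractionation_result")
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Classic equal-variance Student form by default; set `welch = TRUE` for
#' the unequal-variance variant.
#'
#' @param x,y Numeric vectors, each with at least two values.
#' @param welch Use the Welch correction instead of pooled variance.
#' @return A `test_result`: list with `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
student_t_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two observations")
  ht <- t.test(x, y, var.equal = !welch)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 method = if (welch) "welch_t" else "student_t"),
            class = "test_result")
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Omnibus F test across all groups, followed by pairwise t statistics on
#' the pooled within-group variance for the requested comparisons, each
#' raw p multiplied by the number of comparisons (capped at 1).
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param comparisons List of length-2 character vectors naming group
#'   pairs; defaults to all pairs.
#' @return List of class `anova_result` with `f_statistic`, `df`,
#'   `p_value` (omnibus) and a data.frame `comparisons` carrying
#'   `statistic`, `df`, `p_raw`, `p_adjusted` per pair.
#' @export
anova_bonferroni <- function(groups, comparisons = NULL) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  if (length(groups) < 3L)
    stop("omnibus ANOVA needs at least three groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least two observations")
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2, simplify = FALSE)
  }
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  fit <- aov(value ~ group, data = dat)
  tab <- anova(fit)
  f_stat <- tab[["F value"]][1]
  df1 <- tab[["Df"]][1]; df2 <- tab[["Df"]][2]
  mse <- tab[["Mean Sq"]][2]
  means <- vapply(groups, mean, numeric(1))

  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    if (!all(cmp %in% names(groups)))
      stop("comparison references unknown group(s): ",
           paste(cmp, collapse = " vs "))
    se <- sqrt(mse * (1 / sizes[[cmp[1]]] + 1 / sizes[[cmp[2]]]))
    tt <- (means[[cmp[1]]] - means[[cmp[2]]]) / se
    p <- 2 * pt(-abs(tt), df2)
    data.frame(group1 = cmp[1], group2 = cmp[2], statistic = tt, df = df2,
               p_raw = p, p_adjusted = min(1, m * p),
               stringsAsFactors = FALSE)
  })
  structure(list(f_statistic = f_stat, df = c(df1, df2),
                 p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 n_comparisons = m,
                 comparisons = do.call(rbind, rows)),
            class = "anova_result")
}

#' Screen genes for induction relative to a baseline condition
#'
#' A gene is flagged induced at a condition when its mean relative
#' expression exceeds the baseline mean (ratio > 1) and a two-tailed
#' Student's t-test of the replicate values against baseline replicates
#' is significant at `alpha`. Also returns the genes-by-conditions mean
#' fold table (the heatmap table).
#'
#' @param expr Long data.frame with columns `gene`, `condition`,
#'   `replicate`, `value` (per-replicate relative expression).
#' @param baseline Name of the baseline condition (must be present).
#' @param alpha Significance level.
#' @return List of class `induction_screen` with `flags` (data.frame
#'   `gene`, `condition`, `mean_fold`, `p_value`, `induced`) and
#'   `heatmap` (genes x conditions matrix of mean fold vs baseline).
#' @export
induction_screen <- function(expr, baseline, alpha = 0.05) {
  required <- c("gene", "condition", "replicate", "value")
  missing <- setdiff(required, names(expr))
  if (length(missing))
    stop("expression table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (!baseline %in% expr$condition)
    stop("baseline condition '", baseline, "' not present in the table")
  genes <- unique(expr$gene)
  conditions <- setdiff(unique(expr$condition), baseline)

  rows <- list()
  for (g in genes) {
    base_vals <- expr$value[expr$gene == g & expr$condition == baseline]
    if (length(base_vals) < 2L) {
      warning("gene ", g, " lacks baseline replicates; excluded")
      next
    }
    for (cond in conditions) {
      vals <- expr$value[expr$gene == g & expr$condition == cond]
      if (length(vals) < 2L) {
        warning("gene ", g, " has <2 replicates at ", cond, "; excluded")
        next
      }
      ratio <- mean(vals) / mean(base_vals)
      p <- student_t_test(vals, base_vals)$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, mean_fold = ratio, p_value = p,
        induced = ratio > 1 && p < alpha, stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), condition = character(),
               mean_fold = numeric(), p_value = numeric(),
               induced = logical(), stringsAsFactors = FALSE)
  heat <- matrix(NA_real_, length(genes), length(conditions),
                 dimnames = list(genes, conditions))
  if (nrow(flags)) heat[cbind(flags$gene, flags$condition)] <- flags$mean_fold
  structure(list(flags = flags, heatmap = heat, baseline = baseline,
                 alpha = alpha),
            class = "induction_screen")
}
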