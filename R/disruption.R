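# Scoring how much a single-nucleotide substitution perturbs the
# equilibrium pairing ensemble, riboSNitch-style: distance between the
# wild-type and mutant base-pair probability matrices, calibrated against
# an empirical null of random substitutions in the same window.

#' Distance between two base-pair probability matrices
#'
#' Three complementary measures of how far apart two pairing ensembles
#' are, all computed on the upper triangle:
#' * `d_global`: Euclidean distance `sqrt(sum (P1 - P2)^2)`.
#' * `d_local`: the maximum over contiguous intervals `[a, b]` of length
#'   at least `l_min` of `sqrt(sum_(a<=i<j<=b) dP^2 / (b - a + 1))` -- a
#'   length-normalized scan that rewards concentrated perturbations; ties
#'   broken toward the smallest `a`, then smallest `b`.
#' * `pearson_dissim`: `1 - r` between the two upper-triangle vectors
#'   (if either vector has zero variance, `r` is taken as 1 when the
#'   vectors are equal and 0 otherwise).
#'
#' @param p_wt,p_mut Square probability matrices of equal size, or
#'   `bp_matrix` objects.
#' @param l_min Minimum interval length for the local scan.
#' @return A `disruption_score`: list with `d_global`, `d_local`,
#'   `best_interval` (1-based `c(a, b)`), `pearson_dissim`, `n`.
#' @examples
#' f1 <- basepair_probabilities("GGGAAAACCC")
#' f2 <- basepair_probabilities("GGGAAAACCU")
#' disruption_score(f1, f2)$d_global
#' @export
disruption_score <- function(p_wt, p_mut, l_min = 10L) {
  if (inherits(p_wt, "bp_matrix")) p_wt <- p_wt$p
  if (inherits(p_mut, "bp_matrix")) p_mut <- p_mut$p
  stopifnot(is.matrix(p_wt), is.matrix(p_mut))
  n <- nrow(p_wt)
  if (ncol(p_wt) != n || !all(dim(p_mut) == c(n, n)))
    stop("matrices must be square and of identical size")
  l_min <- as.integer(l_min)
  if (l_min < 2L || l_min > n)
    stop("l_min must be in 2..n")

  d2 <- (p_wt - p_mut)^2
  d2[lower.tri(d2, diag = TRUE)] <- 0
  d_global <- sqrt(sum(d2))

  # upper-triangle vectors for the correlation measure
  v1 <- p_wt[upper.tri(p_wt)]
  v2 <- p_mut[upper.tri(p_mut)]
  if (length(v1) == 0L || sd(v1) == 0 || sd(v2) == 0) {
    r <- if (isTRUE(all.equal(v1, v2, tolerance = 0))) 1 else 0
  } else {
    r <- cor(v1, v2)
  }

  # interval scan with column-wise cumulative sums:
  # colcum[i, j] = sum_{i' <= i} d2[i', j]
  colcum <- apply(d2, 2, cumsum)
  best <- c(NA_integer_, NA_integer_)
  best_val <- -Inf
  for (a in seq_len(n - l_min + 1L)) {
    bs <- (a + 1L):n
    # column b contributes its entries with rows in [a, b-1]
    contrib <- colcum[cbind(bs - 1L, bs)] -
      (if (a > 1L) colcum[a - 1L, bs] else 0)
    s <- cumsum(contrib)
    len <- bs - a + 1L
    ok <- len >= l_min
    vals <- s[ok] / len[ok]
    i <- which.max(vals)                 # first max: smallest b wins ties
    if (vals[i] > best_val) {            # strict: smallest a wins ties
      best_val <- vals[i]
      best <- c(a, bs[ok][i])
    }
  }
  structure(list(d_global = d_global,
                 d_local = sqrt(max(best_val, 0)),
                 best_interval = best,
                 pearson_dissim = 1 - r,
                 n = n),
            class = "disruption_score")
}

#' @export
print.disruption_score <- function(x, ...) {
  cat(sprintf(
    "Structure disruption: d_global = %.4g, d_local = %.4g [%d, %d], 1 - r = %.4g\n",
    x$d_global, x$d_local, x$best_interval[1], x$best_interval[2],
    x$pearson_dissim))
  invisible(x)
}

score_metric <- function(score, metric) {
  switch(metric,
         d_global = score$d_global,
         d_local = score$d_local,
         pearson_dissim = score$pearson_dissim,
         stop("unknown metric: ", metric))
}

# all (position, alternative base) substitutions of a sequence, minus the
# observed one; returns a 2-column matrix of position and alt-base index
substitution_pool <- function(bases, exclude_pos, exclude_alt) {
  n <- length(bases)
  pos <- rep(seq_len(n), each = 3L)
  alt <- unlist(lapply(bases, function(bb) setdiff(RNA_BASES, bb)),
                use.names = FALSE)
  keep <- !(pos == exclude_pos & alt == exclude_alt)
  data.frame(pos = pos[keep], alt = alt[keep], stringsAsFactors = FALSE)
}

#' Empirical p-value for a variant's structure disruption
#'
#' Scores the observed substitution against a background of `b` random
#' single-base substitutions of the same sequence (position and
#' alternative base drawn uniformly, the observed substitution excluded),
#' each scored by exactly the same procedure. The add-one estimate
#' `p = (1 + #\{background >= observed\}) / (b + 1)` is never smaller than
#' `1 / (b + 1)` and is uniform under the null.
#'
#' @param seq RNA sequence (window already extracted by the caller; see
#'   [score_variant()] for windowing).
#' @param spliced_pos 1-based position of the variant in `seq`.
#' @param ref,alt Alleles in transcript orientation.
#' @param model A [pair_energy_model()].
#' @param metric Which [disruption_score()] component to compare.
#' @param b Number of background substitutions.
#' @param seed Integer seed; the call is fully reproducible from it.
#' @param alpha Significance level for the `disruptive` flag.
#' @param l_min Passed to [disruption_score()]; capped at the sequence
#'   length.
#' @return A `disruption_call`: list with the observed `score`
#'   (`disruption_score`), `metric`, `observed` (the scalar compared),
#'   `empirical_p`, `disruptive`, `b`, `alpha`, `seed`, and the background
#'   scores in `background`.
#' @export
empirical_pvalue <- function(seq, spliced_pos, ref, alt,
                             model = pair_energy_model(),
                             metric = c("d_local", "d_global",
                                        "pearson_dissim"),
                             b = 200L, seed = NULL, alpha = 0.1,
                             l_min = 10L) {
  metric <- match.arg(metric)
  b <- as.integer(b)
  if (is.na(b) || b < 1L) stop("b (background sample count) must be >= 1")
  bases <- check_bases(seq, RNA_BASES, "RNA sequence")
  n <- length(bases)
  l_min <- min(as.integer(l_min), n)

  wt_fold <- basepair_probabilities(seq, model)
  mut_seq <- apply_variant(seq, spliced_pos, ref, alt)
  obs_score <- disruption_score(wt_fold, basepair_probabilities(mut_seq, model),
                                l_min = l_min)
  observed <- score_metric(obs_score, metric)

  pool <- substitution_pool(bases, spliced_pos, toupper(alt))
  draw_and_score <- function() {
    idx <- sample.int(nrow(pool), b, replace = TRUE)
    vapply(idx, function(i) {
      ms <- apply_variant(seq, pool$pos[i], bases[pool$pos[i]], pool$alt[i])
      score_metric(
        disruption_score(wt_fold, basepair_probabilities(ms, model),
                         l_min = l_min),
        metric)
    }, numeric(1))
  }
  background <- if (is.null(seed)) draw_and_score() else
    withr::with_seed(seed, draw_and_score())

  p <- (1 + sum(background >= observed)) / (b + 1)
  structure(list(score = obs_score, metric = metric, observed = observed,
                 empirical_p = p, disruptive = p <= alpha,
                 b = b, alpha = alpha, seed = seed,
                 background = background),
            class = "disruption_call")
}

#' @export
print.disruption_call <- function(x, ...) {
  cat(sprintf(
    "Disruption call: %s = %.4g, empirical p = %.4g (B = %d)%s\n",
    x$metric, x$observed, x$empirical_p, x$b,
    if (x$disruptive) " -- disruptive" else ""))
  invisible(x)
}

#' Score a variant on a transcript with local windowing
#'
#' Extracts a window of at most `window` bases centered on the variant
#' (clipped at the sequence ends), folds both alleles over that identical
#' window, and delegates to [empirical_pvalue()]. Long transcripts are
#' thereby folded locally around the variant, which is where a single
#' substitution can act.
#'
#' @param transcript_seq Full mature transcript sequence (RNA alphabet;
#'   DNA is transcribed on the plus strand).
#' @param spliced_pos 1-based variant position on the mature transcript.
#' @param ref,alt Alleles in transcript orientation.
#' @param window Maximum window length (bases).
#' @inheritParams empirical_pvalue
#' @return A `disruption_call` (see [empirical_pvalue()]) with `window`
#'   (1-based start/end on the transcript) recorded.
#' @examples
#' hp <- make_hairpin_with_variant(site = "stem", seed = 1)
#' call <- score_variant(hp$sequence, hp$variant$pos, hp$variant$ref,
#'                       hp$variant$alt, b = 50, seed = 1)
#' call$empirical_p
#' @export
score_variant <- function(transcript_seq, spliced_pos, ref, alt,
                          window = 200L, model = pair_energy_model(),
                          metric = "d_local", b = 200L, alpha = 0.1,
                          seed = NULL, l_min = 10L) {
  seq <- toupper(chartr("T", "U", transcript_seq))
  bases <- check_bases(seq, RNA_BASES, "RNA sequence")
  n <- length(bases)
  spliced_pos <- as.integer(spliced_pos)
  if (is.na(spliced_pos) || spliced_pos < 1L || spliced_pos > n)
    stop("spliced_pos out of range 1..", n)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")

  len <- min(window, n)
  start <- spliced_pos - (len - 1L) %/% 2L
  start <- max(1L, min(start, n - len + 1L))
  end <- start + len - 1L
  sub <- substr(seq, start, end)

  call <- empirical_pvalue(sub, spliced_pos - start + 1L, ref, alt,
                           model = model, metric = metric, b = b,
                           seed = seed, alpha = alpha, l_min = l_min)
  call$window <- c(start = start, end = end)
  call
}
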