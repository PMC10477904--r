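# Independent oracles used to verify the implementation paths: each one
# deliberately recomputes the quantity by the most literal route
# available (all-pairs loops, explicit sequence construction, integer
# binomials) rather than reusing package internals.

# all-pairs variant x transcript overlap, literal span/exon checks
naive_intersect <- function(variants, transcripts) {
  rows <- list()
  for (vi in seq_len(nrow(variants))) {
    for (tx in transcripts) {
      if (variants$chrom[vi] != tx$chrom) next
      pos <- variants$pos[vi]
      s <- IRanges::start(tx$exons); e <- IRanges::end(tx$exons)
      if (pos < min(s) || pos > max(e)) next
      exonic <- FALSE
      for (k in seq_along(s)) if (pos >= s[k] && pos <= e[k]) exonic <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = variants$id[vi], transcript_id = tx$id,
        region = if (exonic) "exonic" else "intronic",
        spliced_pos = if (exonic) spliced_pos_oracle(tx, pos)
                      else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(variant_id = character(), transcript_id = character(),
                      region = character(), spliced_pos = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$variant_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# explicit construction of the genomic coordinate of every mature base,
# 5' to 3'; the spliced position of `pos` is its index in that vector
mature_coordinates <- function(tx) {
  coords <- unlist(lapply(seq_along(tx$exons), function(k)
    seq(IRanges::start(tx$exons)[k], IRanges::end(tx$exons)[k])))
  if (tx$strand == "-") rev(coords) else coords
}

spliced_pos_oracle <- function(tx, pos) {
  idx <- match(pos, mature_coordinates(tx))
  if (is.na(idx)) stop("position not exonic")
  idx
}

# upper-tail hypergeometric by direct integer-binomial summation
hyper_oracle <- function(N, K, n, k) {
  i <- seq(k, min(K, n))
  if (!length(i)) return(if (k == 0) 1 else 0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# pooled-variance two-sample t from the textbook formula
student_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tt, df = n1 + n2 - 2,
       p_value = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# BH step-up from its definition (sort, scale, enforce monotonicity)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# random small locus fixtures with varying shape for property tests
random_locus <- function(seed) {
  withr::with_seed(seed, {
    n_tx <- sample(2:12, 1)
    n_v <- sample(0:30, 1)
    frac <- runif(1)
    list(n_tx = n_tx, n_v = n_v, frac = frac)
  })
}
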