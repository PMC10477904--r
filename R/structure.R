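# Equilibrium RNA secondary-structure model: a Boltzmann ensemble over
# non-crossing sets of canonical pairs, with one energy per pair type.
# Deliberately simpler than nearest-neighbour thermodynamics: every number
# it produces can be verified against exhaustive enumeration.

RNA_BASES <- c("A", "C", "G", "U")

#' Per-pair energy model for RNA folding
#'
#' Defines the Boltzmann ensemble used by [basepair_probabilities()]. Each
#' canonical pair (Watson-Crick G-C and A-U, plus the G.U wobble)
#' contributes a single stabilizing energy; structures are non-crossing
#' sets of such pairs with at least `min_hairpin` unpaired bases enclosed
#' by every pair. There are no stacking or loop terms, which keeps the
#' ensemble exactly enumerable for short sequences.
#'
#' @param e_gc,e_au,e_gu Pair energies in kcal/mol (negative = stabilizing).
#' @param temperature Temperature in Kelvin; RT is derived with
#'   R = 0.0019872 kcal/(mol K).
#' @param min_hairpin Minimum number of unpaired bases a pair must enclose
#'   (the standard steric hairpin constraint).
#' @return An object of class `pair_energy_model`.
#' @examples
#' m <- pair_energy_model()
#' m$rt
#' @export
pair_energy_model <- function(e_gc = -3.0, e_au = -2.0, e_gu = -1.0,
                              temperature = 310.15, min_hairpin = 3L) {
  stopifnot(is.finite(e_gc), is.finite(e_au), is.finite(e_gu))
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive, finite Kelvin value")
  min_hairpin <- as.integer(min_hairpin)
  if (is.na(min_hairpin) || min_hairpin < 0)
    stop("min_hairpin must be a non-negative integer")
  structure(
    list(e_gc = e_gc, e_au = e_au, e_gu = e_gu,
         temperature = temperature,
         rt = 0.0019872 * temperature,
         min_hairpin = min_hairpin),
    class = "pair_energy_model")
}

#' @export
print.pair_energy_model <- function(x, ...) {
  cat("Pair-energy RNA folding model\n")
  cat(sprintf("  e(G-C) = %g, e(A-U) = %g, e(G.U) = %g kcal/mol\n",
              x$e_gc, x$e_au, x$e_gu))
  cat(sprintf("  T = %g K (RT = %.5f kcal/mol), min hairpin = %d\n",
              x$temperature, x$rt, x$min_hairpin))
  invisible(x)
}

# 4x4 Boltzmann weight matrix over (A, C, G, U); zero = not pairable
pair_weights <- function(model) {
  w <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  w["G", "C"] <- w["C", "G"] <- exp(-model$e_gc / model$rt)
  w["A", "U"] <- w["U", "A"] <- exp(-model$e_au / model$rt)
  w["G", "U"] <- w["U", "G"] <- exp(-model$e_gu / model$rt)
  w
}

# split into single characters, error on anything outside `alphabet`
check_bases <- function(seq, alphabet, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(b) < 1L) stop(what, " must have length >= 1")
  bad <- setdiff(unique(b), alphabet)
  if (length(bad))
    stop(what, " contains non-", paste(alphabet, collapse = ""),
         " characters: ", paste(bad, collapse = ", "))
  b
}

#' Convert a genomic DNA sequence to the mature-strand RNA sequence
#'
#' The input is given on the plus genomic strand; for a minus-strand
#' transcript it is reverse-complemented before the T to U substitution, so
#' the result always reads 5' to 3' along the mature transcript.
#'
#' @param dna_sequence Character scalar over A/C/G/T.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar over A/C/G/U.
#' @examples
#' transcribe_and_orient("ATGT", "+") # "AUGU"
#' transcribe_and_orient("ATGT", "-") # "ACAU"
#' @export
transcribe_and_orient <- function(dna_sequence, strand = c("+", "-")) {
  strand <- match.arg(strand)
  check_bases(dna_sequence, c("A", "C", "G", "T"), "DNA sequence")
  x <- Biostrings::DNAString(toupper(dna_sequence))
  if (strand == "-") x <- Biostrings::reverseComplement(x)
  as.character(Biostrings::RNAString(x))
}

#' Apply a single-nucleotide substitution to an RNA sequence
#'
#' Alleles are given in transcript orientation (callers working from
#' genomic plus-strand alleles on a minus-strand transcript must complement
#' first; see [orient_alleles()]).
#'
#' @param seq RNA sequence (character scalar over A/C/G/U).
#' @param spliced_pos 1-based position along `seq`.
#' @param ref Expected base at `spliced_pos`; a mismatch is an error.
#' @param alt Substituted base.
#' @return The mutated sequence.
#' @examples
#' apply_variant("GAAAC", 1, "G", "C") # "CAAAC"
#' @export
apply_variant <- function(seq, spliced_pos, ref, alt) {
  b <- check_bases(seq, RNA_BASES, "RNA sequence")
  spliced_pos <- as.integer(spliced_pos)
  if (is.na(spliced_pos) || spliced_pos < 1L || spliced_pos > length(b))
    stop("spliced_pos out of range 1..", length(b))
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% RNA_BASES || !alt %in% RNA_BASES)
    stop("ref and alt must be single RNA bases (A/C/G/U)")
  if (b[spliced_pos] != ref)
    stop(sprintf(
      "reference mismatch at position %d: sequence has %s, expected %s",
      spliced_pos, b[spliced_pos], ref))
  b[spliced_pos] <- alt
  paste(b, collapse = "")
}

#' Equilibrium base-pair probability matrix
#'
#' Computes, for every pair of positions, the probability that the two
#' bases are paired at equilibrium under the Boltzmann ensemble defined by
#' `model`, using inside and outside partition-function recursions. Agrees
#' with the exhaustive-enumeration oracle ([enumerate_oracle()]) to
#' within 1e-9 for every sequence short enough to enumerate.
#'
#' @param seq RNA sequence (A/C/G/U) or DNA (A/C/G/T; auto-transcribed on
#'   the plus strand).
#' @param model A [pair_energy_model()].
#' @return A `bp_matrix`: list with `p` (n x n symmetric probability
#'   matrix), `z` (total partition function), `n`, and `seq`.
#' @examples
#' fold <- basepair_probabilities("GAAAC")
#' fold$p[1, 5] # the single possible G-C pair
#' @export
basepair_probabilities <- function(seq, model = pair_energy_model()) {
  stopifnot(inherits(model, "pair_energy_model"))
  seq <- toupper(seq)
  if (grepl("T", seq, fixed = TRUE) && !grepl("U", seq, fixed = TRUE))
    seq <- chartr("T", "U", seq)
  b <- check_bases(seq, RNA_BASES, "RNA sequence")
  codes <- match(b, RNA_BASES) - 1L
  res <- .fold_bppm(codes, pair_weights(model), model$min_hairpin)
  structure(list(p = res$p, z = res$z, n = length(b), seq = seq),
            class = "bp_matrix")
}

#' @export
print.bp_matrix <- function(x, ...) {
  cat(sprintf("Base-pair probability matrix: %d nt, Z = %.6g\n", x$n, x$z))
  cat(sprintf("  max p(i,j) = %.4f, expected paired bases = %.2f\n",
              if (x$n > 1) max(x$p) else 0, sum(x$p) / 2))
  invisible(x)
}

#' Exhaustive-enumeration oracle for base-pair probabilities
#'
#' Enumerates every non-crossing canonical structure (respecting the
#' model's hairpin constraint) of a short sequence, accumulates Boltzmann
#' weights structure by structure, and derives pair probabilities directly
#' from the definition. Independent of the dynamic-programming route in
#' [basepair_probabilities()]; used to verify it.
#'
#' @inheritParams basepair_probabilities
#' @param max_n Refuse sequences longer than this (enumeration is
#'   exponential).
#' @return A `bp_matrix` (same contract as [basepair_probabilities()]),
#'   with `n_structures` added.
#' @export
enumerate_oracle <- function(seq, model = pair_energy_model(), max_n = 16L) {
  stopifnot(inherits(model, "pair_energy_model"))
  b <- check_bases(toupper(chartr("T", "U", seq)), RNA_BASES, "RNA sequence")
  n <- length(b)
  if (n > max_n)
    stop("enumerate_oracle refuses sequences longer than ", max_n, " nt")
  w <- pair_weights(model)
  mh <- model$min_hairpin

  # all structures on [i..j] as lists of pair index matrices
  enum <- function(i, j) {
    if (i >= j) return(list(NULL))
    out <- enum(i + 1L, j)               # i unpaired
    for (k in seq_len(j)) {
      if (k <= i + mh) next
      if (w[b[i], b[k]] <= 0) next
      inner <- enum(i + 1L, k - 1L)
      outer <- enum(k + 1L, j)
      for (s1 in inner) for (s2 in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
    }
    out
  }

  structures <- enum(1L, n)
  z <- 0
  num <- matrix(0, n, n)
  for (s in structures) {
    wt <- if (is.null(s)) 1 else
      prod(w[cbind(b[s[, 1]], b[s[, 2]])])
    z <- z + wt
    if (!is.null(s)) {
      num[s] <- num[s] + wt
      num[s[, c(2, 1), drop = FALSE]] <- num[s[, c(2, 1), drop = FALSE]] + wt
    }
  }
  structure(list(p = num / z, z = z, n = n,
                 seq = paste(b, collapse = ""),
                 n_structures = length(structures)),
            class = "bp_matrix")
}
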