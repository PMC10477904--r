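# RIP-qPCR quantification: immunoprecipitated signal expressed as percent
# of the input aliquot, and enrichment of the specific antibody over the
# IgG control.

#' Percent of input from RIP/RAP qPCR cycle thresholds
#'
#' Literal form: `100 * 2^(Ct_input - Ct_IP)`. The optional adjusted mode
#' additionally multiplies by the fraction of lysate saved as input
#' (equivalent to shifting `Ct_input` by `-log2(1/fraction)`), for
#' workflows that correct the input aliquot back to the full lysate.
#'
#' @param ct_input,ct_ip Finite Ct values of the input aliquot and the
#'   immunoprecipitate; vectors allowed.
#' @param adjust_for_fraction Apply the input-fraction dilution
#'   correction.
#' @param input_fraction Fraction of lysate saved as input, in (0, 1].
#' @return Percent-of-input value(s).
#' @examples
#' percent_of_input(25, 30)        # 3.125
#' percent_of_input(25, 25)        # 100
#' percent_of_input(25, 30, TRUE)  # 0.3125
#' @export
percent_of_input <- function(ct_input, ct_ip, adjust_for_fraction = FALSE,
                             input_fraction = 0.10) {
  if (!all(is.finite(c(ct_input, ct_ip))))
    stop("Ct values must be finite")
  if (!is.finite(input_fraction) || input_fraction <= 0 ||
      input_fraction > 1)
    stop("input_fraction must lie in (0, 1]")
  pct <- 100 * 2^(ct_input - ct_ip)
  if (adjust_for_fraction) pct <- pct * input_fraction
  pct
}

#' Enrichment of the specific antibody over the IgG control
#'
#' @param pct_specific,pct_igg Percent-of-input of the specific-antibody
#'   and IgG immunoprecipitates; `pct_igg` must be positive.
#' @return Ratio `pct_specific / pct_igg`.
#' @examples
#' specific_over_igg(3.125, 0.3125) # 10
#' @export
specific_over_igg <- function(pct_specific, pct_igg) {
  if (any(!is.finite(pct_igg)) || any(pct_igg <= 0))
    stop("IgG percent-of-input must be strictly positive")
  pct_specific / pct_igg
}

#' Summarize a RIP-qPCR table
#'
#' Adds percent-of-input per row and, per target, the ratio of the
#' specific antibody over IgG (averaging percent-of-input across rows of
#' the same target and antibody first).
#'
#' @param rip_table Data.frame with columns `target`, `antibody`
#'   (values `"specific"` or `"IgG"`), `ct_ip`, `ct_input`.
#' @inheritParams percent_of_input
#' @return List with `table` (input plus a `percent_of_input` column) and
#'   `enrichment` (data.frame `target`, `pct_specific`, `pct_igg`,
#'   `ratio`).
#' @export
summarize_rip <- function(rip_table, adjust_for_fraction = FALSE,
                          input_fraction = 0.10) {
  required <- c("target", "antibody", "ct_ip", "ct_input")
  missing <- setdiff(required, names(rip_table))
  if (length(missing))
    stop("RIP table lacks column(s): ", paste(missing, collapse = ", "))
  ab <- tolower(rip_table$antibody)
  if (!all(ab %in% c("specific", "igg")))
    stop("antibody must be 'specific' or 'IgG'")
  rip_table$percent_of_input <- percent_of_input(
    rip_table$ct_input, rip_table$ct_ip,
    adjust_for_fraction = adjust_for_fraction,
    input_fraction = input_fraction)

  targets <- unique(rip_table$target)
  rows <- lapply(targets, function(tg) {
    sel <- rip_table$target == tg
    ps <- mean(rip_table$percent_of_input[sel & ab == "specific"])
    pi_ <- mean(rip_table$percent_of_input[sel & ab == "igg"])
    data.frame(target = tg, pct_specific = ps, pct_igg = pi_,
               ratio = if (is.finite(pi_) && pi_ > 0)
                 specific_over_igg(ps, pi_) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(table = rip_table, enrichment = do.call(rbind, rows))
}
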