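#' Identification / quantitation filter settings
#'
#' Thresholds governing which MS events enter quantitation and how proteins
#' are called differential. Defaults follow common practice for
#' PeptideProphet/ProteinProphet-scored acrylamide-pair data: peptides are
#' *identified* at probability > 0.2 but only events with probability
#' >= 0.75 are *quantitation grade*; protein identifications carry at most
#' a 5% error rate (confidence >= 0.95); proteins are called differential
#' at a 1.25-fold or greater change with p < 0.05.
#'
#' @param min_peptide_prob_quant Minimum PeptideProphet probability for an
#'   event to be used in quantitation (default 0.75, inclusive).
#' @param min_peptide_prob_ident Minimum probability for an identification
#'   to count towards the "identified" protein tally (default 0.2). Does
#'   not gate quantitation.
#' @param max_protein_error_rate Maximum protein-level error rate; applied
#'   as `protein_confidence >= 1 - max_protein_error_rate` when that
#'   column is present (default 0.05).
#' @param min_fold Minimum linear fold change (either direction) for a
#'   differential call; ties count as changed (default 1.25).
#' @param alpha Significance level for both the t-test and the per-event
#'   empirical test (default 0.05).
#' @param rollup Either `"event"` (default): the protein ratio is the
#'   unweighted mean over all quantitation-grade event log2 ratios, and
#'   the t-test runs over events; or `"peptide"`: events are first
#'   averaged within each peptide sequence and the protein ratio / t-test
#'   use the per-peptide means.
#'
#' @return A list of class `filter_config`.
#' @examples
#' cfg <- filter_config()
#' cfg$min_fold
#' @export
filter_config <- function(min_peptide_prob_quant = 0.75,
                          min_peptide_prob_ident = 0.2,
                          max_protein_error_rate = 0.05,
                          min_fold = 1.25,
                          alpha = 0.05,
                          rollup = c("event", "peptide")) {
  rollup <- match.arg(rollup)
  stopifnot(
    is.numeric(min_peptide_prob_quant), length(min_peptide_prob_quant) == 1,
    min_peptide_prob_quant >= 0, min_peptide_prob_quant <= 1,
    is.numeric(min_peptide_prob_ident), length(min_peptide_prob_ident) == 1,
    min_peptide_prob_ident >= 0, min_peptide_prob_ident <= 1,
    is.numeric(max_protein_error_rate), length(max_protein_error_rate) == 1,
    max_protein_error_rate >= 0, max_protein_error_rate <= 1,
    is.numeric(min_fold), length(min_fold) == 1, min_fold > 1,
    is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1
  )
  structure(
    list(
      min_peptide_prob_quant = min_peptide_prob_quant,
      min_peptide_prob_ident = min_peptide_prob_ident,
      max_protein_error_rate = max_protein_error_rate,
      min_fold = min_fold,
      alpha = alpha,
      rollup = rollup
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  quantitation-grade peptide probability >= %.3g\n",
              x$min_peptide_prob_quant))
  cat(sprintf("  identification peptide probability     >  %.3g\n",
              x$min_peptide_prob_ident))
  cat(sprintf("  protein confidence                     >= %.3g\n",
              1 - x$max_protein_error_rate))
  cat(sprintf("  differential call: >= %.3g-fold, p < %.3g (rollup: %s)\n",
              x$min_fold, x$alpha, x$rollup))
  invisible(x)
}

log2_fold_threshold <- function(cfg) log2(cfg$min_fold)
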