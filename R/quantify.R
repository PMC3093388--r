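#' Event-level case/control log2 ratio
#'
#' The case (heavy, 13C) over control (light, 12C) intensity ratio on the
#' log2 scale. Antisymmetric under channel swap:
#' `event_log2_ratio(h, l) == -event_log2_ratio(l, h)`.
#'
#' @param heavy_intensity,light_intensity Positive intensities (vectorised).
#' @return `log2(heavy_intensity / light_intensity)`.
#' @examples
#' event_log2_ratio(200, 100)  # 1
#' @export
event_log2_ratio <- function(heavy_intensity, light_intensity) {
  if (any(!is.finite(heavy_intensity)) || any(!is.finite(light_intensity)) ||
      any(heavy_intensity <= 0) || any(light_intensity <= 0)) {
    stop("intensities must be finite and strictly positive", call. = FALSE)
  }
  log2(heavy_intensity / light_intensity)
}

#' Two-sided one-sample t-test p-value for a set of event log2 ratios
#'
#' Tests whether the mean log2 ratio differs from 0 across the protein's
#' paired MS events. Degenerate inputs: with zero variance and mean
#' exactly 0 the p-value is 1; with zero variance and a nonzero mean the
#' test statistic is unbounded and the smallest representable positive
#' p-value is returned with a warning.
#'
#' @param event_ratios Numeric vector of length >= 2.
#' @return p-value in (0, 1].
#' @export
ttest_pvalue <- function(event_ratios) {
  x <- event_ratios
  if (length(x) < 2) {
    stop("t-test requires at least 2 event ratios", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("event ratios must be finite", call. = FALSE)
  if (stats::var(x) == 0) {
    if (mean(x) == 0) return(1)
    warning("zero variance with nonzero mean; reporting smallest ",
            "representable p-value", call. = FALSE)
    return(.Machine$double.xmin)
  }
  p <- stats::t.test(x, mu = 0, alternative = "two.sided")$p.value
  max(p, .Machine$double.xmin)
}

#' Roll events up to a per-protein quantitation
#'
#' All events sharing one gene symbol are combined: the protein
#' case/control log2 ratio is the unweighted arithmetic mean over the
#' event log2 ratios, `n_peptides` counts distinct peptide sequences, and
#' a one-sample t-test p-value is attached when at least two ratios are
#' available (NA otherwise). With `cfg$rollup = "peptide"`, events are
#' first averaged within each peptide sequence and the protein mean and
#' t-test operate on the per-peptide means instead.
#'
#' @param events Event tibble (already quantitation-filtered) for exactly
#'   one gene symbol, with a finite `log2_ratio` column.
#' @param cfg A [filter_config()].
#' @return A list of class `protein_quant` with fields `gene_symbol`,
#'   `event_ratios` (the ratios entering the mean/test), `n_events`,
#'   `n_peptides`, `mean_log2_ratio`, `p_ttest`, and placeholders for the
#'   significance call (see [call_significance()]).
#' @export
rollup_protein <- function(events, cfg = filter_config()) {
  stopifnot(nrow(events) >= 1)
  genes <- unique(events$gene_symbol)
  if (length(genes) != 1) {
    stop("rollup_protein() expects events for a single gene symbol, got: ",
         paste(genes, collapse = ", "), call. = FALSE)
  }
  ratios <- events$log2_ratio
  if (any(!is.finite(ratios))) {
    stop("non-finite log2 ratios; run filter_for_quantitation() first",
         call. = FALSE)
  }
  test_ratios <- if (cfg$rollup == "peptide") {
    as.numeric(tapply(ratios, events$peptide_sequence, mean))
  } else {
    ratios
  }
  structure(
    list(
      gene_symbol = genes,
      event_ratios = test_ratios,
      n_events = nrow(events),
      n_peptides = length(unique(events$peptide_sequence)),
      mean_log2_ratio = mean(test_ratios),
      p_ttest = if (length(test_ratios) >= 2) ttest_pvalue(test_ratios)
                else NA_real_,
      all_events_significant = NA,
      significant = NA,
      criterion = NA_character_,
      direction = NA_character_
    ),
    class = "protein_quant"
  )
}

#' Empirical null distribution from a control-control experiment
#'
#' In a control-control experiment the same plasma pool is split, one half
#' labeled heavy and one light, and analysed together: every event's true
#' ratio is 1, so the observed spread of event log2 ratios is a direct
#' empirical null for ratio significance.
#'
#' @param x Either a quantitation-filtered event tibble (its finite
#'   `log2_ratio` values are used) or a numeric vector of log2 ratios.
#' @return A list of class `null_distribution` with sorted `ratios`, `n`,
#'   `mean` and `sd`.
#' @export
build_null <- function(x) {
  ratios <- if (is.data.frame(x)) x$log2_ratio else as.numeric(x)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0) {
    stop("cannot build an empirical null from zero finite ratios",
         call. = FALSE)
  }
  if (length(ratios) == 1) {
    warning("empirical null built from a single ratio; p-values will be ",
            "uninformative", call. = FALSE)
  }
  nd <- structure(
    list(ratios = sort(ratios), n = length(ratios),
         mean = mean(ratios), sd = if (length(ratios) > 1) stats::sd(ratios)
                                   else NA_real_),
    class = "null_distribution"
  )
  message(sprintf("empirical null: n = %d, mean = %.4f, sd = %.4f",
                  nd$n, nd$mean, if (is.na(nd$sd)) 0 else nd$sd))
  nd
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> n = %d, mean = %.4f, sd = %.4f\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Per-event empirical p-value against the control-control null
#'
#' Two-sided rank p-value with add-one smoothing:
#' `p = (1 + #{r in null : |r| >= |observed|}) / (n + 1)`,
#' so p is always positive, equals 1 for an observation no more extreme
#' than every null ratio, and is monotone nonincreasing in `|observed|`.
#'
#' @param observed Numeric vector of observed log2 ratios.
#' @param null A [build_null()] object.
#' @return p-values in (0, 1], same length as `observed`.
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  abs_null <- sort(abs(null$ratios))
  obs <- abs(observed)
  # count of null ratios with |r| >= |obs| = n - #{|r| < |obs|}
  n_less <- findInterval(obs, abs_null, left.open = TRUE)
  (1 + null$n - n_less) / (null$n + 1)
}

#' Apply the dual significance rule to a rolled-up protein
#'
#' A protein ratio is significant if either test fires:
#' \enumerate{
#'   \item the one-sample t-test over its event log2 ratios gives
#'     `p < alpha` (requires >= 2 events);
#'   \item *every* one of its events has empirical p-value `< alpha`
#'     against the control-control null — the only route for
#'     single-event proteins.
#' }
#' Which criterion fired is recorded (`"ttest"`, `"all-events"`, `"both"`,
#' `"none"`). With no null distribution and fewer than 2 events the
#' protein is unquantifiable for significance (`significant = NA`,
#' criterion `"unquantifiable"`).
#'
#' @param pq A `protein_quant` from [rollup_protein()].
#' @param null A [build_null()] object, or NULL if unavailable.
#' @param cfg A [filter_config()].
#' @return `pq` with `all_events_significant`, `significant`, `criterion`
#'   and `direction` filled in (direction via [classify_differential()]).
#' @export
call_significance <- function(pq, null, cfg = filter_config()) {
  stopifnot(inherits(pq, "protein_quant"))
  crit_t <- !is.na(pq$p_ttest) && pq$n_events >= 2 && pq$p_ttest < cfg$alpha
  if (is.null(null)) {
    pq$all_events_significant <- NA
    if (pq$n_events < 2) {
      pq$significant <- NA
      pq$criterion <- "unquantifiable"
      pq$direction <- "unchanged"
      return(pq)
    }
    crit_all <- FALSE
  } else {
    p_evt <- empirical_pvalue(pq$event_ratios, null)
    crit_all <- all(p_evt < cfg$alpha)
    pq$all_events_significant <- crit_all
  }
  pq$significant <- crit_t || crit_all
  pq$criterion <- if (crit_t && crit_all) "both"
                  else if (crit_t) "ttest"
                  else if (crit_all) "all-events"
                  else "none"
  classify_differential(pq, cfg)
}

#' Differential direction at the fold-change threshold
#'
#' A significant protein is called `increased` when its mean log2 ratio is
#' at least `log2(min_fold)` (1.25-fold by default, ties count as
#' changed), `decreased` when at most `-log2(min_fold)`, and `unchanged`
#' otherwise — including every non-significant protein regardless of its
#' fold change.
#'
#' @param pq A `protein_quant` with `significant` set.
#' @param cfg A [filter_config()].
#' @return `pq` with `direction` set.
#' @export
classify_differential <- function(pq, cfg = filter_config()) {
  thr <- log2_fold_threshold(cfg)
  pq$direction <- if (isTRUE(pq$significant) && pq$mean_log2_ratio >= thr) {
    "increased"
  } else if (isTRUE(pq$significant) && pq$mean_log2_ratio <= -thr) {
    "decreased"
  } else {
    "unchanged"
  }
  pq
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf(
    "<protein_quant> %s: mean log2 ratio %.3f over %d events (%d peptides)\n",
    x$gene_symbol, x$mean_log2_ratio, x$n_events, x$n_peptides))
  cat(sprintf("  t-test p = %s; significant = %s (%s); direction = %s\n",
              format(x$p_ttest, digits = 3), x$significant,
              x$criterion, x$direction))
  invisible(x)
}
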