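new_model_profile <- function(model_name, proteins, identified_genes = NULL) {
  stopifnot(is.data.frame(proteins))
  structure(
    list(
      model_name = model_name,
      proteins = tibble::as_tibble(proteins),
      identified_genes = identified_genes
    ),
    class = "model_profile"
  )
}

#' Quantify a full per-model plasma profile
#'
#' Runs the whole per-model computation: identification tally, the
#' quantitation filter, per-gene rollup ([rollup_protein()]) and the dual
#' significance call ([call_significance()]), producing one
#' `model_profile` — the model's plasma profile — with one row per
#' quantified gene. Protein groups are combined by common gene symbol. A
#' Benjamini-Hochberg adjusted t-test p-value column (`p_bh`) is included
#' for information; the differential call itself uses the raw p-values.
#'
#' @param events Raw event tibble for one model (not yet filtered).
#' @param null A [build_null()] object from the control-control
#'   experiment, or NULL (the all-events criterion is then unavailable and
#'   single-event proteins are unquantifiable for significance).
#' @param cfg A [filter_config()].
#' @param model_name Model name; defaults to the table's `model` column.
#' @return A `model_profile`: `model_name`, a `proteins` tibble (columns
#'   `gene_symbol`, `n_events`, `n_peptides`, `mean_log2_ratio`,
#'   `p_ttest`, `p_bh`, `all_events_significant`, `significant`,
#'   `criterion`, `direction`, plus a list-column `event_ratios`), and
#'   `identified_genes` (distinct symbols with any event above the
#'   identification probability threshold).
#' @export
quantify_profile <- function(events, null = NULL, cfg = filter_config(),
                             model_name = NULL) {
  if (is.null(model_name)) {
    model_name <- if ("model" %in% names(events) && nrow(events) > 0) {
      events$model[[1]]
    } else {
      "model"
    }
  }
  identified <- sort(unique(
    events$gene_symbol[!is.na(events$peptide_probability) &
                         events$peptide_probability >
                           cfg$min_peptide_prob_ident]
  ))
  quant <- filter_for_quantitation(events, cfg)
  if (nrow(quant) == 0) {
    empty <- tibble::tibble(
      gene_symbol = character(), n_events = integer(),
      n_peptides = integer(), mean_log2_ratio = numeric(),
      p_ttest = numeric(), p_bh = numeric(),
      all_events_significant = logical(), significant = logical(),
      criterion = character(), direction = character(),
      event_ratios = list()
    )
    return(new_model_profile(model_name, empty, identified))
  }
  quant <- quant[order(quant$gene_symbol), , drop = FALSE]
  pq_list <- lapply(split(quant, quant$gene_symbol), function(ev) {
    call_significance(rollup_protein(ev, cfg), null, cfg)
  })
  field <- function(name, proto) {
    unname(vapply(pq_list, function(x) {
      v <- x[[name]]
      if (is.logical(proto)) as.logical(v) else v
    }, proto))
  }
  pr <- tibble::tibble(
    gene_symbol = field("gene_symbol", character(1)),
    n_events = field("n_events", integer(1)),
    n_peptides = field("n_peptides", integer(1)),
    mean_log2_ratio = field("mean_log2_ratio", numeric(1)),
    p_ttest = field("p_ttest", numeric(1)),
    all_events_significant = field("all_events_significant", logical(1)),
    significant = field("significant", logical(1)),
    criterion = field("criterion", character(1)),
    direction = field("direction", character(1)),
    event_ratios = unname(lapply(pq_list, `[[`, "event_ratios"))
  )
  pr$p_bh <- stats::p.adjust(pr$p_ttest, method = "BH")
  pr <- pr[, c("gene_symbol", "n_events", "n_peptides", "mean_log2_ratio",
               "p_ttest", "p_bh", "all_events_significant", "significant",
               "criterion", "direction", "event_ratios")]
  new_model_profile(model_name, pr, identified)
}

#' Gene-symbol sets of a model profile
#'
#' Accessors for the derived sets of a `model_profile`: all quantified
#' genes, the increased / decreased calls, and their union (the altered
#' set). Increased and decreased are disjoint subsets of the quantified
#' set by construction.
#'
#' @param profile A `model_profile`.
#' @return Character vector of gene symbols.
#' @export
quantified_genes <- function(profile) {
  stopifnot(inherits(profile, "model_profile"))
  profile$proteins$gene_symbol
}

#' @rdname quantified_genes
#' @export
increased_genes <- function(profile) {
  pr <- profile$proteins
  pr$gene_symbol[pr$direction == "increased"]
}

#' @rdname quantified_genes
#' @export
decreased_genes <- function(profile) {
  pr <- profile$proteins
  pr$gene_symbol[pr$direction == "decreased"]
}

#' @rdname quantified_genes
#' @export
altered_genes <- function(profile) {
  c(increased_genes(profile), decreased_genes(profile))
}

#' Per-model summary counts
#'
#' One row per profile with the identified / quantified / increased /
#' decreased tallies. "Identified" is the number of distinct gene symbols
#' passing the identification probability filter (when the profile was
#' built from events; NA for profiles read from reduced tables);
#' "Quantified" counts genes with at least one quantitation-grade event.
#' `increased + decreased <= quantified <= identified` always holds when
#' all counts are available.
#'
#' @param profiles A `model_profile` or list of them.
#' @return A tibble with columns `model`, `identified`, `quantified`,
#'   `increased`, `decreased`.
#' @export
profile_summary <- function(profiles) {
  if (inherits(profiles, "model_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    tibble::tibble(
      model = p$model_name,
      identified = if (is.null(p$identified_genes)) NA_integer_
                   else length(p$identified_genes),
      quantified = nrow(p$proteins),
      increased = length(increased_genes(p)),
      decreased = length(decreased_genes(p))
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.model_profile <- function(x, ...) {
  s <- profile_summary(x)
  cat(sprintf("<model_profile> %s\n", x$model_name))
  cat(sprintf("  identified: %s  quantified: %d  increased: %d  decreased: %d\n",
              ifelse(is.na(s$identified), "?", s$identified),
              s$quantified, s$increased, s$decreased))
  invisible(x)
}
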