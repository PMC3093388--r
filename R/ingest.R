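#' Read a per-event heavy/light intensity table
#'
#' An event table holds one row per quantified heavy/light isotope pair
#' ("MS event"): a peptide observed in one chromatographic fraction at one
#' charge state, with the light (12C, control channel) and heavy (13C, case
#' channel) intensities and the PeptideProphet identification probability.
#' The file is tab-delimited UTF-8 with a mandatory header and `.` decimal
#' separator.
#'
#' Required columns: `gene_symbol`, `peptide_sequence`, `fraction_id`,
#' `charge`, `light_intensity`, `heavy_intensity`, `peptide_probability`.
#' Optional: `model`, `protein_confidence`. Gene symbols are whitespace-
#' trimmed and matched case-sensitively downstream. Rows whose numeric
#' fields do not parse to finite values in range (negative intensities,
#' probabilities outside \[0,1\], `NaN`, text) are rejected with a warning
#' citing the offending row numbers. `log2_ratio = log2(heavy/light)` is
#' added wherever both intensities are positive.
#'
#' @param path Path to a TSV file.
#' @param model Model name to attach when the file has no `model` column.
#' @return A tibble of events (class `tbl_df`), one row per MS event.
#' @seealso [filter_for_quantitation()], [quantify_profile()]
#' @export
read_event_table <- function(path, model = NULL) {
  if (!file.exists(path)) {
    stop("event table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  if (nrow(raw) == 0) {
    stop("empty event table (no data rows): ", path, call. = FALSE)
  }
  required <- c("gene_symbol", "peptide_sequence", "fraction_id", "charge",
                "light_intensity", "heavy_intensity", "peptide_probability")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("event table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ev <- tibble::as_tibble(raw)
  ev$gene_symbol <- trimws(ev$gene_symbol)
  ev$peptide_sequence <- trimws(ev$peptide_sequence)

  num_cols <- c("charge", "light_intensity", "heavy_intensity",
                "peptide_probability")
  if ("protein_confidence" %in% names(ev)) {
    num_cols <- c(num_cols, "protein_confidence")
  }
  bad <- rep(FALSE, nrow(ev))
  for (col in num_cols) {
    parsed <- suppressWarnings(as.numeric(ev[[col]]))
    # optional columns may be genuinely missing (NA in, NA out)
    bad_col <- (!is.na(ev[[col]]) & !is.finite(parsed)) |
      (is.na(ev[[col]]) & col != "protein_confidence")
    ev[[col]] <- parsed
    bad <- bad | bad_col
  }
  bad <- bad |
    ev$light_intensity < 0 | ev$heavy_intensity < 0 |
    ev$peptide_probability < 0 | ev$peptide_probability > 1
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with unparsable or out-of-range ",
            "numeric fields (data rows: ",
            paste(which(bad), collapse = ", "), ")", call. = FALSE)
    ev <- ev[!bad, , drop = FALSE]
  }
  if (!"model" %in% names(ev)) {
    ev$model <- if (is.null(model)) {
      sub("\\.[^.]*$", "", basename(path))
    } else {
      model
    }
  }
  ev$charge <- as.integer(ev$charge)
  ev$log2_ratio <- ifelse(ev$light_intensity > 0 & ev$heavy_intensity > 0,
                          log2(ev$heavy_intensity / ev$light_intensity),
                          NA_real_)
  ev
}

#' Keep only quantitation-grade events
#'
#' Retains the events usable for ratio quantitation: PeptideProphet
#' probability at or above `cfg$min_peptide_prob_quant` (the threshold is
#' inclusive), both channel intensities strictly positive (the log ratio
#' is otherwise undefined), and — when a `protein_confidence` column is
#' present — confidence at least `1 - cfg$max_protein_error_rate`. Events
#' with a missing `protein_confidence` are not penalised; if the column is
#' absent entirely the protein-level filter is skipped with a notice.
#'
#' Filtering is idempotent and monotone: raising any threshold can only
#' shrink the retained set.
#'
#' @param events Event tibble from [read_event_table()] or the synthetic
#'   generator.
#' @param cfg A [filter_config()].
#' @return The filtered event tibble (possibly zero rows, with a warning).
#' @export
filter_for_quantitation <- function(events, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n_in <- nrow(events)
  keep <- !is.na(events$peptide_probability) &
    events$peptide_probability >= cfg$min_peptide_prob_quant &
    events$light_intensity > 0 & events$heavy_intensity > 0
  if ("protein_confidence" %in% names(events)) {
    conf_ok <- is.na(events$protein_confidence) |
      events$protein_confidence >= 1 - cfg$max_protein_error_rate
    keep <- keep & conf_ok
  } else {
    message("no protein_confidence column; protein error-rate filter skipped")
  }
  out <- events[keep, , drop = FALSE]
  message(sprintf(
    "quantitation filter: %d -> %d events (prob >= %.3g, intensities > 0%s)",
    n_in, nrow(out), cfg$min_peptide_prob_quant,
    if ("protein_confidence" %in% names(events))
      sprintf(", confidence >= %.3g", 1 - cfg$max_protein_error_rate) else ""))
  if (nrow(out) == 0) {
    warning("no events remain after quantitation filtering", call. = FALSE)
  }
  out
}

profile_tsv_columns <- c(
  "model", "gene_symbol", "n_events", "n_peptides", "mean_log2_ratio",
  "p_ttest", "p_bh", "all_events_significant", "significant", "criterion",
  "direction"
)

#' Write / read a per-protein profile table
#'
#' `write_profile()` serialises a `model_profile` to a TSV with one row
#' per gene (symbol, event and peptide counts, mean log2 case/control
#' ratio, t-test p-value, the all-events empirical verdict, and the
#' differential call). Numerics are written with 17 significant digits so
#' that `read_profile(write_profile(p))` reproduces every value to 1e-12.
#' Event-level ratios are not part of this reduced representation.
#'
#' @param profile A `model_profile` from [quantify_profile()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "model_profile"))
  pr <- profile$proteins
  if (nrow(pr) == 0) {
    warning("writing empty profile (header only): ", path, call. = FALSE)
  }
  out <- data.frame(model = rep(profile$model_name, nrow(pr)),
                    stringsAsFactors = FALSE)
  for (col in setdiff(profile_tsv_columns, "model")) {
    v <- if (col %in% names(pr)) pr[[col]] else rep(NA, nrow(pr))
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    out[[col]] <- v
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_profile
#' @param identified_genes Optional character vector of gene symbols
#'   passing identification filters, to restore the "identified" tally
#'   (not stored in the TSV).
#' @export
read_profile <- function(path, identified_genes = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA", fileEncoding = "UTF-8")
  missing_cols <- setdiff(profile_tsv_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("profile table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pr <- tibble::as_tibble(raw)
  model_name <- if (nrow(pr) > 0) pr$model[[1]] else NA_character_
  pr$model <- NULL
  for (col in c("n_events", "n_peptides")) pr[[col]] <- as.integer(pr[[col]])
  for (col in c("mean_log2_ratio", "p_ttest", "p_bh")) {
    pr[[col]] <- as.numeric(pr[[col]])
  }
  for (col in c("all_events_significant", "significant")) {
    pr[[col]] <- as.logical(pr[[col]])
  }
  new_model_profile(model_name = model_name, proteins = pr,
                    identified_genes = identified_genes)
}

#' Read an already-called differential table
#'
#' Cancer-side profiles often arrive as reduced tables (the raw events
#' belong to earlier studies): one row per gene with its mean log2
#' case/control ratio and a differential direction. This reader maps that
#' schema onto a `model_profile` so the cross-model operations accept it.
#'
#' Required columns: `gene_symbol`, `mean_log2_ratio`, `direction`
#' (values `increased` / `decreased` / `unchanged`). Optional: `model`.
#'
#' @param path TSV path.
#' @param model Model name when no `model` column is present.
#' @return A `model_profile`; every listed gene counts as quantified.
#' @export
read_differential_table <- function(path, model = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  required <- c("gene_symbol", "mean_log2_ratio", "direction")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("differential table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pr <- tibble::tibble(
    gene_symbol = trimws(raw$gene_symbol),
    n_events = NA_integer_,
    n_peptides = NA_integer_,
    mean_log2_ratio = as.numeric(raw$mean_log2_ratio),
    p_ttest = NA_real_,
    p_bh = NA_real_,
    all_events_significant = NA,
    significant = raw$direction %in% c("increased", "decreased"),
    criterion = "external",
    direction = raw$direction
  )
  bad_dir <- !pr$direction %in% c("increased", "decreased", "unchanged")
  if (any(bad_dir)) {
    stop("unknown direction value(s): ",
         paste(unique(pr$direction[bad_dir]), collapse = ", "), call. = FALSE)
  }
  model_name <- if ("model" %in% names(raw) && nrow(raw) > 0) {
    raw$model[[1]]
  } else if (!is.null(model)) {
    model
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  new_model_profile(model_name = model_name, proteins = pr)
}

#' Read per-model ratio sheets from a supplementary workbook
#'
#' Maps the layout of a published supplementary workbook (one sheet per
#' model, per-protein case/control ratios with identification columns)
#' onto `model_profile` objects. Column names are matched loosely
#' (case-insensitive, punctuation ignored) against the gene symbol, mean
#' log2 ratio, p-value and peptide/event count fields; the differential
#' call is then recomputed at `cfg`'s fold and alpha thresholds rather
#' than trusted from the file.
#'
#' Requires the `readxl` package.
#'
#' @param path Path to an `.xlsx` workbook.
#' @param sheets Sheet names or indices to read (default: all).
#' @param cfg A [filter_config()] supplying the fold/p thresholds.
#' @return A named list of `model_profile` objects, one per sheet.
#' @export
read_supplementary_profiles <- function(path, sheets = NULL,
                                        cfg = filter_config()) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("read_supplementary_profiles() requires the 'readxl' package",
         call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("supplementary workbook not found: ", path, call. = FALSE)
  }
  if (is.null(sheets)) sheets <- readxl::excel_sheets(path)
  find_col <- function(nms, patterns) {
    key <- tolower(gsub("[^a-z0-9]", "", tolower(nms)))
    for (p in patterns) {
      hit <- grep(p, key)
      if (length(hit) > 0) return(hit[[1]])
    }
    NA_integer_
  }
  out <- list()
  for (sh in sheets) {
    tab <- readxl::read_excel(path, sheet = sh)
    nms <- names(tab)
    i_gene <- find_col(nms, c("^genesymbol", "^gene", "^symbol"))
    i_ratio <- find_col(nms, c("log2ratio", "meanlog2", "^ratio", "log2"))
    i_p <- find_col(nms, c("^pvalue", "ttestp", "^p$"))
    i_npep <- find_col(nms, c("peptide.*count", "npeptide", "numpeptide"))
    i_nevt <- find_col(nms, c("event.*count", "nevent", "numevent"))
    if (is.na(i_gene) || is.na(i_ratio)) {
      stop("sheet '", sh, "': could not locate gene-symbol and ratio columns",
           call. = FALSE)
    }
    mean_ratio <- as.numeric(tab[[i_ratio]])
    p <- if (!is.na(i_p)) as.numeric(tab[[i_p]]) else NA_real_
    sig <- !is.na(p) & p < cfg$alpha
    thr <- log2_fold_threshold(cfg)
    pr <- tibble::tibble(
      gene_symbol = trimws(as.character(tab[[i_gene]])),
      n_events = if (!is.na(i_nevt)) as.integer(tab[[i_nevt]]) else NA_integer_,
      n_peptides = if (!is.na(i_npep)) as.integer(tab[[i_npep]])
                   else NA_integer_,
      mean_log2_ratio = mean_ratio,
      p_ttest = p,
      p_bh = NA_real_,
      all_events_significant = NA,
      significant = sig,
      criterion = "external",
      direction = dplyr::case_when(
        sig & mean_ratio >= thr ~ "increased",
        sig & mean_ratio <= -thr ~ "decreased",
        TRUE ~ "unchanged"
      )
    )
    pr <- pr[!is.na(pr$mean_log2_ratio) & nzchar(pr$gene_symbol), ]
    out[[as.character(sh)]] <- new_model_profile(model_name = as.character(sh),
                                                 proteins = pr)
  }
  out
}
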