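#' Assemble a pipeline run configuration
#'
#' Collects everything [run_pipeline()] needs: per-model event-table
#' paths for the confounder models, the control-control table for the
#' empirical null, optional already-called cancer differential tables
#' (reduced schema, see [read_differential_table()]), filter thresholds,
#' the overlap universe mode, an output directory and a seed.
#'
#' `read_run_config()` loads the same structure from a YAML file with
#' keys `models` (name: path), `control_control`, `cancers` (name: path,
#' optional), `out_dir`, `seed`, `universe`, and an optional `filters`
#' block whose entries override [filter_config()] defaults.
#'
#' @param models Named character vector/list of event-table paths (the
#'   confounder models), >= 1 entry.
#' @param control_control Path to the control-control event table, or
#'   NULL (single-event proteins are then unquantifiable for
#'   significance).
#' @param cancers Optional named paths of reduced differential tables.
#' @param cfg A [filter_config()].
#' @param universe `"common"` (overlaps restricted to genes quantified in
#'   all compared models) or `"pairwise"` (each pair restricted to its
#'   own shared genes).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the run manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(models, control_control = NULL, cancers = NULL,
                       cfg = filter_config(),
                       universe = c("common", "pairwise"),
                       out_dir = tempfile("plasmaquant_run_"), seed = 1) {
  universe <- match.arg(universe)
  models <- as.list(models)
  if (length(models) < 1 || is.null(names(models)) ||
      any(!nzchar(names(models)))) {
    stop("at least one named model event table is required", call. = FALSE)
  }
  structure(
    list(models = models, control_control = control_control,
         cancers = if (is.null(cancers)) list() else as.list(cancers),
         cfg = cfg, universe = universe, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path Path to a YAML run-configuration file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$models)) stop("config must list at least one model",
                              call. = FALSE)
  fc <- do.call(filter_config, if (is.null(y$filters)) list() else y$filters)
  run_config(
    models = y$models,
    control_control = y$control_control,
    cancers = y$cancers,
    cfg = fc,
    universe = if (is.null(y$universe)) "common" else y$universe,
    out_dir = if (is.null(y$out_dir)) tempfile("plasmaquant_run_")
              else y$out_dir,
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- sprintf("%.17g", df[[col]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the whole differential pipeline and write its reports
#'
#' Orchestrates the full analysis: reads every model's event table,
#' builds the empirical null from the control-control table, quantifies
#' one profile per model, and writes into `cfg$out_dir`:
#' \itemize{
#'   \item `profile_<model>.tsv` — per-protein quantitation per model;
#'   \item `summary.tsv` — identified / quantified / increased /
#'     decreased per model;
#'   \item `venn_increased.tsv`, `venn_decreased.tsv` — the 7 region
#'     counts (when exactly 3 confounder models are supplied);
#'   \item `overlap_pearson.tsv` — per model pair, percent overlap
#'     (Jaccard and smaller-set denominators) and Pearson r;
#'   \item `patterns.tsv` — gene-by-model direction matrix with the
#'     confounder-vs-cancer pattern class (when cancer tables are given);
#'   \item `prioritized.tsv`, `confounded.tsv` — cancer-restricted
#'     candidates and confounded genes;
#'   \item `ratio_histogram_<model>.png` — event log2 ratio histograms
#'     (when `figures = TRUE`);
#'   \item `run_manifest.json` — configuration, a stable config hash,
#'     seed, filter log, and per-output row counts.
#' }
#' Two runs with the same configuration and seed produce identical
#' numeric outputs.
#'
#' @param config A [run_config()].
#' @param figures Render PNG histograms (default TRUE).
#' @return The output directory, invisibly; the computed objects are
#'   attached as attributes `profiles`, `cancer_profiles`, `null`.
#' @export
run_pipeline <- function(config, figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  fcfg <- config$cfg
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  null <- NULL
  if (!is.null(config$control_control)) {
    cc <- read_event_table(config$control_control, model = "control_control")
    null <- build_null(filter_for_quantitation(cc, fcfg))
  }

  profiles <- list()
  for (m in names(config$models)) {
    ev <- read_event_table(config$models[[m]], model = m)
    profiles[[m]] <- quantify_profile(ev, null, fcfg, model_name = m)
    write_profile(profiles[[m]],
                  file.path(config$out_dir, paste0("profile_", m, ".tsv")))
    if (figures) {
      h <- ratio_histogram(filter_for_quantitation(ev, fcfg))
      ggplot2::ggsave(
        file.path(config$out_dir, paste0("ratio_histogram_", m, ".png")),
        plot(h), width = 5, height = 3.5, dpi = 120)
    }
  }

  summary_tb <- profile_summary(profiles)
  write_tsv_plain(summary_tb, file.path(config$out_dir, "summary.tsv"))

  if (length(profiles) == 3) {
    for (dir in c("increased", "decreased")) {
      vr <- venn_regions(unname(profiles), dir)
      vt <- tibble::tibble(
        region = names(vr),
        n = vapply(vr, length, integer(1)),
        genes = vapply(vr, paste, character(1), collapse = ",")
      )
      write_tsv_plain(vt, file.path(config$out_dir,
                                    paste0("venn_", dir, ".tsv")))
    }
  }

  if (length(profiles) >= 2) {
    pairs <- utils::combn(names(profiles), 2, simplify = FALSE)
    uni_all <- if (config$universe == "common" && length(profiles) >= 2) {
      suppressWarnings(common_quantified(unname(profiles)))
    } else {
      NULL
    }
    op <- dplyr::bind_rows(lapply(pairs, function(pr) {
      a <- profiles[[pr[1]]]; b <- profiles[[pr[2]]]
      uni <- if (is.null(uni_all)) {
        suppressWarnings(common_quantified(list(a, b)))
      } else {
        uni_all
      }
      tibble::tibble(
        model_a = pr[1], model_b = pr[2], n_universe = length(uni),
        overlap_jaccard_pct = overlap_percent(a, b, uni, "jaccard"),
        overlap_smaller_pct = overlap_percent(a, b, uni, "smaller"),
        pearson_r = tryCatch(pearson_profiles(a, b), error = function(e)
          NA_real_)
      )
    }))
    write_tsv_plain(op, file.path(config$out_dir, "overlap_pearson.tsv"))
  }

  cancer_profiles <- list()
  if (length(config$cancers) > 0) {
    for (m in names(config$cancers)) {
      cancer_profiles[[m]] <- read_differential_table(config$cancers[[m]],
                                                      model = m)
    }
    pat <- pattern_classify(unname(profiles), unname(cancer_profiles))
    all_profiles <- c(profiles, cancer_profiles)
    mat <- pat[, c("gene_symbol", "pattern", "conflict")]
    for (m in names(all_profiles)) {
      p <- all_profiles[[m]]
      i <- match(mat$gene_symbol, p$proteins$gene_symbol)
      mat[[m]] <- ifelse(is.na(i), "not-quantified",
                         ifelse(p$proteins$direction[i] == "increased", "up",
                                ifelse(p$proteins$direction[i] == "decreased",
                                       "down", "unchanged")))
    }
    write_tsv_plain(mat, file.path(config$out_dir, "patterns.tsv"))
    pri <- prioritize_cancer_restricted(unname(cancer_profiles),
                                        unname(profiles))
    write_tsv_plain(pri$prioritized,
                    file.path(config$out_dir, "prioritized.tsv"))
    write_tsv_plain(pri$confounded,
                    file.path(config$out_dir, "confounded.tsv"))
  }

  manifest <- list(
    package = "plasmaquant",
    seed = config$seed,
    universe = config$universe,
    filters = unclass(fcfg),
    config_hash = rlang::hash(list(config$models, config$control_control,
                                   config$cancers, unclass(fcfg),
                                   config$universe, config$seed)),
    models = names(config$models),
    cancers = names(config$cancers),
    null_n = if (is.null(null)) 0L else null$n,
    outputs = stats::setNames(
      lapply(names(profiles), function(m) nrow(profiles[[m]]$proteins)),
      names(profiles))
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  out <- config$out_dir
  attr(out, "profiles") <- profiles
  attr(out, "cancer_profiles") <- cancer_profiles
  attr(out, "null") <- null
  invisible(out)
}

#' Histogram of event log2 ratios
#'
#' Bins the event case/control log2 ratios into an odd number of
#' equal-width bins placed symmetrically around 0 (so the central bin
#' straddles 0). Counts conserve the event total.
#'
#' @param events Event tibble with finite `log2_ratio` values (filter
#'   first).
#' @param bins Odd number of bins (default 41; an even request is
#'   incremented).
#' @return A list of class `ratio_histogram`: `counts`, `breaks`,
#'   `mids`, `n`. Has a `plot()` method returning a ggplot.
#' @export
ratio_histogram <- function(events, bins = 41) {
  r <- if (is.data.frame(events)) events$log2_ratio else as.numeric(events)
  r <- r[is.finite(r)]
  if (length(r) == 0) stop("no finite log2 ratios to bin", call. = FALSE)
  bins <- as.integer(bins)
  if (bins < 1) stop("bins must be >= 1", call. = FALSE)
  if (bins %% 2 == 0) bins <- bins + 1L
  lim <- max(abs(r), .Machine$double.eps)
  width <- 2 * lim / bins * (1 + 1e-9)  # widen a hair so ±lim falls inside
  breaks <- width * (seq(0, bins) - bins / 2)
  counts <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE),
                     nbins = bins)
  structure(
    list(counts = counts, breaks = breaks,
         mids = (breaks[-1] + breaks[-length(breaks)]) / 2, n = length(r)),
    class = "ratio_histogram"
  )
}

#' @export
print.ratio_histogram <- function(x, ...) {
  cat(sprintf("<ratio_histogram> %d events in %d bins over [%.3g, %.3g]\n",
              x$n, length(x$counts), min(x$breaks), max(x$breaks)))
  invisible(x)
}

#' @export
plot.ratio_histogram <- function(x, ...) {
  df <- data.frame(mid = x$mids, count = x$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(x$breaks)[1], fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "event log2 (case / control) ratio", y = "events") +
    ggplot2::theme_minimal()
}
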