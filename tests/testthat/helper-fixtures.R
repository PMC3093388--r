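# Shared fixtures: tiny hand-built event tables and profile constructors.

# an event tibble with the columns read_event_table() would produce
make_events <- function(gene, ratio,
                        peptide = paste0("PEP", seq_along(ratio), "K"),
                        prob = 0.95, light = 1e5, model = "test") {
  tibble::tibble(
    model = model,
    gene_symbol = gene,
    peptide_sequence = peptide,
    fraction_id = seq_along(ratio),
    charge = 2L,
    light_intensity = rep_len(light, length(ratio)),
    heavy_intensity = rep_len(light, length(ratio)) * 2^ratio,
    peptide_probability = rep_len(prob, length(ratio)),
    log2_ratio = ratio
  )
}

# a model_profile straight from gene sets + mean ratios (no events)
make_profile <- function(name, genes, ratios, direction) {
  stopifnot(length(genes) == length(ratios), length(genes) == length(direction))
  pr <- tibble::tibble(
    gene_symbol = genes,
    n_events = 3L, n_peptides = 2L,
    mean_log2_ratio = ratios,
    p_ttest = ifelse(direction == "unchanged", 0.5, 0.01),
    p_bh = NA_real_,
    all_events_significant = direction != "unchanged",
    significant = direction != "unchanged",
    criterion = ifelse(direction == "unchanged", "none", "ttest"),
    direction = direction
  )
  new_model_profile(name, pr)
}

# random profile for property tests: genes drawn from a shared pool
random_profile <- function(name, pool, n_quant, p_altered = 0.4) {
  genes <- sort(sample(pool, n_quant))
  u <- runif(length(genes))
  dir <- ifelse(u < p_altered / 2, "increased",
                ifelse(u < p_altered, "decreased", "unchanged"))
  ratios <- ifelse(dir == "increased", runif(length(genes), 0.4, 1.5),
                   ifelse(dir == "decreased", -runif(length(genes), 0.4, 1.5),
                          rnorm(length(genes), 0, 0.1)))
  make_profile(name, genes, ratios, dir)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

write_events_tsv <- function(events, path) {
  df <- as.data.frame(events[, c("model", "gene_symbol", "peptide_sequence",
                                 "fraction_id", "charge", "light_intensity",
                                 "heavy_intensity", "peptide_probability",
                                 "protein_confidence")[
    c("model", "gene_symbol", "peptide_sequence", "fraction_id", "charge",
      "light_intensity", "heavy_intensity", "peptide_probability",
      "protein_confidence") %in% names(events)]])
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- sprintf("%.17g", df[[col]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
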