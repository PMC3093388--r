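#' Configuration for the synthetic event-table generator
#'
#' Describes a simulated isotope-pair plasma experiment with known ground
#' truth. Each protein (gene symbol) is assigned a class — increased,
#' decreased, or null — and a true log2 shift delta (0 for null proteins,
#' `+|N(effect_log2_mean, effect_log2_sd)|` / `-|...|` otherwise). Each
#' protein carries a shifted-Poisson number of peptides (>= 1), each
#' peptide a shifted-Poisson number of MS events. Per event, the light
#' (control) intensity is lognormal, the event log2 ratio is
#' `N(delta, noise_sd)`, and the heavy intensity is constructed as
#' `light * 2^ratio`, so the drawn ratio is recovered exactly. Peptide
#' probabilities are Beta-distributed, so a realistic fraction of events
#' falls below the quantitation-grade threshold.
#'
#' Defaults emulate a plasma study in which roughly 450 proteins are
#' quantified per model, about a third change in abundance, and decreases
#' outnumber increases two-to-three-fold; see the methods vignette for
#' the reasoning behind each value.
#'
#' @param n_proteins Number of simulated proteins (default 450).
#' @param peptides_per_protein Mean peptides per protein, shifted-Poisson
#'   distributed with minimum 1 (default 3).
#' @param events_per_peptide Mean MS events per peptide, shifted-Poisson
#'   with minimum 1 (default 2).
#' @param min_events_per_protein Minimum total events per protein; extra
#'   events are added to randomly chosen peptides when a draw falls short
#'   (default 1, i.e. no floor).
#' @param prop_increased,prop_decreased Class probabilities (defaults
#'   0.12 and 0.30; the remainder is null). Must sum to at most 1.
#' @param effect_log2_mean,effect_log2_sd Mean and sd of the (absolute)
#'   true log2 shift for altered proteins (defaults 0.65 and 0.3).
#' @param noise_sd Standard deviation of the event log2 ratio around the
#'   protein's true shift (default 0.3).
#' @param base_intensity_log_mean,base_intensity_log_sd meanlog / sdlog
#'   of the lognormal light-channel intensity (defaults log(1e6) and 1).
#' @param prob_beta_params Shape parameters of the Beta distribution of
#'   peptide probabilities (default c(8, 1): most events above 0.75).
#' @param two_channel_noise If TRUE, additional independent lognormal
#'   measurement noise (sdlog `noise_sd/2` per channel) multiplies each
#'   channel, a robustness mode in which the drawn ratio is no longer
#'   recovered exactly (default FALSE).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 450,
                         peptides_per_protein = 3,
                         events_per_peptide = 2,
                         min_events_per_protein = 1,
                         prop_increased = 0.12,
                         prop_decreased = 0.30,
                         effect_log2_mean = 0.65,
                         effect_log2_sd = 0.3,
                         noise_sd = 0.3,
                         base_intensity_log_mean = log(1e6),
                         base_intensity_log_sd = 1,
                         prob_beta_params = c(8, 1),
                         two_channel_noise = FALSE) {
  cfg <- list(
    n_proteins = n_proteins,
    peptides_per_protein = peptides_per_protein,
    events_per_peptide = events_per_peptide,
    min_events_per_protein = min_events_per_protein,
    prop_increased = prop_increased,
    prop_decreased = prop_decreased,
    effect_log2_mean = effect_log2_mean,
    effect_log2_sd = effect_log2_sd,
    noise_sd = noise_sd,
    base_intensity_log_mean = base_intensity_log_mean,
    base_intensity_log_sd = base_intensity_log_sd,
    prob_beta_params = prob_beta_params,
    two_channel_noise = two_channel_noise
  )
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(n_proteins) && n_proteins >= 1, "n_proteins must be >= 1")
  chk(peptides_per_protein >= 1, "peptides_per_protein must be >= 1")
  chk(events_per_peptide >= 1, "events_per_peptide must be >= 1")
  chk(min_events_per_protein >= 1, "min_events_per_protein must be >= 1")
  chk(prop_increased >= 0 && prop_increased <= 1,
      "prop_increased must be in [0, 1]")
  chk(prop_decreased >= 0 && prop_decreased <= 1,
      "prop_decreased must be in [0, 1]")
  chk(prop_increased + prop_decreased <= 1,
      "prop_increased + prop_decreased must be <= 1")
  chk(noise_sd > 0, "noise_sd must be > 0")
  chk(effect_log2_sd >= 0, "effect_log2_sd must be >= 0")
  chk(length(prob_beta_params) == 2 && all(prob_beta_params > 0),
      "prob_beta_params must be two positive shapes")
  if (length(problems) > 0) {
    stop("invalid synth_config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# shifted Poisson: support {1, 2, ...} with the requested mean
rpois_shifted <- function(n, mean) 1L + stats::rpois(n, lambda = mean - 1)

# derive independent substream seeds from one global seed (stable across
# sessions; keeps values in 32-bit integer range)
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

random_peptide <- function(n_residues) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P", "Q",
          "S", "T", "V", "W", "Y")
  paste0(paste(sample(aa, n_residues - 1, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1))
}

draw_events_for_protein <- function(gene, delta, cfg, model_name) {
  n_pep <- rpois_shifted(1, cfg$peptides_per_protein)
  n_evt <- rpois_shifted(n_pep, cfg$events_per_peptide)
  deficit <- cfg$min_events_per_protein - sum(n_evt)
  if (deficit > 0) {
    extra <- tabulate(sample.int(n_pep, deficit, replace = TRUE), n_pep)
    n_evt <- n_evt + extra
  }
  peptides <- vapply(seq_len(n_pep), function(i)
    random_peptide(sample(7:15, 1)), character(1))
  n_total <- sum(n_evt)
  ratio <- stats::rnorm(n_total, mean = delta, sd = cfg$noise_sd)
  light <- stats::rlnorm(n_total, meanlog = cfg$base_intensity_log_mean,
                         sdlog = cfg$base_intensity_log_sd)
  heavy <- light * 2^ratio
  if (cfg$two_channel_noise) {
    light <- light * stats::rlnorm(n_total, 0, cfg$noise_sd / 2)
    heavy <- heavy * stats::rlnorm(n_total, 0, cfg$noise_sd / 2)
  }
  tibble::tibble(
    model = model_name,
    gene_symbol = gene,
    peptide_sequence = rep(peptides, times = n_evt),
    fraction_id = sample(1:96, n_total, replace = TRUE),
    charge = sample(2:3, n_total, replace = TRUE),
    light_intensity = light,
    heavy_intensity = heavy,
    peptide_probability = stats::rbeta(n_total, cfg$prob_beta_params[[1]],
                                       cfg$prob_beta_params[[2]]),
    protein_confidence = 1 - stats::rbeta(n_total, 1, 60),
    log2_ratio = log2(heavy / light)
  )
}

generate_events <- function(genes, deltas, cfg, model_name) {
  dplyr::bind_rows(Map(function(g, d) {
    draw_events_for_protein(g, d, cfg, model_name)
  }, genes, deltas))
}

draw_truth <- function(genes, cfg) {
  n <- length(genes)
  cls <- sample(c("increased", "decreased", "null"), n, replace = TRUE,
                prob = c(cfg$prop_increased, cfg$prop_decreased,
                         1 - cfg$prop_increased - cfg$prop_decreased))
  mag <- abs(stats::rnorm(n, cfg$effect_log2_mean, cfg$effect_log2_sd))
  delta <- ifelse(cls == "increased", mag,
                  ifelse(cls == "decreased", -mag, 0))
  tibble::tibble(gene_symbol = genes, delta = delta, class = cls)
}

#' Simulate one case/control experiment with known truth
#'
#' Draws a full event table for one model plus the truth table recording
#' each protein's true log2 shift and class. Fully reproducible: the same
#' `cfg` and `seed` give identical tables.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @param model_name Name placed in the `model` column.
#' @return List with `events` (tibble, the same columns
#'   [read_event_table()] produces) and `truth` (tibble `gene_symbol`,
#'   `delta`, `class`).
#' @export
generate_experiment <- function(cfg = synth_config(), seed = 1,
                                model_name = "synthetic") {
  stopifnot(inherits(cfg, "synth_config"))
  seeds <- derive_seeds(seed, 2)
  genes <- sprintf("G%04d", seq_len(cfg$n_proteins))
  set.seed(seeds[[1]])
  truth <- draw_truth(genes, cfg)
  set.seed(seeds[[2]])
  events <- generate_events(truth$gene_symbol, truth$delta, cfg, model_name)
  list(events = events, truth = truth)
}

#' Simulate a split-sample control-control experiment
#'
#' The same pool labeled heavy and light: every protein's true shift is
#' 0, events are drawn with the same noise model, and the output is the
#' intended input of [build_null()].
#'
#' @inheritParams generate_experiment
#' @return Event tibble.
#' @export
generate_control_control <- function(cfg = synth_config(), seed = 1,
                                     model_name = "control_control") {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seeds(seed, 1)[[1]])
  genes <- sprintf("G%04d", seq_len(cfg$n_proteins))
  generate_events(genes, rep(0, cfg$n_proteins), cfg, model_name)
}

#' Design the sharing structure of a multi-model simulation
#'
#' Helper constructing the `design` argument of [generate_multi_model()]:
#' a data frame in which each row allocates `n` proteins to one Venn
#' region (`models` = model names joined by `&`) with one direction.
#'
#' @param ... Named counts; names are of the form
#'   `"modelA&modelB:increased"`.
#' @return A data frame with columns `models`, `direction`, `n`.
#' @examples
#' sharing_design("m1:increased" = 5, "m1&m2&m3:decreased" = 3)
#' @export
sharing_design <- function(...) {
  args <- c(...)
  stopifnot(length(args) > 0, !is.null(names(args)))
  parts <- strsplit(names(args), ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) {
    stop("design names must look like 'model1&model2:direction'",
         call. = FALSE)
  }
  data.frame(
    models = vapply(parts, `[[`, character(1), 1),
    direction = vapply(parts, `[[`, character(1), 2),
    n = as.integer(args),
    stringsAsFactors = FALSE
  )
}

#' Simulate a family of models with designed sharing
#'
#' Generates one event table per model such that each altered protein
#' belongs to a chosen Venn region: the design says which models alter it
#' and in which direction. A protein altered in several models shares one
#' true log2 shift magnitude across them; magnitudes are floored at 0.4
#' so every designed alteration sits above the default 1.25-fold call
#' threshold and the design is recoverable at low noise. All proteins are
#' present (and hence quantifiable) in every model; the remaining
#' proteins are null everywhere.
#'
#' @param cfg A [synth_config()] (its `prop_*` fields are ignored; the
#'   design determines who is altered).
#' @param model_names Character vector of model names.
#' @param design Data frame from [sharing_design()] (columns `models`,
#'   `direction`, `n`); region counts must sum to at most
#'   `cfg$n_proteins`, and every referenced model must be in
#'   `model_names`.
#' @param seed Integer seed.
#' @return List with `events` (named list of event tibbles, one per
#'   model) and `truth` (tibble `gene_symbol`, `model`, `delta`, `class`,
#'   `region`).
#' @export
generate_multi_model <- function(cfg = synth_config(),
                                 model_names = c("m1", "m2", "m3"),
                                 design, seed = 1) {
  stopifnot(inherits(cfg, "synth_config"), is.data.frame(design),
            all(c("models", "direction", "n") %in% names(design)))
  ref_models <- unique(unlist(strsplit(design$models, "&", fixed = TRUE)))
  unknown <- setdiff(ref_models, model_names)
  if (length(unknown) > 0) {
    stop("design references unknown model(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(design$direction %in% c("increased", "decreased"))) {
    stop("design directions must be 'increased' or 'decreased'",
         call. = FALSE)
  }
  if (sum(design$n) > cfg$n_proteins) {
    stop("design allocates ", sum(design$n), " altered proteins but only ",
         cfg$n_proteins, " proteins are configured", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 1 + length(model_names))
  genes <- sprintf("G%04d", seq_len(cfg$n_proteins))

  set.seed(seeds[[1]])
  assign_order <- sample(genes)  # which genes receive designed regions
  # designed alterations must be callable: floor the magnitude safely
  # above the default 1.25-fold threshold (log2(1.25) ~ 0.322)
  mag <- pmax(abs(stats::rnorm(cfg$n_proteins, cfg$effect_log2_mean,
                               cfg$effect_log2_sd)), 0.4)
  names(mag) <- assign_order
  region_of <- stats::setNames(rep("null", cfg$n_proteins), genes)
  dir_of <- stats::setNames(rep(NA_character_, cfg$n_proteins), genes)
  k <- 1
  for (i in seq_len(nrow(design))) {
    if (design$n[[i]] == 0) next
    gset <- assign_order[k:(k + design$n[[i]] - 1)]
    k <- k + design$n[[i]]
    region_of[gset] <- paste0(design$models[[i]], ":", design$direction[[i]])
    dir_of[gset] <- design$direction[[i]]
  }

  truth_rows <- list()
  events <- list()
  for (j in seq_along(model_names)) {
    m <- model_names[[j]]
    in_region <- vapply(genes, function(g) {
      r <- region_of[[g]]
      if (r == "null") return(FALSE)
      m %in% strsplit(sub(":.*$", "", r), "&", fixed = TRUE)[[1]]
    }, logical(1))
    delta <- ifelse(in_region,
                    ifelse(dir_of[genes] == "increased", 1, -1) * mag[genes],
                    0)
    truth_rows[[m]] <- tibble::tibble(
      gene_symbol = genes, model = m, delta = unname(delta),
      class = ifelse(delta > 0, "increased",
                     ifelse(delta < 0, "decreased", "null")),
      region = unname(region_of[genes])
    )
    set.seed(seeds[[1 + j]])
    events[[m]] <- generate_events(genes, delta, cfg, m)
  }
  list(events = events, truth = dplyr::bind_rows(truth_rows))
}
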