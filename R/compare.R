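#' Genes quantified in every profile
#'
#' The commonly-quantified universe: intersection of the quantified gene
#' sets of two or more model profiles. Mass-spectrometer sampling is
#' stochastic, so restricting to this set puts overlap statistics on a
#' shared footing.
#'
#' @param profiles List of >= 2 `model_profile` objects.
#' @return Character vector of gene symbols (sorted).
#' @export
common_quantified <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  sets <- lapply(profiles, quantified_genes)
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0) {
    warning("no genes are quantified in all profiles", call. = FALSE)
  }
  out
}

#' Three-way Venn regions of increased or decreased proteins
#'
#' Partitions the union of one direction's differential calls across
#' exactly three model profiles into the 7 disjoint Venn regions: three
#' model-unique regions, three pairwise-only regions, and the triple
#' intersection. No common-quantification restriction is applied — a gene
#' simply contributes no membership in a model where it was not called.
#'
#' @param profiles List of exactly 3 `model_profile` objects.
#' @param direction `"increased"` or `"decreased"`.
#' @return Named list of 7 character vectors; names use the model names,
#'   e.g. `"m1"`, `"m1&m2"`, `"m1&m2&m3"`. Region sizes sum to the size
#'   of the union of the three per-model sets.
#' @export
venn_regions <- function(profiles, direction = c("increased", "decreased")) {
  direction <- match.arg(direction)
  if (length(profiles) != 3) {
    stop("venn_regions() requires exactly 3 profiles", call. = FALSE)
  }
  nm <- vapply(profiles, `[[`, character(1), "model_name")
  if (anyDuplicated(nm)) {
    stop("profiles must have distinct model names", call. = FALSE)
  }
  getter <- if (direction == "increased") increased_genes else decreased_genes
  sets <- lapply(profiles, getter)
  names(sets) <- nm
  u <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nm))
  labels <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  region_names <- c(nm,
                    paste(nm[1], nm[2], sep = "&"),
                    paste(nm[1], nm[3], sep = "&"),
                    paste(nm[2], nm[3], sep = "&"),
                    paste(nm, collapse = "&"))
  out <- stats::setNames(
    lapply(region_names, function(r) u[labels == r]),
    region_names
  )
  out
}

#' Percent overlap of altered proteins between two profiles
#'
#' Both profiles' altered sets (increased plus decreased) are restricted
#' to a shared universe — by default the genes quantified in both
#' profiles — and their overlap is reported as a percentage. The default
#' measure is the Jaccard index `100 * |A ∩ B| / |A ∪ B|`;
#' `method = "smaller"` reports `100 * |A ∩ B| / min(|A|, |B|)` instead.
#' The result is 0 when the restricted union (or smaller set) is empty.
#'
#' @param a,b `model_profile` objects.
#' @param universe Character vector of gene symbols to restrict to;
#'   default `common_quantified(list(a, b))`. Pass the three-model common
#'   set to reproduce whole-study overlap tables.
#' @param method `"jaccard"` (default) or `"smaller"`.
#' @return A percentage in \[0, 100\].
#' @export
overlap_percent <- function(a, b, universe = NULL,
                            method = c("jaccard", "smaller")) {
  method <- match.arg(method)
  if (is.null(universe)) {
    universe <- suppressWarnings(common_quantified(list(a, b)))
  }
  A <- intersect(altered_genes(a), universe)
  B <- intersect(altered_genes(b), universe)
  denom <- switch(method,
                  jaccard = length(union(A, B)),
                  smaller = min(length(A), length(B)))
  if (denom == 0) return(0)
  100 * length(intersect(A, B)) / denom
}

#' Pearson correlation of two plasma profiles
#'
#' Correlates the mean log2 case/control ratios over the genes quantified
#' in both profiles. Genes quantified in only one profile are ignored, so
#' the statistic is invariant to them.
#'
#' @param a,b `model_profile` objects sharing at least 3 quantified genes.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_profiles <- function(a, b) {
  shared <- suppressWarnings(common_quantified(list(a, b)))
  if (length(shared) < 3) {
    stop("pearson_profiles() needs >= 3 genes quantified in both profiles",
         call. = FALSE)
  }
  ra <- a$proteins$mean_log2_ratio[match(shared, a$proteins$gene_symbol)]
  rb <- b$proteins$mean_log2_ratio[match(shared, b$proteins$gene_symbol)]
  stats::cor(ra, rb, method = "pearson")
}

#' Classify abundance patterns against cancer profiles
#'
#' Assigns each gene one of the confounder-versus-cancer abundance
#' patterns:
#' \describe{
#'   \item{A}{increased in >= 1 confounder and increased in >= 1 cancer
#'     model;}
#'   \item{B}{increased in >= 1 confounder and decreased in >= 1 cancer
#'     model;}
#'   \item{C}{decreased in >= 1 confounder and increased in >= 1 cancer
#'     model;}
#'   \item{other}{everything else.}
#' }
#' A gene unquantified in a profile contributes no evidence there. When
#' opposite calls across models make more than one label apply, the gene
#' is flagged as a conflict (pattern `"conflict"`, all applicable labels
#' listed) rather than silently resolved.
#'
#' @param confounders,cancers Lists of `model_profile` objects (>= 1
#'   each).
#' @param genes Genes to classify; default: union of all altered sets.
#' @return Tibble with columns `gene_symbol`, `pattern`, `labels`,
#'   `conflict`, and the four evidence flags
#'   `up_confounder` / `down_confounder` / `up_cancer` / `down_cancer`.
#' @export
pattern_classify <- function(confounders, cancers, genes = NULL) {
  stopifnot(length(confounders) >= 1, length(cancers) >= 1)
  if (is.null(genes)) {
    genes <- sort(unique(unlist(c(lapply(confounders, altered_genes),
                                  lapply(cancers, altered_genes)))))
  }
  in_any <- function(profiles, getter) {
    sets <- lapply(profiles, getter)
    genes %in% unique(unlist(sets))
  }
  up_conf <- in_any(confounders, increased_genes)
  dn_conf <- in_any(confounders, decreased_genes)
  up_can <- in_any(cancers, increased_genes)
  dn_can <- in_any(cancers, decreased_genes)
  is_a <- up_conf & up_can
  is_b <- up_conf & dn_can
  is_c <- dn_conf & up_can
  labels <- mapply(function(a, b, c) {
    paste(c("A", "B", "C")[c(a, b, c)], collapse = "/")
  }, is_a, is_b, is_c)
  n_lab <- is_a + is_b + is_c
  pattern <- ifelse(n_lab > 1, "conflict",
                    ifelse(n_lab == 1, labels, "other"))
  tibble::tibble(
    gene_symbol = genes,
    pattern = pattern,
    labels = ifelse(nzchar(labels), labels, "other"),
    conflict = n_lab > 1,
    up_confounder = up_conf, down_confounder = dn_conf,
    up_cancer = up_can, down_cancer = dn_can
  )
}

#' Prioritize cancer-restricted plasma proteins
#'
#' Splits the genes altered in at least one cancer profile into a
#' prioritized list — altered in no confounder profile, hence candidates
#' for cancer-associated changes — and a "confounded" list of genes also
#' altered in >= 1 confounder (less likely to be cancer-specific). Both
#' lists are ordered by the maximum absolute mean log2 ratio across the
#' cancer profiles, descending, with ties broken alphabetically by gene
#' symbol.
#'
#' @param cancers,confounders Lists of `model_profile` objects.
#' @return List with tibbles `prioritized` and `confounded`, columns
#'   `gene_symbol`, `max_abs_log2_ratio`, `n_cancer_models_altered`,
#'   `n_confounder_models_altered`.
#' @export
prioritize_cancer_restricted <- function(cancers, confounders) {
  stopifnot(length(cancers) >= 1)
  cancer_altered <- sort(unique(unlist(lapply(cancers, altered_genes))))
  conf_altered <- unique(unlist(lapply(confounders, altered_genes)))
  score <- function(g) {
    vals <- vapply(cancers, function(p) {
      i <- match(g, p$proteins$gene_symbol)
      if (is.na(i)) NA_real_ else abs(p$proteins$mean_log2_ratio[[i]])
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
  build <- function(genes) {
    tb <- tibble::tibble(
      gene_symbol = genes,
      max_abs_log2_ratio = unname(vapply(genes, score, numeric(1))),
      n_cancer_models_altered = unname(vapply(genes, function(g) {
        sum(vapply(cancers, function(p) g %in% altered_genes(p), logical(1)))
      }, integer(1))),
      n_confounder_models_altered = unname(vapply(genes, function(g) {
        sum(vapply(confounders, function(p) g %in% altered_genes(p),
                   logical(1)))
      }, integer(1)))
    )
    tb[order(-tb$max_abs_log2_ratio, tb$gene_symbol), , drop = FALSE]
  }
  list(
    prioritized = build(setdiff(cancer_altered, conf_altered)),
    confounded = build(intersect(cancer_altered, conf_altered))
  )
}
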