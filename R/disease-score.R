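# Composite disease-gene evidence scoring over four evidence sources, plus
# the literature-based-discovery prediction score from abstract
# co-occurrence counts.

#' Weights for composite evidence scoring
#'
#' Curated gene-disease databases carry the strongest weight (3), direct
#' text mining and GWAS catalogs an intermediate weight (2), and indirect
#' literature-based discovery the weakest (1), so a gene supported by all
#' four sources scores 8.
#'
#' @param disease_db,kinderminer,gwas,skim Per-source weights.
#' @param skim_log_base Logarithm base of the prediction score (default 10).
#' @return A list of class `score_config`.
#' @export
score_config <- function(disease_db = 3, kinderminer = 2, gwas = 2, skim = 1,
                         skim_log_base = 10) {
  w <- c(disease_db = disease_db, kinderminer = kinderminer, gwas = gwas,
         skim = skim)
  if (any(w <= 0)) rlang::abort("weights must be positive.")
  structure(list(weights = w, skim_log_base = skim_log_base),
            class = "score_config")
}

#' Composite evidence score per gene
#'
#' Sums the configured weights over each gene's evidence sources; a gene
#' reported by several sources adds them up (range 1-8 under default
#' weights).
#'
#' @param evidence Tibble `gene`, `source` with source in `disease_db`,
#'   `kinderminer`, `gwas`, `skim`; duplicate (gene, source) records count
#'   once.
#' @param cfg A [score_config()].
#' @return Tibble `gene`, `score`, `sources` (comma-joined).
#' @export
composite_score <- function(evidence, cfg = score_config()) {
  bad <- setdiff(unique(evidence$source), names(cfg$weights))
  if (length(bad)) {
    rlang::abort(paste0("unknown evidence source: ", paste(bad, collapse = ", ")))
  }
  evidence |>
    distinct(.data$gene, .data$source) |>
    group_by(.data$gene) |>
    summarise(score = sum(cfg$weights[.data$source]),
              sources = paste(sort(.data$source), collapse = ","),
              .groups = "drop")
}

#' Literature-based-discovery prediction score
#'
#' `score = -log(fet_p) + n_ab / n_b`: the negative log of the Fisher
#' exact test p-value for the term-pair association plus the sort ratio
#' (abstracts containing both terms over abstracts containing the B term).
#'
#' @param n_ab Abstracts containing both terms (vectorised).
#' @param n_b Abstracts containing the B term.
#' @param fet_p Fisher exact test p-value in (0, 1].
#' @param cfg A [score_config()] (supplies the log base).
#' @return Numeric score(s).
#' @export
skim_prediction_score <- function(n_ab, n_b, fet_p, cfg = score_config()) {
  if (any(fet_p <= 0) || any(fet_p > 1)) {
    rlang::abort("`fet_p` must lie in (0, 1].")
  }
  if (any(n_ab < 0) || any(n_b <= 0) || any(n_ab > n_b)) {
    rlang::abort("counts must satisfy 0 <= n_ab <= n_b with n_b > 0.")
  }
  -log(fet_p, base = cfg$skim_log_base) + n_ab / n_b
}

#' Rank genes by composite score
#'
#' Descending score; ties broken lexicographically by gene id, so the
#' ordering is stable across runs.
#'
#' @param score_table Tibble `gene`, `score` (e.g. from
#'   [composite_score()]).
#' @return The table sorted, with a `rank` column.
#' @export
rank_genes <- function(score_table) {
  score_table |>
    arrange(dplyr::desc(.data$score), .data$gene) |>
    mutate(rank = dplyr::row_number())
}
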