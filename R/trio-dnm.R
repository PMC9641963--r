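# Trio-based de novo mutation-rate estimation: site and individual filter
# cascade, dual-mapping candidate intersection, callability, FNR correction
# and the per-generation rate.

#' Filter configuration for trio genotype tables
#'
#' Defaults are the GATK-style hard thresholds of the pipeline: sites fail
#' on `QD < 2`, `FS > 20`, `MQ < 40`, `MQRankSum` outside `[-2, 4]`,
#' `ReadPosRankSum` outside `[-3, 3]` or `SOR > 3`; individuals fail on
#' depth outside `[0.5, 2] x` their mean depth or `GQ < 60`; for candidate
#' screening a parent fails on any alternate-allele read (`AD > 0`) and the
#' offspring on allelic balance outside `[0.3, 0.7]`.
#'
#' @param depth_means Named numeric vector of per-individual mean depths
#'   (`offspring`, `father`, `mother`).
#' @param qd_min,fs_max,mq_min,mqrs_low,mqrs_high,rprs_low,rprs_high,sor_max
#'   Site-annotation thresholds.
#' @param dp_multipliers Depth window as multipliers of the individual mean.
#' @param gq_min Minimum genotype quality.
#' @param ab_window Offspring allelic-balance window.
#' @return A list of class `trio_filter_config`.
#' @export
trio_filter_config <- function(depth_means = c(offspring = 56, father = 78, mother = 84),
                               qd_min = 2.0, fs_max = 20.0, mq_min = 40.0,
                               mqrs_low = -2.0, mqrs_high = 4.0,
                               rprs_low = -3.0, rprs_high = 3.0,
                               sor_max = 3.0,
                               dp_multipliers = c(0.5, 2),
                               gq_min = 60, ab_window = c(0.3, 0.7)) {
  stopifnot(dp_multipliers[1] < dp_multipliers[2],
            ab_window[1] < ab_window[2],
            all(c("offspring", "father", "mother") %in% names(depth_means)))
  structure(list(depth_means = depth_means, qd_min = qd_min, fs_max = fs_max,
                 mq_min = mq_min, mqrs_low = mqrs_low, mqrs_high = mqrs_high,
                 rprs_low = rprs_low, rprs_high = rprs_high, sor_max = sor_max,
                 dp_multipliers = dp_multipliers, gq_min = gq_min,
                 ab_window = ab_window),
            class = "trio_filter_config")
}

# A missing annotation passes its sub-filter (permissive), so NA never
# fails a site; how many were missing is reported through an attribute.
fails <- function(x, bad) !is.na(x) & bad

#' Site-level annotation filter
#'
#' Adds `site_pass` (logical) and `site_reasons` (comma-joined names of
#' every violated threshold, `""` when passing). Missing annotations are
#' treated as passing their sub-filter.
#'
#' @param table A per-site trio table (one mapping of [simulate_trio()], or
#'   read with [read_trio_table()]).
#' @param cfg A [trio_filter_config()].
#' @return The table with `site_pass` and `site_reasons` columns.
#' @export
site_filter <- function(table, cfg = trio_filter_config()) {
  reasons <- cbind(
    QD = fails(table$qd, table$qd < cfg$qd_min),
    FS = fails(table$fs, table$fs > cfg$fs_max),
    MQ = fails(table$mq, table$mq < cfg$mq_min),
    MQRankSum = fails(table$mq_rank_sum,
                      table$mq_rank_sum < cfg$mqrs_low |
                        table$mq_rank_sum > cfg$mqrs_high),
    ReadPosRankSum = fails(table$read_pos_rank_sum,
                           table$read_pos_rank_sum < cfg$rprs_low |
                             table$read_pos_rank_sum > cfg$rprs_high),
    SOR = fails(table$sor, table$sor > cfg$sor_max)
  )
  n_missing <- sum(is.na(table$qd), is.na(table$fs), is.na(table$mq),
                   is.na(table$mq_rank_sum), is.na(table$read_pos_rank_sum),
                   is.na(table$sor))
  if (n_missing > 0) {
    rlang::inform(sprintf("%d missing site annotation value(s) treated as passing.", n_missing))
  }
  table$site_pass <- rowSums(reasons) == 0L
  table$site_reasons <- apply(reasons, 1L, function(r) {
    paste(colnames(reasons)[r], collapse = ",")
  })
  table
}

#' Per-individual genotype filters
#'
#' Adds, for each of `father`, `mother`, `offspring`: `<ind>_dp_pass`
#' (depth within the individual's window) and `<ind>_gq_pass`; plus the
#' candidate-screening columns `father_ad_pass`/`mother_ad_pass` (no
#' alternate-allele reads in the parent) and `offspring_ab_pass` (allelic
#' balance inside the window, applied to the offspring only).
#'
#' @inheritParams site_filter
#' @return The table with per-individual pass columns.
#' @export
individual_filter <- function(table, cfg = trio_filter_config()) {
  for (ind in trio_individuals) {
    m <- cfg$depth_means[[ind]]
    dp <- table[[paste0(ind, "_dp")]]
    gq <- table[[paste0(ind, "_gq")]]
    table[[paste0(ind, "_dp_pass")]] <-
      !fails(dp, dp < cfg$dp_multipliers[1] * m | dp > cfg$dp_multipliers[2] * m)
    table[[paste0(ind, "_gq_pass")]] <- !fails(gq, gq < cfg$gq_min)
  }
  table$father_ad_pass <- !fails(table$father_ad_alt, table$father_ad_alt > 0L)
  table$mother_ad_pass <- !fails(table$mother_ad_alt, table$mother_ad_alt > 0L)
  ab <- table$offspring_ab
  table$offspring_ab_pass <-
    !fails(ab, ab < cfg$ab_window[1] | ab > cfg$ab_window[2])
  table
}

ensure_filtered <- function(table, cfg) {
  if (!"site_pass" %in% names(table)) table <- site_filter(table, cfg)
  if (!"offspring_ab_pass" %in% names(table)) table <- individual_filter(table, cfg)
  table
}

dp_gq_pass <- function(table) {
  table$father_dp_pass & table$mother_dp_pass & table$offspring_dp_pass &
    table$father_gq_pass & table$mother_gq_pass & table$offspring_gq_pass
}

#' Find dual-configuration de novo candidates
#'
#' A candidate of maternal origin must qualify on both mappings: parents
#' 0/0 and offspring 0/1 on the paternal mapping, parents 1/1 and offspring
#' 0/1 on the maternal mapping, passing the site filter, the parental
#' depth/quality/AD screen and the offspring allelic-balance screen on both
#' tables, and carrying the same evidence token (the stand-in for read-name
#' overlap between the two call sets) in both. Paternal candidates are
#' symmetric with the mapping roles swapped.
#'
#' @param maternal_mapping,paternal_mapping Per-site trio tables for the
#'   two mapping targets (or pass a `trio_tables` object as the first
#'   argument).
#' @param cfg A [trio_filter_config()].
#' @return Tibble `chrom`, `pos`, `origin` (maternal/paternal), `ev`.
#' @export
find_candidates <- function(maternal_mapping, paternal_mapping = NULL,
                            cfg = trio_filter_config()) {
  if (inherits(maternal_mapping, "trio_tables")) {
    trio <- maternal_mapping
    paternal_mapping <- trio$paternal_mapping
    maternal_mapping <- trio$maternal_mapping
  }
  if (!any(maternal_mapping$chrom %in% paternal_mapping$chrom) &&
      nrow(maternal_mapping) > 0 && nrow(paternal_mapping) > 0) {
    rlang::abort("the two mapping tables share no scaffold names; cannot intersect candidates.")
  }
  mat <- ensure_filtered(maternal_mapping, cfg)
  pat <- ensure_filtered(paternal_mapping, cfg)
  screen <- function(tb, parent_gt) {
    ok <- tb$site_pass & dp_gq_pass(tb) &
      tb$father_gt == parent_gt & tb$mother_gt == parent_gt &
      tb$offspring_gt == "0/1" & tb$offspring_ab_pass &
      !is.na(tb$offspring_ev)
    if (parent_gt == "0/0") ok <- ok & tb$father_ad_pass & tb$mother_ad_pass
    tb[ok, c("chrom", "pos", "offspring_ev")]
  }
  intersect_cand <- function(ref_cfg_tb, alt_cfg_tb, origin) {
    inner_join(screen(ref_cfg_tb, "0/0"), screen(alt_cfg_tb, "1/1"),
               by = c("chrom", "pos"), suffix = c("_ref", "_alt")) |>
      filter(.data$offspring_ev_ref == .data$offspring_ev_alt) |>
      transmute(chrom = .data$chrom, pos = .data$pos, origin = origin,
                ev = .data$offspring_ev_ref)
  }
  maternal <- intersect_cand(pat, mat, "maternal")
  paternal <- intersect_cand(mat, pat, "paternal")
  out <- bind_rows(maternal, paternal)
  dup <- duplicated(out[, c("chrom", "pos")])
  arrange(out[!dup, ], .data$chrom, .data$pos)
}

#' Callable sites of a trio table
#'
#' Counts the sites with full detection power: all three individuals pass
#' the depth and genotype-quality filters and both parents pass the
#' alternate-allele screen. Site-level annotation filters and the
#' allelic-balance filter are deliberately not applied here -- their losses
#' are handled by the false-negative-rate correction.
#'
#' @inheritParams site_filter
#' @return Number of callable sites (bp, one table row = one site).
#' @export
callability <- function(table, cfg = trio_filter_config()) {
  tb <- ensure_filtered(table, cfg)
  sum(dp_gq_pass(tb) & tb$father_ad_pass & tb$mother_ad_pass)
}

#' False-negative rate from obligate-heterozygous transmissions
#'
#' At sites where one parent is 0/0 and the other 1/1, the offspring must
#' be heterozygous, so every such site carries a true heterozygous
#' genotype. The FNR combines the fraction of these sites lost to the
#' offspring allelic-balance filter with the fraction lost to the
#' site-level filters: `fnr = 1 - ab_survival * site_survival`.
#'
#' @inheritParams site_filter
#' @return The estimated false-negative rate in `[0, 1)`.
#' @export
estimate_fnr <- function(table, cfg = trio_filter_config()) {
  tb <- ensure_filtered(table, cfg)
  obl <- (tb$father_gt == "0/0" & tb$mother_gt == "1/1") |
    (tb$father_gt == "1/1" & tb$mother_gt == "0/0")
  obl <- obl & tb$offspring_gt == "0/1"
  if (!any(obl)) {
    rlang::abort("no obligate-heterozygous transmission sites; FNR is undefined.")
  }
  ab_surv <- mean(tb$offspring_ab_pass[obl])
  site_surv <- mean(tb$site_pass[obl])
  1 - ab_surv * site_surv
}

#' Per-generation germline mutation rate
#'
#' The diploid callable size is the summed per-assembly callability scaled
#' down by the false-negative rate; the rate is the total candidate count
#' over that size: `rate = (n_maternal + n_paternal) /
#' ((callability_maternal + callability_paternal) * (1 - fnr))`.
#'
#' @param n_maternal,n_paternal Candidate de novo mutation counts by
#'   parental origin.
#' @param callability_maternal,callability_paternal Callable bp on the two
#'   mapping targets (see [callability()]).
#' @param fnr False-negative rate in `[0, 1)`.
#' @return A `mutation_rate_estimate`: list with the inputs,
#'   `diploid_callable` (bp) and `rate` (mutations per site per
#'   generation).
#' @examples
#' est <- mutation_rate(1, 3, 1371536436, 1365805112, fnr = 0.05)
#' round(est$rate * 1e8, 2)  # 0.15 in units of 1e-8
#' @export
mutation_rate <- function(n_maternal, n_paternal, callability_maternal,
                          callability_paternal, fnr) {
  assert_scalar_number(n_maternal, "n_maternal", min = 0)
  assert_scalar_number(n_paternal, "n_paternal", min = 0)
  assert_scalar_number(callability_maternal, "callability_maternal", min = 1)
  assert_scalar_number(callability_paternal, "callability_paternal", min = 1)
  if (!is.numeric(fnr) || fnr < 0 || fnr >= 1) {
    rlang::abort("`fnr` must lie in [0, 1).")
  }
  diploid <- (callability_maternal + callability_paternal) * (1 - fnr)
  structure(list(n_maternal = n_maternal, n_paternal = n_paternal,
                 callability_maternal = callability_maternal,
                 callability_paternal = callability_paternal, fnr = fnr,
                 diploid_callable = diploid,
                 rate = (n_maternal + n_paternal) / diploid),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat("<mutation_rate_estimate>\n")
  cat("  candidates: ", x$n_maternal, " maternal + ", x$n_paternal,
      " paternal\n", sep = "")
  cat("  diploid callable: ", format(x$diploid_callable, big.mark = ","),
      " bp (FNR ", format(100 * x$fnr), "%)\n", sep = "")
  cat("  rate: ", format(signif(x$rate, 3)),
      " per site per generation (", sprintf("%.2f", x$rate * 1e8),
      " x 1e-8)\n", sep = "")
  invisible(x)
}

#' @export
tidy.mutation_rate_estimate <- function(x, ...) {
  tibble(origin = c("maternal", "paternal"),
         n_candidates = c(x$n_maternal, x$n_paternal),
         callability = c(x$callability_maternal, x$callability_paternal))
}

#' @export
glance.mutation_rate_estimate <- function(x, ...) {
  tibble(n_candidates = x$n_maternal + x$n_paternal, fnr = x$fnr,
         diploid_callable = x$diploid_callable, rate = x$rate,
         rate_1e8 = x$rate * 1e8)
}
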