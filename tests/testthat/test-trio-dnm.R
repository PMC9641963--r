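# Trio filter cascade, dual-mapping candidate intersection, callability,
# FNR estimation and the mutation-rate formula.

clean_site <- function(n = 1) {
  tb <- tibble::tibble(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = NA_character_,
    qd = 20, fs = 1, mq = 60, mq_rank_sum = 0, read_pos_rank_sum = 0, sor = 1)
  for (ind in c("father", "mother", "offspring")) {
    m <- c(father = 78, mother = 84, offspring = 56)[[ind]]
    tb[[paste0(ind, "_gt")]] <- "0/0"
    tb[[paste0(ind, "_dp")]] <- as.integer(m)
    tb[[paste0(ind, "_gq")]] <- 99L
    tb[[paste0(ind, "_ad_alt")]] <- 0L
    tb[[paste0(ind, "_ab")]] <- 0
    tb[[paste0(ind, "_ev")]] <- NA_integer_
  }
  tb
}

test_that("site filter fails on each annotation threshold with reason codes", {
  s <- clean_site()
  expect_true(site_filter(s)$site_pass)
  cases <- list(
    list(col = "qd", val = 1.5, reason = "QD"),
    list(col = "fs", val = 25, reason = "FS"),
    list(col = "mq", val = 39, reason = "MQ"),
    list(col = "mq_rank_sum", val = -2.5, reason = "MQRankSum"),
    list(col = "mq_rank_sum", val = 4.5, reason = "MQRankSum"),
    list(col = "read_pos_rank_sum", val = 3.5, reason = "ReadPosRankSum"),
    list(col = "sor", val = 3.5, reason = "SOR"))
  for (cs in cases) {
    bad <- s
    bad[[cs$col]] <- cs$val
    out <- site_filter(bad)
    expect_false(out$site_pass)
    expect_match(out$site_reasons, cs$reason)
  }
  # boundary values pass (strict inequalities)
  edge <- s
  edge$qd <- 2; edge$sor <- 3; edge$mq <- 40
  edge$mq_rank_sum <- 4; edge$read_pos_rank_sum <- -3
  expect_true(site_filter(edge)$site_pass)
  # missing annotations pass their sub-filter, with a note
  na_site <- s
  na_site$qd <- NA_real_
  expect_message(out <- site_filter(na_site), "missing")
  expect_true(out$site_pass)
})

test_that("individual filters apply the depth window, GQ, parental AD and
           offspring AB rules", {
  s <- clean_site()
  s$offspring_dp <- 20L   # below 0.5 x 56
  out <- individual_filter(s)
  expect_false(out$offspring_dp_pass)
  expect_true(out$father_dp_pass)
  s2 <- clean_site(); s2$mother_gq <- 59L
  expect_false(individual_filter(s2)$mother_gq_pass)
  s3 <- clean_site(); s3$father_ad_alt <- 1L
  expect_false(individual_filter(s3)$father_ad_pass)
  s4 <- clean_site(); s4$offspring_ab <- 0.5
  expect_true(individual_filter(s4)$offspring_ab_pass)
  s5 <- clean_site(); s5$offspring_ab <- 0.25
  expect_false(individual_filter(s5)$offspring_ab_pass)
})

test_that("candidate finding recovers planted mutations with their origin and
           requires the dual configuration with a shared token", {
  trio <- fx_trio_clean()
  cand <- find_candidates(trio)
  truth <- dplyr::arrange(trio$truth$dnms, pos)
  expect_equal(cand$pos, truth$pos)
  expect_equal(cand$origin, truth$origin)
  expect_equal(sum(cand$origin == "maternal"), 1L)
  expect_equal(sum(cand$origin == "paternal"), 3L)
  # empty tables yield no candidates
  empty <- clean_site(0)
  expect_equal(nrow(find_candidates(empty, empty)), 0L)
  # a site qualifying on one mapping only (no shared token) is excluded
  g <- generate_genome(71, scaffolds = c(chr1 = 2e4), te_density = 0)
  trio2 <- simulate_trio(g, het_rate = 0, n_dnm_maternal = 0,
                         n_dnm_paternal = 0,
                         annotation_noise = list(n_unshared = 5), seed = 72)
  expect_equal(nrow(find_candidates(trio2)), 0L)
  # disjoint scaffold names cannot be intersected
  other <- clean_site(5)
  other$chrom <- "chrZ"
  expect_error(find_candidates(clean_site(5), other), "scaffold")
})

test_that("origin assignment swaps exactly when the mapping tables swap", {
  trio <- fx_trio_clean()
  swapped <- find_candidates(trio$paternal_mapping, trio$maternal_mapping)
  orig <- find_candidates(trio)
  expect_equal(orig$pos, swapped$pos)
  expect_equal(orig$origin,
               ifelse(swapped$origin == "maternal", "paternal", "maternal"))
})

test_that("callability counts DP/GQ/AD-passing sites and matches a direct
           predicate recount", {
  s <- clean_site(1000)
  expect_equal(callability(s), 1000)
  # 10% offspring GQ failures
  s2 <- s; s2$offspring_gq[1:100] <- 30L
  expect_equal(callability(s2), 900)
  # mixed planted violations vs independent recount
  g <- generate_genome(81, scaffolds = c(chr1 = 2e4), te_density = 0)
  trio <- simulate_trio(g, het_rate = 1e-3, n_dnm_maternal = 0,
                        n_dnm_paternal = 0,
                        annotation_noise = list(frac_gq_low = 0.05,
                                                frac_dp_out = 0.05),
                        seed = 82)
  tb <- individual_filter(trio$maternal_mapping)
  oracle <- sum(
    tb$father_dp >= 39 & tb$father_dp <= 156 &
      tb$mother_dp >= 42 & tb$mother_dp <= 168 &
      tb$offspring_dp >= 28 & tb$offspring_dp <= 112 &
      tb$father_gq >= 60 & tb$mother_gq >= 60 & tb$offspring_gq >= 60 &
      tb$father_ad_alt == 0 & tb$mother_ad_alt == 0)
  expect_equal(callability(trio$maternal_mapping), oracle)
  # site-level and AB columns do not affect callability
  s3 <- s; s3$qd <- 1; s3$offspring_ab <- 0.9
  expect_equal(callability(s3), 1000)
})

test_that("FNR combines allelic-balance and site-filter losses
           multiplicatively", {
  # constructed table: 100 obligate-het sites, 5 AB-violated, 2 site-failed
  s <- clean_site(100)
  s$father_gt <- "0/0"; s$mother_gt <- "1/1"; s$offspring_gt <- "0/1"
  s$mother_ad_alt <- 84L; s$mother_ab <- 1
  s$offspring_ab <- 0.5; s$offspring_ad_alt <- 28L
  s$offspring_ab[1:5] <- 0.1
  s$qd[6:7] <- 1.0
  expect_equal(estimate_fnr(s), 1 - 0.95 * 0.98)
  # no violations: zero FNR
  s0 <- s; s0$offspring_ab <- 0.5; s0$qd <- 20
  expect_equal(estimate_fnr(s0), 0)
  # no obligate-het sites: undefined
  expect_error(estimate_fnr(clean_site(10)), "obligate")
  # simulated: ~5% planted AB violations recovered as ~5% FNR
  g <- generate_genome(91, scaffolds = c(chr1 = 1e5), te_density = 0)
  trio <- simulate_trio(g, het_rate = 0.02, n_dnm_maternal = 0,
                        n_dnm_paternal = 0,
                        annotation_noise = list(frac_ab_violation = 0.05),
                        seed = 92)
  n_obl <- sum(trio$truth$het_sites$config == "obligate")
  expected <- nrow(trio$truth$ab_violations) / n_obl
  expect_equal(estimate_fnr(trio$maternal_mapping), expected, tolerance = 1e-6)
})

test_that("the mutation-rate formula reproduces its worked example and the
           identity rate x callable = candidates holds", {
  est <- mutation_rate(1, 3, 1371536436, 1365805112, fnr = 0.05)
  expect_equal(round(est$rate * 1e8, 2), 0.15)
  expect_equal(signif(est$diploid_callable, 2), 2.6e9)
  expect_equal(est$rate * est$diploid_callable, 4)
  expect_equal(mutation_rate(0, 0, 1e9, 1e9, 0)$rate, 0)
  expect_equal(mutation_rate(2, 0, 1e9, 1e9, 0)$rate, 1e-9)
  expect_error(mutation_rate(1, 3, 1e9, 1e9, fnr = 1), "fnr")
  gl <- glance(est)
  expect_equal(gl$rate_1e8, est$rate * 1e8)
})

test_that("tightening filter thresholds never increases candidates or
           callability", {
  trio <- fx_trio_clean()
  base_cfg <- trio_filter_config()
  tight_gq <- trio_filter_config(gq_min = 100)
  tight_dp <- trio_filter_config(dp_multipliers = c(0.9, 1.1))
  tight_ab <- trio_filter_config(ab_window = c(0.45, 0.55))
  n_cand <- function(cfg) nrow(find_candidates(trio$maternal_mapping,
                                               trio$paternal_mapping, cfg))
  expect_lte(n_cand(tight_gq), n_cand(base_cfg))
  expect_lte(n_cand(tight_dp), n_cand(base_cfg))
  expect_lte(n_cand(tight_ab), n_cand(base_cfg))
  expect_lte(callability(trio$maternal_mapping, tight_gq),
             callability(trio$maternal_mapping, base_cfg))
  expect_lte(callability(trio$maternal_mapping, tight_dp),
             callability(trio$maternal_mapping, base_cfg))
})
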