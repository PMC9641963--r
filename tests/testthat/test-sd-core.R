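# Segmental-duplication filtering: stand-in aligner recall and identity
# accuracy, repeat-mask and high-copy filters against oracles, interval
# graph vs transitive closure, summaries and age conversion.

test_that("self-alignment finds planted duplications with accurate identity", {
  g <- fx_sd_genome()
  pairs <- fx_sd_pairs()
  d <- g$truth$duplications
  # recall against the truth set (each planted pair recovered)
  ov <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2)
  hit <- vapply(seq_len(nrow(d)), function(i) {
    src_len <- d$src_end[i] - d$src_start[i]
    tgt_len <- d$tgt_end[i] - d$tgt_start[i]
    direct <- ov(pairs$start_a, pairs$end_a, d$src_start[i], d$src_end[i]) >
      0.9 * src_len &
      ov(pairs$start_b, pairs$end_b, d$tgt_start[i], d$tgt_end[i]) >
        0.9 * tgt_len
    flipped <- ov(pairs$start_b, pairs$end_b, d$src_start[i], d$src_end[i]) >
      0.9 * src_len &
      ov(pairs$start_a, pairs$end_a, d$tgt_start[i], d$tgt_end[i]) >
        0.9 * tgt_len
    any(direct | flipped)
  }, logical(1))
  expect_gte(sum(hit), 9L)
  # reported identity within 0.02 of the full dynamic-programming oracle
  ora <- vapply(seq_len(nrow(pairs)), function(i) {
    dp_identity(
      extract_interval(g, pairs$chr_a[i], pairs$start_a[i], pairs$end_a[i]),
      extract_interval(g, pairs$chr_b[i], pairs$start_b[i], pairs$end_b[i]))
  }, numeric(1))
  expect_true(all(abs(ora - pairs$identity) < 0.02))
})

test_that("self-alignment of a duplication-free genome is empty and an exact
           tandem copy yields one near-perfect pair", {
  g0 <- generate_genome(111, scaffolds = c(chr1 = 1e5), te_density = 0)
  expect_equal(nrow(naive_self_align(g0, 1000, 0.9)), 0L)
  g1 <- plant_duplications(g0, 1, length_range = c(5000, 5000),
                           identity_range = c(1, 1), tandem_fraction = 1,
                           seed = 112)
  p <- naive_self_align(g1, 1000, 0.9)
  expect_equal(nrow(p), 1L)
  expect_gte(p$identity, 0.999)
  expect_error(naive_self_align(c(chr1 = strrep("A", 1.1e7)), 1000, 0.9),
               "10 Mb", fixed = TRUE)
})

test_that("repeat-mask filter keeps exactly the pairs under the masking
           threshold, checked by interval-intersection recount", {
  pairs <- fx_sd_pairs()
  g <- fx_sd_genome()
  # mask one duplication copy fully, leave the rest untouched
  d <- g$truth$duplications
  track <- tibble::tibble(scaffold = d$tgt_scaffold[1:3],
                          start = d$tgt_start[1:3], end = d$tgt_end[1:3])
  kept <- filter_repeat_masked(pairs, track, sd_config())
  mf <- masked_fractions(pairs, track)
  expect_identical(kept$start_a,
                   pairs$start_a[mf$masked_frac_a <= 0.9 & mf$masked_frac_b <= 0.9])
  expect_lt(nrow(kept), nrow(pairs))
  # boundary: a pair masked over 90% on either side is removed
  p1 <- pairs[1, ]
  full_mask <- tibble::tibble(scaffold = p1$chr_b,
                              start = p1$start_b,
                              end = p1$start_b + ceiling(0.95 * (p1$end_b - p1$start_b)))
  expect_equal(nrow(filter_repeat_masked(p1, full_mask, sd_config())), 0L)
  # empty input allowed
  expect_equal(nrow(filter_repeat_masked(pairs[0, ], track, sd_config())), 0L)
})

test_that("masked-threshold tightening is monotone", {
  pairs <- fx_sd_pairs()
  g <- fx_sd_genome()
  d <- g$truth$duplications
  track <- tibble::tibble(scaffold = d$tgt_scaffold, start = d$tgt_start,
                          end = pmin(d$tgt_end, d$tgt_start +
                                       round(0.5 * (d$tgt_end - d$tgt_start))))
  ths <- c(0.9, 0.6, 0.4, 0.2, 0)
  sizes <- vapply(ths, function(th) {
    nrow(filter_repeat_masked(pairs, track, sd_config(masked_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("duplication-graph components match the transitive-closure oracle", {
  # hand-built: pairs (A,B) and (B,C), all disjoint -> one component of 3
  pairs <- tibble::tibble(
    chr_a = "s", start_a = c(0L, 5000L), end_a = c(1000L, 6000L),
    chr_b = "s", start_b = c(5000L, 9000L), end_b = c(6000L, 10000L),
    identity = 0.95, length = 1000L)
  gr <- build_duplication_graph(pairs)
  expect_equal(dplyr::n_distinct(gr$nodes$component_id), 1L)
  expect_equal(unique(gr$nodes$copy_number), 3L)
  # random instances vs brute-force closure
  for (seed in 1:5) {
    set.seed(seed)
    n_pairs <- 50L
    iv <- function(n) {
      s <- sample.int(20000L, n)
      tibble::tibble(chr = sample(c("s1", "s2"), n, TRUE), start = s,
                     end = s + sample.int(500L, n))
    }
    a <- iv(n_pairs); b <- iv(n_pairs)
    rp <- tibble::tibble(chr_a = a$chr, start_a = a$start, end_a = a$end,
                         chr_b = b$chr, start_b = b$start, end_b = b$end,
                         identity = 0.95, length = 100L)
    gr <- build_duplication_graph(rp)
    oracle <- closure_components(nrow(gr$nodes), gr$edges)
    # same partition: oracle labels refine to identical groupings
    expect_equal(
      as.integer(factor(gr$nodes$component_id,
                        levels = unique(gr$nodes$component_id))),
      as.integer(factor(oracle, levels = unique(oracle))))
  }
})

test_that("high-copy filter removes components above the copy threshold with
           an exact boundary at the configured maximum", {
  star_pairs <- function(k) {
    # k unique intervals: one source aligned to k-1 disjoint copies
    tibble::tibble(
      chr_a = "s", start_a = 0L, end_a = 1000L,
      chr_b = "s", start_b = (seq_len(k - 1L)) * 2000L,
      end_b = (seq_len(k - 1L)) * 2000L + 1000L,
      identity = 0.95, length = 1000L)
  }
  for (k in c(19L, 20L, 21L)) {
    p <- star_pairs(k)
    kept <- filter_high_copy(p, cfg = sd_config())
    if (k <= 20L) expect_equal(nrow(kept), nrow(p))
    else expect_equal(nrow(kept), 0L)
  }
  # tightening max_copies is monotone
  p <- star_pairs(15L)
  sizes <- vapply(c(20, 15, 14, 10, 5), function(mc) {
    nrow(filter_high_copy(p, cfg = sd_config(max_copies = mc)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("summaries merge intervals non-redundantly and are order-invariant", {
  expect_equal(summarize_sd(fx_sd_pairs()[0, ])$duplicated_bases, 0)
  # two pairs sharing an interval: merged bases below the naive sum
  pairs <- tibble::tibble(
    chr_a = "s", start_a = c(0L, 0L), end_a = c(1000L, 1000L),
    chr_b = "s", start_b = c(5000L, 8000L), end_b = c(6000L, 9000L),
    identity = 0.95, length = 1000L)
  s <- summarize_sd(pairs)
  expect_equal(s$duplicated_bases, 3000)
  expect_lt(s$duplicated_bases, 4000)
  # permutation invariance and truth footprint
  p <- fx_sd_pairs()
  s1 <- summarize_sd(p)
  s2 <- summarize_sd(p[sample.int(nrow(p)), ])
  expect_equal(s1$duplicated_bases, s2$duplicated_bases)
  g <- fx_sd_genome()
  d <- g$truth$duplications
  footprint <- sum(d$src_end - d$src_start) + sum(d$tgt_end - d$tgt_start)
  expect_lt(abs(s1$duplicated_bases - footprint) / footprint, 0.05)
  expect_equal(sum(s1$identity_histogram$n_pairs), s1$n_pairs)
})

test_that("divergence converts linearly to age under the configured clock", {
  expect_equal(divergence_to_age(1.0), 0)
  expect_equal(divergence_to_age(0.995), 1e5)
  expect_equal(divergence_to_age(0.99), 2e5)
  expect_equal(divergence_to_age(0.99, sd_config(divergence_per_100ky = 0.01)),
               1e5)
  expect_error(divergence_to_age(1.2), "0, 1")
})
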