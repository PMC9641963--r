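# The generators are pure functions of (parameters, seed) and their truth
# sets record exactly what was planted.

test_that("genome generation is deterministic and validates inputs", {
  g1 <- generate_genome(1, scaffolds = c(chr1 = 5e4), te_density = 0)
  g2 <- generate_genome(1, scaffolds = c(chr1 = 5e4), te_density = 0)
  expect_identical(g1$sequences, g2$sequences)
  expect_equal(nrow(g1$repeat_track), 0L)
  expect_true(grepl("^[ACGT]+$", g1$sequences[["chr1"]]))
  expect_equal(genome_size(g1), 5e4)
  expect_error(generate_genome(1, scaffolds = c(chr1 = -5)), "positive")
  expect_error(generate_genome(1, scaffolds = c(chr1 = 5000)), "10 kb")
})

test_that("planted mobile elements are recorded and findable in sequence", {
  g <- generate_genome(7, scaffolds = c(chr1 = 1e6), te_density = 20)
  expect_equal(nrow(g$truth$tes), nrow(g$repeat_track))
  expect_equal(nrow(g$truth$tes), 20L)
  found <- vapply(seq_len(nrow(g$truth$tes)), function(i) {
    te <- extract_interval(g, g$truth$tes$scaffold[i], g$truth$tes$start[i],
                           g$truth$tes$end[i])
    grepl(te, g$sequences[[g$truth$tes$scaffold[i]]], fixed = TRUE)
  }, logical(1))
  expect_true(all(found))
  expect_true(all(g$truth$tes$end <= 1e6))
})

test_that("planted duplications hit their target identity, measured by a
           full-alignment oracle", {
  g <- fx_sd_genome()
  d <- g$truth$duplications
  expect_equal(nrow(d), 10L)
  oracle_ids <- vapply(seq_len(nrow(d)), function(i) {
    dp_identity(extract_interval(g, d$scaffold[i], d$src_start[i], d$src_end[i]),
                extract_interval(g, d$tgt_scaffold[i], d$tgt_start[i], d$tgt_end[i]))
  }, numeric(1))
  expect_equal(oracle_ids, d$identity, tolerance = 1e-3)
  expect_true(mean(oracle_ids) > 0.94 && mean(oracle_ids) < 0.96)
})

test_that("zero duplication events leave the genome unchanged and an exact
           tandem copy is adjacent", {
  g <- generate_genome(2, scaffolds = c(chr1 = 5e4), te_density = 0)
  expect_identical(plant_duplications(g, 0)$sequences, g$sequences)
  g2 <- plant_duplications(g, 1, length_range = c(5000, 5000),
                           identity_range = c(1, 1), tandem_fraction = 1,
                           seed = 5)
  d <- g2$truth$duplications
  expect_equal(d$tgt_start, d$src_end)
  expect_identical(
    extract_interval(g2, d$scaffold, d$src_start, d$src_end),
    extract_interval(g2, d$tgt_scaffold, d$tgt_start, d$tgt_end))
  expect_equal(d$identity, 1)
})

test_that("planted genes record expected copy numbers by construction", {
  g <- fx_gene_genome()
  genes <- g$truth$genes
  expect_equal(nrow(genes), 20L)
  expect_equal(sum(genes$expected_copies > 1L), 5L)
  # interval-intersection oracle: a gene has >1 expected copies iff its body
  # lies inside a duplication source
  d <- g$truth$duplications
  inside <- vapply(seq_len(nrow(genes)), function(i) {
    any(d$scaffold == genes$scaffold[i] & d$src_start <= genes$start[i] &
          d$src_end >= genes$end[i])
  }, logical(1))
  expect_equal(genes$expected_copies > 1L, inside)
  # spliced lengths equal summed exon lengths
  tm <- transcript_models(g)
  expect_equal(tm$spliced_length,
               vapply(tm$exons, function(e) sum(e$end - e$start), integer(1)))
})

test_that("depth simulation matches its negative-binomial contract", {
  g <- generate_genome(3, scaffolds = c(chr1 = 1e6), te_density = 0)
  tr <- simulate_depth(g, mean_depth = 60, dispersion = 3, seed = 4)
  expect_equal(nrow(tr), 1e4)
  expect_lt(abs(mean(tr$depth) - 60) / 60, 0.02)
  expect_gt(var(tr$depth) / mean(tr$depth), 2)
  # collapsed interval carries proportionally elevated coverage
  coll <- tibble::tibble(scaffold = "chr1", start = 2e5L, end = 4e5L,
                         true_copies = 4L, assembled_copies = 2L)
  tr2 <- simulate_depth(g, 60, 3, collapses = coll, seed = 5)
  sel <- tr2$start >= 2e5 & tr2$end <= 4e5
  expect_lt(abs(mean(tr2$depth[sel]) - 120) / 120, 0.05)
  # Poisson fallback at dispersion 1
  tr3 <- simulate_depth(g, 60, 1, seed = 6)
  expect_true(var(tr3$depth) / mean(tr3$depth) > 0.9 &&
                var(tr3$depth) / mean(tr3$depth) < 1.1)
  expect_error(simulate_depth(g, 60, 3, bin_width = 0), "bin_width")
})

test_that("trio simulation plants the requested mutations with their dual
           configuration and shared evidence token", {
  trio <- fx_trio_clean()
  truth <- trio$truth$dnms
  expect_equal(sum(truth$origin == "maternal"), 1L)
  expect_equal(sum(truth$origin == "paternal"), 3L)
  for (i in seq_len(nrow(truth))) {
    m <- trio$maternal_mapping[trio$maternal_mapping$pos == truth$pos[i], ]
    p <- trio$paternal_mapping[trio$paternal_mapping$pos == truth$pos[i], ]
    ref_cfg <- if (truth$origin[i] == "maternal") p else m
    alt_cfg <- if (truth$origin[i] == "maternal") m else p
    expect_equal(ref_cfg$father_gt, "0/0")
    expect_equal(ref_cfg$mother_gt, "0/0")
    expect_equal(ref_cfg$offspring_gt, "0/1")
    expect_equal(alt_cfg$father_gt, "1/1")
    expect_equal(alt_cfg$mother_gt, "1/1")
    expect_equal(alt_cfg$offspring_gt, "0/1")
    expect_equal(ref_cfg$offspring_ev, alt_cfg$offspring_ev)
    expect_equal(ref_cfg$offspring_ev, truth$ev[i])
  }
})

test_that("a silent trio contains only homozygous-reference sites and noise
           plants recorded AB violations", {
  g <- generate_genome(5, scaffolds = c(chr1 = 2e4), te_density = 0)
  silent <- simulate_trio(g, het_rate = 0, n_dnm_maternal = 0,
                          n_dnm_paternal = 0, seed = 8)
  for (tb in list(silent$maternal_mapping, silent$paternal_mapping)) {
    expect_true(all(tb$father_gt == "0/0"))
    expect_true(all(tb$mother_gt == "0/0"))
    expect_true(all(tb$offspring_gt == "0/0"))
  }
  noisy <- simulate_trio(g, het_rate = 0.02, n_dnm_maternal = 0,
                         n_dnm_paternal = 0,
                         annotation_noise = list(frac_ab_violation = 0.1),
                         seed = 9)
  n_obl <- sum(noisy$truth$het_sites$config == "obligate")
  expect_equal(nrow(noisy$truth$ab_violations), round(0.1 * n_obl))
  viol <- noisy$maternal_mapping$pos %in% noisy$truth$ab_violations$pos
  expect_true(all(noisy$maternal_mapping$offspring_ab[viol] < 0.3 |
                    noisy$maternal_mapping$offspring_ab[viol] > 0.7))
})

test_that("haplotype mutation is conservative: rates zero means identical,
           planted events are recorded with class and size", {
  g <- generate_genome(6, scaffolds = c(chr1 = 5e4), te_density = 0)
  same <- mutate_haplotype(g, snv_rate = 0, small_indel_rate = 0, seed = 1)
  expect_identical(same$haplotype$sequences, g$sequences)
  del <- mutate_haplotype(g, snv_rate = 0, small_indel_rate = 0,
                          sv_events = data.frame(class = "deletion", size = 60),
                          seed = 2)
  expect_equal(nrow(del$truth), 1L)
  expect_equal(del$truth$class, "deletion")
  expect_equal(del$truth$size, 60L)
  expect_equal(nchar(del$haplotype$sequences[["chr1"]]), 5e4 - 60)
  expect_error(
    mutate_haplotype(g, sv_events = data.frame(class = "deletion", size = 6e4)),
    "larger")
  expect_error(
    mutate_haplotype(g, sv_events = data.frame(class = "duplication", size = 10)),
    "unknown SV class")
})

test_that("planted SNV counts follow the binomial expectation", {
  g <- generate_genome(10, scaffolds = c(chr1 = 1e6), te_density = 0)
  mh <- mutate_haplotype(g, snv_rate = 1e-3, small_indel_rate = 0, seed = 3)
  n <- sum(mh$truth$class == "SNV")
  expect_lt(abs(n - 1000), 3 * sqrt(1000 * (1 - 1e-3)))
})
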