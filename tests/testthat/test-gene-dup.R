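# Duplicated-gene calling: isoform eligibility, placement recovery,
# identity/coverage acceptance, mode classification, collapsed flags and
# cross-assembly comparison.

test_that("isoform selection enforces the intron and gene-body rules and
           keeps the longest spliced isoform", {
  tx <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g3"),
    transcript_id = c("g1_t1", "g2_t1", "g3_t1", "g3_t2"),
    n_exons = c(1L, 3L, 2L, 4L),
    gene_body_length = c(5000L, 800L, 2000L, 2000L),
    spliced_length = c(4000L, 700L, 1200L, 2000L))
  kept <- select_isoforms(tx)
  expect_equal(kept$gene_id, "g3")       # g1: single exon; g2: body < 1 kb
  expect_equal(kept$transcript_id, "g3_t2")  # longest spliced isoform
  # spliced-length tie broken by transcript id order
  tie <- tibble::tibble(gene_id = "g", transcript_id = c("g_t2", "g_t1"),
                        n_exons = 2L, gene_body_length = 2000L,
                        spliced_length = 1500L)
  expect_equal(select_isoforms(tie)$transcript_id, "g_t1")
})

test_that("transcripts map back to their own locus and to planted copies;
           scrambled sequence does not map", {
  g <- fx_gene_genome()
  al <- fx_gene_alignments()
  truth <- g$truth$genes
  el <- select_isoforms(transcript_models(g))
  # self-recovery: every eligible transcript has a near-perfect placement
  for (gid in el$gene_id) {
    pl <- al[al$gene_id == gid, ]
    expect_gte(nrow(pl), 1L)
    expect_gte(max(pl$identity), 0.999)
    expect_gte(max(pl$query_coverage), 0.99)
  }
  # duplicated genes have as many placements as expected copies
  for (gid in intersect(el$gene_id, truth$gene_id[truth$expected_copies > 1])) {
    expect_equal(nrow(al[al$gene_id == gid, ]),
                 truth$expected_copies[truth$gene_id == gid])
  }
  # random sequence finds nothing
  set.seed(1)
  scram <- tibble::tibble(
    gene_id = "rand", transcript_id = "rand_t1",
    exons = list(tibble::tibble(start = c(0L, 1500L), end = c(1000L, 2500L))),
    spliced_seq = paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
  expect_equal(nrow(map_transcripts(g, scram)), 0L)
})

test_that("duplication calls recover exactly the planted duplicated genes", {
  g <- fx_gene_genome()
  al <- fx_gene_alignments()
  truth <- g$truth$genes
  el <- select_isoforms(transcript_models(g))
  dups <- call_duplications(al)
  truth_dup <- sort(intersect(
    el$gene_id, truth$gene_id[truth$expected_copies > 1]))
  expect_equal(sort(dups$gene_id), truth_dup)
  expect_equal(dups$copies[order(dups$gene_id)],
               truth$expected_copies[match(truth_dup, truth$gene_id)])
  expect_true(all(dups$status == "resolved"))
})

test_that("identity and coverage thresholds gate duplication acceptance and
           are monotone", {
  al <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1_t1", rank = 1L,
    scaffold = "chr1", start = c(0L, 10000L), end = c(2000L, 12000L),
    identity = c(0.99, 0.99), query_coverage = c(1, 1))
  expect_equal(call_duplications(al)$copies, 2L)
  # divergence above 10% on the second placement: not duplicated
  al2 <- dplyr::mutate(al, identity = c(0.99, 0.85))
  expect_equal(nrow(call_duplications(al2)), 0L)
  # coverage below 90%: not duplicated
  al3 <- dplyr::mutate(al, query_coverage = c(1, 0.8))
  expect_equal(nrow(call_duplications(al3)), 0L)
  # monotonicity under threshold tightening
  g <- fx_gene_genome()
  alg <- fx_gene_alignments()
  copies_at <- function(mi, mc) {
    d <- call_duplications(alg, min_identity = mi, min_coverage = mc)
    sum(d$copies)
  }
  base <- copies_at(0.90, 0.90)
  expect_lte(copies_at(0.95, 0.90), base)
  expect_lte(copies_at(0.99, 0.90), copies_at(0.95, 0.90))
  expect_lte(copies_at(0.90, 0.99), base)
  # copy counts invariant under permutation of a gene's placements
  alg_shuf <- alg[sample.int(nrow(alg)), ]
  alg_shuf <- dplyr::arrange(alg_shuf, .data$rank)
  d1 <- call_duplications(alg)
  d2 <- call_duplications(alg_shuf)
  expect_equal(dplyr::arrange(d1[, c("gene_id", "copies")], gene_id),
               dplyr::arrange(d2[, c("gene_id", "copies")], gene_id))
})

test_that("same-location conflicts keep only the first-ranked gene", {
  al <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2"),
    transcript_id = c("g1_t1", "g1_t1", "g2_t1", "g2_t1"),
    rank = c(1L, 1L, 2L, 2L),
    scaffold = "chr1",
    start = c(0L, 10000L, 100L, 20000L),
    end = c(2000L, 12000L, 2100L, 22000L),
    identity = 0.99, query_coverage = 1)
  dups <- call_duplications(al)
  # g2's first placement overlaps g1's and is dropped; g2 keeps one
  # placement and is no longer duplicated
  expect_equal(dups$gene_id, "g1")
})

test_that("tandem/interspersed classification respects the gap threshold", {
  pl <- function(starts, scaffolds = "chr1") {
    tibble::tibble(scaffold = scaffolds, start = starts, end = starts + 10000L)
  }
  expect_equal(classify_mode(pl(c(0L, 20000L, 45000L, 70000L))), "tandem")
  expect_equal(classify_mode(pl(c(0L, 0L), c("chr1", "chr2"))), "interspersed")
  # boundary at the configured maximum gap
  expect_equal(classify_mode(pl(c(0L, 509000L))), "tandem")        # gap 499 kb
  expect_equal(classify_mode(pl(c(0L, 511000L))), "interspersed")  # gap 501 kb
})

test_that("genes over collapsed segments are flagged with implied missing
           copies", {
  segs <- tibble::tibble(scaffold = "chr1",
                         start = c(0L, 50000L), end = c(20000L, 60000L),
                         copy_number = c(4L, 2L), mean_depth = c(120, 60),
                         n_bins = c(200L, 100L))
  genes <- tibble::tibble(gene_id = c("slfn_like", "normal"),
                          scaffold = "chr1",
                          start = c(5000L, 50000L), end = c(10000L, 55000L),
                          copies = 1L)
  fl <- flag_collapsed_genes(genes, segs)
  expect_equal(fl$status, c("collapsed", "resolved"))
  expect_equal(fl$implied_extra_copies, c(3, 0))
  # below half overlap: resolved
  genes2 <- tibble::tibble(gene_id = "edge", scaffold = "chr1",
                           start = 15000L, end = 30000L, copies = 1L)
  expect_equal(flag_collapsed_genes(genes2, segs)$status, "resolved")
})

test_that("cross-assembly comparison equals the set-algebra oracle", {
  tbl <- function(...) {
    d <- tibble::tribble(...)
    names(d) <- c("gene_id", "copies")
    d
  }
  calls <- list(
    hapA = tbl(~g, ~c, "g1", 2L, "g2", 2L, "g3", 1L, "g4", 3L, "g5", 2L),
    hapB = tbl(~g, ~c, "g1", 2L, "g2", 1L, "g3", 1L, "g4", 2L, "g5", 2L),
    outA = tbl(~g, ~c, "g1", 1L, "g2", 1L, "g3", 1L, "g4", 1L, "g5", 2L),
    outB = tbl(~g, ~c, "g1", 1L, "g2", 1L, "g3", 2L, "g4", 1L))
  expect_message(
    res <- compare_copy_numbers(calls, c("hapA", "hapB"), c("outA", "outB")),
    "absent")
  # oracle: intersect the per-condition sets directly
  oracle <- Reduce(intersect, list(
    calls$hapA$gene_id[calls$hapA$copies >= 2],
    calls$hapB$gene_id[calls$hapB$copies >= 2],
    calls$outA$gene_id[calls$outA$copies == 1],
    calls$outB$gene_id[calls$outB$copies == 1]))
  expect_equal(res$gene_id, sort(oracle))
  expect_equal(res$gene_id, c("g1", "g4"))
})
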