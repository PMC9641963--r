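# Duplicated-gene calling from spliced-transcript multi-mapping: isoform
# eligibility, desk-scale spliced placement search, identity/coverage
# acceptance, tandem/interspersed classification, collapsed-gene flagging
# and cross-assembly copy-number comparison.

#' Select one eligible isoform per gene
#'
#' Keeps genes with at least one intron (two or more exons) and a gene body
#' of at least `min_gene_body` (default 1 kb), retaining the isoform with
#' the longest spliced sequence (ties broken by transcript id order).
#'
#' @param transcripts Tibble with at least `gene_id`, `transcript_id`,
#'   `n_exons`, `gene_body_length`, `spliced_length` (see
#'   [transcript_models()]).
#' @param min_gene_body Minimum gene body span in bp.
#' @return The filtered transcript tibble, one row per eligible gene.
#' @export
select_isoforms <- function(transcripts, min_gene_body = 1000) {
  transcripts |>
    filter(.data$n_exons >= 2L, .data$gene_body_length >= min_gene_body) |>
    arrange(.data$gene_id, dplyr::desc(.data$spliced_length),
            .data$transcript_id) |>
    distinct(.data$gene_id, .keep_all = TRUE)
}

#' Map spliced transcripts back to a genome (desk scale)
#'
#' Stand-in for a production splice-aware mapper: seeds each exon with
#' exact k-mers, clusters seed hits into candidate gene placements using
#' the exon offsets of the source model, and refines each candidate by
#' per-exon global-local alignment. Reports every placement with identity
#' (matched bases over aligned columns of the spliced sequence; introns
#' excluded) and query coverage (aligned spliced bases over spliced
#' length), best placement first.
#'
#' @param genome A `syn_genome` or named character vector of sequences.
#' @param transcripts Tibble from [select_isoforms()] (needs `exons`
#'   list-column and `spliced_seq`).
#' @param k Seed k-mer length (default 21).
#' @param stride Seed spacing along each exon in bp (default 20).
#' @return Tibble `gene_id`, `transcript_id`, `rank` (input order of the
#'   gene), `scaffold`, `start`, `end`, `identity`, `query_coverage`, one
#'   row per placement; transcripts with no placement are absent.
#' @export
map_transcripts <- function(genome, transcripts, k = 21, stride = 20) {
  seqs <- if (inherits(genome, "syn_genome")) genome$sequences else genome
  if (sum(nchar(seqs)) > 1e7) {
    rlang::abort("genome exceeds 10 Mb; map with an external spliced aligner instead.")
  }
  if (nrow(transcripts) == 0L) return(empty_gene_alignments())
  subj <- Biostrings::DNAStringSet(seqs)
  out <- vector("list", nrow(transcripts))
  for (ti in seq_len(nrow(transcripts))) {
    tr <- transcripts[ti, ]
    ex <- tr$exons[[1]]
    ex_len <- ex$end - ex$start
    ex_off_spliced <- cumsum(c(0L, ex_len))[seq_len(nrow(ex))]
    ex_off_genomic <- ex$start - ex$start[1]
    spliced <- tr$spliced_seq
    # seeds: (exon index, offset within exon, k-mer)
    seeds <- purrr::map(seq_len(nrow(ex)), function(e) {
      L <- ex_len[e]
      if (L < k) return(NULL)
      off <- unique(c(seq(0L, L - k, by = stride), L - k))
      tibble(exon = e, off = off,
             kmer = substring(spliced, ex_off_spliced[e] + off + 1L,
                              ex_off_spliced[e] + off + k))
    }) |> bind_rows()
    if (nrow(seeds) == 0L) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$kmer))
    hits <- purrr::map(names(seqs), function(sc) {
      m <- Biostrings::matchPDict(pd, subj[[sc]])
      st <- Biostrings::startIndex(m)
      n_hit <- lengths(st)
      if (sum(n_hit) == 0L) return(NULL)
      tibble(seed = rep(seq_along(st), n_hit),
             scaffold = sc,
             gpos = unlist(st) - 1L)      # 0-based
    }) |> bind_rows()
    if (nrow(hits) == 0L) next
    hits <- hits |>
      mutate(exon = seeds$exon[.data$seed], off = seeds$off[.data$seed],
             pred_gene_start = .data$gpos - .data$off -
               ex_off_genomic[.data$exon]) |>
      arrange(.data$scaffold, .data$pred_gene_start)
    # cluster predicted gene starts within 100 bp
    hits <- hits |>
      group_by(.data$scaffold) |>
      mutate(cluster = cumsum(c(1L, diff(.data$pred_gene_start) > 100L))) |>
      ungroup()
    placements <- hits |>
      group_by(.data$scaffold, .data$cluster) |>
      summarise(gene_start = as.integer(round(median(.data$pred_gene_start))),
                n_exons_hit = dplyr::n_distinct(.data$exon),
                .groups = "drop")
    pl <- purrr::pmap(placements, function(scaffold, cluster, gene_start,
                                           n_exons_hit) {
      slen <- nchar(seqs[[scaffold]])
      pad <- 30L
      tot_match <- 0; tot_cols <- 0; tot_q <- 0
      tgt0 <- NA_integer_; tgt1 <- NA_integer_
      for (e in seq_len(nrow(ex))) {
        w0 <- gene_start + ex_off_genomic[e] - pad
        w1 <- w0 + ex_len[e] + 2L * pad
        if (w1 <= 0L || w0 >= slen) next
        w0 <- max(0L, w0); w1 <- min(slen, w1)
        if (w1 - w0 < k) next
        eseq <- substring(spliced, ex_off_spliced[e] + 1L,
                          ex_off_spliced[e] + ex_len[e])
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(eseq),
          Biostrings::DNAString(substr(seqs[[scaffold]], w0 + 1L, w1)),
          type = "global-local",
          substitutionMatrix = submat(-2),
          gapOpening = 6, gapExtension = 2)
        cols <- aln_cols(pa)
        frac_match <- Biostrings::nmatch(pa) / cols
        if (frac_match < 0.75) next   # exon absent at this locus
        tot_match <- tot_match + Biostrings::nmatch(pa)
        tot_cols <- tot_cols + cols
        tot_q <- tot_q + ex_len[e]
        s0 <- w0 + Biostrings::start(Biostrings::subject(pa)) - 1L
        s1 <- w0 + Biostrings::end(Biostrings::subject(pa))
        tgt0 <- min(tgt0, s0, na.rm = TRUE)
        tgt1 <- max(tgt1, s1, na.rm = TRUE)
      }
      if (tot_cols == 0) return(NULL)
      tibble(gene_id = tr$gene_id, transcript_id = tr$transcript_id,
             scaffold = scaffold, start = tgt0, end = tgt1,
             identity = tot_match / tot_cols,
             query_coverage = tot_q / nchar(spliced))
    }) |> bind_rows()
    if (nrow(pl)) {
      out[[ti]] <- pl |>
        arrange(dplyr::desc(.data$identity * .data$query_coverage)) |>
        mutate(rank = ti, .after = "transcript_id")
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty_gene_alignments() else res
}

empty_gene_alignments <- function() {
  tibble(gene_id = character(), transcript_id = character(), rank = integer(),
         scaffold = character(), start = integer(), end = integer(),
         identity = double(), query_coverage = double())
}

#' Call duplicated genes from transcript placements
#'
#' A placement passes with identity of at least `min_identity` (at most 10%
#' divergence by default) and query coverage of at least `min_coverage`
#' (90% of the spliced length by default). When passing placements of two
#' genes overlap the same target location by at least 1 bp, only the gene
#' with the lower rank (earlier in the input) keeps that placement. Genes
#' with two or more surviving placements are reported as duplications.
#'
#' @param alignments Placement tibble from [map_transcripts()] (or PAF-like
#'   input with the same columns).
#' @param min_identity Minimum placement identity (default 0.90).
#' @param min_coverage Minimum query coverage (default 0.90).
#' @param tandem_max_gap Passed to [classify_mode()].
#' @return Tibble `gene_id`, `copies`, `mode`, `status`, `placements`
#'   (list-column of placement tibbles).
#' @export
call_duplications <- function(alignments, min_identity = 0.90,
                              min_coverage = 0.90, tandem_max_gap = 5e5) {
  passing <- alignments |>
    filter(.data$identity >= min_identity,
           .data$query_coverage >= min_coverage) |>
    arrange(.data$rank)
  # same-location conflict: first-ranked gene wins
  if (nrow(passing) > 1L) {
    keep <- rep(TRUE, nrow(passing))
    for (i in 2:nrow(passing)) {
      prev <- which(keep[seq_len(i - 1L)])
      prev <- prev[passing$gene_id[prev] != passing$gene_id[i]]
      if (length(prev)) {
        clash <- passing$scaffold[prev] == passing$scaffold[i] &
          passing$start[prev] < passing$end[i] &
          passing$end[prev] > passing$start[i]
        if (any(clash)) keep[i] <- FALSE
      }
    }
    passing <- passing[keep, ]
  }
  empty <- tibble(gene_id = character(), copies = integer(),
                  mode = character(), status = character(),
                  placements = list())
  if (nrow(passing) == 0L) return(empty)
  res <- passing |>
    group_by(.data$gene_id) |>
    filter(dplyr::n() >= 2L) |>
    summarise(copies = dplyr::n(),
              placements = list(pick_cols(dplyr::pick(dplyr::everything()))),
              .groups = "drop")
  if (nrow(res) == 0L) return(empty)
  res |>
    rowwise() |>
    mutate(mode = classify_mode(.data$placements, tandem_max_gap),
           status = "resolved") |>
    ungroup() |>
    select("gene_id", "copies", "mode", "status", "placements")
}

pick_cols <- function(d) d[, c("scaffold", "start", "end", "identity", "query_coverage")]

#' Classify a duplication as tandem or interspersed
#'
#' Tandem means all placements lie on one scaffold with every gap between
#' consecutive placements at most `tandem_max_gap` (default 500 kb);
#' anything else is interspersed.
#'
#' @param placements Tibble `scaffold`, `start`, `end` (>= 2 rows).
#' @param tandem_max_gap Maximum consecutive gap in bp.
#' @return `"tandem"` or `"interspersed"`.
#' @export
classify_mode <- function(placements, tandem_max_gap = 5e5) {
  if (dplyr::n_distinct(placements$scaffold) > 1L) return("interspersed")
  p <- arrange(placements, .data$start)
  gaps <- p$start[-1] - p$end[-nrow(p)]
  if (length(gaps) == 0L || all(gaps <= tandem_max_gap)) "tandem" else "interspersed"
}

#' Flag genes lying in collapsed duplications
#'
#' A gene whose body overlaps decoded copy-number segments above copy 2
#' over at least half its length is flagged `collapsed`; the implied number
#' of missing copies is the decoded copy number minus the assembled copy
#' count.
#'
#' @param genes Tibble `gene_id`, `scaffold`, `start`, `end` and optionally
#'   `copies` (assembled copy count, default 1).
#' @param copy_segments Segment tibble from [viterbi_decode()].
#' @param min_overlap Minimum overlapped fraction of the gene body
#'   (default 0.5).
#' @return `genes` with `status` (`collapsed`/`resolved`) and
#'   `implied_extra_copies` columns.
#' @export
flag_collapsed_genes <- function(genes, copy_segments, min_overlap = 0.5) {
  if (!"copies" %in% names(genes)) genes$copies <- 1L
  coll <- filter(copy_segments, .data$copy_number > 2L)
  g_iv <- tibble(scaffold = genes$scaffold, start = genes$start,
                 end = genes$end)
  ovl <- covered_bases(g_iv, coll)
  frac <- ovl / (genes$end - genes$start)
  max_cn <- vapply(seq_len(nrow(genes)), function(i) {
    sel <- coll$scaffold == genes$scaffold[i] &
      coll$start < genes$end[i] & coll$end > genes$start[i]
    if (any(sel)) max(coll$copy_number[sel]) else NA_integer_
  }, numeric(1))
  genes |>
    mutate(status = ifelse(frac >= min_overlap, "collapsed", "resolved"),
           implied_extra_copies = ifelse(.data$status == "collapsed",
                                         pmax(0, max_cn - .data$copies), 0))
}

#' Genes duplicated in one assembly pair but single-copy in another
#'
#' Returns the genes with at least two copies in both assemblies of
#' `group_a` and exactly one copy in both assemblies of `group_b`. Genes
#' absent from any assembly's table are excluded (reported via a message).
#'
#' @param copies_by_assembly Named list of tibbles `gene_id`, `copies`,
#'   one per assembly; copy counts must include single-copy genes.
#' @param group_a,group_b Character vectors of two assembly names each.
#' @return Tibble `gene_id` plus one copy-count column per assembly.
#' @export
compare_copy_numbers <- function(copies_by_assembly, group_a, group_b) {
  stopifnot(length(group_a) == 2L, length(group_b) == 2L,
            all(c(group_a, group_b) %in% names(copies_by_assembly)))
  asms <- c(group_a, group_b)
  tbl <- purrr::reduce(purrr::imap(copies_by_assembly[asms], function(d, nm) {
    d <- d[, c("gene_id", "copies")]
    names(d)[2] <- paste0("copies_", nm)
    d
  }), function(x, y) full_join(x, y, by = "gene_id"))
  missing <- tbl |>
    filter(dplyr::if_any(dplyr::starts_with("copies_"), is.na))
  if (nrow(missing)) {
    rlang::inform(sprintf(
      "%d gene(s) absent from at least one assembly; excluded.", nrow(missing)))
  }
  tbl <- dplyr::anti_join(tbl, missing, by = "gene_id")
  ok_a <- Reduce(`&`, lapply(group_a, function(a) tbl[[paste0("copies_", a)]] >= 2L))
  ok_b <- Reduce(`&`, lapply(group_b, function(b) tbl[[paste0("copies_", b)]] == 1L))
  arrange(tbl[ok_a & ok_b, ], .data$gene_id)
}
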