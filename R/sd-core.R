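# Segmental-duplication post-processing: desk-scale self-alignment,
# repeat-mask filter, transitive-copy interval graph, high-copy removal,
# summaries and divergence-to-age conversion.
#
# A duplication-pair table is a tibble with columns chr_a, start_a, end_a,
# chr_b, start_b, end_b, identity, length (0-based half-open coordinates,
# canonical ordering interval_a < interval_b by (scaffold, start)).

#' Configuration for segmental-duplication filtering
#'
#' @param masked_threshold Pairs are removed when either copy is repeat
#'   masked over more than this fraction (default 0.90).
#' @param max_copies Pairs in interval-graph components with more unique
#'   intervals than this are removed (default 20).
#' @param min_length Minimum aligned length in bp for the stand-in aligner.
#' @param min_identity Minimum identity for the stand-in aligner.
#' @param divergence_per_100ky Sequence divergence accumulating between two
#'   duplicate copies per 100,000 years (default 0.005, i.e. 0.5%).
#' @param generations_per_year Generations per year (default 3; recorded for
#'   reporting, not used in the age formula).
#' @return A list of class `sd_config`.
#' @export
sd_config <- function(masked_threshold = 0.90, max_copies = 20,
                      min_length = 1000, min_identity = 0.9,
                      divergence_per_100ky = 0.005,
                      generations_per_year = 3) {
  stopifnot(masked_threshold >= 0, masked_threshold <= 1, max_copies >= 1,
            min_length > 0, min_identity >= 0, min_identity <= 1,
            divergence_per_100ky > 0, generations_per_year > 0)
  structure(list(masked_threshold = masked_threshold, max_copies = max_copies,
                 min_length = min_length, min_identity = min_identity,
                 divergence_per_100ky = divergence_per_100ky,
                 generations_per_year = generations_per_year),
            class = "sd_config")
}

empty_pairs <- function() {
  tibble(chr_a = character(), start_a = integer(), end_a = integer(),
         chr_b = character(), start_b = integer(), end_b = integer(),
         identity = double(), length = integer())
}

canonical_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  flip <- pairs$chr_b < pairs$chr_a |
    (pairs$chr_b == pairs$chr_a & pairs$start_b < pairs$start_a)
  flipped <- pairs
  flipped[flip, c("chr_a", "start_a", "end_a", "chr_b", "start_b", "end_b")] <-
    pairs[flip, c("chr_b", "start_b", "end_b", "chr_a", "start_a", "end_a")]
  arrange(flipped, .data$chr_a, .data$start_a, .data$chr_b, .data$start_b)
}

#' Desk-scale self-alignment for duplication discovery
#'
#' Finds non-self local duplication pairs within a small genome by exact
#' k-mer anchoring (k-mers occurring more than once), diagonal clustering,
#' and local-alignment refinement of candidate interval pairs. This is a
#' stand-in for a production self-aligner: it refuses genomes above 10 Mb,
#' where external alignment output should be read with [read_sd_pairs()]
#' instead.
#'
#' @param genome A `syn_genome` or named character vector of sequences.
#' @param min_length Minimum aligned length in bp (default 1000).
#' @param min_identity Minimum identity in aligned columns (default 0.9).
#' @param k Anchor k-mer size (default 25).
#' @param max_occ K-mers occurring more often than this are skipped
#'   (protects against mobile-element blowup).
#' @return A duplication-pair tibble (see module header) in canonical order.
#' @export
naive_self_align <- function(genome, min_length = 1000, min_identity = 0.9,
                             k = 25, max_occ = 40) {
  seqs <- if (inherits(genome, "syn_genome")) genome$sequences else genome
  total <- sum(nchar(seqs))
  if (total > 1e7) {
    rlang::abort("genome exceeds 10 Mb; run an external self-aligner and load its output with read_sd_pairs().")
  }
  # global k-mer table across scaffolds
  km <- purrr::map(names(seqs), function(sc) {
    ks <- kmers(seqs[[sc]], k)
    tibble(scaffold = sc, pos = seq_along(ks) - 1L, kmer = ks)
  }) |> bind_rows()
  dup <- duplicated(km$kmer) | duplicated(km$kmer, fromLast = TRUE)
  km <- km[dup, ]
  if (nrow(km) == 0L) return(empty_pairs())
  grp <- split(seq_len(nrow(km)), km$kmer)
  grp <- grp[lengths(grp) >= 2L & lengths(grp) <= max_occ]
  if (length(grp) == 0L) return(empty_pairs())
  # anchor pairs (i < j in global order)
  cmb <- do.call(cbind, lapply(grp, function(ix) utils::combn(sort(ix), 2L)))
  anchors <- tibble(i = cmb[1, ], j = cmb[2, ])
  anchors <- anchors |>
    mutate(chr_a = km$scaffold[.data$i], pos_a = km$pos[.data$i],
           chr_b = km$scaffold[.data$j], pos_b = km$pos[.data$j],
           diag = .data$pos_b - .data$pos_a) |>
    filter(!(.data$chr_a == .data$chr_b & .data$diag == 0L))
  if (nrow(anchors) == 0L) return(empty_pairs())
  # cluster by (chr pair, diagonal band), then split on large A-position gaps
  band <- 100L
  max_gap <- 500L
  anchors <- anchors |>
    mutate(band_id = paste(.data$chr_a, .data$chr_b,
                           .data$diag %/% band, sep = "|")) |>
    arrange(.data$band_id, .data$pos_a)
  cands <- anchors |>
    group_by(.data$band_id) |>
    mutate(cluster = cumsum(c(1L, diff(.data$pos_a) > max_gap))) |>
    group_by(.data$band_id, .data$cluster) |>
    summarise(chr_a = .data$chr_a[1], chr_b = .data$chr_b[1],
              a0 = min(.data$pos_a), a1 = max(.data$pos_a) + k,
              b0 = min(.data$pos_b), b1 = max(.data$pos_b) + k,
              n_anchors = dplyr::n(), .groups = "drop") |>
    filter(.data$a1 - .data$a0 >= 0.5 * min_length, .data$n_anchors >= 3L)
  if (nrow(cands) == 0L) return(empty_pairs())
  # refine each candidate by chaining its anchors: exact-overlap extension
  # plus pairwise alignment of the inter-anchor gaps only (linear in the
  # number of divergent sites, never quadratic in the candidate length)
  anchors <- anchors |>
    group_by(.data$band_id) |>
    mutate(cluster = cumsum(c(1L, diff(.data$pos_a) > max_gap))) |>
    ungroup() |>
    mutate(cand_id = paste(.data$band_id, .data$cluster, sep = "#"))
  cands <- mutate(cands, cand_id = paste(.data$band_id, .data$cluster, sep = "#"))
  out <- purrr::map(seq_len(nrow(cands)), function(ci) {
    cd <- cands[ci, ]
    an <- anchors[anchors$cand_id == cd$cand_id, ]
    an <- arrange(an, .data$pos_a)
    # keep a clean monotone chain
    keep <- rep(TRUE, nrow(an))
    last <- 1L
    if (nrow(an) > 1L) for (t in 2:nrow(an)) {
      d_i <- an$pos_a[t] - an$pos_a[last]; d_j <- an$pos_b[t] - an$pos_b[last]
      if (d_j > 0L && (d_i == d_j || (d_i >= k && d_j >= k))) last <- t
      else keep[t] <- FALSE
    }
    an <- an[keep, ]
    if (nrow(an) < 2L) return(NULL)
    ops <- chain_ops(an$pos_a, an$pos_b, seqs[[cd$chr_a]], seqs[[cd$chr_b]], k)
    po <- ops_parse(ops)
    cols <- sum(po$len)
    if (cols == 0L) return(NULL)
    tibble(
      chr_a = cd$chr_a,
      start_a = an$pos_a[1], end_a = an$pos_a[nrow(an)] + k,
      chr_b = cd$chr_b,
      start_b = an$pos_b[1], end_b = an$pos_b[nrow(an)] + k,
      identity = sum(po$len[po$op == "="]) / cols,
      length = as.integer(cols)
    )
  }) |> bind_rows()
  if (nrow(out) == 0L) return(empty_pairs())
  out <- filter(out, .data$identity >= min_identity,
                .data$length >= min_length,
                !(.data$chr_a == .data$chr_b & .data$start_a == .data$start_b))
  out <- canonical_pairs(out)
  dedupe_pairs(out)
}

# Merge near-duplicate reports of the same pair (both intervals overlap by
# >= 50% reciprocally): keep the longest.
dedupe_pairs <- function(pairs) {
  if (nrow(pairs) <= 1L) return(pairs)
  pairs <- arrange(pairs, dplyr::desc(.data$length))
  keep <- rep(TRUE, nrow(pairs))
  recip <- function(s1, e1, s2, e2) {
    ov <- pmin(e1, e2) - pmax(s1, s2)
    ov >= 0.5 * (e1 - s1) & ov >= 0.5 * (e2 - s2)
  }
  for (i in seq_len(nrow(pairs) - 1L)) {
    if (!keep[i]) next
    j <- (i + 1L):nrow(pairs)
    dup <- keep[j] &
      pairs$chr_a[j] == pairs$chr_a[i] & pairs$chr_b[j] == pairs$chr_b[i] &
      recip(pairs$start_a[j], pairs$end_a[j], pairs$start_a[i], pairs$end_a[i]) &
      recip(pairs$start_b[j], pairs$end_b[j], pairs$start_b[i], pairs$end_b[i])
    keep[j][dup] <- FALSE
  }
  canonical_pairs(pairs[keep, ])
}

#' Compute repeat-masked fractions for duplication pairs
#'
#' @param pairs Duplication-pair tibble.
#' @param repeat_track Tibble `scaffold`, `start`, `end` of masked intervals
#'   (union over repeat families; 0-based half-open).
#' @return `pairs` with columns `masked_frac_a`, `masked_frac_b` added.
#' @export
masked_fractions <- function(pairs, repeat_track) {
  if (nrow(pairs) == 0L) {
    return(mutate(pairs, masked_frac_a = double(0), masked_frac_b = double(0)))
  }
  a <- tibble(scaffold = pairs$chr_a, start = pairs$start_a, end = pairs$end_a)
  b <- tibble(scaffold = pairs$chr_b, start = pairs$start_b, end = pairs$end_b)
  mutate(pairs,
         masked_frac_a = covered_bases(a, repeat_track) / (a$end - a$start),
         masked_frac_b = covered_bases(b, repeat_track) / (b$end - b$start))
}

#' Remove duplication pairs dominated by repeat masking
#'
#' A pair is removed when either copy is repeat masked over more than the
#' configured threshold (default 90%). Input order is preserved.
#'
#' @param pairs Duplication-pair tibble.
#' @param repeat_track Masked-interval tibble (`scaffold`, `start`, `end`).
#' @param cfg An [sd_config()].
#' @return Filtered pairs with `masked_frac_a`/`masked_frac_b` columns.
#' @export
filter_repeat_masked <- function(pairs, repeat_track, cfg = sd_config()) {
  pairs <- masked_fractions(pairs, repeat_track)
  filter(pairs, .data$masked_frac_a <= cfg$masked_threshold,
         .data$masked_frac_b <= cfg$masked_threshold)
}

interval_key <- function(chr, start, end) paste(chr, start, end, sep = ":")

#' Build the transitive-copy interval graph of a duplication set
#'
#' Every distinct interval occurring in the pair table becomes a node
#' (intervals identical by exact coordinates are merged). Edges connect the
#' two intervals of each alignment pair, and any two intervals sharing at
#' least 1 bp on the same scaffold. The number of unique intervals in each
#' connected component is the component's repeat copy number, so copies
#' missed by the aligner are still counted through transitivity.
#'
#' @param pairs Duplication-pair tibble.
#' @return A `dup_graph`: list with `nodes` (tibble `scaffold`, `start`,
#'   `end`, `node_id`, `component_id`, `copy_number`) and `edges` (tibble
#'   `from`, `to`, `kind` with kind in `alignment`/`overlap`).
#' @export
build_duplication_graph <- function(pairs) {
  ivs <- bind_rows(
    tibble(scaffold = pairs$chr_a, start = pairs$start_a, end = pairs$end_a),
    tibble(scaffold = pairs$chr_b, start = pairs$start_b, end = pairs$end_b)
  ) |> distinct() |> arrange(.data$scaffold, .data$start, .data$end)
  nodes <- mutate(ivs, node_id = dplyr::row_number())
  key <- interval_key(nodes$scaffold, nodes$start, nodes$end)
  lookup <- setNames(nodes$node_id, key)
  edges_aln <- if (nrow(pairs)) tibble(
    from = unname(lookup[interval_key(pairs$chr_a, pairs$start_a, pairs$end_a)]),
    to = unname(lookup[interval_key(pairs$chr_b, pairs$start_b, pairs$end_b)]),
    kind = "alignment"
  ) else tibble(from = integer(), to = integer(), kind = character())
  # overlap edges: any two node intervals sharing >= 1 bp on a scaffold
  edges_ov <- purrr::map(unique(nodes$scaffold), function(sc) {
    sub <- filter(nodes, .data$scaffold == sc)
    if (nrow(sub) < 2L) return(NULL)
    r <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    hits <- IRanges::findOverlaps(r, r, minoverlap = 1L)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    sel <- qi < si
    if (!any(sel)) return(NULL)
    tibble(from = sub$node_id[qi[sel]], to = sub$node_id[si[sel]],
           kind = "overlap")
  }) |> bind_rows()
  edges <- bind_rows(edges_aln, edges_ov)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    vertices = data.frame(name = nodes$node_id), directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(nodes$node_id)]
  nodes$component_id <- as.integer(membership)
  nodes <- nodes |>
    group_by(.data$component_id) |>
    mutate(copy_number = dplyr::n()) |>
    ungroup()
  structure(list(nodes = nodes, edges = edges), class = "dup_graph")
}

#' @export
print.dup_graph <- function(x, ...) {
  cat("<dup_graph> ", nrow(x$nodes), " interval node(s), ",
      nrow(x$edges), " edge(s), ",
      dplyr::n_distinct(x$nodes$component_id), " component(s)\n", sep = "")
  invisible(x)
}

#' Remove pairs belonging to high-copy components
#'
#' Drops every pair whose intervals lie in a connected component with more
#' unique intervals than `cfg$max_copies` (default 20) -- the signature of
#' unmasked high-copy mobile elements rather than segmental duplication.
#'
#' @param pairs Duplication-pair tibble.
#' @param graph A `dup_graph` built from exactly these pairs (built on the
#'   fly when omitted).
#' @param cfg An [sd_config()].
#' @return Filtered pairs, order preserved.
#' @export
filter_high_copy <- function(pairs, graph = NULL, cfg = sd_config()) {
  if (nrow(pairs) == 0L) return(pairs)
  graph <- graph %||% build_duplication_graph(pairs)
  cn <- setNames(graph$nodes$copy_number,
                 interval_key(graph$nodes$scaffold, graph$nodes$start,
                              graph$nodes$end))
  key_a <- interval_key(pairs$chr_a, pairs$start_a, pairs$end_a)
  key_b <- interval_key(pairs$chr_b, pairs$start_b, pairs$end_b)
  if (any(!(key_a %in% names(cn))) || any(!(key_b %in% names(cn)))) {
    rlang::abort("internal consistency error: a pair interval is missing from the graph.")
  }
  pairs[pmax(cn[key_a], cn[key_b]) <= cfg$max_copies, ]
}

#' Summarise a segmental-duplication set
#'
#' @param pairs Duplication-pair tibble.
#' @param identity_breaks Histogram break points for identity (default 2%
#'   bins from 80% to 100%).
#' @return An `sd_summary`: list with `n_pairs`, `duplicated_bases`
#'   (non-redundant union of all member intervals) and `identity_histogram`
#'   (tibble `bin_low`, `bin_high`, `n_pairs`, `bases`).
#' @export
summarize_sd <- function(pairs, identity_breaks = seq(0.8, 1, by = 0.02)) {
  ivs <- bind_rows(
    tibble(scaffold = pairs$chr_a, start = pairs$start_a, end = pairs$end_a),
    tibble(scaffold = pairs$chr_b, start = pairs$start_b, end = pairs$end_b)
  )
  merged <- 0
  if (nrow(ivs)) {
    merged <- sum(vapply(split(ivs, ivs$scaffold), function(s) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = s$start + 1L, end = s$end))))
    }, numeric(1)))
  }
  bins <- if (nrow(pairs)) {
    idx <- pmin(pmax(findInterval(pairs$identity, identity_breaks,
                                  rightmost.closed = TRUE), 1L),
                length(identity_breaks) - 1L)
    tibble(bin_low = identity_breaks[-length(identity_breaks)],
           bin_high = identity_breaks[-1]) |>
      mutate(n_pairs = tabulate(idx, length(identity_breaks) - 1L),
             bases = as.numeric(tapply(pairs$length, factor(idx, levels = seq_len(length(identity_breaks) - 1L)), sum, default = 0)))
  } else {
    tibble(bin_low = identity_breaks[-length(identity_breaks)],
           bin_high = identity_breaks[-1], n_pairs = 0L, bases = 0)
  }
  structure(list(n_pairs = nrow(pairs), duplicated_bases = merged,
                 identity_histogram = bins),
            class = "sd_summary")
}

#' @export
print.sd_summary <- function(x, ...) {
  cat("<sd_summary> ", x$n_pairs, " pair(s), ",
      format(x$duplicated_bases, big.mark = ","),
      " non-redundant duplicated bases\n", sep = "")
  invisible(x)
}

#' Convert duplication identity to an approximate age
#'
#' Uses a linear molecular clock: `age = (1 - identity) /
#' divergence_per_100ky * 100,000` years. The calibration constant is
#' configuration (default 0.5% divergence per 100,000 years), not a
#' hard-coded value.
#'
#' @param identity Identity fraction(s) in `[0, 1]`.
#' @param cfg An [sd_config()].
#' @return Age(s) in years.
#' @export
divergence_to_age <- function(identity, cfg = sd_config()) {
  if (any(is.na(identity)) || any(identity < 0) || any(identity > 1)) {
    rlang::abort("`identity` must lie in [0, 1].")
  }
  (1 - identity) / cfg$divergence_per_100ky * 1e5
}
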