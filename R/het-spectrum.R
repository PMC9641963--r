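# Heterozygosity spectrum between two haplotype assemblies: desk-scale
# whole-genome alignment into blocks, variant classification (SNV, small
# and large indels, inversions, translocations, copy-number variants), gap
# filtering, size spectrum with peak detection and heterozygosity rates.
#
# Alignment blocks are tibbles with columns chr_a, start_a, end_a, chr_b,
# start_b, end_b, orient (forward/reverse), kind (primary/dup), ops.
# Ops strings are CIGAR-like runs over codes '=' match, 'X' mismatch,
# 'D' bases of A absent from B, 'I' bases of B absent from A, and 'C'
# B-only bases re-assigned to a duplicate block (copy gain).

#' Align two haplotypes into blocks (desk scale)
#'
#' Stand-in for a production whole-genome aligner on small genomes: exact
#' unique k-mers anchor the two haplotypes (forward and reverse-complement),
#' anchors are chained into colinear blocks that split on orientation
#' changes or diagonal jumps, inter-anchor gaps are resolved by pairwise
#' alignment, and unanchored insertions matching their flanking sequence
#' are re-assigned to duplicate blocks so copy-number gains are represented
#' as double block coverage.
#'
#' @param hap_a,hap_b `syn_genome` objects or named character vectors;
#'   scaffolds are paired by name.
#' @param k Anchor k-mer length (default 31).
#' @param max_join Maximum diagonal jump in bp bridged inside one block
#'   (default 6000); larger jumps split blocks.
#' @param cnv_min Minimum unanchored insertion size checked for duplicate
#'   rescue (default 100 bp).
#' @return A block tibble (see module header).
#' @export
align_haplotypes <- function(hap_a, hap_b, k = 31, max_join = 6000,
                             cnv_min = 100) {
  a_seqs <- if (inherits(hap_a, "syn_genome")) hap_a$sequences else hap_a
  b_seqs <- if (inherits(hap_b, "syn_genome")) hap_b$sequences else hap_b
  shared <- intersect(names(a_seqs), names(b_seqs))
  if (length(shared) == 0L) rlang::abort("no shared scaffold names between haplotypes.")
  purrr::map(shared, function(sc) {
    align_scaffold_pair(sc, a_seqs[[sc]], b_seqs[[sc]], k, max_join, cnv_min)
  }) |> bind_rows()
}

align_scaffold_pair <- function(sc, a, b, k, max_join, cnv_min) {
  na_ <- nchar(a); nb_ <- nchar(b)
  if (na_ < k || nb_ < k) return(NULL)
  ka <- kmers(a, k); kb <- kmers(b, k)
  rb <- revcomp(b); krb <- kmers(rb, k)
  ua <- which(!(duplicated(ka) | duplicated(ka, fromLast = TRUE)))
  ub <- which(!(duplicated(kb) | duplicated(kb, fromLast = TRUE)))
  urb <- which(!(duplicated(krb) | duplicated(krb, fromLast = TRUE)))
  mf <- match(ka[ua], kb[ub])
  mr <- match(ka[ua], krb[urb])
  fwd <- tibble(i = ua[!is.na(mf)] - 1L, j = ub[mf[!is.na(mf)]] - 1L,
                orient = "forward")
  rev_ <- tibble(i = ua[!is.na(mr)] - 1L, j = urb[mr[!is.na(mr)]] - 1L,
                 orient = "reverse")
  rev_ <- rev_[!(rev_$i %in% fwd$i), ]
  anchors <- bind_rows(fwd, rev_) |> arrange(.data$i)
  if (nrow(anchors) < 3L) return(NULL)
  # chain: break on orientation change, non-monotone partner, or large
  # diagonal jump
  n <- nrow(anchors)
  dj <- diff(anchors$j); di <- diff(anchors$i)
  same_or <- anchors$orient[-1] == anchors$orient[-n]
  brk <- !same_or | (dj <= 0L) | (abs(dj - di) > max_join)
  chain <- cumsum(c(1L, as.integer(brk)))
  anchors$chain <- chain
  # drop noise chains
  keep_chains <- anchors |>
    count(.data$chain) |>
    filter(.data$n >= 3L) |>
    pull(.data$chain)
  blocks <- purrr::map(keep_chains, function(ch) {
    an <- anchors[anchors$chain == ch, ]
    # drop anchors overlapping the previous kept one with unequal offsets
    keep <- rep(TRUE, nrow(an))
    last <- 1L
    if (nrow(an) > 1L) for (t in 2:nrow(an)) {
      d_i <- an$i[t] - an$i[last]; d_j <- an$j[t] - an$j[last]
      if (d_i == d_j || (d_i >= k && d_j >= k)) last <- t else keep[t] <- FALSE
    }
    an <- an[keep, ]
    if (nrow(an) < 2L) return(NULL)
    orient <- an$orient[1]
    bs <- if (orient == "forward") b else rb
    ops <- chain_ops(an$i, an$j, a, bs, k)
    i0 <- an$i[1]; i1 <- an$i[nrow(an)] + k
    j0 <- an$j[1]; j1 <- an$j[nrow(an)] + k
    if (orient == "forward") {
      tibble(chr_a = sc, start_a = i0, end_a = i1, chr_b = sc,
             start_b = j0, end_b = j1, orient = orient, kind = "primary",
             ops = ops)
    } else {
      tibble(chr_a = sc, start_a = i0, end_a = i1, chr_b = sc,
             start_b = nb_ - j1, end_b = nb_ - j0, orient = orient,
             kind = "primary", ops = ops)
    }
  }) |> bind_rows()
  if (is.null(blocks) || nrow(blocks) == 0L) return(NULL)
  rescue_duplicates(blocks, a, b, cnv_min)
}

# Build the ops string for one chain of clean anchors. Consecutive anchors
# with equal offsets and overlap (d <= k) extend a match run; other gaps
# are resolved by pairwise alignment of the inter-anchor segments.
chain_ops <- function(ai, aj, a, b, k) {
  n <- length(ai)
  parts <- character(0)
  run_eq <- k   # the first anchor's k matched bases
  if (n > 1L) for (t in 2:n) {
    d_i <- ai[t] - ai[t - 1L]; d_j <- aj[t] - aj[t - 1L]
    if (d_i == d_j && d_i <= k) {
      run_eq <- run_eq + d_i
    } else {
      ga <- substr(a, ai[t - 1L] + k + 1L, ai[t])
      gb <- substr(b, aj[t - 1L] + k + 1L, aj[t])
      if (nchar(ga) * nchar(gb) > 25e6) {
        # refuse quadratic blowup: emit blunt mismatch+indel runs
        m <- min(nchar(ga), nchar(gb))
        seg <- paste0(if (m > 0) paste0(m, "X") else "",
                      if (nchar(ga) > m) paste0(nchar(ga) - m, "D") else "",
                      if (nchar(gb) > m) paste0(nchar(gb) - m, "I") else "")
      } else {
        seg <- align_ops(ga, gb)
      }
      parts <- c(parts, paste0(run_eq, "="), seg)
      run_eq <- k
    }
  }
  parts <- c(parts, paste0(run_eq, "="))
  # merge adjacent equal-code runs
  po <- ops_parse(paste0(parts, collapse = ""))
  grp <- cumsum(c(1L, as.integer(po$op[-1] != po$op[-nrow(po)])))
  merged <- tibble(len = as.integer(tapply(po$len, grp, sum)),
                   op = po$op[!duplicated(grp)])
  paste0(merged$len, merged$op, collapse = "")
}

# Re-assign large unanchored insertions that match their flanking sequence
# to duplicate blocks: the matching flank region of A becomes covered by a
# second block, the signature of a copy-number gain.
rescue_duplicates <- function(blocks, a, b, cnv_min) {
  extra <- list()
  for (bi in seq_len(nrow(blocks))) {
    blk <- blocks[bi, ]
    if (blk$orient != "forward") next
    po <- ops_parse(blk$ops)
    if (nrow(po) == 0L) next
    a_adv <- ifelse(po$op %in% c("=", "X", "D"), po$len, 0L)
    b_adv <- ifelse(po$op %in% c("=", "X", "I", "C"), po$len, 0L)
    a_pos <- blk$start_a + cumsum(c(0L, a_adv))[seq_len(nrow(po))]
    b_pos <- blk$start_b + cumsum(c(0L, b_adv))[seq_len(nrow(po))]
    ins <- which(po$op == "I" & po$len >= cnv_min)
    changed <- FALSE
    for (t in ins) {
      L <- po$len[t]
      ins_seq <- substr(b, b_pos[t] + 1L, b_pos[t] + L)
      left0 <- max(0L, a_pos[t] - L)
      ctx <- list(
        left = c(left0, a_pos[t]),
        right = c(a_pos[t], min(nchar(a), a_pos[t] + L))
      )
      best <- NULL
      for (side in names(ctx)) {
        rng <- ctx[[side]]
        if (rng[2] - rng[1] < 0.8 * L) next
        ctx_seq <- substr(a, rng[1] + 1L, rng[2])
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(ins_seq), Biostrings::DNAString(ctx_seq),
          type = "local",
          substitutionMatrix = submat(-1),
          gapOpening = 6, gapExtension = 2)
        if (aln_cols(pa) >= 0.8 * L &&
            Biostrings::nmatch(pa) / aln_cols(pa) >= 0.9) {
          s0 <- rng[1] + Biostrings::start(Biostrings::subject(pa)) - 1L
          s1 <- rng[1] + Biostrings::end(Biostrings::subject(pa))
          best <- c(s0, s1)
          break
        }
      }
      if (!is.null(best)) {
        po$op[t] <- "C"
        changed <- TRUE
        extra <- c(extra, list(tibble(
          chr_a = blk$chr_a, start_a = best[1], end_a = best[2],
          chr_b = blk$chr_b, start_b = b_pos[t], end_b = b_pos[t] + L,
          orient = "forward", kind = "dup",
          ops = paste0(L, "=")
        )))
      }
    }
    if (changed) {
      blocks$ops[bi] <- paste0(po$len, po$op, collapse = "")
    }
  }
  bind_rows(blocks, bind_rows(extra))
}

#' Classify differences between two haplotypes from alignment blocks
#'
#' SNVs come from mismatch columns and indels from maximal gap runs inside
#' syntenic forward blocks (insertions overlapping a translocated block's
#' target are suppressed as alignment artifacts); reverse-orientation
#' blocks at their expected position are inversions; blocks of at least
#' `min_trans_size` mapping far from their expected position are
#' translocations (inverted translocations when also reversed); regions of
#' haplotype A covered by a different number of blocks than their
#' counterpart are copy-number variants.
#'
#' @param blocks Block tibble from [align_haplotypes()] or
#'   [read_blocks()].
#' @param min_trans_size Minimum block size in bp called as a translocation
#'   (default 1000).
#' @param syn_tol Maximum deviation in bp from the scaffold's dominant
#'   diagonal still considered syntenic (default 20 kb).
#' @return Variant tibble: `class` (`SNV`, `small_indel`, `large_indel`,
#'   `inversion`, `translocation`, `inverted_translocation`, `CNV`),
#'   `size`, `scaffold`, `pos` (haplotype A), `pos_b` (haplotype B; NA for
#'   block-level classes) and `indel_type` (`insertion`/`deletion`/NA).
#' @export
classify_variants <- function(blocks, min_trans_size = 1000, syn_tol = 20000) {
  if (nrow(blocks) == 0L) return(empty_variants())
  fwd <- filter(blocks, .data$orient == "forward", .data$kind == "primary")
  # dominant diagonal per scaffold pair (longest forward block)
  ref_diag <- fwd |>
    mutate(len = .data$end_a - .data$start_a,
           diag = .data$start_b - .data$start_a) |>
    group_by(.data$chr_a, .data$chr_b) |>
    slice_max(.data$len, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    select("chr_a", "chr_b", ref_diag = "diag")
  blk <- blocks |>
    left_join(ref_diag, by = c("chr_a", "chr_b")) |>
    mutate(diag = .data$start_b - .data$start_a,
           syntenic = !is.na(.data$ref_diag) &
             abs(.data$diag - .data$ref_diag) <= syn_tol)
  syn_fwd <- filter(blk, .data$orient == "forward", .data$kind == "primary",
                    .data$syntenic)
  # input consistency: one-to-one forward blocks must not overlap on A
  if (nrow(syn_fwd) > 1L) {
    for (sc in unique(syn_fwd$chr_a)) {
      s <- arrange(filter(syn_fwd, .data$chr_a == sc), .data$start_a)
      if (nrow(s) > 1L &&
          any(s$start_a[-1] < s$end_a[-nrow(s)] - 50L)) {
        rlang::abort(sprintf("overlapping one-to-one blocks on scaffold %s.", sc))
      }
    }
  }
  trans_blocks <- filter(blk, .data$kind == "primary", !.data$syntenic,
                         .data$end_a - .data$start_a >= min_trans_size)
  # per-column events inside syntenic forward blocks
  small <- purrr::map(seq_len(nrow(syn_fwd)), function(i) {
    b <- syn_fwd[i, ]
    po <- ops_parse(b$ops)
    if (nrow(po) == 0L) return(NULL)
    a_adv <- ifelse(po$op %in% c("=", "X", "D"), po$len, 0L)
    b_adv <- ifelse(po$op %in% c("=", "X", "I", "C"), po$len, 0L)
    a_pos <- b$start_a + cumsum(c(0L, a_adv))[seq_len(nrow(po))]
    b_pos <- b$start_b + cumsum(c(0L, b_adv))[seq_len(nrow(po))]
    snv_rows <- which(po$op == "X")
    snvs <- if (length(snv_rows)) {
      off <- unlist(lapply(po$len[snv_rows], seq_len)) - 1L
      tibble(class = "SNV", size = 1L,
             scaffold = b$chr_a,
             pos = rep(a_pos[snv_rows], po$len[snv_rows]) + off,
             pos_b = rep(b_pos[snv_rows], po$len[snv_rows]) + off,
             indel_type = NA_character_)
    } else NULL
    ind_rows <- which(po$op %in% c("I", "D"))
    inds <- if (length(ind_rows)) {
      tibble(class = ifelse(po$len[ind_rows] <= 50L, "small_indel", "large_indel"),
             size = po$len[ind_rows],
             scaffold = b$chr_a,
             pos = a_pos[ind_rows], pos_b = b_pos[ind_rows],
             indel_type = ifelse(po$op[ind_rows] == "I", "insertion", "deletion"))
    } else NULL
    bind_rows(snvs, inds)
  }) |> bind_rows()
  # suppress insertions that are really the paste site of a translocation
  if (nrow(small) && nrow(trans_blocks)) {
    ins <- small$indel_type %in% "insertion"
    iv <- tibble(scaffold = small$scaffold[ins], start = small$pos_b[ins],
                 end = small$pos_b[ins] + small$size[ins])
    tv <- tibble(scaffold = trans_blocks$chr_b, start = trans_blocks$start_b,
                 end = trans_blocks$end_b)
    drop <- covered_bases(iv, tv) / (iv$end - iv$start) >= 0.5
    small <- small[!(seq_len(nrow(small)) %in% which(ins)[drop]), ]
  }
  inv <- blk |>
    filter(.data$orient == "reverse", .data$kind == "primary", .data$syntenic) |>
    transmute(class = "inversion", size = .data$end_a - .data$start_a,
              scaffold = .data$chr_a, pos = .data$start_a,
              pos_b = .data$start_b, indel_type = NA_character_)
  trans <- trans_blocks |>
    transmute(class = as.character(ifelse(.data$orient == "reverse",
                                          "inverted_translocation",
                                          "translocation")),
              size = .data$end_a - .data$start_a,
              scaffold = .data$chr_a, pos = .data$start_a,
              pos_b = .data$start_b, indel_type = NA_character_)
  # CNV: regions of A covered by more than one forward block
  cnv <- purrr::map(unique(blocks$chr_a), function(sc) {
    s <- filter(blocks, .data$chr_a == sc, .data$orient == "forward")
    if (nrow(s) < 2L) return(NULL)
    r <- IRanges::IRanges(start = s$start_a + 1L, end = s$end_a)
    cov <- IRanges::coverage(r)
    hi <- IRanges::slice(cov, lower = 2L, rangesOnly = TRUE)
    hi <- hi[IRanges::width(hi) >= 50L]   # block-end abutment is not a CNV
    if (length(hi) == 0L) return(NULL)
    tibble(class = "CNV", size = IRanges::width(hi),
           scaffold = sc, pos = IRanges::start(hi) - 1L,
           pos_b = NA_integer_, indel_type = NA_character_)
  }) |> bind_rows()
  out <- bind_rows(small, inv, trans, cnv)
  if (nrow(out) == 0L) return(empty_variants())
  out$gap_fraction <- 0
  arrange(out, .data$scaffold, .data$pos)
}

empty_variants <- function() {
  tibble(class = character(), size = integer(), scaffold = character(),
         pos = integer(), pos_b = integer(), indel_type = character(),
         gap_fraction = double())
}

#' Drop variants dominated by assembly gaps
#'
#' Recomputes each variant's gap fraction against a track of N runs and
#' removes variants in which more than half the feature consists of gaps
#' (strictly greater than 0.5; a variant at exactly 50% is retained). SNVs
#' are never removed. With no track, all variants are retained with a
#' warning.
#'
#' @param variants Variant tibble from [classify_variants()].
#' @param n_track Tibble `scaffold`, `start`, `end` of N runs on haplotype
#'   A, or a list with elements `a` and `b` for both haplotypes (`b` used
#'   for insertions), or `NULL`.
#' @return The filtered variant tibble with `gap_fraction` updated.
#' @export
gap_filter <- function(variants, n_track = NULL) {
  if (is.null(n_track)) {
    rlang::warn("no N track supplied; all variants retained.")
    return(variants)
  }
  track_a <- if (is.list(n_track) && !is.data.frame(n_track)) n_track$a else n_track
  track_b <- if (is.list(n_track) && !is.data.frame(n_track)) n_track$b else NULL
  gf <- variants$gap_fraction
  on_a <- is.na(variants$indel_type) | variants$indel_type == "deletion"
  if (any(on_a) && !is.null(track_a)) {
    iv <- tibble(scaffold = variants$scaffold[on_a],
                 start = variants$pos[on_a],
                 end = variants$pos[on_a] + variants$size[on_a])
    gf[on_a] <- covered_bases(iv, track_a) / pmax(1L, iv$end - iv$start)
  }
  ins <- !on_a
  tb <- track_b %||% track_a
  if (any(ins) && !is.null(tb) && !anyNA(variants$pos_b[ins])) {
    iv <- tibble(scaffold = variants$scaffold[ins],
                 start = variants$pos_b[ins],
                 end = variants$pos_b[ins] + variants$size[ins])
    gf[ins] <- covered_bases(iv, tb) / pmax(1L, iv$end - iv$start)
  }
  variants$gap_fraction <- gf
  variants[variants$class == "SNV" | variants$gap_fraction <= 0.5, ]
}

#' Size spectrum and peak detection of classified variants
#'
#' Bins variant sizes per class and reports peaks: bins that are local
#' maxima exceeding `peak_factor` times the median occupied bin count of
#' their class.
#'
#' @param variants Variant tibble.
#' @param bin_width Histogram bin width in bp (default 100).
#' @param classes Classes to include (default: everything except SNV).
#' @param peak_factor Multiple of the median occupied bin count a local
#'   maximum must exceed (default 3).
#' @return A `spectrum_summary`: list with `counts` (tibble `class`, `n`),
#'   `histogram` (tibble `class`, `bin_low`, `bin_high`, `n`) and `peaks`
#'   (tibble `class`, `size` = lower bin edge, `n`).
#' @export
size_spectrum <- function(variants, bin_width = 100, classes = NULL,
                          peak_factor = 3) {
  classes <- classes %||% setdiff(unique(variants$class), "SNV")
  v <- filter(variants, .data$class %in% classes)
  counts <- count(variants, .data$class, name = "n")
  hist <- v |>
    mutate(bin_low = (.data$size %/% bin_width) * bin_width) |>
    count(.data$class, .data$bin_low, name = "n") |>
    mutate(bin_high = .data$bin_low + bin_width) |>
    select("class", "bin_low", "bin_high", "n")
  peaks <- hist |>
    group_by(.data$class) |>
    arrange(.data$bin_low, .by_group = TRUE) |>
    mutate(med = median(.data$n),
           prev = dplyr::lag(.data$n, default = 0L),
           nxt = dplyr::lead(.data$n, default = 0L),
           is_peak = .data$n > peak_factor * .data$med &
             .data$n >= .data$prev & .data$n >= .data$nxt) |>
    ungroup() |>
    filter(.data$is_peak) |>
    select("class", size = "bin_low", "n")
  structure(list(counts = counts, histogram = hist, peaks = peaks,
                 bin_width = bin_width),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat("  ", x$counts$class[i], ": ", x$counts$n[i], "\n", sep = "")
  }
  if (nrow(x$peaks)) {
    cat("  peaks: ",
        paste0(x$peaks$class, "@", x$peaks$size, "bp", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.spectrum_summary <- function(x, ...) x$histogram

#' @export
glance.spectrum_summary <- function(x, ...) {
  tibble(n_variants = sum(x$counts$n), n_classes = nrow(x$counts),
         n_peaks = nrow(x$peaks))
}

#' Total aligned bases of a block set
#'
#' Haplotype-A bases inside syntenic forward one-to-one blocks, the
#' denominator for heterozygosity rates.
#'
#' @param blocks Block tibble.
#' @param syn_tol Synteny tolerance, as in [classify_variants()].
#' @return Number of bases.
#' @export
aligned_bases <- function(blocks, syn_tol = 20000) {
  fwd <- filter(blocks, .data$orient == "forward", .data$kind == "primary")
  if (nrow(fwd) == 0L) return(0)
  ref <- fwd |>
    mutate(len = .data$end_a - .data$start_a,
           diag = .data$start_b - .data$start_a) |>
    group_by(.data$chr_a) |>
    mutate(ref_diag = .data$diag[which.max(.data$len)]) |>
    ungroup() |>
    filter(abs(.data$diag - .data$ref_diag) <= syn_tol)
  sum(ref$end_a - ref$start_a)
}

#' Heterozygosity rates from classified variants
#'
#' The SNV rate is SNV count over aligned bases; the full-spectrum rate
#' additionally counts every base affected by indels and structural
#' variants (variant sizes), both as percentages.
#'
#' @param variants Variant tibble.
#' @param aligned_bases Denominator in bp (see [aligned_bases()]).
#' @return List with `snv_percent` and `full_spectrum_percent`.
#' @export
heterozygosity_rates <- function(variants, aligned_bases) {
  if (is.na(aligned_bases) || aligned_bases <= 0) {
    rlang::abort("`aligned_bases` must be positive.")
  }
  n_snv <- sum(variants$class == "SNV")
  other <- sum(variants$size[variants$class != "SNV"])
  list(snv_percent = 100 * n_snv / aligned_bases,
       full_spectrum_percent = 100 * (n_snv + other) / aligned_bases)
}
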