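# Synthetic genomes with planted, machine-readable ground truth. All
# coordinates are 0-based, half-open. Every generator is a pure function of
# its parameters and seed.

empty_truth <- function() {
  list(
    tes = tibble(scaffold = character(), start = integer(), end = integer(),
                 length = integer()),
    duplications = tibble(scaffold = character(), src_start = integer(),
                          src_end = integer(), tgt_scaffold = character(),
                          tgt_start = integer(), tgt_end = integer(),
                          identity = double(), mode = character()),
    genes = tibble(gene_id = character(), scaffold = character(),
                   start = integer(), end = integer(), n_exons = integer(),
                   exons = list(), expected_copies = integer()),
    collapses = tibble(scaffold = character(), start = integer(),
                       end = integer(), true_copies = integer(),
                       assembled_copies = integer()),
    dnms = tibble(scaffold = character(), pos = integer(), origin = character(),
                  ev = integer()),
    variants = tibble(scaffold = character(), pos = integer(),
                      class = character(), size = integer())
  )
}

new_syn_genome <- function(sequences, repeat_track, truth, seed) {
  structure(
    list(sequences = sequences, repeat_track = repeat_track, truth = truth,
         seed = as.integer(seed)),
    class = "syn_genome"
  )
}

#' @export
print.syn_genome <- function(x, ...) {
  cat("<syn_genome> ", length(x$sequences), " scaffold(s), ",
      format(sum(nchar(x$sequences)), big.mark = ","), " bp\n", sep = "")
  cat("  repeat track: ", nrow(x$repeat_track), " interval(s)\n", sep = "")
  planted <- vapply(x$truth, nrow, integer(1))
  planted <- planted[planted > 0]
  if (length(planted)) {
    cat("  planted truth: ",
        paste(names(planted), planted, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Total length of a synthetic genome in bp
#' @param genome A `syn_genome`.
#' @return A single number.
#' @export
genome_size <- function(genome) sum(nchar(genome$sequences))

# Sample a free interval of length `len` on any scaffold, avoiding the
# `occupied` track (tibble scaffold/start/end) with `buffer` bp of margin.
sample_free_interval <- function(seq_lengths, len, occupied, buffer = 0L,
                                 max_tries = 200L, scaffold = NULL) {
  scs <- names(seq_lengths)
  ok <- seq_lengths >= len
  if (!is.null(scaffold)) ok <- ok & scs == scaffold
  if (!any(ok)) return(NULL)
  w <- as.numeric(seq_lengths[ok] - len + 1)
  cand_scs <- scs[ok]
  for (i in seq_len(max_tries)) {
    sc <- if (length(cand_scs) == 1L) cand_scs else sample(cand_scs, 1L, prob = w)
    start <- sample.int(seq_lengths[[sc]] - len + 1L, 1L) - 1L
    iv <- tibble(scaffold = sc, start = max(0L, start - buffer),
                 end = min(seq_lengths[[sc]], start + len + buffer))
    if (!any(overlaps_any(iv, occupied))) {
      return(tibble(scaffold = sc, start = start, end = start + len))
    }
  }
  NULL
}

#' Generate a random genome with interspersed mobile-element copies
#'
#' Builds one or more scaffolds of uniform-composition random sequence and
#' plants exact copies of a small library of mobile-element consensus
#' sequences at a configurable density. Element lengths default to 300 bp,
#' 500 bp and 4.5 kb, the characteristic sizes of the transposable-element
#' families that dominate rodent structural variation. Planted copies are
#' recorded in the repeat track and in the truth set.
#'
#' @param seed Integer RNG seed; output is a pure function of seed and
#'   parameters.
#' @param scaffolds Integer vector of scaffold lengths in bp (names become
#'   scaffold identifiers; unnamed scaffolds are called `scaffold_1`, ...).
#' @param te_library Lengths in bp of the mobile-element consensus sequences.
#' @param te_density Planted element copies per Mb of genome.
#' @return A `syn_genome`: list with `sequences` (named character vector),
#'   `repeat_track` (tibble `scaffold`, `start`, `end`; 0-based half-open),
#'   `truth` (list of truth tibbles) and `seed`.
#' @examples
#' g <- generate_genome(1, scaffolds = c(chr1 = 50000), te_density = 0)
#' genome_size(g)
#' @export
generate_genome <- function(seed, scaffolds = c(chr1 = 1e6),
                            te_library = c(300, 500, 4500),
                            te_density = 20) {
  if (any(scaffolds <= 0)) rlang::abort("scaffold lengths must be positive.")
  if (any(scaffolds < 1e4)) rlang::abort("scaffold lengths must be >= 10 kb.")
  assert_scalar_number(te_density, "te_density", min = 0)
  scaffolds <- round(scaffolds)
  if (is.null(names(scaffolds))) {
    names(scaffolds) <- paste0("scaffold_", seq_along(scaffolds))
  }
  with_seed(seed, {
    seqs <- vapply(scaffolds, function(n) rand_dna(n), character(1))
    lens <- setNames(as.integer(scaffolds), names(scaffolds))
    truth <- empty_truth()
    track <- tibble(scaffold = character(), start = integer(), end = integer())
    n_te <- round(te_density * sum(lens) / 1e6)
    if (n_te > 0) {
      consensi <- vapply(te_library, function(L) rand_dna(L), character(1))
      fams <- sample.int(length(te_library), n_te, replace = TRUE)
      for (i in seq_len(n_te)) {
        L <- as.integer(te_library[fams[i]])
        iv <- sample_free_interval(lens, L, track, buffer = 10L)
        if (is.null(iv)) next
        substr(seqs[[iv$scaffold]], iv$start + 1L, iv$end) <- consensi[fams[i]]
        track <- bind_rows(track, iv)
      }
      track <- arrange(track, .data$scaffold, .data$start)
      truth$tes <- mutate(track, length = .data$end - .data$start)
    }
    new_syn_genome(seqs, track, truth, seed)
  })
}

#' Plant segmental duplications into a synthetic genome
#'
#' Each event copies a randomly chosen source segment, applies point
#' substitutions until the copy reaches a sampled target identity (achieved
#' identity is recorded in the truth set), and writes the copy either
#' immediately adjacent to the source (tandem) or at a random distant
#' position (interspersed). Copies overwrite existing sequence so scaffold
#' lengths and all previously recorded coordinates stay valid.
#'
#' @param genome A `syn_genome`.
#' @param n_events Number of duplication events.
#' @param length_range Two-element bp range for the duplicated segment.
#' @param identity_range Two-element range in (0.5, 1] for the target
#'   sequence identity between source and copy.
#' @param tandem_fraction Fraction of events placed tandemly.
#' @param seed Integer RNG seed.
#' @return The genome with copies written and `truth$duplications` extended
#'   (columns `scaffold`, `src_start`, `src_end`, `tgt_scaffold`,
#'   `tgt_start`, `tgt_end`, `identity`, `mode`).
#' @export
plant_duplications <- function(genome, n_events,
                               length_range = c(5000, 20000),
                               identity_range = c(0.9, 1),
                               tandem_fraction = 0.5, seed = 1) {
  stopifnot(inherits(genome, "syn_genome"))
  assert_scalar_number(n_events, "n_events", min = 0)
  if (identity_range[1] <= 0.5 || identity_range[2] > 1) {
    rlang::abort("identity_range must lie within (0.5, 1].")
  }
  if (n_events == 0) return(genome)
  with_seed(seed, {
    seqs <- genome$sequences
    lens <- setNames(as.integer(nchar(seqs)), names(seqs))
    if (length_range[2] > max(lens)) {
      rlang::abort("length_range exceeds the largest scaffold.")
    }
    occupied <- bind_rows(
      genome$repeat_track,
      tibble(scaffold = genome$truth$duplications$scaffold,
             start = genome$truth$duplications$src_start,
             end = genome$truth$duplications$src_end),
      tibble(scaffold = genome$truth$duplications$tgt_scaffold,
             start = genome$truth$duplications$tgt_start,
             end = genome$truth$duplications$tgt_end)
    )
    recs <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      L <- sample_range(length_range[1], length_range[2])
      tandem <- runif(1) < tandem_fraction
      placed <- FALSE
      for (try in 1:100) {
        if (tandem) {
          # source must leave room for an adjacent same-length copy
          src <- sample_free_interval(lens - L, L, occupied, buffer = 50L)
          if (is.null(src)) break
          tgt <- tibble(scaffold = src$scaffold, start = src$end,
                        end = src$end + L)
        } else {
          src <- sample_free_interval(lens, L, occupied, buffer = 50L)
          if (is.null(src)) break
          tgt <- sample_free_interval(lens, L, bind_rows(occupied, src),
                                      buffer = 50L)
          if (is.null(tgt)) next
        }
        if (any(overlaps_any(tgt, bind_rows(occupied, src)))) next
        placed <- TRUE
        break
      }
      if (!placed) {
        rlang::abort(sprintf(
          "could not place duplication event %d of %d (genome too crowded).",
          i, n_events))
      }
      id_target <- runif(1, identity_range[1], identity_range[2])
      n_sub <- round((1 - id_target) * L)
      copy <- substr(seqs[[src$scaffold]], src$start + 1L, src$end)
      if (n_sub > 0) copy <- substitute_bases(copy, sample.int(L, n_sub))
      substr(seqs[[tgt$scaffold]], tgt$start + 1L, tgt$end) <- copy
      occupied <- bind_rows(occupied, src, tgt)
      recs[[i]] <- tibble(
        scaffold = src$scaffold, src_start = src$start, src_end = src$end,
        tgt_scaffold = tgt$scaffold, tgt_start = tgt$start, tgt_end = tgt$end,
        identity = 1 - n_sub / L,
        mode = if (tandem) "tandem" else "interspersed"
      )
    }
    genome$sequences <- seqs
    genome$truth$duplications <- bind_rows(genome$truth$duplications,
                                           bind_rows(recs))
    genome
  })
}

#' Plant multi-exon gene models onto a synthetic genome
#'
#' Genes are annotations over existing sequence (no bases are modified): a
#' gene body is placed either fully inside the source interval of a planted
#' duplication (so its spliced sequence also occurs in every copy) or in
#' unique sequence. The truth set records the expected genomic copy count of
#' each gene. Exon/intron structure is sampled subject to minimum exon
#' (50 bp) and intron (30 bp) sizes.
#'
#' @param genome A `syn_genome`, typically after [plant_duplications()].
#' @param n_genes Number of genes to plant.
#' @param exons_per_gene Two-element range of exon counts (1 allowed, so
#'   single-exon genes can exercise eligibility filters).
#' @param gene_length_range Two-element bp range for the gene body
#'   (minimum allowed 200 bp).
#' @param dup_overlap_fraction Fraction of genes placed inside duplication
#'   source intervals.
#' @param seed Integer RNG seed.
#' @return The genome with `truth$genes` extended; exon intervals are stored
#'   as a list-column of tibbles (`start`, `end`).
#' @export
plant_genes <- function(genome, n_genes, exons_per_gene = c(1, 6),
                        gene_length_range = c(600, 15000),
                        dup_overlap_fraction = 0.25, seed = 1) {
  stopifnot(inherits(genome, "syn_genome"))
  if (gene_length_range[1] < 200) {
    rlang::abort("gene_length_range minimum must be >= 200 bp.")
  }
  if (n_genes == 0) return(genome)
  with_seed(seed, {
    lens <- setNames(as.integer(nchar(genome$sequences)),
                     names(genome$sequences))
    dups <- genome$truth$duplications
    dup_ivs <- bind_rows(
      tibble(scaffold = dups$scaffold, start = dups$src_start, end = dups$src_end),
      tibble(scaffold = dups$tgt_scaffold, start = dups$tgt_start, end = dups$tgt_end)
    )
    occupied <- bind_rows(
      tibble(scaffold = genome$truth$genes$scaffold,
             start = genome$truth$genes$start, end = genome$truth$genes$end)
    )
    n_in_dup <- round(n_genes * dup_overlap_fraction)
    recs <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      in_dup <- i <= n_in_dup
      L <- sample_range(gene_length_range[1], gene_length_range[2])
      iv <- NULL
      for (try in 1:200) {
        if (in_dup) {
          if (nrow(dups) == 0L) {
            rlang::abort("dup_overlap_fraction > 0 but no duplications planted.")
          }
          j <- sample.int(nrow(dups), 1L)
          room <- dups$src_end[j] - dups$src_start[j] - L
          if (room < 0) next
          start <- dups$src_start[j] + sample.int(room + 1L, 1L) - 1L
          cand <- tibble(scaffold = dups$scaffold[j], start = start,
                         end = start + L)
          if (any(overlaps_any(cand, occupied))) next
          iv <- cand
        } else {
          cand <- sample_free_interval(lens, L, bind_rows(occupied, dup_ivs),
                                       buffer = 20L)
          if (is.null(cand)) next
          iv <- cand
        }
        break
      }
      if (is.null(iv)) {
        rlang::abort(sprintf("could not place gene %d of %d.", i, n_genes))
      }
      occupied <- bind_rows(occupied, iv)
      # exon/intron split of the body
      n_ex <- sample_range(exons_per_gene[1], exons_per_gene[2])
      min_ex <- 50L; min_in <- 30L
      while (n_ex > 1L && (n_ex * min_ex + (n_ex - 1L) * min_in) > L) {
        n_ex <- n_ex - 1L
      }
      n_parts <- 2L * n_ex - 1L
      base <- rep(c(min_ex, min_in), length.out = n_parts)
      extra <- L - sum(base)
      add <- if (extra > 0) as.integer(stats::rmultinom(1, extra, rep(1, n_parts))) else rep(0L, n_parts)
      part_len <- base + add
      offs <- cumsum(c(0L, part_len))
      exon_idx <- seq(1L, n_parts, by = 2L)
      exons <- tibble(start = iv$start + offs[exon_idx],
                      end = iv$start + offs[exon_idx + 1L])
      n_copies <- 1L
      if (nrow(dups)) {
        inside <- dups$scaffold == iv$scaffold &
          dups$src_start <= iv$start & dups$src_end >= iv$end
        n_copies <- 1L + sum(inside)
      }
      recs[[i]] <- tibble(
        gene_id = sprintf("gene_%03d", i), scaffold = iv$scaffold,
        start = iv$start, end = iv$end, n_exons = n_ex,
        exons = list(exons), expected_copies = n_copies
      )
    }
    genome$truth$genes <- bind_rows(genome$truth$genes, bind_rows(recs))
    genome
  })
}

#' Transcript models of the genes planted in a synthetic genome
#'
#' Extracts one spliced isoform per planted gene: exon coordinates, gene
#' body span and the spliced (intron-free) sequence.
#'
#' @param genome A `syn_genome` after [plant_genes()].
#' @return Tibble with columns `gene_id`, `transcript_id`, `scaffold`,
#'   `start`, `end`, `n_exons`, `gene_body_length`, `spliced_length`,
#'   `exons` (list-column) and `spliced_seq`.
#' @export
transcript_models <- function(genome) {
  stopifnot(inherits(genome, "syn_genome"))
  g <- genome$truth$genes
  if (nrow(g) == 0L) {
    return(tibble(gene_id = character(), transcript_id = character(),
                  scaffold = character(), start = integer(), end = integer(),
                  n_exons = integer(), gene_body_length = integer(),
                  spliced_length = integer(), exons = list(),
                  spliced_seq = character()))
  }
  spliced <- map2_chr_(g$scaffold, g$exons, function(sc, ex) {
    paste0(substring(genome$sequences[[sc]], ex$start + 1L, ex$end),
           collapse = "")
  })
  tibble(
    gene_id = g$gene_id,
    transcript_id = paste0(g$gene_id, "_t1"),
    scaffold = g$scaffold, start = g$start, end = g$end,
    n_exons = g$n_exons,
    gene_body_length = g$end - g$start,
    spliced_length = nchar(spliced),
    exons = g$exons,
    spliced_seq = spliced
  )
}

map2_chr_ <- function(x, y, f) vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))
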