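# Readers and writers for the plain-text formats the pipeline consumes and
# emits: FASTA, BED 3+, bedGraph, the tab-separated duplication-pair table,
# alignment-block and variant tables, and the VCF-like trio dialect.
# All interval formats are 0-based half-open; trio positions are 1-based.

#' Write genome sequences to FASTA
#' @param genome A `syn_genome` or named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "syn_genome")) genome$sequences else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write intervals as BED
#' @param intervals Tibble `scaffold`, `start`, `end` (extra columns kept).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED 3+ file
#' @param path BED file.
#' @param extra_names Names for columns beyond the first three.
#' @return Tibble `scaffold`, `start`, `end` plus any extra columns.
#' @export
read_bed <- function(path, extra_names = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  names(x)[1:3] <- c("scaffold", "start", "end")
  if (ncol(x) > 3L && !is.null(extra_names)) {
    names(x)[4:(3 + length(extra_names))] <- extra_names
  }
  x
}

#' Write a depth track as bedGraph
#' @param track A `depth_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(as_tibble(track)[, c("scaffold", "start", "end", "depth")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a fixed-bin bedGraph into a depth track
#' @param path bedGraph file with uniform bins.
#' @return A `depth_track` tibble.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("scaffold", "start", "end", "depth"),
                       show_col_types = FALSE, progress = FALSE)
  bw <- unique(x$end - x$start)
  if (length(bw) > 1L) rlang::abort("bedGraph bins are not uniform.")
  structure(x, class = c("depth_track", class(x)), bin_width = as.integer(bw))
}

#' Write a duplication-pair table
#'
#' Tab-separated with header `chrA startA endA chrB startB endB identity
#' length` (self-alignment table dialect, 0-based half-open).
#'
#' @param pairs Duplication-pair tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sd_pairs <- function(pairs, path) {
  out <- pairs[, c("chr_a", "start_a", "end_a", "chr_b", "start_b", "end_b",
                   "identity", "length")]
  names(out) <- c("chrA", "startA", "endA", "chrB", "startB", "endB",
                  "identity", "length")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a duplication-pair table
#' @param path TSV with the `write_sd_pairs()` header.
#' @return Duplication-pair tibble.
#' @export
read_sd_pairs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrA", "startA", "endA", "chrB", "startB", "endB", "identity",
            "length")
  if (!all(need %in% names(x))) {
    rlang::abort("duplication-pair table is missing required columns.")
  }
  x <- x[, need]
  names(x) <- c("chr_a", "start_a", "end_a", "chr_b", "start_b", "end_b",
                "identity", "length")
  x
}

#' Write graph components as TSV
#' @param graph A `dup_graph`.
#' @param path Output file (`component_id interval copy_number`).
#' @return `path`, invisibly.
#' @export
write_components <- function(graph, path) {
  out <- graph$nodes |>
    transmute(component_id = .data$component_id,
              interval = sprintf("%s:%d-%d", .data$scaffold, .data$start,
                                 .data$end),
              copy_number = .data$copy_number)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write alignment blocks as TSV
#' @param blocks Block tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  readr::write_tsv(blocks, path)
  invisible(path)
}

#' Read alignment blocks from TSV
#' @param path TSV written by [write_blocks()] (or derived from an external
#'   aligner's delta output).
#' @return Block tibble.
#' @export
read_blocks <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"kind" %in% names(x)) x$kind <- "primary"
  x
}

#' Write classified variants as TSV
#' @param variants Variant tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

# -- trio tables ------------------------------------------------------------

#' Write a trio genotype table in the VCF-like TSV dialect
#'
#' Columns `CHROM POS REF ALT QD FS MQ MQRankSum ReadPosRankSum SOR` then
#' one column per individual with packed `GT:DP:GQ:AD:EV` (AD is the
#' alternate-allele read count; EV the evidence token, `.` when absent).
#'
#' @param table A per-site trio table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trio_table <- function(table, path) {
  out <- tibble(CHROM = table$chrom, POS = table$pos, REF = table$ref,
                ALT = ifelse(is.na(table$alt), ".", table$alt),
                QD = table$qd, FS = table$fs, MQ = table$mq,
                MQRankSum = table$mq_rank_sum,
                ReadPosRankSum = table$read_pos_rank_sum, SOR = table$sor)
  for (ind in trio_individuals) {
    ev <- table[[paste0(ind, "_ev")]]
    out[[ind]] <- sprintf("%s:%d:%d:%d:%s",
                          table[[paste0(ind, "_gt")]],
                          table[[paste0(ind, "_dp")]],
                          table[[paste0(ind, "_gq")]],
                          table[[paste0(ind, "_ad_alt")]],
                          ifelse(is.na(ev), ".", as.character(ev)))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a trio genotype table from the VCF-like TSV dialect
#'
#' Inverse of [write_trio_table()]. Allelic balance is recomputed as
#' `AD / DP`.
#'
#' @param path TSV file.
#' @return A per-site trio tibble.
#' @export
read_trio_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble(chrom = x$CHROM, pos = x$POS, ref = x$REF,
                alt = ifelse(x$ALT == ".", NA_character_, x$ALT),
                qd = x$QD, fs = x$FS, mq = x$MQ, mq_rank_sum = x$MQRankSum,
                read_pos_rank_sum = x$ReadPosRankSum, sor = x$SOR)
  for (ind in trio_individuals) {
    f <- stringr::str_split_fixed(x[[ind]], ":", 5L)
    out[[paste0(ind, "_gt")]] <- f[, 1]
    dp <- as.integer(f[, 2])
    ad <- as.integer(f[, 4])
    out[[paste0(ind, "_dp")]] <- dp
    out[[paste0(ind, "_gq")]] <- as.integer(f[, 3])
    out[[paste0(ind, "_ad_alt")]] <- ad
    out[[paste0(ind, "_ab")]] <- ifelse(dp > 0L, ad / dp, 0)
    out[[paste0(ind, "_ev")]] <- suppressWarnings(
      as.integer(ifelse(f[, 5] == ".", NA, f[, 5])))
  }
  out
}

#' Read a standard VCF into the trio table layout
#'
#' Accepts a VCF with FORMAT fields `GT:DP:GQ:AD` for exactly three samples
#' (father, mother, offspring in column order unless `sample_order` is
#' given). Allelic balance is computed as alt reads over total reads from
#' AD; the evidence token is absent (NA).
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param sample_order Character vector mapping VCF sample columns to
#'   `father`, `mother`, `offspring`.
#' @return A per-site trio tibble.
#' @export
read_trio_vcf <- function(path, sample_order = c("father", "mother", "offspring")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    rlang::abort("reading standard VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  get_info <- function(key) {
    m <- stringr::str_match(fix$INFO, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    as.numeric(m)
  }
  out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
                alt = ifelse(fix$ALT %in% c(".", ""), NA_character_, fix$ALT),
                qd = get_info("QD"), fs = get_info("FS"), mq = get_info("MQ"),
                mq_rank_sum = get_info("MQRankSum"),
                read_pos_rank_sum = get_info("ReadPosRankSum"),
                sor = get_info("SOR"))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)
  for (s in seq_along(sample_order)) {
    ind <- sample_order[s]
    col <- samples[s]
    ad2 <- stringr::str_split_fixed(ad[, col], ",", 2L)
    ad_ref <- suppressWarnings(as.integer(ad2[, 1]))
    ad_alt <- suppressWarnings(as.integer(ad2[, 2]))
    tot <- ad_ref + ad_alt
    out[[paste0(ind, "_gt")]] <- gsub("\\|", "/", gt[, col])
    out[[paste0(ind, "_dp")]] <- as.integer(dp[, col])
    out[[paste0(ind, "_gq")]] <- as.integer(gq[, col])
    out[[paste0(ind, "_ad_alt")]] <- ad_alt
    out[[paste0(ind, "_ab")]] <- ifelse(!is.na(tot) & tot > 0L, ad_alt / tot, 0)
    out[[paste0(ind, "_ev")]] <- NA_integer_
  }
  out
}
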