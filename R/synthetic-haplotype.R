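# Second-haplotype simulation: plants SNVs, small indels and structural
# variants into a copy of a genome, recording every event with its class,
# size and position on the original (haplotype A) coordinate system.

#' Derive a second haplotype with planted variants
#'
#' Returns a mutated copy of the genome together with a truth list of every
#' planted difference. Positions in the truth set refer to the input
#' (haplotype A) coordinates. Events are placed with generous spacing so
#' that each one is recoverable in isolation by whole-genome alignment.
#'
#' SV classes: `insertion` (novel sequence), `deletion`, `inversion`
#' (segment reverse-complemented in place), `translocation` (segment excised
#' and re-inserted at a distant position on the same scaffold) and `CNV`
#' (segment tandem-duplicated in the second haplotype).
#'
#' @param genome A `syn_genome` (haplotype A).
#' @param snv_rate Per-bp substitution probability.
#' @param small_indel_rate Per-bp probability of a 1-10 bp indel.
#' @param sv_events Tibble or data frame with columns `class` and `size`
#'   (bp), one row per planted SV; `NULL` for none.
#' @param seed Integer RNG seed.
#' @return A list with `haplotype` (a `syn_genome`, haplotype B) and `truth`
#'   (tibble `scaffold`, `pos`, `class`, `size`).
#' @export
mutate_haplotype <- function(genome, snv_rate = 1e-3, small_indel_rate = 0,
                             sv_events = NULL, seed = 1) {
  stopifnot(inherits(genome, "syn_genome"))
  assert_scalar_number(snv_rate, "snv_rate", min = 0, max = 1)
  assert_scalar_number(small_indel_rate, "small_indel_rate", min = 0, max = 1)
  sv_events <- if (is.null(sv_events)) {
    tibble(class = character(), size = integer())
  } else {
    as_tibble(sv_events)
  }
  bad <- setdiff(sv_events$class, c("insertion", "deletion", "inversion",
                                    "translocation", "CNV"))
  if (length(bad)) {
    rlang::abort(paste0("unknown SV class: ", paste(bad, collapse = ", ")))
  }
  with_seed(seed, {
    lens <- setNames(as.integer(nchar(genome$sequences)),
                     names(genome$sequences))
    if (nrow(sv_events) && max(sv_events$size) >= max(lens)) {
      rlang::abort("an SV is larger than the largest scaffold.")
    }
    occupied <- tibble(scaffold = character(), start = integer(),
                       end = integer())
    events <- list()
    # SVs first (largest footprints). Translocations get a paired paste
    # anchor at least 50 kb away on the same scaffold.
    if (nrow(sv_events)) {
      for (i in seq_len(nrow(sv_events))) {
        cls <- sv_events$class[i]
        s <- as.integer(sv_events$size[i])
        foot <- if (cls == "insertion") 1L else s
        iv <- sample_free_interval(lens, foot, occupied, buffer = 300L)
        if (is.null(iv)) rlang::abort(sprintf("no room for SV event %d.", i))
        occupied <- bind_rows(occupied, iv)
        ev <- tibble(scaffold = iv$scaffold, start = iv$start,
                     end = iv$start + foot, class = cls, size = s,
                     payload = NA_character_)
        if (cls == "insertion") ev$payload <- rand_dna(s)
        if (cls == "translocation") {
          for (try in 1:200) {
            anchor <- sample_free_interval(lens, 1L, occupied, buffer = 300L,
                                           scaffold = iv$scaffold)
            if (!is.null(anchor) &&
                abs(anchor$start - iv$start) >= min(50000L, lens[[iv$scaffold]] %/% 3L)) break
            anchor <- NULL
          }
          if (is.null(anchor)) rlang::abort(sprintf("no paste site for translocation %d.", i))
          occupied <- bind_rows(occupied, anchor)
          events <- c(events, list(tibble(
            scaffold = anchor$scaffold, start = anchor$start,
            end = anchor$start, class = "trans_paste", size = s,
            payload = substr(genome$sequences[[iv$scaffold]],
                             iv$start + 1L, iv$start + s)
          )))
        }
        events <- c(events, list(ev))
      }
    }
    # small indels
    n_ind <- rbinom(1L, sum(lens), small_indel_rate)
    for (i in seq_len(n_ind)) {
      s <- sample.int(10L, 1L)
      del <- runif(1) < 0.5
      foot <- if (del) s else 1L
      iv <- sample_free_interval(lens, foot, occupied, buffer = 60L)
      if (is.null(iv)) break
      occupied <- bind_rows(occupied, iv)
      events <- c(events, list(tibble(
        scaffold = iv$scaffold, start = iv$start, end = iv$start + foot,
        class = if (del) "deletion" else "insertion", size = s,
        payload = if (del) NA_character_ else rand_dna(s)
      )))
    }
    # SNVs: avoid SV/indel footprints, allowed near each other
    n_snv <- rbinom(1L, sum(lens), snv_rate)
    if (n_snv > 0) {
      per_sc <- table(sample(names(lens), n_snv, replace = TRUE,
                             prob = as.numeric(lens)))
      for (sc in names(per_sc)) {
        pos <- sample.int(lens[[sc]], per_sc[[sc]]) - 1L
        cand <- tibble(scaffold = sc, start = pos, end = pos + 1L)
        keep <- !overlaps_any(mutate(cand, start = pmax(0L, .data$start - 2L),
                                     end = .data$end + 2L), occupied)
        cand <- cand[keep, ]
        if (nrow(cand)) {
          events <- c(events, list(mutate(cand, class = "SNV", size = 1L,
                                          payload = NA_character_)))
        }
      }
    }
    ev <- if (length(events)) arrange(bind_rows(events), .data$scaffold, .data$start)
          else tibble(scaffold = character(), start = integer(), end = integer(),
                      class = character(), size = integer(), payload = character())
    # Build haplotype B scaffold by scaffold by walking the event list.
    seqs_b <- genome$sequences
    for (sc in names(seqs_b)) {
      esc <- filter(ev, .data$scaffold == sc)
      if (nrow(esc) == 0L) next
      a <- genome$sequences[[sc]]
      pieces <- character(0)
      cursor <- 0L  # 0-based position of next unconsumed A base
      for (j in seq_len(nrow(esc))) {
        e <- esc[j, ]
        if (e$start > cursor) {
          pieces <- c(pieces, substr(a, cursor + 1L, e$start))
        }
        seg <- if (e$end > e$start) substr(a, e$start + 1L, e$end) else ""
        pieces <- c(pieces, switch(
          e$class,
          SNV = substitute_bases(seg, 1L),
          insertion = paste0(seg, e$payload),
          deletion = "",
          inversion = revcomp(seg),
          CNV = paste0(seg, seg),
          translocation = "",            # excised; re-inserted at paste anchor
          trans_paste = e$payload
        ))
        cursor <- e$end
      }
      if (cursor < nchar(a)) pieces <- c(pieces, substr(a, cursor + 1L, nchar(a)))
      seqs_b[[sc]] <- paste0(pieces, collapse = "")
    }
    truth <- ev |>
      filter(.data$class != "trans_paste") |>
      select("scaffold", pos = "start", "class", "size")
    hap_b <- new_syn_genome(seqs_b, genome$repeat_track, empty_truth(),
                            genome$seed)
    hap_b$truth$variants <- truth
    list(haplotype = hap_b, truth = truth)
  })
}
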