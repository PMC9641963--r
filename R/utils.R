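# Internal helpers shared across modules: seeded RNG scopes, raw-byte
# sequence surgery, k-mer extraction, interval arithmetic and CIGAR-like
# operation strings.

.BASES <- charToRaw("ACGT")

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single integer.")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Uniform integer in [lo, hi] (safe when lo == hi, unlike sample()).
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

rand_dna <- function(n) {
  rawToChar(.BASES[sample.int(4L, n, replace = TRUE)])
}

# Substitute bases at 1-based positions with a uniformly chosen different base.
substitute_bases <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  r <- charToRaw(seq)
  cur <- match(r[pos], .BASES)
  cur[is.na(cur)] <- 1L  # N or other: treat as A so substitution stays ACGT
  shift <- sample.int(3L, length(pos), replace = TRUE)
  r[pos] <- .BASES[(cur - 1L + shift) %% 4L + 1L]
  rawToChar(r)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# All k-mers of a string as a character vector (position i -> k-mer starting
# at i, 1-based).
kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Do any intervals in `a` (tibble scaffold/start/end, 0-based half-open)
# overlap any in `b`?
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  out <- logical(nrow(a))
  for (sc in unique(a$scaffold)) {
    ia <- which(a$scaffold == sc)
    ib <- which(b$scaffold == sc)
    if (length(ib) == 0L) next
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    out[ia] <- IRanges::overlapsAny(ra, rb)
  }
  out
}

# Total bases of each interval in `a` covered by the union of intervals in
# `b` (both 0-based half-open tibbles with scaffold/start/end).
covered_bases <- function(a, b) {
  out <- numeric(nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  for (sc in unique(a$scaffold)) {
    ia <- which(a$scaffold == sc)
    ib <- which(b$scaffold == sc)
    if (length(ib) == 0L) next
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::reduce(IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib]))
    ov <- IRanges::findOverlaps(ra, rb)
    if (length(ov) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      ra[S4Vectors::queryHits(ov)], rb[S4Vectors::subjectHits(ov)]
    ))
    out[ia] <- out[ia] + as.numeric(tapply(w, factor(S4Vectors::queryHits(ov), levels = seq_along(ra)), sum, default = 0))
  }
  out
}

# -- CIGAR-like operation strings ------------------------------------------
# Ops are written from the reference (haplotype A) point of view:
#   '=' match, 'X' mismatch, 'D' bases of A absent from B (deletion in B),
#   'I' bases of B absent from A (insertion in B).

ops_compress <- function(codes) {
  if (length(codes) == 0L) return("")
  r <- rle(codes)
  paste0(r$lengths, r$values, collapse = "")
}

ops_parse <- function(ops) {
  if (is.na(ops) || ops == "") {
    return(tibble(len = integer(0), op = character(0)))
  }
  m <- str_match_all(ops, "(\\d+)([=XIDC])")[[1]]
  tibble(len = as.integer(m[, 2]), op = m[, 3])
}

# Convert a global pairwise alignment of A-segment vs B-segment to an ops
# string. Uses the aligned (gapped) strings.
aln_to_ops <- function(a_gapped, b_gapped) {
  a <- charToRaw(a_gapped)
  b <- charToRaw(b_gapped)
  gap <- charToRaw("-")
  code <- character(length(a))
  is_gap_a <- a == gap
  is_gap_b <- b == gap
  code[is_gap_a] <- "I"
  code[is_gap_b] <- "D"
  both <- !is_gap_a & !is_gap_b
  code[both & a == b] <- "="
  code[both & a != b] <- "X"
  ops_compress(code)
}

.pkg_cache <- new.env(parent = emptyenv())

submat <- function(mismatch = -2) {
  key <- paste0("submat", mismatch)
  if (is.null(.pkg_cache[[key]])) {
    .pkg_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = mismatch, baseOnly = FALSE)
  }
  .pkg_cache[[key]]
}

# Positional comparison of two equal-length strings into =/X ops.
cmp_ops <- function(x, y) {
  rx <- charToRaw(x); ry <- charToRaw(y)
  ops_compress(ifelse(rx == ry, "=", "X"))
}

# Aligned-column count of a PairwiseAlignments object (S4-safe).
aln_cols <- function(pa) {
  nchar(as.character(Biostrings::alignedPattern(pa)))
}

# Global alignment of two segments returning an ops string. Scoring favours
# mismatches over spurious indel pairs so substitution-only divergence stays
# as 'X' columns.
align_ops <- function(a_seg, b_seg) {
  if (nchar(a_seg) == 0L && nchar(b_seg) == 0L) return("")
  if (nchar(a_seg) == 0L) return(paste0(nchar(b_seg), "I"))
  if (nchar(b_seg) == 0L) return(paste0(nchar(a_seg), "D"))
  if (nchar(a_seg) == nchar(b_seg)) return(cmp_ops(a_seg, b_seg))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a_seg), Biostrings::DNAString(b_seg),
    type = "global", substitutionMatrix = submat(-2),
    gapOpening = 6, gapExtension = 2
  )
  aln_to_ops(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa))
  )
}

`%||%` <- rlang::`%||%`

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    rlang::abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  invisible(x)
}
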