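# Shared fixtures, built once per test run, and independent oracles used
# across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# 300 kb genome with 10 planted duplications at ~95% identity, no mobile
# elements (so every self-alignment pair is a planted duplication).
fx_sd_genome <- function() fixture("sd_genome", function() {
  g <- generate_genome(101, scaffolds = c(chr1 = 3e5), te_density = 0)
  plant_duplications(g, 10, length_range = c(4000, 8000),
                     identity_range = c(0.945, 0.955),
                     tandem_fraction = 0.5, seed = 102)
})

fx_sd_pairs <- function() fixture("sd_pairs", function() {
  naive_self_align(fx_sd_genome(), min_length = 1000, min_identity = 0.9)
})

# genome with planted genes, some inside 2-copy duplications
fx_gene_genome <- function() fixture("gene_genome", function() {
  g <- generate_genome(201, scaffolds = c(chr1 = 2e5, chr2 = 1e5),
                       te_density = 0)
  g <- plant_duplications(g, 5, length_range = c(8000, 15000),
                          identity_range = c(0.93, 0.99),
                          tandem_fraction = 0.4, seed = 202)
  plant_genes(g, 20, exons_per_gene = c(2, 5),
              gene_length_range = c(1200, 6000),
              dup_overlap_fraction = 0.25, seed = 203)
})

fx_gene_alignments <- function() fixture("gene_alignments", function() {
  g <- fx_gene_genome()
  map_transcripts(g, select_isoforms(transcript_models(g)))
})

# clean 50 kb trio with 1 maternal + 3 paternal de novo mutations
fx_trio_clean <- function() fixture("trio_clean", function() {
  g <- generate_genome(301, scaffolds = c(chr1 = 5e4), te_density = 0)
  simulate_trio(g, het_rate = 2e-3, n_dnm_maternal = 1, n_dnm_paternal = 3,
                seed = 302)
})

# --- independent oracles ---------------------------------------------------

# Brute-force connected components by transitive closure over the edge
# relation (boolean matrix powering); returns a canonical partition label
# per node.
closure_components <- function(n_nodes, edges) {
  adj <- diag(TRUE, n_nodes)
  if (nrow(edges)) {
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj[cbind(edges$to, edges$from)] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  apply(adj, 1L, function(r) min(which(r)))
}

# Exhaustive best-path enumeration over all state sequences of an HMM
# (independent of the Viterbi implementation; feasible for S^T up to ~1e6).
brute_best_path <- function(counts, hmm) {
  S <- length(hmm$states)
  Tn <- length(counts)
  em <- sapply(seq_len(S), function(s) {
    if (hmm$poisson) dpois(counts, hmm$mu[s], log = TRUE)
    else dnbinom(counts, size = hmm$size[s], mu = hmm$mu[s], log = TRUE)
  })
  em <- matrix(em, nrow = Tn)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  ll <- hmm$log_init[grid[, 1]] + em[cbind(1L, grid[, 1])]
  if (Tn > 1) for (t in 2:Tn) {
    ll <- ll + hmm$log_trans[cbind(grid[, t - 1L], grid[, t])] +
      em[cbind(t, grid[, t])]
  }
  hmm$states[grid[which.max(ll), ]]
}

# Log-likelihood of a given state path under an HMM (direct computation).
path_loglik <- function(counts, states_path, hmm) {
  idx <- match(states_path, hmm$states)
  em <- vapply(seq_along(counts), function(t) {
    s <- idx[t]
    if (hmm$poisson) dpois(counts[t], hmm$mu[s], log = TRUE)
    else dnbinom(counts[t], size = hmm$size[s], mu = hmm$mu[s], log = TRUE)
  }, numeric(1))
  trans <- if (length(idx) > 1) {
    sum(hmm$log_trans[cbind(idx[-length(idx)], idx[-1])])
  } else 0
  hmm$log_init[idx[1]] + trans + sum(em)
}

# Global-alignment identity of two sequences (full dynamic programming via
# Biostrings), the oracle for reported pair identities.
dp_identity <- function(x, y) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 6, gapExtension = 2)
  gp <- as.character(Biostrings::alignedPattern(pa))
  Biostrings::nmatch(pa) / nchar(gp)
}

extract_interval <- function(genome, scaffold, start, end) {
  substr(genome$sequences[[scaffold]], start + 1L, end)
}
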