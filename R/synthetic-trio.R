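# Trio genotype-table simulation on two mapping targets (maternal and
# paternal assemblies) with planted de novo mutations, inherited
# heterozygous sites, obligate-heterozygous transmission sites and
# configurable filter violations.

default_noise <- function() {
  list(frac_ab_violation = 0, frac_site_fail = 0, frac_gq_low = 0,
       frac_dp_out = 0, n_unshared = 0)
}

trio_individuals <- c("father", "mother", "offspring")

#' Simulate trio genotype tables on two mapping targets
#'
#' Emits one per-site table per mapping target (maternal and paternal
#' assembly) at base-pair resolution. Planted de novo mutations appear in
#' the dual configuration used for candidate calling: a mutation of
#' maternal origin is (parents 0/0, offspring 0/1) on the paternal mapping
#' and (parents 1/1, offspring 0/1) on the maternal mapping, with a shared
#' integer evidence token standing in for read-name overlap between the two
#' call sets; paternal mutations are symmetric. Inherited sites include
#' obligate-heterozygous transmissions (one parent 0/0, the other 1/1,
#' offspring 0/1), the substrate for false-negative-rate estimation.
#'
#' Site and genotype annotations default to clearly passing values
#' (QD = 20, FS = 1, MQ = 60, rank sums 0, SOR = 1, GQ = 99, DP near the
#' individual mean); violations are injected explicitly through
#' `annotation_noise` and recorded in the truth set.
#'
#' @param genome A `syn_genome`.
#' @param het_rate Per-bp probability of an inherited variant site.
#' @param n_dnm_maternal,n_dnm_paternal Planted de novo mutation counts by
#'   parental origin.
#' @param depth_means Named numeric vector of mean depths for `offspring`,
#'   `father`, `mother`.
#' @param annotation_noise List with any of `frac_ab_violation` (fraction of
#'   obligate-het sites whose offspring allelic balance is pushed outside
#'   0.3-0.7), `frac_site_fail` (fraction of obligate-het sites given a
#'   failing site annotation), `frac_gq_low`, `frac_dp_out` (fractions of
#'   all sites where one individual fails GQ or DP), `n_unshared`
#'   (candidate-configuration sites present on one mapping only, without a
#'   shared evidence token).
#' @param seed Integer RNG seed.
#' @return A `trio_tables` object: list with `maternal_mapping` and
#'   `paternal_mapping` tibbles (one row per genome position), `depth_means`
#'   and `truth` (list of tibbles: `dnms`, `ab_violations`, `site_fail`,
#'   `gq_low`, `dp_out`, `het_sites`).
#' @export
simulate_trio <- function(genome, het_rate = 1e-3, n_dnm_maternal = 1,
                          n_dnm_paternal = 3,
                          depth_means = c(offspring = 56, father = 78, mother = 84),
                          annotation_noise = list(), seed = 1) {
  stopifnot(inherits(genome, "syn_genome"))
  assert_scalar_number(het_rate, "het_rate", min = 0, max = 1)
  assert_scalar_number(n_dnm_maternal, "n_dnm_maternal", min = 0)
  assert_scalar_number(n_dnm_paternal, "n_dnm_paternal", min = 0)
  if (any(depth_means <= 0)) rlang::abort("depth means must be positive.")
  noise <- utils::modifyList(default_noise(), annotation_noise)

  with_seed(seed, {
    chrom <- rep(names(genome$sequences), nchar(genome$sequences))
    pos <- unlist(lapply(nchar(genome$sequences), seq_len), use.names = FALSE)
    n <- length(pos)
    ref <- unlist(strsplit(paste0(genome$sequences, collapse = ""), ""),
                  use.names = FALSE)

    base_table <- function() {
      tb <- tibble(chrom = chrom, pos = pos, ref = ref, alt = NA_character_,
                   qd = 20, fs = 1, mq = 60, mq_rank_sum = 0,
                   read_pos_rank_sum = 0, sor = 1)
      for (ind in trio_individuals) {
        m <- depth_means[[ind]]
        dp <- pmin(pmax(rpois(n, m), ceiling(0.5 * m) + 1L), floor(2 * m) - 1L)
        tb[[paste0(ind, "_gt")]] <- "0/0"
        tb[[paste0(ind, "_dp")]] <- as.integer(dp)
        tb[[paste0(ind, "_gq")]] <- 99L
        tb[[paste0(ind, "_ad_alt")]] <- 0L
        tb[[paste0(ind, "_ab")]] <- 0
        tb[[paste0(ind, "_ev")]] <- NA_integer_
      }
      tb
    }
    mat <- base_table()
    pat <- base_table()

    het_ab <- function(k) pmin(0.68, pmax(0.32, rnorm(k, 0.5, 0.05)))

    set_gt <- function(tb, i, ind, gt) {
      dp <- tb[[paste0(ind, "_dp")]][i]
      tb[[paste0(ind, "_gt")]][i] <- gt
      if (gt == "0/1") {
        ab <- het_ab(length(i))
        tb[[paste0(ind, "_ab")]][i] <- ab
        tb[[paste0(ind, "_ad_alt")]][i] <- as.integer(round(ab * dp))
      } else if (gt == "1/1") {
        tb[[paste0(ind, "_ab")]][i] <- 1
        tb[[paste0(ind, "_ad_alt")]][i] <- dp
      } else {
        tb[[paste0(ind, "_ab")]][i] <- 0
        tb[[paste0(ind, "_ad_alt")]][i] <- 0L
      }
      tb
    }

    # inherited variant sites (same configuration on both mappings)
    n_het <- rbinom(1L, n, het_rate)
    avail <- sample.int(n)          # random site order; consume from front
    take <- function(k) {
      if (k > length(avail)) rlang::abort("more planted sites requested than positions available.")
      if (k == 0L) return(integer(0))
      out <- avail[seq_len(k)]; avail <<- avail[-seq_len(k)]; out
    }
    het_idx <- take(n_het)
    cfg <- if (n_het > 0) sample(c("father_het", "mother_het", "both_het", "obligate"),
                                 n_het, replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
           else character(0)
    alt_base <- function(i, tb) {
      tb$alt[i] <- vapply(tb$ref[i], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
      tb
    }
    apply_both <- function(f) { mat <<- f(mat); pat <<- f(pat) }
    for (cc in unique(cfg)) {
      i <- het_idx[cfg == cc]
      if (length(i) == 0L) next
      apply_both(function(tb) {
        tb <- alt_base(i, tb)
        if (cc == "father_het") {
          for (j in i) tb <- set_gt(tb, j, "father", "0/1")
          child <- sample(c("0/0", "0/1"), length(i), replace = TRUE)
          for (k in seq_along(i)) tb <- set_gt(tb, i[k], "offspring", child[k])
        } else if (cc == "mother_het") {
          for (j in i) tb <- set_gt(tb, j, "mother", "0/1")
          child <- sample(c("0/0", "0/1"), length(i), replace = TRUE)
          for (k in seq_along(i)) tb <- set_gt(tb, i[k], "offspring", child[k])
        } else if (cc == "both_het") {
          for (j in i) {
            tb <- set_gt(tb, j, "father", "0/1")
            tb <- set_gt(tb, j, "mother", "0/1")
            tb <- set_gt(tb, j, "offspring", sample(c("0/0", "0/1", "1/1"), 1L))
          }
        } else { # obligate: one parent 1/1, the other 0/0, child 0/1
          hom_parent <- sample(c("father", "mother"), length(i), replace = TRUE)
          for (k in seq_along(i)) {
            tb <- set_gt(tb, i[k], hom_parent[k], "1/1")
            tb <- set_gt(tb, i[k], "offspring", "0/1")
          }
        }
        tb
      })
    }
    obligate_idx <- het_idx[cfg == "obligate"]

    # de novo mutations
    n_dnm <- n_dnm_maternal + n_dnm_paternal
    dnm_idx <- take(n_dnm)
    origin <- c(rep("maternal", n_dnm_maternal), rep("paternal", n_dnm_paternal))
    ev_token <- if (n_dnm > 0) sample.int(1e6, n_dnm) else integer(0)
    for (k in seq_len(n_dnm)) {
      i <- dnm_idx[k]
      # table where parents read 0/0 and the child 0/1
      plant_ref_cfg <- function(tb) {
        tb <- alt_base(i, tb)
        tb <- set_gt(tb, i, "offspring", "0/1")
        tb[[paste0("offspring", "_ev")]][i] <- ev_token[k]
        tb
      }
      # table where parents read 1/1 and the child 0/1
      plant_alt_cfg <- function(tb) {
        tb <- alt_base(i, tb)
        tb <- set_gt(tb, i, "father", "1/1")
        tb <- set_gt(tb, i, "mother", "1/1")
        tb <- set_gt(tb, i, "offspring", "0/1")
        tb[[paste0("offspring", "_ev")]][i] <- ev_token[k]
        tb
      }
      if (origin[k] == "maternal") {
        pat <- plant_ref_cfg(pat); mat <- plant_alt_cfg(mat)
      } else {
        mat <- plant_ref_cfg(mat); pat <- plant_alt_cfg(pat)
      }
    }
    truth <- list(
      dnms = tibble(scaffold = chrom[dnm_idx], pos = pos[dnm_idx],
                    origin = origin, ev = ev_token),
      het_sites = tibble(scaffold = chrom[het_idx], pos = pos[het_idx],
                         config = cfg),
      ab_violations = tibble(scaffold = character(), pos = integer()),
      site_fail = tibble(scaffold = character(), pos = integer()),
      gq_low = tibble(scaffold = character(), pos = integer(),
                      individual = character()),
      dp_out = tibble(scaffold = character(), pos = integer(),
                      individual = character())
    )

    # unshared pseudo-candidates: DNM configuration on one mapping only
    if (noise$n_unshared > 0) {
      i <- take(noise$n_unshared)
      for (k in seq_along(i)) {
        tb_name <- sample(c("mat", "pat"), 1L)
        tb <- if (tb_name == "mat") mat else pat
        tb <- alt_base(i[k], tb)
        tb <- set_gt(tb, i[k], "offspring", "0/1")
        tb[["offspring_ev"]][i[k]] <- sample.int(1e6, 1L) + 2e6L
        if (tb_name == "mat") mat <- tb else pat <- tb
      }
    }

    # planted violations
    if (noise$frac_ab_violation > 0 && length(obligate_idx)) {
      k <- round(noise$frac_ab_violation * length(obligate_idx))
      i <- obligate_idx[seq_len(k)]
      if (k > 0) {
        bad_ab <- ifelse(runif(k) < 0.5, runif(k, 0.02, 0.25), runif(k, 0.75, 0.98))
        apply_both(function(tb) {
          tb$offspring_ab[i] <- bad_ab
          tb$offspring_ad_alt[i] <- as.integer(round(bad_ab * tb$offspring_dp[i]))
          tb
        })
        truth$ab_violations <- tibble(scaffold = chrom[i], pos = pos[i])
      }
    }
    if (noise$frac_site_fail > 0 && length(obligate_idx)) {
      pool <- setdiff(obligate_idx, obligate_idx[seq_len(
        round(noise$frac_ab_violation * length(obligate_idx)))])
      k <- round(noise$frac_site_fail * length(obligate_idx))
      k <- min(k, length(pool))
      i <- pool[seq_len(k)]
      if (k > 0) {
        apply_both(function(tb) { tb$qd[i] <- 1.0; tb })
        truth$site_fail <- tibble(scaffold = chrom[i], pos = pos[i])
      }
    }
    if (noise$frac_gq_low > 0) {
      k <- round(noise$frac_gq_low * n)
      i <- take(k)
      ind <- sample(trio_individuals, k, replace = TRUE)
      apply_both(function(tb) {
        for (u in unique(ind)) tb[[paste0(u, "_gq")]][i[ind == u]] <- 30L
        tb
      })
      truth$gq_low <- tibble(scaffold = chrom[i], pos = pos[i], individual = ind)
    }
    if (noise$frac_dp_out > 0) {
      k <- round(noise$frac_dp_out * n)
      i <- take(k)
      ind <- sample(trio_individuals, k, replace = TRUE)
      apply_both(function(tb) {
        for (u in unique(ind)) {
          tb[[paste0(u, "_dp")]][i[ind == u]] <-
            as.integer(floor(0.3 * depth_means[[u]]))
        }
        tb
      })
      truth$dp_out <- tibble(scaffold = chrom[i], pos = pos[i], individual = ind)
    }

    structure(
      list(maternal_mapping = mat, paternal_mapping = pat,
           depth_means = depth_means, truth = truth),
      class = "trio_tables"
    )
  })
}

#' @export
print.trio_tables <- function(x, ...) {
  cat("<trio_tables> ", nrow(x$maternal_mapping), " sites per mapping; ",
      nrow(x$truth$dnms), " planted DNM(s)\n", sep = "")
  invisible(x)
}
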