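# Copy-number decoding of binned read depth with a hidden Markov model.
# Hidden states are copy numbers 0..max_state; emissions are negative
# binomial (Poisson fallback when the baseline is underdispersed) with mean
# and variance scaled from the copy-number-two baseline.

#' Estimate the copy-number-two depth baseline from a track
#'
#' The copy-two peak is located as the mode of the trimmed per-bin count
#' histogram (unit bins lightly smoothed with a +/-2 moving average; ties
#' resolved to the lower count) -- robust against collapsed and zero-depth
#' regions that bias a plain mean. Because the mode of an overdispersed
#' count distribution sits below its mean, `mu2` is then refined as the
#' median of the bins within half to one-and-a-half times the mode, a
#' window that spans only the copy-two peak (the copy-one and copy-three
#' means fall on its edges). The baseline variance is taken over bins
#' within `mu2 +/- 3 * sqrt(mu2)`.
#'
#' @param track A `depth_track` (or tibble with a `depth` column).
#' @param trim Quantile pair trimmed off before locating the mode.
#' @return List with `mu2` and `var2`.
#' @export
estimate_baseline <- function(track, trim = c(0.01, 0.99)) {
  counts <- track$depth
  if (length(counts) < 1000L) {
    rlang::abort("baseline estimation needs at least 1000 bins.")
  }
  q <- quantile(counts, trim, names = FALSE)
  kept <- counts[counts >= q[1] & counts <= q[2]]
  tab <- tabulate(kept + 1L)           # unit bins over 0..max
  sm <- stats::filter(tab, rep(1 / 5, 5L), sides = 2)
  sm[is.na(sm)] <- 0
  peak <- which.max(sm) - 1L           # which.max takes the first (lower) tie
  win <- counts[counts >= 0.5 * peak & counts <= 1.5 * peak]
  mu2 <- if (length(win)) median(win) else as.numeric(peak)
  vwin <- counts[abs(counts - mu2) <= 3 * sqrt(mu2)]
  var2 <- if (length(vwin) > 1L) var(vwin) else 0
  list(mu2 = as.numeric(mu2), var2 = as.numeric(var2))
}

#' Emission parameters for one copy-number state
#'
#' Means scale linearly with copy number relative to the copy-two baseline:
#' `mu_c = (c/2) * mu2` for `c >= 1`, and `mu_0 = epsilon0 * mu2` so the
#' zero state keeps finite likelihoods. Variances scale as `(c/2) * var2`,
#' floored at `1.01 * mu_c` to keep the negative-binomial form valid.
#'
#' @param c Copy-number state (>= 0).
#' @param mu2,var2 Baseline mean and variance at copy number two.
#' @param epsilon0 Mean multiplier for the zero state (default 0.02).
#' @return List with `mu`, `var`, and negative-binomial `size` and `prob`
#'   (NA when the variance floor leaves the state effectively Poisson).
#' @export
nb_params <- function(c, mu2, var2, epsilon0 = 0.02) {
  if (mu2 <= 0) rlang::abort("`mu2` must be positive.")
  if (c < 0) rlang::abort("copy-number state must be >= 0.")
  mu <- if (c == 0) epsilon0 * mu2 else (c / 2) * mu2
  v <- max((c / 2) * var2, mu * 1.01)
  size <- mu^2 / (v - mu)
  prob <- mu / v
  list(mu = mu, var = v, size = size, prob = prob)
}

#' Construct a copy-number HMM
#'
#' States are copy numbers `0..max_state`. The transition matrix is sticky:
#' stay probability `1 - epsilon_transition` with the remainder split
#' uniformly among the other states, matching 100 bp bins against
#' multi-kilobase duplications. Emissions are negative binomial scaled from
#' the baseline via [nb_params()]; when `var2 <= mu2` the model falls back
#' to Poisson emissions.
#'
#' @param mu2,var2 Copy-two baseline mean and variance (see
#'   [estimate_baseline()]).
#' @param max_state Largest copy-number state (default 12).
#' @param epsilon_transition Total probability of leaving a state per bin
#'   (default 1e-4).
#' @param epsilon0 Zero-state mean multiplier (default 0.02).
#' @return A `cn_hmm` object.
#' @export
cn_hmm <- function(mu2, var2, max_state = 12, epsilon_transition = 1e-4,
                   epsilon0 = 0.02) {
  if (max_state < 2) rlang::abort("`max_state` must be >= 2.")
  if (mu2 <= 0) rlang::abort("`mu2` must be positive.")
  states <- 0:max_state
  poisson <- var2 <= mu2
  pars <- lapply(states, function(s) nb_params(s, mu2, max(var2, mu2), epsilon0))
  n <- length(states)
  trans <- matrix(epsilon_transition / (n - 1), n, n)
  diag(trans) <- 1 - epsilon_transition
  structure(list(states = states,
                 mu = vapply(pars, `[[`, numeric(1), "mu"),
                 var = vapply(pars, `[[`, numeric(1), "var"),
                 size = vapply(pars, `[[`, numeric(1), "size"),
                 poisson = poisson,
                 log_trans = log(trans),
                 log_init = rep(-log(n), n)),
            class = "cn_hmm")
}

#' @export
print.cn_hmm <- function(x, ...) {
  cat("<cn_hmm> states 0..", max(x$states), ", ",
      if (x$poisson) "Poisson" else "negative-binomial",
      " emissions, mu2 = ", format(x$mu[which(x$states == 2)]), "\n", sep = "")
  invisible(x)
}

# T x S matrix of emission log-densities
emission_loglik <- function(counts, hmm) {
  S <- length(hmm$states)
  out <- matrix(NA_real_, length(counts), S)
  for (s in seq_len(S)) {
    out[, s] <- if (hmm$poisson) {
      dpois(counts, lambda = hmm$mu[s], log = TRUE)
    } else {
      dnbinom(counts, size = hmm$size[s], mu = hmm$mu[s], log = TRUE)
    }
  }
  out
}

#' Viterbi decoding of a depth track into copy-number segments
#'
#' Computes the maximum-likelihood state path in log space per scaffold,
#' merges consecutive equal states into segments, and absorbs segments
#' shorter than `min_segment_bins` into whichever neighbouring state
#' explains the segment's bins with the higher emission likelihood.
#'
#' @param track A `depth_track` (tibble `scaffold`, `start`, `end`,
#'   `depth`).
#' @param hmm A [cn_hmm()].
#' @param min_segment_bins Minimum surviving segment length in bins
#'   (default 5).
#' @return A `cn_decode`: list with `path` (the track plus a `state`
#'   column), `segments` (tibble `scaffold`, `start`, `end`, `copy_number`,
#'   `mean_depth`, `n_bins`), `log_lik` of the decoded path and the `hmm`.
#' @export
viterbi_decode <- function(track, hmm, min_segment_bins = 5) {
  if (nrow(track) == 0L) rlang::abort("empty depth track.")
  paths <- vector("list", 0L)
  total_ll <- 0
  track <- arrange(as_tibble(track), .data$scaffold, .data$start)
  for (sc in unique(track$scaffold)) {
    sub <- filter(track, .data$scaffold == sc)
    em <- emission_loglik(sub$depth, hmm)
    if (any(!is.finite(em))) {
      bad <- which(!is.finite(em), arr.ind = TRUE)[1, 1]
      rlang::abort(sprintf("non-finite emission log-likelihood at bin %d of %s.",
                           bad, sc))
    }
    Tn <- nrow(em); S <- ncol(em)
    delta <- matrix(-Inf, Tn, S)
    psi <- matrix(0L, Tn, S)
    delta[1, ] <- hmm$log_init + em[1, ]
    if (Tn > 1) for (t in 2:Tn) {
      cand <- delta[t - 1, ] + hmm$log_trans   # S x S: from x to
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta[t, ] <- cand[cbind(psi[t, ], seq_len(S))] + em[t, ]
    }
    state_idx <- integer(Tn)
    state_idx[Tn] <- which.max(delta[Tn, ])
    if (Tn > 1) for (t in (Tn - 1):1) state_idx[t] <- psi[t + 1, state_idx[t + 1]]
    total_ll <- total_ll + max(delta[Tn, ])
    path <- hmm$states[state_idx]
    path <- absorb_short_segments(path, em, min_segment_bins, hmm$states)
    sub$state <- path
    paths[[sc]] <- sub
  }
  path_tbl <- bind_rows(paths)
  segments <- path_tbl |>
    group_by(.data$scaffold) |>
    mutate(seg = cumsum(c(1L, diff(.data$state) != 0L))) |>
    group_by(.data$scaffold, .data$seg) |>
    summarise(start = min(.data$start), end = max(.data$end),
              copy_number = .data$state[1],
              mean_depth = mean(.data$depth), n_bins = dplyr::n(),
              .groups = "drop") |>
    select(-"seg") |>
    arrange(.data$scaffold, .data$start)
  structure(list(path = path_tbl, segments = segments, log_lik = total_ll,
                 hmm = hmm),
            class = "cn_decode")
}

# Replace runs shorter than min_bins by the neighbouring state with higher
# summed emission log-likelihood over the run's bins; repeat to fixpoint.
absorb_short_segments <- function(path, em, min_bins, states) {
  if (min_bins <= 1L) return(path)
  repeat {
    r <- rle(path)
    # never absorb a run that is the whole scaffold
    if (length(r$lengths) <= 1L) return(path)
    short <- which(r$lengths < min_bins)
    if (length(short) == 0L) return(path)
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    lo <- ends[i] - r$lengths[i] + 1L
    hi <- ends[i]
    nbr <- c(if (i > 1L) r$values[i - 1L], if (i < length(r$values)) r$values[i + 1L])
    nbr <- unique(nbr)
    ll <- vapply(nbr, function(s) sum(em[lo:hi, match(s, states)]), numeric(1))
    path[lo:hi] <- nbr[which.max(ll)]
  }
}

#' @export
print.cn_decode <- function(x, ...) {
  collapsed <- sum(x$segments$copy_number > 2)
  cat("<cn_decode> ", nrow(x$path), " bins, ", nrow(x$segments),
      " segment(s) (", collapsed, " above copy 2), log-lik ",
      format(x$log_lik), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cn_decode <- function(x, ...) x$segments

#' @export
glance.cn_decode <- function(x, ...) {
  tibble(n_bins = nrow(x$path), n_segments = nrow(x$segments),
         collapsed_bases = sum((x$segments$end - x$segments$start)[
           x$segments$copy_number > 2]),
         log_lik = x$log_lik)
}

#' Bases missing from an assembly due to collapsed duplications
#'
#' For every decoded segment with copy number above the assembled copy
#' count, the missing sequence is
#' `length * (decoded - assembled) / assembled` -- each assembled copy
#' stands for `decoded / assembled` true copies.
#'
#' @param segments Segment tibble from [viterbi_decode()] (`tidy()` of a
#'   `cn_decode`).
#' @param assembled_copies Copies represented in the track: 2 for a
#'   combined diploid track (default), 1 for a single haplotype.
#' @return Estimated missing bases (bp).
#' @export
missing_bases <- function(segments, assembled_copies = 2) {
  if (assembled_copies <= 0) rlang::abort("`assembled_copies` must be positive.")
  len <- segments$end - segments$start
  sum(len * pmax(0, segments$copy_number - assembled_copies) / assembled_copies)
}

#' Read-depth check of duplicated gene copies
#'
#' A duplicated gene passes when the mean depth over each annotated copy is
#' at least `threshold_fraction` of the genome average -- a permissive
#' threshold chosen for recall: spurious copies in an assembly attract only
#' a fraction of the true depth. Genes with a copy covered by no bins are
#' flagged indeterminate and excluded from the denominator.
#'
#' @param gene_intervals Tibble `gene`, `scaffold`, `start`, `end` -- one
#'   row per annotated gene copy.
#' @param track A `depth_track`.
#' @param mean_depth Genome average depth (taken as given, not recomputed).
#' @param threshold_fraction Fraction of `mean_depth` each copy must reach
#'   (default 0.5); the comparison is `>=`.
#' @return A `busco_check`: list with `genes` (tibble `gene`, `status` in
#'   pass/fail/indeterminate, `min_copy_depth`), `n_pass`, `n_eval` and
#'   `percent_pass` (rounded to the nearest integer).
#' @export
busco_depth_check <- function(gene_intervals, track, mean_depth,
                              threshold_fraction = 0.5) {
  thr <- threshold_fraction * mean_depth
  per_copy <- gene_intervals |>
    mutate(.copy = dplyr::row_number()) |>
    rowwise() |>
    mutate(copy_depth = {
      sel <- track$scaffold == .data$scaffold &
        track$start < .data$end & track$end > .data$start
      if (any(sel)) mean(track$depth[sel]) else NA_real_
    }) |>
    ungroup()
  genes <- per_copy |>
    group_by(.data$gene) |>
    summarise(min_copy_depth = suppressWarnings(min(.data$copy_depth)),
              indeterminate = anyNA(.data$copy_depth), .groups = "drop") |>
    mutate(status = dplyr::case_when(
      .data$indeterminate ~ "indeterminate",
      .data$min_copy_depth >= thr ~ "pass",
      TRUE ~ "fail")) |>
    select("gene", "status", "min_copy_depth")
  n_ind <- sum(genes$status == "indeterminate")
  if (n_ind > 0) {
    rlang::inform(sprintf("%d gene(s) had a copy with no depth bins; excluded from the summary.", n_ind))
  }
  n_eval <- sum(genes$status != "indeterminate")
  n_pass <- sum(genes$status == "pass")
  structure(list(genes = genes, n_pass = n_pass, n_eval = n_eval,
                 percent_pass = if (n_eval > 0) round(100 * n_pass / n_eval) else NA_real_),
            class = "busco_check")
}

#' @export
print.busco_check <- function(x, ...) {
  cat("<busco_check> ", x$n_pass, "/", x$n_eval, " genes pass (",
      x$percent_pass, "%)\n", sep = "")
  invisible(x)
}

#' @export
tidy.busco_check <- function(x, ...) x$genes

#' @export
glance.busco_check <- function(x, ...) {
  tibble(n_pass = x$n_pass, n_eval = x$n_eval, percent_pass = x$percent_pass)
}
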