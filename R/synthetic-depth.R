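# Binned read-depth simulation with negative-binomial noise and planted
# collapsed duplications (proportionally elevated coverage).

#' Simulate a binned read-depth track over a genome
#'
#' Per-bin counts are drawn from a negative binomial with mean
#' `mean_depth * true_copies / assembled_copies` inside collapsed intervals
#' and `mean_depth` elsewhere. `dispersion` is the variance/mean ratio; a
#' value of 1 gives Poisson counts.
#'
#' @param genome A `syn_genome` (only scaffold lengths are used).
#' @param mean_depth Mean per-bin coverage at the baseline (copy-number 2)
#'   state.
#' @param dispersion Variance/mean ratio, >= 1.
#' @param bin_width Bin width in bp (default 100).
#' @param collapses Tibble with columns `scaffold`, `start`, `end`,
#'   `true_copies`, `assembled_copies` describing collapsed regions;
#'   `NULL` for none.
#' @param seed Integer RNG seed.
#' @return A `depth_track` tibble with columns `scaffold`, `start`, `end`,
#'   `depth`; bin width stored in `attr(, "bin_width")`.
#' @export
simulate_depth <- function(genome, mean_depth = 60, dispersion = 3,
                           bin_width = 100, collapses = NULL, seed = 1) {
  stopifnot(inherits(genome, "syn_genome"))
  assert_scalar_number(mean_depth, "mean_depth", min = 1e-9)
  assert_scalar_number(dispersion, "dispersion", min = 1)
  if (bin_width <= 0) rlang::abort("`bin_width` must be positive.")
  collapses <- collapses %||% tibble(scaffold = character(), start = integer(),
                                     end = integer(), true_copies = integer(),
                                     assembled_copies = integer())
  with_seed(seed, {
    bins <- purrr::map(names(genome$sequences), function(sc) {
      n <- nchar(genome$sequences[[sc]]) %/% bin_width
      if (n == 0L) return(NULL)
      start <- (seq_len(n) - 1L) * as.integer(bin_width)
      tibble(scaffold = sc, start = start, end = start + as.integer(bin_width))
    })
    track <- bind_rows(bins)
    mu <- rep(mean_depth, nrow(track))
    if (nrow(collapses)) {
      for (i in seq_len(nrow(collapses))) {
        sel <- track$scaffold == collapses$scaffold[i] &
          track$start >= collapses$start[i] & track$end <= collapses$end[i]
        mu[sel] <- mean_depth * collapses$true_copies[i] /
          collapses$assembled_copies[i]
      }
    }
    depth <- if (dispersion == 1) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = mu / (dispersion - 1))
    }
    track$depth <- as.integer(depth)
    structure(track, class = c("depth_track", class(track)),
              bin_width = as.integer(bin_width))
  })
}
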