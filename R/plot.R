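# ggplot2 views of the main result types.

#' @describeIn simulate_depth Plot a depth track, optionally overlaying
#'   decoded copy-number segments.
#' @param object A `depth_track`.
#' @param segments Optional segment tibble from [viterbi_decode()].
#' @param ... Unused.
#' @export
autoplot.depth_track <- function(object, segments = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$start, y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~scaffold, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "depth per bin")
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_depth, yend = .data$mean_depth,
                   colour = factor(.data$copy_number)),
      linewidth = 1.2, inherit.aes = FALSE) +
      ggplot2::labs(colour = "copy number")
  }
  p
}

#' @describeIn viterbi_decode Plot the decoded path over the depth bins.
#' @param object A `cn_decode`.
#' @param ... Unused.
#' @export
autoplot.cn_decode <- function(object, ...) {
  autoplot.depth_track(
    structure(object$path, class = c("depth_track", class(object$path))),
    segments = object$segments)
}

#' @describeIn summarize_sd Plot the identity histogram of a duplication
#'   set (duplicated bases per identity bin).
#' @param object An `sd_summary`.
#' @param ... Unused.
#' @export
autoplot.sd_summary <- function(object, ...) {
  ggplot2::ggplot(object$identity_histogram,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$bases)) +
    ggplot2::geom_col(fill = "steelblue", width = diff(
      object$identity_histogram$bin_low[1:2]) * 0.9) +
    ggplot2::labs(x = "pairwise identity", y = "aligned duplicated bases")
}

#' @describeIn size_spectrum Plot the per-class variant size spectrum with
#'   detected peaks marked.
#' @param object A `spectrum_summary`.
#' @param ... Unused.
#' @export
autoplot.spectrum_summary <- function(object, ...) {
  p <- ggplot2::ggplot(object$histogram,
                       ggplot2::aes(x = .data$bin_low, y = .data$n)) +
    ggplot2::geom_col(width = object$bin_width * 0.9, fill = "grey40") +
    ggplot2::facet_wrap(~class, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "variant size (bp)", y = "count")
  if (nrow(object$peaks)) {
    p <- p + ggplot2::geom_point(
      data = object$peaks,
      ggplot2::aes(x = .data$size, y = .data$n),
      colour = "red", shape = 25, fill = "red",
      position = ggplot2::position_nudge(y = 1))
  }
  p
}
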