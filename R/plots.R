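#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-position base-call composition
#'
#' One line per base symbol; `type = "fraction"` (default) normalises by
#' per-position coverage, `type = "count"` shows raw counts.
#'
#' @param object A `basecall_counts` tibble.
#' @param type `"fraction"` or `"count"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot basecall_counts
#' @export
autoplot.basecall_counts <- function(object, type = c("fraction", "count"), ...) {
  type <- match.arg(type)
  long <- tidyr::pivot_longer(object, dplyr::all_of(BASE_SYMBOLS),
                              names_to = "base", values_to = "count")
  if (type == "fraction") {
    long <- dplyr::mutate(long, value = .data$count / .data$coverage)
    ylab <- "fraction of calls"
  } else {
    long <- dplyr::mutate(long, value = .data$count)
    ylab <- "base calls"
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$value,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "read position", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-position mean quality profile
#'
#' @param object A `quality_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quality_profile
#' @export
autoplot.quality_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$mean_q)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "read position", y = "mean Phred quality") +
    ggplot2::theme_minimal()
}

#' Heat map of a pairwise positional KL divergence matrix
#'
#' @param object A `kl_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kl_matrix
#' @export
autoplot.kl_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$to, .data$from,
                                             fill = .data$kl)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "KL (bits)") +
    ggplot2::labs(x = "position j (encoding)", y = "position i (true)") +
    ggplot2::theme_minimal()
}

#' Heat map of KL effect sizes against the null calibration
#'
#' @param object An `effect_size_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effect_size_matrix
#' @export
autoplot.effect_size_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$to, .data$from,
                                             fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "z") +
    ggplot2::labs(x = "position j", y = "position i") +
    ggplot2::theme_minimal()
}
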