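# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_histogram geom_segment labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Sliding-window Ka/Ks profile plot
#'
#' Ka/Ks along the codon alignment with the neutral expectation (ratio 1)
#' marked; windows with undefined ratios (Ks = 0) are dropped from the line.
#'
#' @param object A `kaks_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kaks_profile
#' @export
autoplot.kaks_profile <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$ratio))
  ggplot(d, aes(x = (.data$start + .data$end) / 2, y = .data$ratio)) +
    geom_line(colour = "steelblue") +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    labs(x = "alignment position (bp, window midpoint)", y = "Ka/Ks",
         title = "Sliding-window selection pressure") +
    theme_minimal()
}

#' Ks distribution of dated blocks or pairs
#'
#' Histogram of synonymous distances — the classic duplication-age spectrum
#' in which whole-genome and recent large-scale duplication events appear as
#' peaks.
#'
#' @param ks Numeric vector of Ks values, or a dated block table with a
#'   `mean_ks` column, or a pair table with a `Ks` column.
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot.
#' @export
plot_ks_distribution <- function(ks, binwidth = 0.05) {
  if (is.data.frame(ks)) {
    ks <- if ("mean_ks" %in% names(ks)) ks$mean_ks else ks$Ks
  }
  d <- tibble(ks = ks[is.finite(ks)])
  ggplot(d, aes(x = .data$ks)) +
    geom_histogram(binwidth = binwidth, fill = "steelblue", colour = "white") +
    labs(x = "Ks (synonymous substitutions/site)", y = "gene pairs",
         title = "Synonymous-distance distribution") +
    theme_minimal()
}

#' Ka/Ks versus Ks scatter of duplicated pairs
#'
#' @param pairs Tibble with `Ks` and `ratio` columns (e.g. the pipeline's
#'   `pair_kaks`).
#' @return A ggplot.
#' @export
plot_selection_pressure <- function(pairs) {
  d <- dplyr::filter(as_tibble(pairs), is.finite(.data$Ks),
                     !is.na(.data$ratio))
  ggplot(d, aes(x = .data$Ks, y = .data$ratio)) +
    geom_point(colour = "steelblue", alpha = 0.7) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    labs(x = "Ks", y = "Ka/Ks", title = "Selection pressure on duplicated pairs") +
    theme_minimal()
}

#' Microsynteny map of a block
#'
#' The two regions as horizontal gene tracks with conserved pairs linked.
#'
#' @param object A `synteny_block`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synteny_block
#' @export
autoplot.synteny_block <- function(object, ...) {
  mk <- function(region, y) {
    region$flanking %>%
      mutate(y = y, label = paste0(region$species_id, ":", region$chromosome))
  }
  tracks <- bind_rows(mk(object$region_a, 1), mk(object$region_b, 0))
  links <- object$pairs
  ggplot() +
    geom_segment(data = tracks,
                 aes(x = .data$start, xend = .data$end, y = .data$y,
                     yend = .data$y),
                 linewidth = 4, colour = "grey70") +
    geom_segment(data = links,
                 aes(x = (.data$start_a + .data$end_a) / 2, y = 1,
                     xend = (.data$start_b + .data$end_b) / 2, yend = 0),
                 colour = "steelblue", alpha = 0.8) +
    labs(x = "position (bp)", y = NULL,
         title = paste(object$region_a$anchor, "&", object$region_b$anchor)) +
    theme_minimal()
}
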