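#' Cohort skip-transcript matrix plot
#'
#' Subjects-by-signatures tile plot with the screen's fraction bins
#' (below report threshold, report-flag, flag-high, above high), the display
#' used to survey the landscape of alternative transcripts across a cohort.
#'
#' @param object A [flag_candidates()] `cohort_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_screen <- function(object, ...) {
  q <- object$quants |>
    mutate(subject_id = factor(.data$subject_id,
                               levels = object$roster$subject_id))
  ggplot2::ggplot(q, ggplot2::aes(x = .data$label, y = .data$subject_id,
                                  fill = .data$bin)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(
      values = setNames(c("grey95", "grey75", "grey50", "grey20"),
                        fraction_bin_labels(object$config)),
      drop = FALSE, name = "fraction") +
    ggplot2::labs(x = "skip signature", y = NULL,
                  title = "Exon-skipping transcripts across the cohort") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cohort_screen
#' @param x A `cohort_screen`.
#' @param y Unused.
#' @export
plot.cohort_screen <- function(x, y, ...) print(autoplot.cohort_screen(x, ...))

#' Trio support plot for a deletion call
#'
#' Split-read and discordant-pair support per trio member, the evidence
#' pattern that distinguishes a de novo deletion (child-only support) from an
#' inherited one.
#'
#' @param object A [call_deletion()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deletion_call <- function(object, ...) {
  d <- object$members |>
    tidyr::pivot_longer(c("split_support", "discordant_support"),
                        names_to = "evidence", values_to = "reads")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$member, y = .data$reads,
                                  fill = .data$evidence)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = object$label,
                  subtitle = sprintf("inheritance: %s", object$inheritance)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
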