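# ggplot2 views of the main result types. These are quick QC figures, not
# publication graphics.

#' Plot the MRSD distribution of a scored table
#'
#' Histogram of log10 MRSD for feasible transcripts, annotated with the
#' count of unfeasible transcripts.
#'
#' @param object An `mrsd_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrsd_table
#' @export
autoplot.mrsd_table <- function(object, ...) {
  fin <- object[is.finite(object$mrsd_millions), , drop = FALSE]
  n_unf <- sum(!is.finite(object$mrsd_millions), na.rm = TRUE)
  ggplot2::ggplot(fin, ggplot2::aes(x = log10(.data$mrsd_millions), fill = .data$class)) +
    ggplot2::geom_histogram(bins = 40, colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(
      x = "log10 MRSD (millions of reads)", y = "transcripts",
      title = sprintf(
        "MRSD distribution (%d feasible, %d unfeasible)", nrow(fin), n_unf
      ),
      subtitle = sprintf(
        "r = %s, p = %s, m = %s, n = %s", object$r[1], object$p[1],
        object$m[1], object$n_samples[1]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an MRSD-vs-TPM comparison
#'
#' Log-log scatter of MRSD against TPM with the fitted line.
#'
#' @param object An `mrsd_tpm_fit` from [compare_tpm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrsd_tpm_fit
#' @export
autoplot.mrsd_tpm_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = log10(.data$tpm), y = log10(.data$mrsd_millions))
  ) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "firebrick") +
    ggplot2::labs(
      x = "log10 TPM", y = "log10 MRSD (millions of reads)",
      title = sprintf(
        "MRSD vs TPM: r^2 = %.3f, slope = %.2f (n = %d)",
        object$r_squared, object$slope, object$n
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot ranked splice events
#'
#' Read count against rank, distinguishing singleton from non-singleton
#' events.
#'
#' @param events Ranked event tibble from [rank_events()] or
#'   [detect_events()].
#' @return A ggplot object.
#' @export
plot_event_ranks <- function(events) {
  stopifnot("rank" %in% names(events))
  ggplot2::ggplot(
    events,
    ggplot2::aes(
      x = .data$rank, y = .data$read_count,
      colour = ifelse(.data$singleton, "singleton", "non-singleton")
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "supporting reads", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap background medians
#'
#' Median retained singleton / non-singleton event counts by control-cohort
#' size.
#'
#' @param object A `bootstrap_summary` from [bootstrap_background()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bootstrap_summary
#' @export
autoplot.bootstrap_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("median_singletons", "median_non_singletons"),
    names_to = "type", values_to = "median_events"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = factor(.data$control_size), y = .data$median_events,
      group = .data$type, colour = .data$type
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "control cohort size", y = "median retained events", colour = NULL) +
    ggplot2::theme_minimal()
}
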