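# ggplot2 methods for the main result types

#' Plot per-gene allelic bias with confidence intervals
#' @param object An `allele_bias` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allele_bias
#' @export
autoplot.allele_bias <- function(object, ...) {
  df <- filter(as_tibble(object), .data$estimable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(y = "strain-A allelic bias (95% CI)", x = NULL,
                  title = "Per-gene allelic bias") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null distribution with the observed count
#' @param object An `enrichment_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_test
#' @export
autoplot.enrichment_test <- function(object, ...) {
  df <- tibble(null_count = object$null_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "candidate genes overlapping random matched regions",
      y = "permutations",
      title = sprintf("Observed = %d, empirical p = %.3g (%d permutations)",
                      object$observed, object$p_empirical, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Plot glucose-tolerance curves by group
#'
#' @param curves GTT tibble (`animal`, `group`, `time`, `glucose`).
#' @return A ggplot object: per-animal curves with the group mean overlaid.
#' @export
plot_gtt <- function(curves) {
  ggplot2::ggplot(as_tibble(curves),
                  ggplot2::aes(x = .data$time, y = .data$glucose,
                               colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$animal), alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1.2) +
    ggplot2::labs(x = "minutes post-injection", y = "glucose (mg/dL)",
                  title = "Glucose tolerance test") +
    ggplot2::theme_minimal()
}
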