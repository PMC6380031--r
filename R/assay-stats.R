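#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, technical replicates are averaged on the Ct scale, then
#' `dCt = mean(target Ct) - mean(reference Ct)`. Each sample's `ddCt` is its
#' `dCt` minus the mean `dCt` of the control group, and relative expression
#' is `efficiency^(-ddCt)` (default efficiency 2, i.e. the classic
#' 2^-ddCt with 100% amplification). By construction the control group's
#' relative expression has geometric mean exactly 1.
#'
#' @param records Ct tibble with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct` (e.g. from [simulate_ct_table()] or a TSV).
#' @param control_group Name of the control group.
#' @param reference_gene Name of the normalizer gene (e.g. "Atp5b").
#' @param target_gene Target gene; default: the unique non-reference gene.
#' @param efficiency Amplification efficiency as a fold-per-cycle base.
#' @return A `ddct_tbl` tibble, one row per sample: `sample`, `group`,
#'   `delta_ct`, `delta_delta_ct`, `rel_expr`.
#' @examples
#' ct <- tibble::tibble(
#'   sample = rep(c("c1", "t1"), each = 2),
#'   group = rep(c("control", "treated"), each = 2),
#'   gene = rep(c("Hamp", "Atp5b"), 2),
#'   replicate = 1L,
#'   ct = c(22, 18, 20, 18))
#' delta_delta_ct(ct, "control", "Atp5b")  # treated fold = 4
#' @export
delta_delta_ct <- function(records, control_group, reference_gene = "Atp5b",
                           target_gene = NULL, efficiency = 2) {
  records <- as_tibble(records)
  if (!control_group %in% records$group) {
    abort_param(sprintf("control group '%s' not found", control_group))
  }
  if (!reference_gene %in% records$gene) {
    abort_param(sprintf("reference gene '%s' not found", reference_gene))
  }
  target_gene <- target_gene %||% setdiff(unique(records$gene), reference_gene)
  if (length(target_gene) != 1L) {
    abort_param("specify `target_gene`: more than one non-reference gene present")
  }
  missing_ref <- records |>
    group_by(.data$sample) |>
    summarise(has_ref = any(.data$gene == reference_gene),
              has_tgt = any(.data$gene == target_gene)) |>
    filter(!.data$has_ref | !.data$has_tgt)
  if (nrow(missing_ref) > 0) {
    abort_validation(sprintf(
      "samples missing a %s measurement: %s",
      ifelse(missing_ref$has_ref[1], "target", "reference-gene"),
      paste(missing_ref$sample, collapse = ", ")))
  }
  per_sample <- records |>
    filter(.data$gene %in% c(target_gene, reference_gene)) |>
    group_by(.data$sample, .data$group, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct") |>
    mutate(delta_ct = .data[[target_gene]] - .data[[reference_gene]])
  ctrl_mean <- mean(per_sample$delta_ct[per_sample$group == control_group])
  out <- per_sample |>
    mutate(delta_delta_ct = .data$delta_ct - ctrl_mean,
           rel_expr = efficiency^(-.data$delta_delta_ct)) |>
    select("sample", "group", "delta_ct", "delta_delta_ct", "rel_expr")
  structure(out, class = c("ddct_tbl", class(out)),
            control_group = control_group, reference_gene = reference_gene,
            target_gene = target_gene, efficiency = efficiency)
}

#' @method glance ddct_tbl
#' @export
glance.ddct_tbl <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              mean_fold = mean(.data$rel_expr),
              geomean_fold = exp(mean(log(.data$rel_expr))),
              sd_fold = sd(.data$rel_expr), .groups = "drop")
}

#' Glucose-tolerance-test area under the curve
#'
#' Trapezoidal integral of glucose over the recorded times, per animal. The
#' total AUC integrates the raw curve; the incremental AUC subtracts each
#' animal's baseline (t = 0) value first and, when `floor_negative = TRUE`,
#' clips below-baseline excursions at zero before integrating.
#'
#' @param curves Tibble `animal`, `time` (min, starting at 0), `glucose`
#'   (mg/dL); extra columns such as `group` are carried through.
#' @param floor_negative Clip negative excursions in the incremental AUC.
#' @return Tibble per animal: `auc_total`, `auc_incremental` (mg/dL * min).
#' @examples
#' g <- tibble::tibble(animal = "m1", time = c(0, 15, 30, 60, 120),
#'                     glucose = c(100, 200, 200, 150, 100))
#' gtt_auc(g)$auc_total  # 18000
#' @export
gtt_auc <- function(curves, floor_negative = TRUE) {
  curves <- as_tibble(curves)
  keep <- intersect(c("group"), names(curves))
  curves |>
    group_by(dplyr::across(dplyr::all_of(c("animal", keep)))) |>
    summarise(
      auc_total = {
        if (is.unsorted(.data$time, strictly = TRUE)) {
          abort_validation("times must be strictly increasing within an animal")
        }
        if (dplyr::n() < 2) abort_param("need at least two timepoints")
        pracma::trapz(.data$time, .data$glucose)
      },
      auc_incremental = {
        exc <- .data$glucose - .data$glucose[1]
        if (floor_negative) exc <- pmax(exc, 0)
        pracma::trapz(.data$time, exc)
      },
      .groups = "drop"
    )
}

grubbs_critical <- function(n, alpha) {
  t2 <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

#' Grubbs outlier screen
#'
#' Two-sided Grubbs test: the maximum studentized deviation
#' `G = max |x - mean(x)| / sd(x)` is compared against the t-based critical
#' value at level `alpha`. By default a single pass is performed (the
#' classical single-outlier test); `max_outliers > 1` repeats
#' remove-and-retest. With fewer than 3 values or zero standard deviation
#' the test is not applicable and nothing is removed.
#'
#' @param values Numeric vector.
#' @param alpha Significance level.
#' @param max_outliers Cap on iterative removals.
#' @return A `grubbs_test` object: list with `outlier_indices` (positions in
#'   the input), `cleaned` values, per-iteration `statistic` and
#'   `critical_value`, `alpha`, and `applicable`.
#' @examples
#' grubbs_screen(c(1.0, 1.1, 0.9, 1.05, 8.0))$outlier_indices  # 5
#' @export
grubbs_screen <- function(values, alpha = 0.05, max_outliers = 1L) {
  alpha <- check_prob(alpha, "alpha")
  max_outliers <- check_count(max_outliers, "max_outliers")
  idx <- seq_along(values)
  removed <- integer(0)
  stat <- numeric(0); crit <- numeric(0)
  applicable <- length(values) >= 3 && sd(values) > 0
  x <- values
  if (applicable) {
    for (k in seq_len(max_outliers)) {
      n <- length(x)
      if (n < 3 || sd(x) == 0) break
      g <- max(abs(x - mean(x))) / sd(x)
      gc <- grubbs_critical(n, alpha)
      stat <- c(stat, g); crit <- c(crit, gc)
      if (g <= gc) break
      worst <- which.max(abs(x - mean(x)))
      removed <- c(removed, idx[worst])
      idx <- idx[-worst]
      x <- x[-worst]
    }
  }
  structure(
    list(outlier_indices = removed, cleaned = x,
         statistic = stat, critical_value = crit,
         alpha = alpha, applicable = applicable, n = length(values)),
    class = "grubbs_test"
  )
}

#' @export
print.grubbs_test <- function(x, ...) {
  if (!x$applicable) {
    cat("Grubbs screen: not applicable (n < 3 or zero variance)\n")
  } else if (length(x$outlier_indices) == 0) {
    cat(sprintf("Grubbs screen: no outlier (G = %.3f, crit = %.3f, alpha = %g)\n",
                x$statistic[1], x$critical_value[1], x$alpha))
  } else {
    cat(sprintf("Grubbs screen: removed index %s (alpha = %g)\n",
                paste(x$outlier_indices, collapse = ", "), x$alpha))
  }
  invisible(x)
}

#' @rdname grubbs_screen
#' @param x A `grubbs_test` object.
#' @param ... Unused.
#' @method tidy grubbs_test
#' @export
tidy.grubbs_test <- function(x, ...) {
  k <- length(x$statistic)
  tibble(iteration = seq_len(k), statistic = x$statistic,
         critical_value = x$critical_value,
         removed_index = c(x$outlier_indices,
                           rep(NA_integer_, k - length(x$outlier_indices))))
}

#' @rdname grubbs_screen
#' @method glance grubbs_test
#' @export
glance.grubbs_test <- function(x, ...) {
  tibble(n = x$n, n_outliers = length(x$outlier_indices),
         alpha = x$alpha, applicable = x$applicable)
}

#' Normality-gated log10 transform
#'
#' Screens a phenotype vector with a Shapiro-Wilk test; if normality is
#' rejected at `alpha` the values are log10-transformed, otherwise returned
#' untouched. The decision, test statistic and level are recorded so every
#' report can state what was done. Non-positive values with a transform
#' indicated raise an error (no silent offsets).
#'
#' @param values Numeric vector.
#' @param alpha Level of the normality screen.
#' @return A `transform_decision` list: `values` (possibly transformed),
#'   `transformed` (logical), `statistic`, `p_value`, `alpha`.
#' @export
log10_policy <- function(values, alpha = 0.05) {
  alpha <- check_prob(alpha, "alpha")
  sw <- shapiro.test(values)
  transform <- sw$p.value < alpha
  if (transform && any(values <= 0)) {
    abort_param(paste(
      "log10 transform indicated but values <= 0 are present;",
      "offset or exclude them explicitly before calling"))
  }
  structure(
    list(values = if (transform) log10(values) else values,
         transformed = transform,
         statistic = unname(sw$statistic), p_value = sw$p.value,
         alpha = alpha),
    class = "transform_decision"
  )
}

#' @export
print.transform_decision <- function(x, ...) {
  cat(sprintf(
    "log10 policy: %s (Shapiro-Wilk W = %.4f, p = %.3g, alpha = %g)\n",
    if (x$transformed) "transformed" else "left untransformed",
    x$statistic, x$p_value, x$alpha))
  invisible(x)
}
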