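#' Simulate a qPCR Ct table with planted group fold-changes
#'
#' Generates per-replicate Ct values for a target gene and a reference gene
#' (no group effect) such that a group's target Ct differs from the control
#' group's by `-log2(fold_change)`, plus Gaussian noise of SD `ct_noise_sd`
#' cycles. With zero noise the delta-delta-Ct method recovers each planted
#' fold exactly.
#'
#' @param groups Tibble with columns `group` and `fold_change`; exactly one
#'   group must have `fold_change == 1` semantics as control (pass its name
#'   via `control_group`, default the first group).
#' @param config A [sim_config()] (uses `ct_noise_sd` and the seed).
#' @param control_group Name of the control group.
#' @param n_samples Biological replicates per group.
#' @param n_replicates Technical replicates per sample (assays in duplicate).
#' @param target_gene,reference_gene Gene labels used in the output.
#' @param base_target_ct,base_reference_ct Control-group mean Ct values.
#' @return Tibble `sample`, `group`, `gene`, `replicate`, `ct` covering both
#'   genes for every sample.
#' @export
simulate_ct_table <- function(groups, config,
                              control_group = groups$group[1],
                              n_samples = 6L, n_replicates = 2L,
                              target_gene = "target",
                              reference_gene = "reference",
                              base_target_ct = 24, base_reference_ct = 20) {
  stopifnot(inherits(config, "sim_config"))
  groups <- as_tibble(groups)
  if (nrow(groups) < 1L) abort_param("`groups` must contain at least one group")
  if (any(groups$fold_change <= 0)) abort_param("fold changes must be positive")
  if (!control_group %in% groups$group) {
    abort_param(sprintf("control group '%s' not present", control_group))
  }
  n_samples <- check_count(n_samples, "n_samples")
  n_replicates <- check_count(n_replicates, "n_replicates")
  with_stream_seed(config$seed, "ct", {
    ctrl_fold <- groups$fold_change[groups$group == control_group][1]
    purrr::map_dfr(seq_len(nrow(groups)), function(g) {
      # shift relative to control so the control group sits at fold 1
      shift <- -log2(groups$fold_change[g] / ctrl_fold)
      purrr::map_dfr(seq_len(n_samples), function(s) {
        id <- sprintf("%s_s%02d", groups$group[g], s)
        tibble(
          sample = id,
          group = groups$group[g],
          gene = rep(c(target_gene, reference_gene), each = n_replicates),
          replicate = rep(seq_len(n_replicates), 2L),
          ct = c(base_target_ct + shift + rnorm(n_replicates, 0, config$ct_noise_sd),
                 base_reference_ct + rnorm(n_replicates, 0, config$ct_noise_sd))
        )
      })
    })
  })
}

#' Simulate glucose-tolerance-test curves
#'
#' Emulates an intraperitoneal GTT: glucose at baseline (t = 0) then at 15,
#' 30, 60 and 120 min post-injection. Each animal's curve is baseline plus a
#' peak-and-decay excursion `peak * (t/t_peak) * exp(1 - t/t_peak)` (maximum
#' `peak` at `t_peak`), with Gaussian noise of SD `gtt_noise_sd` mg/dL,
#' floored at 1 mg/dL.
#'
#' @param groups Tibble with columns `group`, `baseline` (mg/dL), `peak`
#'   (mg/dL excursion) and optionally `n_animals` (default 8).
#' @param config A [sim_config()] (uses `gtt_noise_sd` and the seed).
#' @param t_peak Time of the excursion maximum in minutes.
#' @param times Sampling times in minutes.
#' @return Tibble `animal`, `group`, `time`, `glucose`.
#' @export
simulate_gtt_table <- function(groups, config, t_peak = 30,
                               times = c(0, 15, 30, 60, 120)) {
  stopifnot(inherits(config, "sim_config"))
  groups <- as_tibble(groups)
  if (!all(c("group", "baseline", "peak") %in% names(groups))) {
    abort_param("`groups` needs columns group, baseline, peak")
  }
  if (!"n_animals" %in% names(groups)) groups$n_animals <- 8L
  with_stream_seed(config$seed, "gtt", {
    purrr::map_dfr(seq_len(nrow(groups)), function(g) {
      purrr::map_dfr(seq_len(groups$n_animals[g]), function(a) {
        excursion <- groups$peak[g] * (times / t_peak) * exp(1 - times / t_peak)
        tibble(
          animal = sprintf("%s_m%02d", groups$group[g], a),
          group = groups$group[g],
          time = times,
          glucose = pmax(1, groups$baseline[g] + excursion +
                           rnorm(length(times), 0, config$gtt_noise_sd))
        )
      })
    })
  })
}
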