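#' Assign reads to parental haplotypes at diagnostic sites
#'
#' For each read, the read sequence is compared base-by-base against each
#' strain haplotype, restricted to SNV-type diagnostic sites falling inside
#' the read's span on the reference frame. The haplotype with fewer
#' mismatches wins; equal mismatch counts, or zero covered diagnostic sites,
#' give an `ambiguous` call — a tie is never forced to a haplotype
#' (the analogue of disallowing multimapping). Indel-type diagnostic sites
#' shift local alignment rather than offering a clean base comparison and are
#' not scored.
#'
#' @param reads Tibble with `read_id`, `seq`, `ref_start`, `ref_end`
#'   (0-based half-open span on the reference frame), e.g. from
#'   [simulate_reads()] with maps supplied.
#' @param hap_a,hap_b Haplotype sequences (same frame as the maps).
#' @param sites Diagnostic sites from [diagnostic_sites()], 1-based `pos` on
#'   the reference frame, with `allele_a`, `allele_b`, `type`.
#' @param map_a,map_b [coord_map]s from the reference frame to each
#'   haplotype; identity maps assumed when `NULL`.
#' @return Tibble `read_id`, `call` (`"strainA"`, `"strainB"`,
#'   `"ambiguous"`), `n_diagnostic_covered`, `mismatches_vs_a`,
#'   `mismatches_vs_b`.
#' @export
assign_reads <- function(reads, hap_a, hap_b, sites,
                         map_a = NULL, map_b = NULL) {
  reads <- as_tibble(reads)
  if (nrow(reads) > 0 && any(nchar(reads$seq) == 0)) {
    abort_param("degenerate (empty) read sequence")
  }
  id_map <- new_coord_map(tibble(chrom = character(0), threshold = integer(0),
                                 delta = integer(0), fp_start = integer(0),
                                 fp_end = integer(0)))
  map_a <- map_a %||% id_map
  map_b <- map_b %||% id_map
  n <- nrow(reads)
  mm_a <- integer(n); mm_b <- integer(n); covered <- integer(n)
  snv <- filter(as_tibble(sites), .data$type == "snv")
  if (n > 0 && nrow(snv) > 0) {
    ch <- snv$chrom[1] %||% "region"
    rlen <- nchar(reads$seq)
    # read start boundary lifted onto each haplotype frame once
    a0 <- lift_positions(map_a, ch, reads$ref_start, side = "start")
    b0 <- lift_positions(map_b, ch, reads$ref_start, side = "start")
    for (k in seq_len(nrow(snv))) {
      p <- snv$pos[k]                     # 1-based reference position
      in_span <- reads$ref_start < p & p <= reads$ref_end
      if (!any(in_span)) next
      covered[in_span] <- covered[in_span] + 1L
      pa <- lift_positions(map_a, ch, p - 1L, side = "start") + 1L
      pb <- lift_positions(map_b, ch, p - 1L, side = "start") + 1L
      base_a <- substr(hap_a, pa, pa)
      base_b <- substr(hap_b, pb, pb)
      off_a <- pa - a0
      off_b <- pb - b0
      ok_a <- in_span & off_a >= 1L & off_a <= rlen
      ok_b <- in_span & off_b >= 1L & off_b <= rlen
      rb_a <- substr(reads$seq[ok_a], off_a[ok_a], off_a[ok_a])
      rb_b <- substr(reads$seq[ok_b], off_b[ok_b], off_b[ok_b])
      mm_a[ok_a] <- mm_a[ok_a] + (rb_a != base_a)
      mm_b[ok_b] <- mm_b[ok_b] + (rb_b != base_b)
    }
  }
  call <- rep("ambiguous", n)
  call[covered > 0 & mm_a < mm_b] <- "strainA"
  call[covered > 0 & mm_b < mm_a] <- "strainB"
  tibble(read_id = reads$read_id, call = call,
         n_diagnostic_covered = covered,
         mismatches_vs_a = mm_a, mismatches_vs_b = mm_b)
}

#' Count haplotype-assigned reads per gene
#'
#' A read increments a gene's haplotype counter iff its half-open span
#' overlaps the gene interval by at least one base. Ambiguous reads are
#' tallied separately and excluded from the haplotype counters; genes with
#' no reads are reported with zeros.
#'
#' @param reads Tibble with `read_id`, `chrom` (optional if single), and
#'   `ref_start`/`ref_end` spans.
#' @param assignments Output of [assign_reads()].
#' @param genes Gene interval tibble (`chrom`, `start`, `end`, `name`).
#' @return Tibble `gene`, `n_a`, `n_b`, `n_ambiguous`.
#' @export
count_reads_per_gene <- function(reads, assignments, genes) {
  reads <- as_tibble(reads)
  genes <- as_tibble(genes)
  df <- left_join(reads, assignments, by = "read_id")
  if (!"chrom" %in% names(df)) df$chrom <- genes$chrom[1]
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(g) {
    hit <- df$chrom == genes$chrom[g] &
      overlaps_halfopen(df$ref_start, df$ref_end, genes$start[g], genes$end[g])
    tibble(
      gene = genes$name[g],
      n_a = sum(hit & df$call == "strainA"),
      n_b = sum(hit & df$call == "strainB"),
      n_ambiguous = sum(hit & df$call == "ambiguous")
    )
  })
  out
}

#' Upper-quartile normalization of a count matrix
#'
#' Scales each sample so that the 75th percentile of its nonzero gene counts
#' equals the geometric mean of those percentiles across samples; the scale
#' factors are returned alongside the normalized matrix.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns.
#' @param p Quantile used (default 0.75).
#' @return List with `normalized` (matrix) and `factors` (named per-sample
#'   divisors).
#' @export
uq_normalize <- function(counts, p = 0.75) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1) abort_param("`counts` needs at least one sample")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  q <- vapply(seq_len(ncol(counts)), function(j) {
    nz <- counts[counts[, j] > 0, j]
    if (length(nz) == 0) {
      abort_validation(sprintf("sample '%s' has no nonzero counts", colnames(counts)[j]))
    }
    quantile(nz, p, names = FALSE)
  }, numeric(1))
  target <- exp(mean(log(q)))
  factors <- setNames(q / target, colnames(counts))
  list(normalized = sweep(counts, 2, factors, "/"), factors = factors)
}

#' Per-gene allelic bias with an exact binomial test
#'
#' The allelic bias of a gene is the proportion of haplotype-assigned reads
#' carrying the strain-A haplotype, `n_a / (n_a + n_b)` (ambiguous reads
#' carry no allelic information and are excluded from the denominator, but
#' reported). Deviation from the balanced expectation of 0.5 is tested with
#' a two-sided exact binomial test and a Clopper-Pearson 95% interval; a
#' `mid_p` variant halves the probability of the observed count to
#' counteract discreteness.
#'
#' @param counts Tibble with `gene`, `n_a`, `n_b` (e.g. from
#'   [count_reads_per_gene()]); other columns are preserved.
#' @param mid_p Use the mid-p two-sided binomial p-value.
#' @param conf_level Confidence level of the Clopper-Pearson interval.
#' @return An `allele_bias` tibble adding `bias`, `p_value`, `ci_low`,
#'   `ci_high` and `estimable`; genes with zero assigned reads are returned
#'   with `estimable = FALSE` and `NA` statistics rather than silent NaNs.
#' @examples
#' allele_bias(tibble::tibble(gene = "g", n_a = 30, n_b = 10))
#' @export
allele_bias <- function(counts, mid_p = FALSE, conf_level = 0.95) {
  counts <- as_tibble(counts)
  res <- purrr::pmap_dfr(
    list(counts$n_a, counts$n_b),
    function(na, nb) {
      tot <- na + nb
      if (tot == 0) {
        return(tibble(bias = NA_real_, p_value = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, estimable = FALSE))
      }
      bt <- binom.test(na, tot, p = 0.5, conf.level = conf_level)
      p <- if (mid_p) {
        lo <- pbinom(na - 1, tot, 0.5) + 0.5 * dbinom(na, tot, 0.5)
        hi <- pbinom(na, tot, 0.5, lower.tail = FALSE) + 0.5 * dbinom(na, tot, 0.5)
        min(1, 2 * min(lo, hi))
      } else {
        bt$p.value
      }
      tibble(bias = na / tot, p_value = p,
             ci_low = bt$conf.int[1], ci_high = bt$conf.int[2],
             estimable = TRUE)
    }
  )
  out <- dplyr::bind_cols(counts, res)
  class(out) <- c("allele_bias", class(out))
  out
}

#' Two-group comparison of per-animal allelic bias
#'
#' Cross-animal significance for allelic imbalance: a plain two-sample
#' t-test on per-animal bias values (Welch by default).
#'
#' @param data Tibble with one bias value per animal.
#' @param bias_col,group_col Column names.
#' @param ... Passed to [stats::t.test()].
#' @return One-row tibble `estimate_diff`, `statistic`, `p_value`, `df`.
#' @export
compare_bias_groups <- function(data, bias_col = "bias", group_col = "group", ...) {
  f <- stats::as.formula(paste(bias_col, "~", group_col))
  tt <- stats::t.test(f, data = data, ...)
  tibble(estimate_diff = unname(diff(rev(tt$estimate))),
         statistic = unname(tt$statistic),
         p_value = tt$p.value, df = unname(tt$parameter))
}
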