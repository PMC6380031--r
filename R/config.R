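#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults describe a small two-strain mouse-cross study: a
#' multi-chromosome toy genome, per-strain SNV/indel sets dense enough to give
#' tens of diagnostic sites per gene-scale region, F1-hybrid reads with a 75%
#' allelic fraction at the focal gene, candidate-gene/QTL interval sets with a
#' tunable enrichment level, qPCR Ct tables and glucose-tolerance curves
#' sampled at 0/15/30/60/120 min.
#'
#' @param seed Integer seed; every generator derives its own stream from it,
#'   so identical config + seed gives byte-identical outputs.
#' @param n_chromosomes Number of chromosomes in the synthetic reference.
#' @param chrom_length Length of each chromosome in bases.
#' @param snv_rate Per-base probability of a strain SNV (per strain).
#' @param indel_rate Per-base probability of a short indel (per strain).
#' @param max_indel_len Maximum inserted/deleted length in bases.
#' @param n_genes Number of gene intervals to place.
#' @param gene_len_range Length-2 range of gene lengths (bases).
#' @param n_candidate_genes Number of genes designated as candidates
#'   (e.g. iron-homeostasis genes) for the enrichment test.
#' @param n_qtl Number of disjoint QTL intervals.
#' @param qtl_len_range Length-2 range of QTL lengths (bases).
#' @param enrichment_fraction Proportion of candidate genes forced to
#'   intersect a QTL; `NA` places candidates uniformly, independent of QTL
#'   (the null configuration).
#' @param allelic_fraction Probability a simulated F1 read originates from the
#'   strain-A haplotype.
#' @param n_reads Number of reads simulated per gene region.
#' @param read_len Read length in bases.
#' @param seq_error_rate Per-base sequencing error probability.
#' @param ct_noise_sd Gaussian noise SD on simulated Ct values (cycles).
#' @param gtt_noise_sd Gaussian noise SD on simulated glucose values (mg/dL).
#' @param n_perm Number of permutations for the enrichment test.
#'
#' @return A `sim_config` object (named list).
#' @examples
#' cfg <- sim_config(seed = 7, n_chromosomes = 1, chrom_length = 5000)
#' cfg$snv_rate
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 200000L,
                       snv_rate = 0.008,
                       indel_rate = 8e-4,
                       max_indel_len = 6L,
                       n_genes = 40L,
                       gene_len_range = c(1000L, 3000L),
                       n_candidate_genes = 15L,
                       n_qtl = 8L,
                       qtl_len_range = c(3000L, 8000L),
                       enrichment_fraction = 0.6,
                       allelic_fraction = 0.75,
                       n_reads = 2000L,
                       read_len = 100L,
                       seq_error_rate = 0.001,
                       ct_noise_sd = 0.15,
                       gtt_noise_sd = 10,
                       n_perm = 1000L) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    chrom_length = check_count(chrom_length, "chrom_length"),
    snv_rate = check_prob(snv_rate, "snv_rate"),
    indel_rate = check_prob(indel_rate, "indel_rate"),
    max_indel_len = check_count(max_indel_len, "max_indel_len"),
    n_genes = check_count(n_genes, "n_genes"),
    gene_len_range = check_range(gene_len_range, "gene_len_range"),
    n_candidate_genes = check_count(n_candidate_genes, "n_candidate_genes", min = 0L),
    n_qtl = check_count(n_qtl, "n_qtl", min = 0L),
    qtl_len_range = check_range(qtl_len_range, "qtl_len_range"),
    enrichment_fraction = if (length(enrichment_fraction) == 1L &&
                              is.na(enrichment_fraction)) {
      NA_real_
    } else {
      check_prob(enrichment_fraction, "enrichment_fraction")
    },
    allelic_fraction = check_prob(allelic_fraction, "allelic_fraction"),
    n_reads = check_count(n_reads, "n_reads", min = 0L),
    read_len = check_count(read_len, "read_len"),
    seq_error_rate = check_prob(seq_error_rate, "seq_error_rate"),
    ct_noise_sd = check_pos(ct_noise_sd, "ct_noise_sd", strict = FALSE),
    gtt_noise_sd = check_pos(gtt_noise_sd, "gtt_noise_sd", strict = FALSE),
    n_perm = check_count(n_perm, "n_perm")
  )
  if (cfg$n_candidate_genes > cfg$n_genes) {
    abort_param("`n_candidate_genes` cannot exceed `n_genes`")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = "-")))
  invisible(x)
}
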