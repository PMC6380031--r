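# shared fixture builders; everything is generated in code at test time

small_study <- function(seed = 101, chrom_length = 6000L, snv_rate = 0.012,
                        indel_rate = 0.002, ...) {
  cfg <- sim_config(seed = seed, n_chromosomes = 1L,
                    chrom_length = chrom_length, snv_rate = snv_rate,
                    indel_rate = indel_rate, ...)
  ref <- simulate_reference(cfg)
  list(cfg = cfg, ref = ref, variants = simulate_strain_variants(ref, cfg))
}

# region haplotypes + local diagnostic sites for ASE tests
ase_fixture <- function(seed = 11, indel_rate = 0, n_reads = 2000L,
                        allelic_fraction = 0.75, seq_error_rate = 0,
                        chrom_length = 6000L, region = c(1000L, 4000L)) {
  st <- small_study(seed = seed, chrom_length = chrom_length,
                    indel_rate = indel_rate, n_reads = n_reads,
                    allelic_fraction = allelic_fraction,
                    seq_error_rate = seq_error_rate)
  reg <- tibble::tibble(chrom = "chr1", start = region[1], end = region[2])
  ha <- haplotype_region(st$ref, dplyr::filter(st$variants, strain == "strainA"), reg)
  hb <- haplotype_region(st$ref, dplyr::filter(st$variants, strain == "strainB"), reg)
  sites <- diagnostic_sites(st$variants) |>
    dplyr::filter(pos > reg$start, pos <= reg$end) |>
    dplyr::mutate(pos = pos - reg$start)
  reads <- simulate_reads(ha$seq, hb$seq, st$cfg, map_a = ha$map, map_b = hb$map)
  c(st, list(region = reg, ha = ha, hb = hb, sites = sites, reads = reads))
}

# brute-force all-pairs overlap count (independent oracle)
brute_overlap_count <- function(genes, regions) {
  sum(vapply(seq_len(nrow(genes)), function(i) {
    any(vapply(seq_len(nrow(regions)), function(j) {
      genes$chrom[i] == regions$chrom[j] &&
        genes$start[i] < regions$end[j] && regions$start[j] < genes$end[i]
    }, logical(1)))
  }, logical(1)))
}

# exact two-sided binomial p by direct tail-sum enumeration
enum_binom_p <- function(k, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-12)])
}
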