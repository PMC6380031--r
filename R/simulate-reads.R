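#' Simulate F1-hybrid reads from two haplotypes of a gene region
#'
#' Each read originates from the strain-A haplotype with probability
#' `allelic_fraction` (e.g. 0.75 emulates a gene where three quarters of the
#' reads carry one parental allele). Start positions are uniform over the
#' chosen haplotype, substitution errors are injected per base at
#' `seq_error_rate`, and the true haplotype label plus true origin
#' coordinates are attached — a "seeded alignment", so no external aligner
#' is needed downstream.
#'
#' @param hap_a,hap_b Haplotype sequences of the region (character scalars),
#'   e.g. from [haplotype_region()].
#' @param config A [sim_config()] providing `n_reads`, `read_len`,
#'   `allelic_fraction`, `seq_error_rate` and the seed.
#' @param map_a,map_b Optional region-local [coord_map]s for the two
#'   haplotypes; when supplied, each read also carries its span on the
#'   reference frame (`ref_start`, `ref_end`, 0-based half-open), computed by
#'   inverse-lifting the haplotype coordinates.
#' @return Tibble `read_id`, `hap_truth` (`"A"`/`"B"`), `hap_start` (1-based
#'   on the origin haplotype), `seq`, `n_errors`, and `ref_start`/`ref_end`
#'   when maps are given. Zero `n_reads` yields an empty tibble.
#' @export
simulate_reads <- function(hap_a, hap_b, config, map_a = NULL, map_b = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$read_len
  if (nchar(hap_a) < L || nchar(hap_b) < L) {
    abort_param("read_len exceeds a haplotype length")
  }
  n <- config$n_reads
  empty <- tibble(read_id = character(0), hap_truth = character(0),
                  hap_start = integer(0), seq = character(0),
                  n_errors = integer(0))
  if (n == 0) return(empty)
  with_stream_seed(config$seed, "reads", {
    from_a <- runif(n) < config$allelic_fraction
    hlen <- ifelse(from_a, nchar(hap_a), nchar(hap_b))
    start <- vapply(hlen - L + 1L, function(m) sample.int(m, 1L), integer(1))
    seqs <- ifelse(from_a,
                   substring(hap_a, start, start + L - 1L),
                   substring(hap_b, start, start + L - 1L))
    n_err <- integer(n)
    if (config$seq_error_rate > 0) {
      err <- matrix(runif(n * L) < config$seq_error_rate, nrow = n)
      hit <- which(rowSums(err) > 0)
      for (i in hit) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        at <- which(err[i, ])
        chars[at] <- vapply(chars[at],
                            function(b) sample(setdiff(DNA_BASES, b), 1L),
                            character(1))
        seqs[i] <- paste(chars, collapse = "")
        n_err[i] <- length(at)
      }
    }
    out <- tibble(
      read_id = sprintf("read%06d", seq_len(n)),
      hap_truth = ifelse(from_a, "A", "B"),
      hap_start = as.integer(start),
      seq = seqs,
      n_errors = n_err
    )
    if (!is.null(map_a) && !is.null(map_b)) {
      inv_a <- invert_coord_map(map_a)
      inv_b <- invert_coord_map(map_b)
      ch_a <- unique(c(map_a$chrom, "region"))[1]
      ch_b <- unique(c(map_b$chrom, "region"))[1]
      rs <- re <- integer(n)
      ia <- which(from_a); ib <- which(!from_a)
      if (length(ia)) {
        rs[ia] <- lift_positions(inv_a, ch_a, start[ia] - 1L, side = "start")
        re[ia] <- lift_positions(inv_a, ch_a, start[ia] + L - 1L, side = "end")
      }
      if (length(ib)) {
        rs[ib] <- lift_positions(inv_b, ch_b, start[ib] - 1L, side = "start")
        re[ib] <- lift_positions(inv_b, ch_b, start[ib] + L - 1L, side = "end")
      }
      out$ref_start <- rs
      out$ref_end <- re
    }
    out
  })
}
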