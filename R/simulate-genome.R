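#' Simulate a synthetic reference genome
#'
#' Draws `n_chromosomes` i.i.d. uniform DNA sequences of `chrom_length` bases.
#' Deterministic for a given config seed.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `chrom`, `seq`, `length`.
#' @examples
#' ref <- simulate_reference(sim_config(seed = 7, n_chromosomes = 1,
#'                                      chrom_length = 1000))
#' nchar(ref$seq)
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream_seed(config$seed, "reference", {
    tibble(
      chrom = paste0("chr", seq_len(config$n_chromosomes)),
      seq = vapply(seq_len(config$n_chromosomes),
                   function(i) random_dna(config$chrom_length), character(1)),
      length = as.integer(config$chrom_length)
    )
  })
}

genome_sizes <- function(genome) {
  if (all(c("chrom", "length") %in% names(genome))) {
    tibble(chrom = genome$chrom, size = as.integer(genome$length))
  } else if (all(c("chrom", "seq") %in% names(genome))) {
    tibble(chrom = genome$chrom, size = nchar(genome$seq))
  } else if (all(c("chrom", "size") %in% names(genome))) {
    tibble(chrom = genome$chrom, size = as.integer(genome$size))
  } else {
    abort_param("`genome` must have columns chrom + seq, length or size")
  }
}

# draw one strain's variants on one chromosome; positions are 1-based VCF
# anchors; candidates that would overlap an already-kept variant footprint
# are rejected
simulate_variants_chrom <- function(seq, chrom, config) {
  n <- nchar(seq)
  n_snv <- rbinom(1L, n, config$snv_rate)
  n_ind <- rbinom(1L, n, config$indel_rate)
  cand <- tibble(
    pos = c(if (n_snv > 0) sort(sample.int(n, n_snv)) else integer(0),
            if (n_ind > 0) sort(sample.int(n, n_ind)) else integer(0)),
    type = rep(c("snv", "indel"), c(n_snv, n_ind))
  ) |> arrange(.data$pos)
  if (nrow(cand) == 0) {
    return(tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), type = character(0)))
  }
  ref <- character(nrow(cand)); alt <- character(nrow(cand))
  fp_end <- integer(nrow(cand))   # 1-based last reference base touched
  keep <- logical(nrow(cand))
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- cand$pos[i]
    if (p <= last_end) next
    base <- substr(seq, p, p)
    if (cand$type[i] == "snv") {
      ref[i] <- base
      alt[i] <- sample(setdiff(DNA_BASES, base), 1L)
      fp_end[i] <- p
    } else {
      len <- sample.int(config$max_indel_len, 1L)
      if (runif(1) < 0.5 && p + len <= n) {        # deletion
        ref[i] <- substr(seq, p, p + len)
        alt[i] <- base
        fp_end[i] <- p + len
      } else {                                     # insertion
        ref[i] <- base
        alt[i] <- paste0(base, random_dna(len))
        fp_end[i] <- p
      }
    }
    keep[i] <- TRUE
    last_end <- fp_end[i]
  }
  tibble(chrom = chrom, pos = cand$pos, ref = ref, alt = alt,
         type = cand$type)[keep, ]
}

#' Simulate per-strain small-variant sets
#'
#' Draws SNVs and short indels independently for each strain against the
#' reference, mimicking the differences between two inbred strains (e.g.
#' LG/J vs SM/J). Variants never overlap within a strain; an SNV's alternate
#' allele always differs from the reference base; indels use the VCF
#' anchor-base convention.
#'
#' @param reference Genome tibble from [simulate_reference()].
#' @param config A [sim_config()].
#' @param strains Character vector of two strain names.
#' @return Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `strain`, `type` (`"snv"` or `"indel"`).
#' @export
simulate_strain_variants <- function(reference, config,
                                     strains = c("strainA", "strainB")) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(reference) == 0) abort_param("`reference` genome is empty")
  if (length(strains) != 2L) abort_param("`strains` must name two strains")
  with_stream_seed(config$seed, "variants", {
    purrr::map_dfr(strains, function(st) {
      purrr::map_dfr(seq_len(nrow(reference)), function(i) {
        simulate_variants_chrom(reference$seq[i], reference$chrom[i], config)
      }) |> mutate(strain = st)
    }) |> select("chrom", "pos", "ref", "alt", "strain", "type")
  })
}

place_interval <- function(sizes, len, forbid = NULL, inside = NULL,
                           max_try = 200L, what = "interval") {
  for (try in seq_len(max_try)) {
    if (!is.null(inside)) {
      # force >= 1 base of overlap with the chosen window
      i <- sample.int(nrow(inside), 1L)
      ch <- inside$chrom[i]
      size <- inside$size[i]
      lo <- max(0L, inside$start[i] - len + 1L)
      hi <- min(size - len, inside$end[i] - 1L)
      if (hi < lo) next
      start <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    } else {
      i <- sample.int(nrow(sizes), 1L, prob = sizes$size)
      ch <- sizes$chrom[i]
      if (sizes$size[i] <= len) next
      start <- sample.int(sizes$size[i] - len + 1L, 1L) - 1L
    }
    cand <- list(chrom = ch, start = start, end = start + len)
    if (!is.null(forbid) && nrow(forbid) > 0) {
      clash <- forbid$chrom == cand$chrom &
        overlaps_halfopen(forbid$start, forbid$end, cand$start, cand$end)
      if (any(clash)) next
    }
    return(cand)
  }
  abort(sprintf("could not place %s after %d attempts (infeasible packing?)",
                what, max_try), class = "strainase_packing_error")
}

#' Simulate gene and QTL annotations with a planted enrichment level
#'
#' Places `n_qtl` mutually disjoint QTL intervals, then `n_genes` gene
#' intervals of which the first `n_candidate_genes` are designated candidate
#' genes (the synthetic analogue of an iron-homeostasis gene set). Exactly
#' `round(enrichment_fraction * n_candidate_genes)` candidates are forced to
#' intersect a QTL and the rest are forced outside every QTL; with
#' `enrichment_fraction = NA` candidates are placed uniformly, independent of
#' the QTL (the null configuration). Ground truth is recorded per gene.
#'
#' @param genome Genome tibble (or a `chrom`/`size` tibble; sequences are not
#'   needed to place intervals).
#' @param config A [sim_config()].
#' @return List with tibbles `genes` (`chrom,start,end,name,strand,candidate,
#'   in_qtl`) and `qtl` (`chrom,start,end,name`); BED-style 0-based half-open.
#' @export
simulate_annotations <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- genome_sizes(genome)
  if (any(sizes$size < max(config$qtl_len_range, config$gene_len_range))) {
    abort_param("chromosomes are shorter than the longest requested interval")
  }
  with_stream_seed(config$seed, "annotations", {
    qtl <- NULL
    for (q in seq_len(config$n_qtl)) {
      len <- sample(seq(config$qtl_len_range[1], config$qtl_len_range[2]), 1L)
      hit <- place_interval(sizes, len, forbid = qtl, what = sprintf("QTL %d", q))
      qtl <- bind_rows(qtl, tibble(chrom = hit$chrom, start = hit$start,
                                   end = hit$end, name = sprintf("qtl%02d", q)))
    }
    qtl <- qtl %||% tibble(chrom = character(0), start = integer(0),
                           end = integer(0), name = character(0))
    qtl_win <- left_join(qtl, sizes, by = "chrom")

    n_cand <- config$n_candidate_genes
    ef <- config$enrichment_fraction
    n_in <- if (is.na(ef)) NA_integer_ else as.integer(round(ef * n_cand))
    genes <- purrr::map_dfr(seq_len(config$n_genes), function(g) {
      len <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]), 1L)
      candidate <- g <= n_cand
      if (candidate && !is.na(n_in) && g <= n_in && nrow(qtl) > 0) {
        hit <- place_interval(sizes, len, inside = qtl_win,
                              what = sprintf("candidate gene %d in QTL", g))
      } else if (candidate && !is.na(n_in)) {
        hit <- place_interval(sizes, len, forbid = qtl,
                              what = sprintf("candidate gene %d outside QTL", g))
      } else {
        hit <- place_interval(sizes, len, what = sprintf("gene %d", g))
      }
      tibble(chrom = hit$chrom, start = hit$start, end = hit$end,
             name = sprintf("gene%03d", g),
             strand = sample(c("+", "-"), 1L),
             candidate = candidate)
    })
    genes$in_qtl <- purrr::map_lgl(seq_len(nrow(genes)), function(i) {
      any(qtl$chrom == genes$chrom[i] &
            overlaps_halfopen(qtl$start, qtl$end, genes$start[i], genes$end[i]))
    })
    list(genes = genes, qtl = qtl)
  })
}
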