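#' Build a strain-specific genome by substituting per-strain alleles
#'
#' Replaces reference bases with the strain's alternate alleles (SNVs and
#' short indels, VCF anchor-base convention) and returns the edited genome
#' together with the indel-aware [coord_map] needed to lift annotations onto
#' strain coordinates. Variants are validated before any editing: every
#' `ref` allele must match the reference sequence at its position, and no
#' two variants may overlap.
#'
#' @param reference Genome tibble (`chrom`, `seq`).
#' @param variants Variant tibble (`chrom`, `pos` 1-based, `ref`, `alt`),
#'   e.g. one strain's rows from [simulate_strain_variants()] or
#'   [read_variants_vcf()].
#' @param strain Optional strain label stored on the result.
#' @return List with `genome` (tibble `chrom`, `seq`, `length`) and `map`
#'   (a [coord_map] from reference to strain coordinates). An empty variant
#'   set returns the reference unchanged with an identity map.
#' @examples
#' ref <- tibble::tibble(chrom = "chr1", seq = "ACGT")
#' v <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "C", alt = "CAA")
#' apply_variants(ref, v)$genome$seq  # "ACAAGT"
#' @export
apply_variants <- function(reference, variants, strain = NULL) {
  v <- as_tibble(variants)
  if (nrow(v) > 0 && (any(nchar(v$ref) == 0) || any(nchar(v$alt) == 0))) {
    abort_validation("empty alleles are forbidden (use the VCF anchor-base convention)")
  }
  v <- arrange(v, .data$chrom, .data$pos)
  seqs <- character(nrow(reference))
  for (i in seq_len(nrow(reference))) {
    ch <- reference$chrom[i]
    s <- reference$seq[i]
    vc <- v[v$chrom == ch, , drop = FALSE]
    if (nrow(vc) == 0) { seqs[i] <- s; next }
    ends <- vc$pos + nchar(vc$ref) - 1L
    if (any(ends > nchar(s))) {
      bad <- which(ends > nchar(s))[1]
      abort_validation(sprintf("variant at %s:%d extends past the chromosome end",
                               ch, vc$pos[bad]))
    }
    obs <- substring(s, vc$pos, ends)
    if (any(obs != vc$ref)) {
      bad <- which(obs != vc$ref)[1]
      abort_validation(sprintf(
        "ref allele mismatch at %s:%d (expected '%s', reference has '%s')",
        ch, vc$pos[bad], vc$ref[bad], obs[bad]))
    }
    if (nrow(vc) > 1 && any(vc$pos[-1] <= ends[-nrow(vc)])) {
      bad <- which(vc$pos[-1] <= ends[-nrow(vc)])[1]
      abort_validation(sprintf("overlapping variants at %s:%d and %s:%d",
                               ch, vc$pos[bad], ch, vc$pos[bad + 1]))
    }
    edited <- Biostrings::replaceAt(
      Biostrings::DNAString(s),
      IRanges::IRanges(vc$pos, ends),
      as.character(vc$alt)
    )
    seqs[i] <- as.character(edited)
  }
  genome <- tibble(chrom = reference$chrom, seq = seqs, length = nchar(seqs))
  list(genome = genome,
       map = coord_map_from_variants(v),
       strain = strain)
}

#' Diagnostic sites: positions where two strains carry different alleles
#'
#' A read from an F1 hybrid can only be assigned to a parental haplotype at
#' positions where the parents differ — including positions variant in only
#' one strain. Positions at which both strains carry the same alternate
#' allele are not diagnostic.
#'
#' @param variants Long variant tibble with a `strain` column holding both
#'   strains' variants against the same reference.
#' @param strain_a,strain_b The two strain labels to contrast; default the
#'   first two labels present.
#' @return Tibble `chrom`, `pos` (1-based), `allele_a`, `allele_b`, `type`
#'   (`"snv"` if both alleles are single bases, else `"indel"`), sorted and
#'   unique.
#' @export
diagnostic_sites <- function(variants, strain_a = NULL, strain_b = NULL) {
  v <- as_tibble(variants)
  if (!"strain" %in% names(v)) abort_param("`variants` must have a `strain` column")
  labs <- unique(v$strain)
  strain_a <- strain_a %||% labs[1]
  strain_b <- strain_b %||% labs[2]
  a <- filter(v, .data$strain == strain_a)
  b <- filter(v, .data$strain == strain_b)
  merged <- dplyr::full_join(
    select(a, "chrom", "pos", ref_a = "ref", allele_a = "alt"),
    select(b, "chrom", "pos", ref_b = "ref", allele_b = "alt"),
    by = c("chrom", "pos")
  ) |>
    mutate(
      # a strain without a variant at the position carries the reference base
      allele_a = dplyr::coalesce(.data$allele_a, .data$ref_b),
      allele_b = dplyr::coalesce(.data$allele_b, .data$ref_a)
    ) |>
    filter(.data$allele_a != .data$allele_b) |>
    mutate(type = ifelse(nchar(.data$allele_a) == 1 & nchar(.data$allele_b) == 1 &
                           dplyr::coalesce(nchar(.data$ref_a), 1L) == 1L &
                           dplyr::coalesce(nchar(.data$ref_b), 1L) == 1L,
                         "snv", "indel")) |>
    select("chrom", "pos", "allele_a", "allele_b", "type") |>
    distinct() |>
    arrange(.data$chrom, .data$pos)
  merged
}

#' Count diagnostic sites in a gene body plus its proximal promoter
#'
#' Counts sites falling in the union of the gene body and a `promoter_bp`
#' window upstream of the gene's start on its annotated strand (mirroring a
#' coding region + 1000 bp proximal promoter screen). A promoter window
#' running past the chromosome start is truncated at position 1 with a
#' message; strand `"."` is treated as `"+"` with a message.
#'
#' @param sites Diagnostic-site tibble from [diagnostic_sites()].
#' @param gene One-row tibble (`chrom`, `start`, `end`, `strand`; 0-based
#'   half-open).
#' @param promoter_bp Upstream window size in bases (default 1000).
#' @return Integer count.
#' @export
count_variants_in_region <- function(sites, gene, promoter_bp = 1000L) {
  if (nrow(gene) != 1L) abort_param("`gene` must be a single interval")
  promoter_bp <- check_count(promoter_bp, "promoter_bp", min = 0L)
  strand <- col_or(gene, "strand", "+")
  if (identical(strand, ".")) {
    inform("gene strand is '.'; assuming '+' for the promoter window")
    strand <- "+"
  }
  if (strand == "+") {
    p_start <- gene$start - promoter_bp
    p_end <- gene$start
  } else {
    p_start <- gene$end
    p_end <- gene$end + promoter_bp
  }
  if (p_start < 0) {
    inform(sprintf("promoter window truncated at chromosome start for %s",
                   col_or(gene, "name", "gene")))
    p_start <- 0L
  }
  s <- filter(sites, .data$chrom == gene$chrom)
  x <- s$pos - 1L  # 0-based site coordinate
  in_body <- x >= gene$start & x < gene$end
  in_prom <- x >= p_start & x < p_end
  sum(in_body | in_prom)
}

#' Extract the two haplotype sequences of a region, with local coordinate maps
#'
#' Convenience for the ASE pipeline: restricts the reference and one strain's
#' variants to a region, applies the variants, and returns the region
#' haplotype with a region-local [coord_map] (coordinates relative to the
#' region start). Variants straddling the region boundary are dropped with a
#' warning.
#'
#' @param reference Genome tibble (`chrom`, `seq`).
#' @param variants One strain's variant tibble.
#' @param region One-row interval tibble (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return List with `seq`, `map` (local), `offset` (= `region$start`) and
#'   `variants` (the local 1-based variant table used).
#' @export
haplotype_region <- function(reference, variants, region) {
  if (nrow(region) != 1L) abort_param("`region` must be a single interval")
  i <- match(region$chrom, reference$chrom)
  if (is.na(i)) abort_validation(sprintf("chromosome %s not in reference", region$chrom))
  sub <- substr(reference$seq[i], region$start + 1L, region$end)
  v <- filter(as_tibble(variants), .data$chrom == region$chrom)
  ends <- v$pos + nchar(v$ref) - 1L
  inside <- v$pos > region$start & ends <= region$end
  if (any(!inside & (v$pos <= region$end & ends > region$start))) {
    warn("variants straddling the region boundary were dropped")
  }
  v <- v[inside, , drop = FALSE]
  v$pos <- v$pos - region$start
  local_ref <- tibble(chrom = region$chrom, seq = sub)
  built <- apply_variants(local_ref, v)
  list(seq = built$genome$seq, map = built$map,
       offset = as.integer(region$start), variants = v)
}
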