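# I/O boundary: FASTA/FASTQ via Biostrings, VCF via vcfR, BED and the other
# tables via readr.
# Coordinates convert here and nowhere else: VCF 1-based, BED 0-based
# half-open, package tibbles 0-based half-open for intervals and 1-based for
# variant positions.

#' Read / write genomes as FASTA
#'
#' @param genome Genome tibble (`chrom`, `seq`).
#' @param path File path.
#' @return `read_genome_fasta()` returns a genome tibble; the writer returns
#'   `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(setNames(genome$seq, genome$chrom))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(chrom = sub("\\s.*", "", names(x)),
         seq = unname(as.character(x)),
         length = Biostrings::width(x))
}

#' Read / write variant tables as VCF 4.2
#'
#' One strain per file; positions 1-based with the anchor-base convention
#' for indels. On read, the `ref` allele of every record is checked against
#' the reference genome when one is supplied; multi-allelic records are
#' split into one row per alternate allele and symbolic alleles (`<...>`)
#' are rejected.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param path File path (written gzipped; any extension).
#' @param strain Strain label stored in the header and the `strain` column.
#' @param reference Optional genome tibble for ref-allele validation.
#' @return The reader returns a variant tibble; the writer returns `path`.
#' @export
write_variants_vcf <- function(variants, path, strain = "strain") {
  v <- as_tibble(variants)
  fix <- cbind(
    CHROM = as.character(v$chrom), POS = as.character(v$pos),
    ID = rep(".", nrow(v)), REF = v$ref, ALT = v$alt,
    QUAL = rep(".", nrow(v)), FILTER = rep("PASS", nrow(v)),
    INFO = rep(".", nrow(v))
  )
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##source=strainase %s", packageVersion("strainase")),
            sprintf("##strain=%s", strain))
  vcf <- methods::new(methods::className("vcfR", "vcfR"), meta = meta,
                      fix = fix,
                      gt = matrix(character(0), nrow = nrow(v), ncol = 0))
  vcfR::write.vcf(vcf, path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path, reference = NULL, strain = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (is.null(strain)) {
    hdr <- grep("^##strain=", vcf@meta, value = TRUE)
    strain <- if (length(hdr)) sub("^##strain=", "", hdr[1]) else "strain"
  }
  out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT, strain = strain) |>
    tidyr::separate_longer_delim("alt", delim = ",")
  if (any(grepl("^<.*>$", out$alt))) {
    abort_validation("symbolic ALT alleles are not supported")
  }
  out$type <- ifelse(nchar(out$ref) == 1 & nchar(out$alt) == 1, "snv", "indel")
  if (!is.null(reference)) {
    for (ch in unique(out$chrom)) {
      i <- match(ch, reference$chrom)
      if (is.na(i)) abort_validation(sprintf("chromosome %s not in reference", ch))
      sel <- out$chrom == ch
      obs <- substring(reference$seq[i], out$pos[sel],
                       out$pos[sel] + nchar(out$ref[sel]) - 1L)
      if (any(obs != out$ref[sel])) {
        bad <- which(obs != out$ref[sel])[1]
        abort_validation(sprintf(
          "ref allele mismatch at %s:%d on load", ch, out$pos[sel][bad]))
      }
    }
  }
  out
}

#' Read / write interval tables as BED
#'
#' BED is 0-based half-open, identical to the package's interval convention,
#' so coordinates pass through unchanged; the 6-column layout is read and
#' written as headerless TSV.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optional
#'   `name`, `strand`).
#' @param path File path.
#' @return The reader returns an interval tibble; the writer returns `path`.
#' @export
write_bed <- function(intervals, path) {
  iv <- as_tibble(intervals)
  df <- tibble(
    chrom = iv$chrom, start = iv$start, end = iv$end,
    name = col_or(iv, "name", "."), score = 0L,
    strand = col_or(iv, "strand", ".")
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(df)))]
  as_tibble(df) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select(dplyr::any_of(c("chrom", "start", "end", "name", "strand")))
}

#' Read / write reads as FASTQ with truth labels in the read names
#'
#' Truth metadata (haplotype of origin and reference-frame span) is encoded
#' after a reserved `|` delimiter in the read name so a round trip preserves
#' the simulation ground truth.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param path File path.
#' @return The reader returns a read tibble; the writer returns `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  ids <- paste(reads$read_id, reads$hap_truth,
               col_or(reads, "ref_start", NA), col_or(reads, "ref_end", NA),
               sep = "|")
  x <- Biostrings::DNAStringSet(setNames(reads$seq, ids))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  parts <- stringr::str_split_fixed(names(x), stringr::fixed("|"), 4)
  tibble(
    read_id = parts[, 1],
    hap_truth = parts[, 2],
    ref_start = suppressWarnings(as.integer(parts[, 3])),
    ref_end = suppressWarnings(as.integer(parts[, 4])),
    seq = unname(as.character(x))
  )
}

#' Read / write coordinate maps as TSV
#'
#' A chain-like plain-text table of breakpoints: one indel event per line
#' with its source threshold, signed offset and footprint.
#'
#' @param map A [coord_map].
#' @param path File path.
#' @return The reader returns a `coord_map`; the writer returns `path`.
#' @export
write_coord_map <- function(map, path) {
  readr::write_tsv(as_tibble(map), path)
  invisible(path)
}

#' @rdname write_coord_map
#' @export
read_coord_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chrom = readr::col_character(),
                          threshold = readr::col_integer(),
                          delta = readr::col_integer(),
                          fp_start = readr::col_integer(),
                          fp_end = readr::col_integer()))
  new_coord_map(df)
}
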