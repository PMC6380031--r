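test_that("apply_variants edits sequences and reports length changes", {
  ref <- tibble::tibble(chrom = "chr1", seq = "ACGT")
  # single substitution, identity map
  out <- apply_variants(ref, tibble::tibble(chrom = "chr1", pos = 2L,
                                            ref = "C", alt = "T"))
  expect_equal(out$genome$seq, "ATGT")
  expect_equal(nrow(out$map), 0L)
  # insertion: C -> CAA shifts everything after position 2 by +2
  out <- apply_variants(ref, tibble::tibble(chrom = "chr1", pos = 2L,
                                            ref = "C", alt = "CAA"))
  expect_equal(out$genome$seq, "ACAAGT")
  expect_equal(lift_positions(out$map, "chr1", c(0, 1, 2, 3)), c(0, 1, 4, 5))
  # empty variant set: unchanged genome, identity map
  out <- apply_variants(ref, tibble::tibble(chrom = character(0), pos = integer(0),
                                            ref = character(0), alt = character(0)))
  expect_equal(out$genome$seq, "ACGT")
  expect_equal(lift_positions(out$map, "chr1", 0:3), 0:3)
})

test_that("apply_variants validates ref alleles and overlaps", {
  ref <- tibble::tibble(chrom = "chr1", seq = "ACGTACGT")
  expect_error(
    apply_variants(ref, tibble::tibble(chrom = "chr1", pos = 2L, ref = "G", alt = "T")),
    regexp = "chr1:2", class = "strainase_validation_error")
  expect_error(
    apply_variants(ref, tibble::tibble(chrom = "chr1", pos = c(2L, 3L),
                                       ref = c("CG", "G"), alt = c("C", "A"))),
    class = "strainase_validation_error")
  expect_error(
    apply_variants(ref, tibble::tibble(chrom = "chr1", pos = 2L, ref = "", alt = "A")),
    class = "strainase_validation_error")
})

test_that("length conservation holds across random variant sets", {
  st <- small_study(seed = 17, chrom_length = 8000L, indel_rate = 0.004)
  for (s in c("strainA", "strainB")) {
    vs <- dplyr::filter(st$variants, strain == s)
    out <- apply_variants(st$ref, vs, strain = s)
    expect_equal(out$genome$length - st$ref$length,
                 sum(nchar(vs$alt) - nchar(vs$ref)))
  }
})

test_that("interval lifting shifts by cumulative offsets and is monotone", {
  v <- tibble::tibble(chrom = "chr1", pos = c(2L, 30L),
                      ref = c("C", "AGG"), alt = c("CAA", "A"))
  m <- coord_map_from_variants(v)
  g <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L, name = "g1")
  lifted <- lift_intervals(g, m)
  expect_equal(lifted$start, 12L)  # +2 from the upstream insertion
  expect_equal(lifted$end, 22L)
  expect_false(lifted$lift_flagged)
  # variants entirely after the interval leave it unchanged
  g2 <- tibble::tibble(chrom = "chr1", start = 0L, end = 2L)
  expect_equal(lift_intervals(g2, m)$start, 0L)
  expect_equal(lift_intervals(g2, m)$end, 2L)
  # monotonicity over a grid of boundaries
  x <- 0:60
  lx <- lift_positions(m, "chr1", x)
  expect_true(all(diff(lx) >= 0))
})

test_that("SNV-only variant sets lift every interval to itself", {
  st <- small_study(seed = 19, chrom_length = 5000L, snv_rate = 0.02,
                    indel_rate = 0)
  va <- dplyr::filter(st$variants, strain == "strainA")
  m <- apply_variants(st$ref, va)$map
  iv <- tibble::tibble(chrom = "chr1",
                       start = seq(0L, 4500L, by = 137L))
  iv$end <- iv$start + 100L
  lifted <- lift_intervals(iv, m)
  expect_equal(sort(lifted$start), sort(iv$start))
  expect_equal(sort(lifted$end), sort(iv$end))
})

test_that("endpoints inside deletions follow the clamp/strict policy", {
  # deletion removes 0-based bases [2, 4)
  v <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "CGG", alt = "C")
  m <- coord_map_from_variants(v)
  iv <- tibble::tibble(chrom = "chr1", start = 3L, end = 10L)
  clamped <- lift_intervals(iv, m)
  expect_true(clamped$lift_flagged)
  expect_equal(clamped$start, 2L)   # both deletion edges collapse to image 2
  expect_equal(clamped$end, 8L)
  expect_error(lift_intervals(iv, m, policy = "strict"),
               class = "strainase_validation_error")
})

test_that("diagnostic sites are the strain-allele differences", {
  mk <- function(pos, ref, alt, strain) {
    tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                   strain = strain, type = ifelse(nchar(ref) == nchar(alt),
                                                  "snv", "indel"))
  }
  # identical variant sets: nothing diagnostic
  v <- dplyr::bind_rows(mk(5L, "C", "T", "A"), mk(5L, "C", "T", "B"))
  expect_equal(nrow(diagnostic_sites(v, "A", "B")), 0L)
  # one-sided variant is diagnostic; shared variant is excluded
  v <- dplyr::bind_rows(mk(5L, "C", "T", "A"), mk(5L, "C", "T", "B"),
                        mk(9L, "G", "A", "A"))
  d <- diagnostic_sites(v, "A", "B")
  expect_equal(d$pos, 9L)
  expect_equal(d$allele_a, "A")
  expect_equal(d$allele_b, "G")  # strain B carries the reference base
  # differing alleles at the same position are diagnostic
  v <- dplyr::bind_rows(mk(5L, "C", "T", "A"), mk(5L, "C", "G", "B"))
  expect_equal(diagnostic_sites(v, "A", "B")$pos, 5L)
})

test_that("variant counting covers gene body plus strand-aware promoter", {
  sites <- tibble::tibble(chrom = "chr1",
                          pos = c(50L, 150L, 250L, 350L, 996L),
                          allele_a = "A", allele_b = "C", type = "snv")
  gene_plus <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L,
                              name = "g", strand = "+")
  # body: pos 150, 250; promoter [0,100): pos 50
  expect_equal(count_variants_in_region(sites, gene_plus, promoter_bp = 100L), 3L)
  gene_minus <- dplyr::mutate(gene_plus, strand = "-")
  # minus-strand promoter is [300, 400): pos 350
  expect_equal(count_variants_in_region(sites, gene_minus, promoter_bp = 100L), 3L)
  # empty window
  empty <- tibble::tibble(chrom = "chr1", pos = integer(0),
                          allele_a = character(0), allele_b = character(0),
                          type = character(0))
  expect_equal(count_variants_in_region(empty, gene_plus, promoter_bp = 100L), 0L)
  # truncation at the chromosome start is messaged, not silent
  g0 <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L, strand = "+")
  expect_message(count_variants_in_region(sites, g0, promoter_bp = 100L),
                 "truncated")
  # planted ground truth: generator-placed sites are recovered exactly
  st <- small_study(seed = 23, chrom_length = 5000L)
  d <- diagnostic_sites(st$variants)
  g <- tibble::tibble(chrom = "chr1", start = 2000L, end = 3000L, strand = "+")
  manual <- sum((d$pos - 1) >= 1000 & (d$pos - 1) < 3000)
  expect_equal(count_variants_in_region(d, g, promoter_bp = 1000L), manual)
})
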