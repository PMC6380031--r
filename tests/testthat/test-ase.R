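test_that("error-free reads covering diagnostic SNVs are assigned perfectly", {
  fx <- ase_fixture(seed = 11, indel_rate = 0, n_reads = 2000L,
                    seq_error_rate = 0)
  asg <- assign_reads(fx$reads, fx$ha$seq, fx$hb$seq, fx$sites,
                      map_a = fx$ha$map, map_b = fx$hb$map)
  covered <- asg$n_diagnostic_covered > 0
  expect_true(all(asg$call[!covered] == "ambiguous"))
  truth <- ifelse(fx$reads$hap_truth == "A", "strainA", "strainB")
  expect_equal(asg$call[covered], truth[covered])
  # the winning haplotype always has strictly fewer mismatches
  called <- asg$call != "ambiguous"
  expect_true(all(ifelse(asg$call[called] == "strainA",
                         asg$mismatches_vs_a[called] < asg$mismatches_vs_b[called],
                         asg$mismatches_vs_b[called] < asg$mismatches_vs_a[called])))
})

test_that("reads covering no diagnostic site are ambiguous", {
  hap <- strrep("ACGT", 50)
  reads <- tibble::tibble(read_id = "r1", seq = substr(hap, 1, 50),
                          ref_start = 0L, ref_end = 50L)
  sites <- tibble::tibble(chrom = "region", pos = 150L, allele_a = "A",
                          allele_b = "C", type = "snv")
  asg <- assign_reads(reads, hap, hap, sites)
  expect_equal(asg$call, "ambiguous")
  expect_equal(asg$n_diagnostic_covered, 0L)
  expect_error(assign_reads(dplyr::mutate(reads, seq = ""), hap, hap, sites),
               class = "strainase_param_error")
})

test_that("with indels present error-free reads are never assigned to the wrong strain", {
  fx <- ase_fixture(seed = 42, indel_rate = 0.003, n_reads = 3000L,
                    seq_error_rate = 0)
  asg <- assign_reads(fx$reads, fx$ha$seq, fx$hb$seq, fx$sites,
                      map_a = fx$ha$map, map_b = fx$hb$map)
  wrong <- (fx$reads$hap_truth == "A" & asg$call == "strainB") |
    (fx$reads$hap_truth == "B" & asg$call == "strainA")
  # frame shifts can tie reads into ambiguity but misassignment stays rare
  # (bounded by reads whose ref span itself is distorted by an indel start)
  expect_lte(mean(wrong), 0.005)
})

test_that("per-gene counts match the brute-force overlap oracle", {
  withr::with_seed(77, {
    reads <- tibble::tibble(
      read_id = sprintf("r%03d", 1:300),
      chrom = "chr1",
      ref_start = sample(0:900, 300, replace = TRUE))
    reads$ref_end <- reads$ref_start + 50L
    asg <- tibble::tibble(read_id = reads$read_id,
                          call = sample(c("strainA", "strainB", "ambiguous"),
                                        300, replace = TRUE))
    genes <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 180L, 400L, 650L, 900L),
                            end = c(120L, 360L, 600L, 820L, 950L),
                            name = paste0("g", 1:5))
    counts <- count_reads_per_gene(reads, asg, genes)
    for (g in seq_len(nrow(genes))) {
      hits <- vapply(seq_len(nrow(reads)), function(i) {
        reads$ref_start[i] < genes$end[g] && genes$start[g] < reads$ref_end[i]
      }, logical(1))
      expect_equal(counts$n_a[g], sum(hits & asg$call == "strainA"))
      expect_equal(counts$n_b[g], sum(hits & asg$call == "strainB"))
      expect_equal(counts$n_ambiguous[g], sum(hits & asg$call == "ambiguous"))
    }
  })
})

test_that("read-gene overlap uses half-open semantics", {
  genes <- tibble::tibble(chrom = "c", start = 140L, end = 300L, name = "g")
  asg <- tibble::tibble(read_id = c("a", "b"), call = "strainA")
  reads <- tibble::tibble(read_id = c("a", "b"), chrom = "c",
                          ref_start = c(100L, 100L), ref_end = c(150L, 140L))
  counts <- count_reads_per_gene(reads, asg, genes)
  expect_equal(counts$n_a, 1L)  # [100,150) overlaps, [100,140) abuts
})

test_that("upper-quartile normalization equalizes nonzero upper quartiles", {
  withr::with_seed(88, {
    m <- matrix(rpois(500, 20), ncol = 5,
                dimnames = list(NULL, paste0("s", 1:5)))
    m[sample(length(m), 80)] <- 0
    m2 <- sweep(m, 2, c(1, 2, 0.5, 3, 1.7), "*")
    norm <- uq_normalize(m2)
    uq <- apply(norm$normalized, 2, function(x) quantile(x[x > 0], 0.75))
    expect_lt(diff(range(uq)) / mean(uq), 1e-9)
    # doubling a sample halves nothing: B = 2A normalizes to identical columns
    two <- cbind(A = m[, 1], B = 2 * m[, 1])
    n2 <- uq_normalize(two)
    expect_equal(n2$normalized[, "A"], n2$normalized[, "B"],
                 ignore_attr = TRUE)
    # single sample returned unchanged with factor 1
    one <- uq_normalize(m[, 1, drop = FALSE])
    expect_equal(unname(one$factors), 1)
    expect_equal(one$normalized, m[, 1, drop = FALSE])
    expect_error(uq_normalize(cbind(a = c(0, 0, 0))),
                 class = "strainase_validation_error")
  })
})

test_that("allele bias matches the enumeration oracle and handles edge cases", {
  ab <- allele_bias(tibble::tibble(gene = "g", n_a = 30, n_b = 10))
  expect_equal(ab$bias, 0.75)
  # symmetric null: bias 0.5 and the maximal two-sided p
  ab50 <- allele_bias(tibble::tibble(gene = "g", n_a = 50, n_b = 50))
  expect_equal(ab50$bias, 0.5)
  expect_equal(ab50$p_value, 1.0, tolerance = 1e-12)
  # exact tail-sum oracle over a grid of counts
  for (counts in list(c(75, 25), c(7, 3), c(40, 60), c(1, 10))) {
    ab <- allele_bias(tibble::tibble(gene = "g", n_a = counts[1], n_b = counts[2]))
    expect_equal(ab$p_value, enum_binom_p(counts[1], sum(counts)),
                 tolerance = 1e-12)
  }
  # zero totals are an explicit non-estimable result
  ab0 <- allele_bias(tibble::tibble(gene = "g", n_a = 0, n_b = 0))
  expect_false(ab0$estimable)
  expect_true(is.na(ab0$bias))
})

test_that("label swap maps bias to 1 - bias with the same p-value", {
  withr::with_seed(99, {
    na <- rbinom(50, 200, runif(50, 0.2, 0.8))
    nb <- 200 - na
    fwd <- allele_bias(tibble::tibble(gene = paste0("g", 1:50), n_a = na, n_b = nb))
    rev <- allele_bias(tibble::tibble(gene = paste0("g", 1:50), n_a = nb, n_b = na))
    expect_equal(rev$bias, 1 - fwd$bias)
    expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
    expect_equal(rev$ci_low, 1 - fwd$ci_high, tolerance = 1e-9)
  })
})

test_that("group comparison of per-animal bias behaves like a t-test", {
  withr::with_seed(13, {
    df <- tibble::tibble(
      bias = c(rnorm(8, 0.75, 0.03), rnorm(8, 0.5, 0.03)),
      group = rep(c("F1", "balanced"), each = 8))
    res <- compare_bias_groups(df)
    expect_lt(res$p_value, 1e-6)
    ref <- t.test(bias ~ group, data = df)
    expect_equal(res$p_value, ref$p.value)
  })
})
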