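#' Count candidate genes overlapping a region set
#'
#' A gene counts once if its interval overlaps at least one region by at
#' least one base (half-open coordinates, so abutting intervals do not
#' overlap).
#'
#' @param genes,regions Interval tibbles (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return Integer count of overlapping genes.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' q <- tibble::tibble(chrom = "chr1", start = 150, end = 300)
#' count_region_overlaps(g, q)  # 1
#' @export
count_region_overlaps <- function(genes, regions) {
  genes <- as_tibble(genes); regions <- as_tibble(regions)
  if (nrow(genes) == 0 || nrow(regions) == 0) return(0L)
  miss <- setdiff(unique(genes$chrom), unique(regions$chrom))
  # a gene on a chromosome absent from the region set simply cannot overlap;
  # a full mismatch of naming schemes, however, is an input error
  if (length(intersect(unique(genes$chrom), unique(regions$chrom))) == 0) {
    abort_validation(paste0(
      "no shared chromosome names between genes and regions; unmatched: ",
      paste(miss, collapse = ", ")))
  }
  sum(overlap_any(genes, regions))
}

# vectorized any-overlap flag per gene; plain arithmetic so it is cheap
# inside the permutation loop (GenomicRanges serves as the oracle in tests)
overlap_any <- function(genes, regions) {
  vapply(seq_len(nrow(genes)), function(i) {
    any(regions$chrom == genes$chrom[i] &
          overlaps_halfopen(regions$start, regions$end,
                            genes$start[i], genes$end[i]))
  }, logical(1))
}

# precompute, per chromosome, the gaps left by an exclusion set and the
# number of feasible start positions they offer for a given length
build_gap_index <- function(chrom_sizes, exclude) {
  idx <- list()
  for (i in seq_len(nrow(chrom_sizes))) {
    ch <- chrom_sizes$chrom[i]
    size <- chrom_sizes$size[i]
    ex <- exclude[exclude$chrom == ch, , drop = FALSE]
    if (nrow(ex) == 0) {
      gs <- 0L; ge <- size
    } else {
      ex <- ex[order(ex$start), , drop = FALSE]
      # merge overlapping exclusions
      ms <- ex$start[1]; me <- ex$end[1]; gs <- integer(0); ge <- integer(0)
      if (nrow(ex) > 1) {
        for (j in 2:nrow(ex)) {
          if (ex$start[j] <= me) me <- max(me, ex$end[j])
          else { gs <- c(gs, ms); ge <- c(ge, me); ms <- ex$start[j]; me <- ex$end[j] }
        }
      }
      gs <- c(gs, ms); ge <- c(ge, me)
      gap_s <- c(0L, ge); gap_e <- c(gs, size)
      ok <- gap_e > gap_s
      gs <- gap_s[ok]; ge <- gap_e[ok]
    }
    idx[[ch]] <- list(gap_start = as.integer(gs), gap_end = as.integer(ge))
  }
  idx
}

draw_region <- function(gaps, len) {
  feas <- pmax(0L, gaps$gap_end - gaps$gap_start - len + 1L)
  total <- sum(feas)
  if (total == 0) return(NULL)
  g <- sample.int(length(feas), 1L, prob = feas)
  start <- gaps$gap_start[g] + sample.int(feas[g], 1L) - 1L
  c(start, start + len)
}

#' Sample random regions matched to a template, avoiding an exclusion set
#'
#' Draws one random region per template interval with exactly the same
#' length, on the same chromosome, uniformly among all start positions whose
#' full extent avoids the exclusion set. Sampled regions may not overlap one
#' another (enforced by redrawing). This is the null model for the QTL
#' enrichment permutation test: random non-QTL regions of matched size.
#'
#' @param template Interval tibble whose lengths/chromosomes are matched
#'   (e.g. the QTL set).
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param exclude Interval tibble to avoid entirely (typically the template
#'   itself); `NULL` for no exclusion.
#' @param seed Optional integer seed for reproducibility.
#' @param same_chrom Keep each sampled region on its template chromosome
#'   (default); `FALSE` allows genome-wide placement (size-weighted).
#' @param max_try Redraw cap per interval before erroring.
#' @return Interval tibble like `template` with new `start`/`end`.
#' @export
sample_matched_regions <- function(template, chrom_sizes, exclude = NULL,
                                   seed = NULL, same_chrom = TRUE,
                                   max_try = 1000L) {
  template <- as_tibble(template)
  chrom_sizes <- as_tibble(chrom_sizes)
  exclude <- if (is.null(exclude)) {
    tibble(chrom = character(0), start = integer(0), end = integer(0))
  } else as_tibble(exclude)
  run <- function() {
    gap_idx <- build_gap_index(chrom_sizes, exclude)
    draw_set(template, chrom_sizes, gap_idx, same_chrom, max_try)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

# Low-level sampler shared with permutation_test (gap index precomputed).
# Sequential dart-throwing can corner itself when the gaps are tight even
# though a feasible configuration exists, so a failed set is restarted from
# scratch a bounded number of times before declaring infeasibility. Longest
# intervals are placed first to keep restarts rare.
draw_set <- function(template, chrom_sizes, gap_idx, same_chrom, max_try,
                     max_restart = 100L) {
  n <- nrow(template)
  ord <- order(template$end - template$start, decreasing = TRUE)
  for (restart in seq_len(max_restart)) {
    out_start <- integer(n); out_end <- integer(n); out_chrom <- character(n)
    failed <- FALSE
    for (i in ord) {
      len <- template$end[i] - template$start[i]
      placed <- FALSE
      for (try in seq_len(max_try)) {
        ch <- if (same_chrom) template$chrom[i] else
          sample(chrom_sizes$chrom, 1L, prob = chrom_sizes$size)
        hit <- draw_region(gap_idx[[ch]], len)
        if (is.null(hit)) {
          if (same_chrom) break else next
        }
        prev <- out_end > 0L
        clash <- any(prev & out_chrom == ch &
                       overlaps_halfopen(out_start, out_end, hit[1], hit[2]))
        if (!clash) {
          out_chrom[i] <- ch; out_start[i] <- hit[1]; out_end[i] <- hit[2]
          placed <- TRUE
          break
        }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) {
      return(tibble(chrom = out_chrom, start = out_start, end = out_end,
                    name = col_or(template, "name", paste0("rand", seq_len(n)))))
    }
  }
  abort(sprintf(
    "no feasible placement for the template set after %d restarts",
    max_restart), class = "strainase_packing_error")
}

#' Permutation test for candidate-gene enrichment in QTL intervals
#'
#' Compares the observed number of candidate genes overlapping the QTL set
#' against a null distribution obtained by redrawing, `n_perm` times, a set
#' of random non-QTL regions matched to the QTL in number, length and
#' chromosome ([sample_matched_regions()] with the QTL as exclusion). The
#' empirical p-value uses the +1 correction
#' `(1 + sum(null >= observed)) / (n_perm + 1)`, so its minimum is
#' `1/(n_perm + 1)` and it is never zero.
#'
#' @param genes Candidate gene intervals.
#' @param qtl QTL intervals.
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; identical seed gives identical null counts.
#' @param alternative `"greater"` (enrichment, default), `"less"` or
#'   `"two.sided"`.
#' @param same_chrom Passed to the region sampler.
#' @return An `enrichment_test` object: list with `observed`, `null_counts`,
#'   `p_empirical`, `z`, `n_perm`, `seed`, `alternative`. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
permutation_test <- function(genes, qtl, chrom_sizes, n_perm = 1000L,
                             seed = 1L, alternative = c("greater", "less", "two.sided"),
                             same_chrom = TRUE) {
  alternative <- match.arg(alternative)
  n_perm <- check_count(n_perm, "n_perm")
  genes <- as_tibble(genes); qtl <- as_tibble(qtl)
  chrom_sizes <- as_tibble(chrom_sizes)
  observed <- count_region_overlaps(genes, qtl)
  gl <- select(genes, "chrom", "start", "end")
  null_counts <- withr::with_seed(split_seed(seed, "enrichment"), {
    gap_idx <- build_gap_index(chrom_sizes, qtl)
    vapply(seq_len(n_perm), function(b) {
      rand <- draw_set(qtl, chrom_sizes, gap_idx, same_chrom, 1000L)
      sum(overlap_any(gl, rand))
    }, numeric(1))
  })
  p_greater <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  p_less <- (1 + sum(null_counts <= observed)) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  z <- if (sd(null_counts) > 0) (observed - mean(null_counts)) / sd(null_counts) else NA_real_
  structure(
    list(observed = observed, null_counts = as.integer(null_counts),
         p_empirical = p, z = z, n_perm = n_perm, seed = as.integer(seed),
         alternative = alternative),
    class = "enrichment_test"
  )
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat("Permutation test for region-set enrichment\n")
  cat(sprintf("  observed overlaps : %d\n", x$observed))
  cat(sprintf("  null mean (sd)    : %.2f (%.2f)\n",
              mean(x$null_counts), sd(x$null_counts)))
  cat(sprintf("  z                 : %.2f\n", x$z))
  cat(sprintf("  empirical p (%s): %.4g  [%d permutations]\n",
              x$alternative, x$p_empirical, x$n_perm))
  invisible(x)
}

#' @rdname permutation_test
#' @param x An `enrichment_test` object.
#' @param ... Unused.
#' @method tidy enrichment_test
#' @export
tidy.enrichment_test <- function(x, ...) {
  tibble(permutation = seq_along(x$null_counts), null_count = x$null_counts)
}

#' @rdname permutation_test
#' @method glance enrichment_test
#' @export
glance.enrichment_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null_counts),
         null_sd = sd(x$null_counts), z = x$z,
         p_empirical = x$p_empirical, n_perm = x$n_perm,
         alternative = x$alternative, seed = x$seed)
}
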