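# internal helpers: parameter checks and hierarchical seed splitting

abort_param <- function(msg, ...) {
  abort(msg, class = "strainase_param_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "strainase_validation_error", ...)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    abort_param(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort_param(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) abort_param(sprintf("`%s` must be a single %s number", name,
                               if (strict) "positive" else "non-negative"))
  as.numeric(x)
}

check_range <- function(x, name) {
  if (length(x) != 2L || !is.numeric(x) || any(is.na(x)) || any(x < 1) || x[1] > x[2]) {
    abort_param(sprintf("`%s` must be a length-2 increasing positive range", name))
  }
  as.integer(x)
}

# One global integer seed, split deterministically per generator stream so the
# streams are independent yet fully reproducible. Kept below 2^31 - 1.
.seed_streams <- c(
  reference = 1L, variants = 2L, annotations = 3L, reads = 4L,
  ct = 5L, gtt = 6L, enrichment = 7L, sampler = 8L, demo = 9L
)

split_seed <- function(seed, stream) {
  if (!stream %in% names(.seed_streams)) {
    abort_param(sprintf("unknown seed stream '%s'", stream))
  }
  (abs(as.integer(seed)) %% 2147482L) * 1000L + .seed_streams[[stream]]
}

with_stream_seed <- function(seed, stream, code) {
  withr::with_seed(split_seed(seed, stream), code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# half-open overlap on 0-based [start, end) intervals
overlaps_halfopen <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# column with default: tibbles warn on `$` for missing columns
col_or <- function(df, nm, default) {
  if (nm %in% names(df)) df[[nm]] else default
}
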