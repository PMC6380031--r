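#' Indel-aware coordinate maps between reference and strain genomes
#'
#' A coordinate map is a tibble of indel events, one row per indel, with the
#' piecewise-constant offset they induce on all downstream coordinates.
#' Substitutions never change coordinates and are not represented. All
#' coordinates here are 0-based boundaries, so the same lift applies to the
#' start and the end of a half-open interval.
#'
#' Columns:
#' * `chrom` — chromosome
#' * `threshold` — 0-based source coordinate at and beyond which the event's
#'   offset applies (end of the event's source footprint)
#' * `delta` — signed length change (`nchar(alt) - nchar(ref)`)
#' * `fp_start`, `fp_end` — half-open source footprint of bases that have no
#'   image on the target (deleted bases); zero-length for insertions
#'
#' @name coord_map
NULL

new_coord_map <- function(df, from = "reference", to = "strain") {
  df <- as_tibble(df)
  df <- arrange(df, .data$chrom, .data$threshold)
  structure(df, class = c("coord_map", class(df)), from = from, to = to)
}

#' Build a coordinate map from a variant table
#'
#' @param variants Variant tibble with columns `chrom`, `pos` (1-based VCF
#'   anchor), `ref`, `alt`. SNVs contribute nothing; indels shift all
#'   downstream coordinates by `nchar(alt) - nchar(ref)`.
#' @return A `coord_map` tibble (identity map if there are no indels).
#' @examples
#' v <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "C", alt = "CAA")
#' m <- coord_map_from_variants(v)
#' lift_positions(m, "chr1", c(0, 2, 5))
#' @export
coord_map_from_variants <- function(variants) {
  v <- as_tibble(variants)
  indels <- filter(v, nchar(.data$ref) != nchar(.data$alt))
  if (nrow(indels) == 0) {
    return(new_coord_map(tibble(
      chrom = character(), threshold = integer(),
      delta = integer(), fp_start = integer(), fp_end = integer()
    )))
  }
  rlen <- nchar(indels$ref)
  alen <- nchar(indels$alt)
  # deletion of d bases: footprint = the deleted bases after the anchor,
  # 0-based [pos, pos + d); insertion: zero-length footprint at boundary pos
  fp_start <- indels$pos            # 0-based index of first base after anchor
  fp_end <- indels$pos + pmax(rlen - 1L, 0L)
  new_coord_map(tibble(
    chrom = indels$chrom,
    threshold = as.integer(fp_end),
    delta = as.integer(alen - rlen),
    fp_start = as.integer(fp_start),
    fp_end = as.integer(fp_end)
  ))
}

#' Invert a coordinate map
#'
#' Swaps the roles of source and target: insertions on the forward map become
#' deletion-like footprints on the inverse, and vice versa. Lifting a
#' coordinate forward then backward is the identity for every coordinate
#' outside indel footprints.
#'
#' @param map A `coord_map`.
#' @return The inverse `coord_map`.
#' @export
invert_coord_map <- function(map) {
  if (nrow(map) == 0) {
    return(new_coord_map(map[, c("chrom", "threshold", "delta", "fp_start", "fp_end")],
                         from = attr(map, "to"), to = attr(map, "from")))
  }
  inv <- map |>
    as_tibble() |>
    group_by(.data$chrom) |>
    arrange(.data$threshold, .by_group = TRUE) |>
    mutate(
      off_after = cumsum(.data$delta),
      off_before = .data$off_after - .data$delta,
      # image of the source footprint start on the target
      t_start = .data$fp_start + .data$off_before,
      t_fp_start = .data$t_start,
      t_fp_end = .data$t_start + pmax(.data$delta, 0L),
      t_threshold = .data$t_fp_end,
      t_delta = -.data$delta
    ) |>
    ungroup()
  new_coord_map(
    tibble(
      chrom = inv$chrom,
      threshold = as.integer(inv$t_threshold),
      delta = as.integer(inv$t_delta),
      fp_start = as.integer(inv$t_fp_start),
      fp_end = as.integer(inv$t_fp_end)
    ),
    from = attr(map, "to"), to = attr(map, "from")
  )
}

# Core lift of 0-based boundaries on one chromosome.
#
# Tie-breaking at exact event boundaries makes forward-then-inverse lifting
# the identity for intervals that do not intersect an indel footprint:
# a start boundary sitting exactly at an insertion point is pushed past the
# inserted bases (threshold <= x), while an end boundary stays before them
# (threshold < x, for zero-footprint events only). Deletion-footprint ends
# always use <=, so an interval ending flush with a deleted segment lands
# flush with its image.
lift_boundaries <- function(map, chrom, x, policy = c("clamp", "strict"),
                            side = c("start", "end")) {
  policy <- match.arg(policy)
  side <- match.arg(side)
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) {
    return(list(pos = as.integer(x), flagged = logical(length(x))))
  }
  m <- m[order(m$threshold), , drop = FALSE]
  offs <- cumsum(m$delta)
  flagged <- logical(length(x))
  x <- as.integer(x)
  # a position strictly inside a deleted segment has no image
  has_fp <- m$fp_end > m$fp_start
  if (any(has_fp)) {
    fs <- m$fp_start[has_fp]; fe <- m$fp_end[has_fp]
    for (i in seq_along(x)) {
      hit <- which(x[i] > fs & x[i] < fe)
      if (length(hit)) {
        if (policy == "strict") {
          abort_validation(sprintf(
            "position %d on %s lies inside a deleted segment [%d,%d)",
            x[i], chrom, fs[hit[1]], fe[hit[1]]
          ))
        }
        x[i] <- if (side == "start") fe[hit[1]] else fs[hit[1]]
        flagged[i] <- TRUE
      }
    }
  }
  idx <- findInterval(x, m$threshold)   # number of thresholds <= x
  off <- ifelse(idx == 0L, 0L, offs[pmax(idx, 1L)])
  if (side == "end") {
    empty_fp <- m$fp_end == m$fp_start
    for (i in seq_along(x)) {
      at <- which(m$threshold == x[i] & empty_fp)
      if (length(at)) off[i] <- off[i] - sum(m$delta[at])
    }
  }
  list(pos = as.integer(x + off), flagged = flagged)
}

#' Lift 0-based positions through a coordinate map
#'
#' @param map A `coord_map`.
#' @param chrom Chromosome name (scalar).
#' @param pos Vector of 0-based boundary coordinates.
#' @param policy `"clamp"` (default) moves a position inside a deleted segment
#'   to the segment's edge and flags it; `"strict"` raises an error.
#' @param side Whether the coordinates are interval starts (`"start"`, also
#'   appropriate for single positions) or ends (`"end"`); this only changes
#'   the tie-break at exact indel boundaries.
#' @return Integer vector of lifted positions. Flags are available via
#'   [lift_intervals()] which reports them per interval.
#' @export
lift_positions <- function(map, chrom, pos, policy = c("clamp", "strict"),
                           side = c("start", "end")) {
  lift_boundaries(map, chrom, pos, policy, side)$pos
}

#' Lift annotation intervals through a coordinate map
#'
#' Shifts the start and end of each half-open interval by the cumulative
#' indel offset at that coordinate. Lifting with an identity (empty) map is
#' the identity, and lifting is monotone. An endpoint inside a deleted
#' segment is handled per `policy` and never silently: with `"clamp"` it is
#' moved to the deletion's left edge and the interval is flagged.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and any other columns, which are preserved.
#' @param map A `coord_map` whose source frame matches `intervals`.
#' @param policy `"clamp"` or `"strict"`; see [lift_positions()].
#' @return The input tibble with `start`/`end` lifted and a logical
#'   `lift_flagged` column marking clamped endpoints.
#' @examples
#' v <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "C", alt = "CAA")
#' m <- coord_map_from_variants(v)
#' g <- tibble::tibble(chrom = "chr1", start = 10L, end = 20L, name = "g1")
#' lift_intervals(g, m)
#' @export
lift_intervals <- function(intervals, map, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  iv <- as_tibble(intervals)
  if (nrow(iv) == 0) return(mutate(iv, lift_flagged = logical(0)))
  out <- vector("list", nrow(iv))
  for (ch in unique(iv$chrom)) {
    sel <- iv$chrom == ch
    s <- lift_boundaries(map, ch, iv$start[sel], policy, side = "start")
    e <- lift_boundaries(map, ch, iv$end[sel], policy, side = "end")
    piece <- iv[sel, , drop = FALSE]
    piece$start <- s$pos
    piece$end <- e$pos
    piece$lift_flagged <- s$flagged | e$flagged
    out[[ch]] <- piece
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}
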