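# Interval algebra on 0-based half-open interval tibbles. The merged-set
# operations (merge/intersect/subtract/overlap length) are vectorized sweeps
# over a linearized coordinate space -- at desk scale this outperforms S4
# range containers by a wide margin and is verified against a per-base
# bitmask oracle. GenomicRanges is used for overlap queries, nearest
# distances and coverage piling.

# Linear layout: map each chromosome to a disjoint global coordinate slab
# (slab width = max end + 1, so intervals on different chromosomes can
# never merge).
lin_layout <- function(...) {
  xs <- list(...)
  all <- bind_rows(map(xs, function(x) x[, c("chrom", "end")]))
  m <- all |> group_by(.data$chrom) |> summarise(mx = max(.data$end), .groups = "drop") |>
    arrange(.data$chrom)
  off <- c(0, cumsum(m$mx + 1))[seq_len(nrow(m))]
  list(off = setNames(off, m$chrom), bounds = c(off, sum(m$mx + 1)),
       chroms = m$chrom)
}

to_lin <- function(x, layout) {
  list(s = x$start + layout$off[x$chrom], e = x$end + layout$off[x$chrom])
}

from_lin <- function(s, e, layout) {
  if (length(s) == 0) return(empty_intervals())
  i <- findInterval(s, layout$bounds)
  off <- layout$bounds[i]
  tibble(chrom = layout$chroms[i], start = as.double(s - off),
         end = as.double(e - off), name = NA_character_, score = NA_real_,
         strand = NA_character_)
}

# Merge possibly-overlapping linear intervals (abutting runs join).
merge_lin <- function(s, e) {
  if (length(s) == 0) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ecm <- cummax(e)
  new <- c(TRUE, s[-1] > ecm[-length(ecm)])
  list(s = s[new], e = ecm[c(which(new)[-1] - 1L, length(s))])
}

# Boolean sweep over two merged linear interval lists. keep(da, db) decides
# which inter-event segments survive.
sweep_lin <- function(a, b, keep) {
  pos <- c(a$s, a$e, b$s, b$e)
  if (length(pos) == 0) return(list(s = numeric(0), e = numeric(0)))
  da <- c(rep(1, length(a$s)), rep(-1, length(a$e)), rep(0, length(b$s) * 2))
  db <- c(rep(0, length(a$s) * 2), rep(1, length(b$s)), rep(-1, length(b$e)))
  o <- order(pos)
  pos <- pos[o]
  dac <- cumsum(da[o]); dbc <- cumsum(db[o])
  last <- !duplicated(pos, fromLast = TRUE)
  p <- pos[last]; dac <- dac[last]; dbc <- dbc[last]
  n <- length(p)
  if (n < 2) return(list(s = numeric(0), e = numeric(0)))
  act <- keep(dac[-n], dbc[-n])
  list(s = p[-n][act], e = p[-1][act])
}

# Build GRanges for two tables on a common seqlevel universe.
pair_granges <- function(a, b) {
  lev <- union(unique(a$chrom), unique(b$chrom))
  if (length(lev) == 0) lev <- "chrUnused"
  ga <- GenomicRanges::GRanges(
    seqnames = factor(a$chrom, levels = lev),
    ranges = IRanges::IRanges(start = a$start + 1, end = a$end))
  gb <- GenomicRanges::GRanges(
    seqnames = factor(b$chrom, levels = lev),
    ranges = IRanges::IRanges(start = b$start + 1, end = b$end))
  list(a = ga, b = gb)
}

#' Total base pairs shared by two interval sets
#'
#' Both sets are merged first, so overlapping records within one set are
#' counted once. Symmetric in its arguments.
#'
#' @param a,b Interval tibbles.
#' @return Total intersection length in bp (a single number).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' overlap_bp(a, b) # 50
#' @export
overlap_bp <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  lay <- lin_layout(a, b)
  ov <- sweep_lin(merge_lin_tbl(a, lay), merge_lin_tbl(b, lay),
                  function(da, db) da > 0 & db > 0)
  sum(ov$e - ov$s)
}

merge_lin_tbl <- function(x, lay) {
  l <- to_lin(x, lay)
  merge_lin(l$s, l$e)
}

#' Intersect two interval sets
#' @param a,b Interval tibbles.
#' @return Merged interval tibble covering the bases present in both sets.
#' @export
interval_intersect <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  lay <- lin_layout(a, b)
  ov <- sweep_lin(merge_lin_tbl(a, lay), merge_lin_tbl(b, lay),
                  function(da, db) da > 0 & db > 0)
  from_lin(ov$s, ov$e, lay)
}

#' Merge an interval set
#'
#' Overlapping and abutting records are joined; the result is sorted and
#' non-overlapping. Idempotent.
#'
#' @param a Interval tibble.
#' @return Merged interval tibble.
#' @export
interval_merge <- function(a) {
  a <- as_intervals(a)
  if (nrow(a) == 0) return(empty_intervals())
  lay <- lin_layout(a)
  m <- merge_lin_tbl(a, lay)
  from_lin(m$s, m$e, lay)
}

#' Subtract one interval set from another
#' @param a,b Interval tibbles.
#' @return Merged interval tibble covering the bases of `a` not in `b`.
#' @export
interval_subtract <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  if (nrow(a) == 0) return(empty_intervals())
  if (nrow(b) == 0) return(interval_merge(a))
  lay <- lin_layout(a, b)
  ov <- sweep_lin(merge_lin_tbl(a, lay), merge_lin_tbl(b, lay),
                  function(da, db) da > 0 & db == 0)
  from_lin(ov$s, ov$e, lay)
}

#' Promoter windows around transcription start sites
#'
#' One window `[tss - flank, tss + flank)` per gene, clipped at chromosome
#' ends. The default total width of 2 kb follows the convention of defining
#' a promoter as the 2 kb region surrounding the TSS.
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @param sizes Chromosome sizes tibble.
#' @param flank Half-width in bp (default 1000, i.e. a 2 kb window).
#' @return Interval tibble with `name` = `gene_id`, in input gene order.
#' @export
promoter_windows <- function(genes, sizes, flank = 1000) {
  sz <- setNames(as.double(sizes$size), sizes$chrom)
  unknown <- setdiff(unique(genes$chrom), names(sz))
  if (length(unknown) > 0) {
    abort(sprintf("promoter_windows: unknown chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (any(genes$tss < 0 | genes$tss >= sz[genes$chrom])) {
    abort("promoter_windows: TSS outside chromosome bounds")
  }
  tibble(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - flank),
    end = unname(pmin(sz[genes$chrom], genes$tss + flank)),
    name = genes$gene_id,
    score = NA_real_, strand = genes$strand %||% NA_character_
  )
}

#' Distance from each record of one set to the nearest record of another
#'
#' Overlapping (or directly abutting) records have distance 0; records on
#' chromosomes absent from `b` get `Inf`.
#'
#' @param a,b Interval tibbles (`b` non-empty).
#' @return `a` with an added `distance` column (bp gap), in `a`'s canonical
#'   order.
#' @export
distance_to_nearest <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  if (nrow(b) == 0) abort("distance_to_nearest: b is empty")
  if (nrow(a) == 0) return(mutate(a, distance = double()))
  g <- pair_granges(a, b)
  hits <- GenomicRanges::distanceToNearest(g$a, g$b)
  d <- rep(Inf, nrow(a))
  d[S4Vectors::queryHits(hits)] <- as.double(S4Vectors::mcols(hits)$distance)
  mutate(a, distance = d)
}

#' Fraction of a genome covered by an interval set
#'
#' Records are merged first, so overlapping records are counted once.
#'
#' @param a Interval tibble.
#' @param genome_bp Total genome size in bp.
#' @return Covered fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(a, genome_bp) {
  if (genome_bp <= 0) abort("coverage_fraction: genome_bp must be positive")
  m <- interval_merge(a)
  sum(m$end - m$start) / genome_bp
}

#' Fraction of records narrower than a width threshold
#'
#' Strict inequality: records exactly at the threshold are not counted.
#'
#' @param a Non-empty interval tibble.
#' @param threshold Width threshold in bp (default 750, roughly five
#'   nucleosomes).
#' @return Fraction of records with width < `threshold`.
#' @export
width_fraction_below <- function(a, threshold = 750) {
  a <- as_intervals(a)
  if (nrow(a) == 0) abort("width_fraction_below: empty interval set")
  mean((a$end - a$start) < threshold)
}

#' Shared and unique binding-site fractions across peak sets
#'
#' For each set, the fraction of its records overlapping (by at least 1 bp)
#' a record of any other set, and the complementary unique fraction.
#'
#' @param sets Named list of interval tibbles (at least two).
#' @return Tibble with one row per set: `name`, `n_sites`, `frac_shared`,
#'   `frac_unique`.
#' @export
overlap_summary <- function(sets) {
  if (length(sets) < 2) abort("overlap_summary: need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- map(sets, as_intervals)
  purrr::imap(sets, function(x, nm) {
    others <- bind_rows(sets[setdiff(names(sets), nm)])
    if (nrow(x) == 0) {
      return(tibble(name = nm, n_sites = 0L, frac_shared = NA_real_, frac_unique = NA_real_))
    }
    g <- pair_granges(x, others)
    shared <- GenomicRanges::countOverlaps(g$a, g$b) > 0
    tibble(name = nm, n_sites = nrow(x),
           frac_shared = mean(shared), frac_unique = mean(!shared))
  }) |> bind_rows()
}

#' Union of peak sets with per-region contributing-set counts
#'
#' Merges all sets into the regions bound by at least one of them, and for
#' each merged region counts how many of the input sets contribute at least
#' one overlapping record.
#'
#' @param sets Named list of interval tibbles.
#' @return Interval tibble of merged regions with an `n_sets` column.
#' @export
site_union <- function(sets) {
  sets <- map(sets, as_intervals)
  all <- bind_rows(sets)
  if (nrow(all) == 0) return(mutate(empty_intervals(), n_sets = integer()))
  u <- interval_merge(all)
  counts <- rep(0L, nrow(u))
  for (x in sets) {
    if (nrow(x) == 0) next
    g <- pair_granges(u, x)
    counts <- counts + as.integer(GenomicRanges::countOverlaps(g$a, g$b) > 0)
  }
  mutate(u, n_sets = counts)
}
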