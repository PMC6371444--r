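# Score matrices and average profiles over binned windows, signal
# correlation with clustering order, per-site methylation/accessibility
# summaries and sequence composition.

# Integral step function of a run-length signal track in global
# coordinates: S(x) = integral of signal over [0, x).
signal_integral <- function(track, sizes) {
  offsets <- chrom_offsets(sizes)
  if (nrow(track) == 0) {
    return(list(breaks = 0, cum = 0, slope = 0, offsets = offsets))
  }
  g <- globalize(track, offsets)
  o <- order(g$gstart)
  gs <- g$gstart[o]; ge <- g$gend[o]; v <- g$value[o]
  area <- (ge - gs) * v
  cuma <- cumsum(area)
  breaks <- as.double(rbind(gs, ge))
  cum <- as.double(rbind(c(0, head(cuma, -1)), cuma))
  slope <- as.double(rbind(v, rep(0, length(v))))
  list(breaks = breaks, cum = cum, slope = slope, offsets = offsets)
}

signal_integral_eval <- function(si, x) {
  i <- findInterval(x, si$breaks)
  out <- numeric(length(x))
  pos <- i > 0
  out[pos] <- si$cum[i[pos]] + si$slope[i[pos]] * (x[pos] - si$breaks[i[pos]])
  out
}

#' Binned signal score matrix around region centres
#'
#' Each region contributes one row: the window `[centre - flank,
#' centre + flank)` (centre = floor midpoint; even-width ties resolve
#' leftward) split into `n_bins` equal-width bins, each bin valued by the
#' mean per-base signal. Windows clipped at chromosome ends are padded with
#' zeros. When `2 * flank` is not a multiple of `n_bins`, bin widths differ
#' by at most 1 bp.
#'
#' @param track Signal track (see [signal_track()] / [read_bedgraph()]).
#' @param regions Interval tibble of regions.
#' @param sizes Chromosome sizes tibble; defaults to the track's attached
#'   sizes.
#' @param flank Half-window in bp (default 2000).
#' @param n_bins Number of bins (default 100).
#' @return Object of class `chromstrat_score_matrix`: list with `matrix`
#'   (regions x bins), `regions`, `bin_mid` (bin midpoints relative to the
#'   centre), `flank`, `n_bins`.
#' @export
score_matrix <- function(track, regions, sizes = attr(track, "sizes"),
                         flank = 2000, n_bins = 100) {
  if (is.null(sizes)) abort("score_matrix: no chromosome sizes available")
  regions <- as_intervals(regions, sizes = sizes)
  if (nrow(regions) == 0) abort("score_matrix: no regions")
  if (n_bins < 1) abort("score_matrix: n_bins must be >= 1")
  si <- signal_integral(track, sizes)
  offsets <- si$offsets
  sz <- setNames(as.double(sizes$size), sizes$chrom)
  centre <- floor((regions$start + regions$end) / 2)
  edges_rel <- round(seq(-flank, flank, length.out = n_bins + 1))
  # per-region global clamp range
  g0 <- offsets[regions$chrom]
  lo <- g0
  hi <- g0 + sz[regions$chrom]
  mat <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  gcentre <- g0 + centre
  Fe <- matrix(0, nrow = nrow(regions), ncol = n_bins + 1)
  for (j in seq_len(n_bins + 1)) {
    x <- pmin(pmax(gcentre + edges_rel[j], lo), hi)
    Fe[, j] <- signal_integral_eval(si, x)
  }
  widths <- diff(edges_rel)
  for (j in seq_len(n_bins)) {
    mat[, j] <- (Fe[, j + 1] - Fe[, j]) / widths[j]
  }
  rownames(mat) <- regions$name %||% NULL
  structure(list(matrix = mat, regions = regions,
                 bin_mid = (edges_rel[-1] + edges_rel[-(n_bins + 1)]) / 2,
                 flank = flank, n_bins = n_bins),
            class = "chromstrat_score_matrix")
}

#' Average signal profile of a score matrix
#' @param sm A `chromstrat_score_matrix`.
#' @return Tibble `bin`, `rel_pos` (bp from centre), `mean_signal`.
#' @export
average_profile <- function(sm) {
  tibble(bin = seq_len(sm$n_bins), rel_pos = sm$bin_mid,
         mean_signal = colMeans(sm$matrix))
}

#' Pearson correlation matrix with hierarchical-clustering order
#'
#' Computes pairwise Pearson correlations between per-site signal vectors
#' and orders the matrix by average-linkage hierarchical clustering on the
#' Euclidean distances between the correlation-matrix rows.
#'
#' @param signals Data frame (or named list of equal-length numeric
#'   vectors): one column per data set, one row per site.
#' @return Object of class `chromstrat_cormat`: list with `r` (correlation
#'   matrix), `order` (leaf order indices), `labels`.
#' @export
correlation_cluster <- function(signals) {
  m <- as.matrix(as.data.frame(signals))
  if (ncol(m) < 2) abort("correlation_cluster: need at least 2 signal vectors")
  if (nrow(m) < 3) abort("correlation_cluster: need at least 3 sites")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    abort("correlation_cluster: zero-variance signal vector")
  }
  r <- cor(m, method = "pearson")
  hc <- hclust(dist(r), method = "average")
  structure(list(r = r, order = hc$order, labels = colnames(m)[hc$order]),
            class = "chromstrat_cormat")
}

#' Mean methylation (or accessibility) ratio within sites
#'
#' For each site, the mean of per-position ratios `methylated / total` over
#' positions inside the site with coverage strictly greater than `min_cov`.
#' Serves both bisulphite CpG methylation and NOMe-seq GCH accessibility
#' tables. Sites without any qualifying position get `NA`.
#'
#' @param meth Methylation tibble (see [read_methylation()]).
#' @param sites Interval tibble.
#' @param min_cov Coverage threshold (positions with `total > min_cov`
#'   qualify; default 5).
#' @return `sites` with added `mean_methylation` and `n_covered_sites`
#'   columns.
#' @export
site_mean_methylation <- function(meth, sites, min_cov = 5) {
  sites <- as_tibble(sites)
  keep <- filter(meth, .data$total > min_cov)
  out <- mutate(sites, mean_methylation = NA_real_, n_covered_sites = 0L)
  if (nrow(keep) == 0 || nrow(sites) == 0) return(out)
  pos_iv <- tibble(chrom = keep$chrom, start = keep$pos, end = keep$pos + 1)
  g <- pair_granges(sites, pos_iv)
  hits <- GenomicRanges::findOverlaps(g$a, g$b)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) > 0) {
    d <- tibble(site = qi, ratio = keep$methylated[si] / keep$total[si]) |>
      group_by(.data$site) |>
      summarise(m = mean(.data$ratio), k = dplyr::n(), .groups = "drop")
    out$mean_methylation[d$site] <- d$m
    out$n_covered_sites[d$site] <- d$k
  }
  out
}

site_views <- function(genome, sites) {
  missing <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing) > 0) {
    abort(sprintf("chromosome(s) missing from genome: %s",
                  paste(missing, collapse = ", ")))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(sites$end > lens[sites$chrom])) {
    abort("site extends beyond sequence end")
  }
  sites
}

per_site_letters <- function(genome, sites, fun) {
  sites <- site_views(genome, as_tibble(sites))
  idx_by_chrom <- split(seq_len(nrow(sites)), sites$chrom)
  out <- NULL
  for (ch in names(idx_by_chrom)) {
    i <- idx_by_chrom[[ch]]
    v <- Biostrings::Views(genome[[ch]], start = sites$start[i] + 1,
                           end = sites$end[i])
    res <- fun(v)
    if (is.null(out)) out <- matrix(0, nrow = nrow(sites), ncol = ncol(res),
                                    dimnames = list(NULL, colnames(res)))
    out[i, ] <- res
  }
  out
}

#' Per-site nucleotide density
#'
#' Fractions of A, C, G and T over each site's sequence; ambiguous bases
#' (N) are excluded from the denominator.
#'
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome.
#' @param sites Interval tibble.
#' @return `sites` with added `A`, `C`, `G`, `T` fraction columns.
#' @export
nucleotide_density <- function(genome, sites) {
  counts <- per_site_letters(genome, sites, function(v) {
    Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  })
  denom <- rowSums(counts)
  frac <- counts / ifelse(denom == 0, NA, denom)
  bind_cols(as_tibble(sites), as_tibble(frac))
}

#' Per-site overlapping dinucleotide frequencies
#'
#' The 16 dinucleotide fractions over each site's sequence, counted in
#' overlapping windows of two; windows containing an ambiguous base do not
#' contribute.
#'
#' @inheritParams nucleotide_density
#' @return `sites` with 16 added fraction columns (`AA` ... `TT`).
#' @export
dinucleotide_frequency <- function(genome, sites) {
  counts <- per_site_letters(genome, sites, function(v) {
    Biostrings::dinucleotideFrequency(v)
  })
  denom <- rowSums(counts)
  frac <- counts / ifelse(denom == 0, NA, denom)
  bind_cols(as_tibble(sites), as_tibble(frac))
}

#' CpG dinucleotide density per interval
#'
#' CpG count divided by interval width in bp.
#'
#' @inheritParams nucleotide_density
#' @param intervals Interval tibble.
#' @return `intervals` with an added `cpg_density` column.
#' @export
cpg_density <- function(genome, intervals) {
  counts <- per_site_letters(genome, intervals, function(v) {
    Biostrings::dinucleotideFrequency(v)
  })
  mutate(as_tibble(intervals),
         cpg_density = unname(counts[, "CG"]) / (.data$end - .data$start))
}
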