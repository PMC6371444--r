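# Rule-based classification of regulatory elements from histone-mark peak
# sets: promoter classes, distal enhancers, collapsed chromatin states,
# CpG-island methylation status and chromatin-loop anchor types.

overlaps_any <- function(x, feature) {
  if (nrow(x) == 0) return(logical(0))
  if (is.null(feature) || nrow(feature) == 0) return(rep(FALSE, nrow(x)))
  g <- pair_granges(x, feature)
  GenomicRanges::countOverlaps(g$a, g$b) > 0
}

#' Classify promoter windows by their histone marks
#'
#' A window is labelled by the marks it overlaps (>= 1 bp), with precedence
#' bivalent (H3K4me3 and H3K27me3) > active (H3K4me3 and H3K27ac) >
#' facultative repressed (H3K27me3) > constitutively repressed (H3K9me3) >
#' unclassified. Bivalency takes priority because it is defined by the very
#' co-occurrence the other classes would mask; windows carrying all three of
#' H3K4me3/H3K27ac/H3K27me3 are therefore called bivalent and flagged in the
#' `multi_mark` column.
#'
#' @param windows Promoter window tibble (see [promoter_windows()]).
#' @param marks Named list of interval tibbles; must contain `H3K4me3`,
#'   `H3K27ac`, `H3K27me3`, `H3K9me3`.
#' @return `windows` with added `label` (one of `active`, `bivalent`,
#'   `facultative_repressed`, `constitutive_repressed`, `unclassified`) and
#'   `multi_mark` columns.
#' @export
classify_promoters <- function(windows, marks) {
  need <- c("H3K4me3", "H3K27ac", "H3K27me3", "H3K9me3")
  missing <- setdiff(need, names(marks))
  if (length(missing) > 0) {
    abort(sprintf("classify_promoters: missing mark set(s): %s",
                  paste(missing, collapse = ", ")))
  }
  k4 <- overlaps_any(windows, marks$H3K4me3)
  k27ac <- overlaps_any(windows, marks$H3K27ac)
  k27me3 <- overlaps_any(windows, marks$H3K27me3)
  k9 <- overlaps_any(windows, marks$H3K9me3)
  label <- dplyr::case_when(
    k4 & k27me3 ~ "bivalent",
    k4 & k27ac ~ "active",
    k27me3 ~ "facultative_repressed",
    k9 ~ "constitutive_repressed",
    TRUE ~ "unclassified"
  )
  mutate(as_tibble(windows), label = label, multi_mark = k4 & k27ac & k27me3)
}

#' Classify distal enhancers as active or poised
#'
#' Candidates are H3K4me1 peaks at least `min_tss_distance` bp away from
#' every annotated TSS. A candidate is `active` if it overlaps (>= 1 bp)
#' each of H3K27ac, p300 and a DNaseI-accessible site, otherwise `poised`.
#'
#' @param k4me1 H3K4me1 peak tibble.
#' @param tss Gene tibble (`chrom`, `tss`) or an interval tibble of TSS
#'   positions.
#' @param k27ac,p300,dnase Interval tibbles of the supporting marks.
#' @param min_tss_distance Minimum distance from a TSS (default 2000 bp).
#' @return Tibble of candidate enhancers with a `label` column
#'   (`active` / `poised`) and the TSS `distance`.
#' @export
classify_enhancers <- function(k4me1, tss, k27ac, p300, dnase,
                               min_tss_distance = 2000) {
  k4me1 <- as_intervals(k4me1)
  if ("tss" %in% names(tss)) {
    tss_iv <- tibble(chrom = tss$chrom, start = tss$tss, end = tss$tss + 1)
  } else {
    tss_iv <- as_intervals(tss)
  }
  cand <- distance_to_nearest(k4me1, tss_iv)
  cand <- filter(cand, .data$distance >= min_tss_distance)
  if (nrow(cand) == 0) return(mutate(cand, label = character(0)))
  act <- overlaps_any(cand, as_intervals(k27ac)) &
    overlaps_any(cand, as_intervals(p300)) &
    overlaps_any(cand, as_intervals(dnase))
  mutate(cand, label = if_else(act, "active", "poised"))
}

#' Default chromatin-state collapse table
#'
#' Maps the 15 Roadmap-style segmentation states onto the six collapsed
#' labels used throughout the package: promoters and flanking promoters to
#' `active_promoter`; strong/weak transcription and transcription at gene
#' ends to `transcription`; genic and other enhancers to `active_enhancer`;
#' bivalent promoters, flanking bivalent promoters and bivalent enhancers to
#' `bivalent`; polycomb, weak polycomb, zinc-finger repeats and
#' heterochromatin to `repressive`; and quiescent chromatin to `unmarked`.
#'
#' @return Tibble with columns `state`, `label`.
#' @export
default_state_collapse <- function() {
  tibble::tribble(
    ~state, ~label,
    "TssA", "active_promoter",
    "TssAFlnk", "active_promoter",
    "TxFlnk", "transcription",
    "Tx", "transcription",
    "TxWk", "transcription",
    "EnhG", "active_enhancer",
    "Enh", "active_enhancer",
    "ZNF/Rpts", "repressive",
    "Het", "repressive",
    "TssBiv", "bivalent",
    "BivFlnk", "bivalent",
    "EnhBiv", "bivalent",
    "ReprPC", "repressive",
    "ReprPCWk", "repressive",
    "Quies", "unmarked"
  )
}

#' Collapse a chromatin-state segmentation
#'
#' Relabels every segment via a state-to-label mapping, merges abutting
#' same-label segments, and reports per-label genome fractions.
#'
#' @param segmentation Interval tibble whose `name` column holds state
#'   names.
#' @param mapping Tibble with columns `state`, `label` (default:
#'   [default_state_collapse()]).
#' @return List with `segments` (relabelled, merged-per-label interval
#'   tibble) and `fractions` (tibble `label`, `bp`, `fraction` of the total
#'   segmented bp).
#' @export
collapse_states <- function(segmentation, mapping = default_state_collapse()) {
  segmentation <- as_intervals(segmentation)
  unmapped <- setdiff(unique(segmentation$name), mapping$state)
  if (length(unmapped) > 0) {
    abort(sprintf("collapse_states: unmapped state name(s): %s",
                  paste(unmapped, collapse = ", ")))
  }
  lab <- setNames(mapping$label, mapping$state)
  seg <- mutate(segmentation, label = lab[.data$name])
  merged <- seg |>
    group_by(.data$label) |>
    group_split() |>
    map(function(d) mutate(interval_merge(d), name = d$label[1])) |>
    bind_rows() |>
    sort_intervals()
  total <- sum(segmentation$end - segmentation$start)
  fractions <- merged |>
    group_by(label = .data$name) |>
    summarise(bp = sum(.data$end - .data$start), .groups = "drop") |>
    mutate(fraction = .data$bp / total)
  list(segments = merged, fractions = fractions)
}

#' Classify CpG islands as methylated or unmethylated
#'
#' Each island is split into `n_bins` equal-width bins; within each bin the
#' mean of per-site methylation ratios is taken over CpG sites with coverage
#' strictly greater than `min_cov`, and the island mean is the mean over
#' non-empty bins. Islands with mean methylation above 50% are `methylated`
#' (strictly above: a mean of exactly 0.5 is `unmethylated`); islands with
#' no sufficiently covered site are `no_data`. An island is a promoter
#' island when it overlaps at least one TSS window.
#'
#' @param islands CpG-island interval tibble.
#' @param tss_windows Promoter window tibble (for the promoter-island flag).
#' @param meth CpG methylation table (see [read_methylation()]).
#' @param n_bins Number of equal-width bins per island (default 40).
#' @param min_cov Coverage threshold; sites with `total > min_cov` qualify
#'   (default 5).
#' @return `islands` with added `is_promoter_island`, `mean_methylation`,
#'   `n_informative_bins` and `label` columns.
#' @export
classify_cpg_islands <- function(islands, tss_windows, meth, n_bins = 40,
                                 min_cov = 5) {
  if (n_bins < 1) abort("classify_cpg_islands: n_bins must be >= 1")
  islands <- as_intervals(islands)
  if (any(meth$context != "CpG")) {
    abort("classify_cpg_islands: methylation table context must be CpG")
  }
  is_prom <- overlaps_any(islands, as_intervals(tss_windows))
  sites <- filter(meth, .data$total > min_cov)
  out <- islands
  out$is_promoter_island <- is_prom
  mm <- rep(NA_real_, nrow(islands))
  nb <- integer(nrow(islands))
  if (nrow(sites) > 0 && nrow(islands) > 0) {
    site_iv <- tibble(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1)
    g <- pair_granges(islands, site_iv)
    hits <- GenomicRanges::findOverlaps(g$a, g$b)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi) > 0) {
      width <- islands$end[qi] - islands$start[qi]
      rel <- (sites$pos[si] - islands$start[qi]) / width
      bin <- pmin(floor(rel * n_bins) + 1, n_bins)
      ratio <- sites$methylated[si] / sites$total[si]
      d <- tibble(island = qi, bin = bin, ratio = ratio) |>
        group_by(.data$island, .data$bin) |>
        summarise(bin_mean = mean(.data$ratio), .groups = "drop") |>
        group_by(.data$island) |>
        summarise(mean_methylation = mean(.data$bin_mean),
                  n_informative_bins = dplyr::n(), .groups = "drop")
      mm[d$island] <- d$mean_methylation
      nb[d$island] <- d$n_informative_bins
    }
  }
  out$mean_methylation <- mm
  out$n_informative_bins <- nb
  out$label <- dplyr::case_when(
    is.na(mm) ~ "no_data",
    mm > 0.5 ~ "methylated",
    TRUE ~ "unmethylated"
  )
  out
}

#' Classify loop anchors as Type A or Type B
#'
#' An anchor is Type A when it overlaps (>= 1 bp) at least one active
#' promoter or active enhancer, otherwise Type B. The two anchors of a loop
#' are classified independently.
#'
#' @param loops Loop tibble (see [read_bedpe()]) or an interval tibble of
#'   anchors.
#' @param active_promoters,active_enhancers Interval tibbles of active
#'   elements.
#' @return Interval tibble of anchors with a `label` column
#'   (`TypeA` / `TypeB`).
#' @export
classify_anchors <- function(loops, active_promoters, active_enhancers) {
  anchors <- if ("chrom_a" %in% names(loops)) loop_anchors(loops) else as_intervals(loops)
  act <- overlaps_any(anchors, as_intervals(active_promoters)) |
    overlaps_any(anchors, as_intervals(active_enhancers))
  mutate(anchors, label = if_else(act, "TypeA", "TypeB"))
}
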