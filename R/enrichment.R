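# Monte-Carlo randomization test for segment-annotation overlap enrichment.
#
# Null model: each segment is independently re-placed uniformly at random
# within the workspace (the mappable genome), preserving its length and
# restricted to workspace intervals long enough to contain it; sampled
# segments may overlap each other. The observed total base-pair overlap with
# the annotation is compared to the overlap distribution across iterations.
# This is the simplest defensible null for observed-over-expected fold
# enrichment of peak sets at annotations; no isochore or composition
# matching is attempted.

#' Build a workspace from a chromosome sizes table
#'
#' The default workspace is the whole genome: one interval per chromosome.
#'
#' @param sizes Chromosome sizes tibble (`chrom`, `size`).
#' @return Merged interval tibble spanning every chromosome.
#' @export
genome_workspace <- function(sizes) {
  as_intervals(tibble(chrom = sizes$chrom, start = 0, end = as.double(sizes$size)))
}

# Map an interval set into the concatenated workspace coordinate system
# (x is intersected with the workspace first) and return its
# cumulative-coverage step function there.
conc_intervals <- function(x, workspace, ws_goff) {
  xi <- interval_intersect(x, workspace)
  if (nrow(xi) == 0) return(list(cs = numeric(0), ce = numeric(0)))
  # workspace is merged and canonically sorted, and every xi piece lies
  # within exactly one workspace interval
  lay <- lin_layout(xi, workspace)
  wl <- to_lin(workspace, lay)
  xl <- to_lin(xi, lay)
  si <- findInterval(xl$s, wl$s)
  list(cs = xl$s - wl$s[si] + ws_goff[si],
       ce = xl$e - wl$s[si] + ws_goff[si])
}

conc_coverage <- function(x, workspace, ws_goff) {
  ci <- conc_intervals(x, workspace, ws_goff)
  coverage_fun(ci$cs, ci$ce)
}

# Internal: shared geometry preparation for the sampler. Workspace intervals
# are laid out in a concatenated linear coordinate; the annotation becomes a
# cumulative-coverage step function F so that the overlap of a placed
# segment [s, e) is F(e) - F(s).
null_geometry <- function(segments, annotation, workspace) {
  workspace <- interval_merge(workspace)
  if (nrow(workspace) == 0) abort("empty workspace")
  # concatenated layout: one slot per workspace interval
  ws_len <- workspace$end - workspace$start
  ws_goff <- c(0, cumsum(ws_len))[seq_len(nrow(workspace))]
  cf <- conc_coverage(annotation, workspace, ws_goff)
  seg_len <- as.double(segments$end - segments$start)
  n_seg <- length(seg_len)
  m <- length(ws_len)
  if (n_seg > 0 && max(seg_len) > max(ws_len)) {
    abort("a segment is longer than every workspace interval")
  }
  # eligible start positions per (segment, workspace interval)
  elig <- matrix(0, nrow = max(n_seg, 1), ncol = m)
  if (n_seg > 0) {
    for (i in seq_len(m)) elig[, i] <- pmax(ws_len[i] - seg_len + 1, 0)
  }
  total <- rowSums(elig)
  if (n_seg > 0 && any(total <= 0)) {
    abort("a segment is longer than every workspace interval")
  }
  cum_elig <- elig
  if (m > 1) for (i in 2:m) cum_elig[, i] <- cum_elig[, i - 1] + elig[, i]
  list(workspace = workspace, ws_len = ws_len, ws_goff = ws_goff,
       cf = cf, seg_len = seg_len, n_seg = n_seg,
       elig = elig, cum_elig = cum_elig, total = total)
}

# Internal: draw k placements per segment (consumes the current RNG stream).
# Returns concatenated-coordinate starts/ends, column-major by iteration.
draw_placements <- function(geom, k) {
  n_seg <- geom$n_seg
  m <- length(geom$ws_len)
  u <- matrix(runif(n_seg * k) * geom$total, nrow = n_seg)
  idx <- matrix(1L, nrow = n_seg, ncol = k)
  if (m > 1) {
    for (i in seq_len(m - 1)) idx <- idx + (u >= geom$cum_elig[, i])
  }
  lin <- rep(seq_len(n_seg), k) + (as.vector(idx) - 1L) * n_seg
  offset_in_ws <- as.vector(u) - (geom$cum_elig[lin] - geom$elig[lin])
  s <- floor(offset_in_ws) + geom$ws_goff[as.vector(idx)]
  list(s = s, e = s + rep(geom$seg_len, k), k = k)
}

# Total overlap per iteration for drawn placements against a coverage fn.
placement_overlaps <- function(cf, pl, n_seg) {
  ov <- coverage_eval(cf, pl$e) - coverage_eval(cf, pl$s)
  colSums(matrix(ov, nrow = n_seg))
}

# Internal: sample total null overlaps. Returns a vector of length n_iter.
sample_null_core <- function(geom, n_iter, seed, chunk_bp = 4e6) {
  if (geom$n_seg == 0) return(rep(0, n_iter))
  out <- numeric(n_iter)
  chunk <- max(1L, as.integer(chunk_bp / geom$n_seg))
  done <- 0L
  withr::with_seed(seed, {
    while (done < n_iter) {
      k <- min(chunk, n_iter - done)
      pl <- draw_placements(geom, k)
      out[done + seq_len(k)] <- placement_overlaps(geom$cf, pl, geom$n_seg)
      done <- done + k
    }
  })
  out
}

#' Sample the null distribution of total overlap
#'
#' Draws `n_iter` randomizations in which every segment is independently
#' re-placed uniformly within the workspace (length preserved), and records
#' the total bp overlap with the annotation for each iteration.
#' Deterministic for a given seed.
#'
#' @param segments Interval tibble of segments (e.g. remodeller peaks).
#' @param annotation Interval tibble of the annotation being tested.
#' @param workspace Interval tibble of the mappable genome.
#' @param n_iter Number of randomizations.
#' @param seed Integer seed.
#' @return Numeric vector of `n_iter` total overlaps (bp).
#' @export
sample_null_overlaps <- function(segments, annotation, workspace, n_iter, seed) {
  segments <- as_intervals(segments)
  geom <- null_geometry(segments, as_intervals(annotation), as_intervals(workspace))
  sample_null_core(geom, n_iter, seed)
}

#' Exact expected overlap for a single segment on a contiguous workspace
#'
#' Closed-form mean, over all `W - L + 1` possible placements of a segment
#' of length `L` on a workspace `[0, W)`, of its overlap with an annotation.
#' Computed by summing per-base inclusion probabilities; serves as the
#' independent oracle for the Monte-Carlo sampler.
#'
#' @param L Segment length (bp).
#' @param annotation Interval tibble on a single chromosome spanned by the
#'   workspace (coordinates in `[0, W)`).
#' @param W Workspace length (bp).
#' @return Expected overlap in bp.
#' @export
analytic_expected_overlap <- function(L, annotation, W) {
  if (L > W) abort("analytic_expected_overlap: L > W")
  ann <- interval_merge(annotation)
  if (nrow(ann) > 0 && (length(unique(ann$chrom)) > 1 || any(ann$end > W))) {
    abort("analytic_expected_overlap: annotation must lie on one chromosome within [0, W)")
  }
  if (nrow(ann) == 0) return(0)
  n_place <- W - L + 1
  total <- 0
  for (i in seq_len(nrow(ann))) {
    b <- seq(ann$start[i], ann$end[i] - 1)
    covering <- pmin(b, W - L) - pmax(0, b - L + 1) + 1
    total <- total + sum(covering)
  }
  total / n_place
}

#' Fold enrichment of segments at an annotation
#'
#' Observed total overlap is compared to the randomization null. The fold is
#' `(observed + 1) / (expected + 1)` with a 1 bp pseudocount on each side so
#' the fold stays finite when the expected overlap is near zero. The
#' empirical p-value uses the `(1 + k) / (1 + n)` estimator on the tail in
#' the direction of the observed effect (upper tail when fold >= 1, lower
#' tail otherwise), so p is never exactly 0. Scores above one indicate
#' enrichment, below one depletion.
#'
#' @inheritParams sample_null_overlaps
#' @param segments_name,feature_name Labels carried into the result.
#' @return One-row tibble of class `chromstrat_enrichment` with columns
#'   `segments_name`, `feature_name`, `observed_bp`, `expected_bp`, `fold`,
#'   `p_empirical`, `q_bh`, `n_iter`, `seed`.
#' @export
fold_enrichment <- function(segments, annotation, workspace, n_iter = 10000,
                            seed = 1L, segments_name = "segments",
                            feature_name = "feature") {
  segments <- as_intervals(segments)
  annotation <- as_intervals(annotation)
  workspace <- as_intervals(workspace)
  geom <- null_geometry(segments, annotation, workspace)
  null <- sample_null_core(geom, n_iter, seed)
  observed <- overlap_bp(segments, interval_intersect(annotation, workspace))
  res <- enrichment_row(observed, null, n_iter, seed, segments_name, feature_name)
  class(res) <- c("chromstrat_enrichment", class(res))
  res
}

# Shared observed-vs-null summarisation.
enrichment_row <- function(observed, null, n_iter, seed, segments_name, feature_name) {
  expected <- mean(null)
  fold <- (observed + 1) / (expected + 1)
  p_upper <- (1 + sum(null >= observed)) / (n_iter + 1)
  p_lower <- (1 + sum(null <= observed)) / (n_iter + 1)
  p <- if (fold >= 1) p_upper else p_lower
  tibble(
    segments_name = segments_name, feature_name = feature_name,
    observed_bp = observed, expected_bp = expected, fold = fold,
    p_empirical = p, p_enrich = p_upper, q_bh = NA_real_,
    n_iter = as.integer(n_iter), seed = as.integer(seed)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values, clipped at 1, preserving input order. A thin
#' validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Vector of adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("bh_adjust: p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Two-sample contrast between group mean enrichment folds
#'
#' Pooled-variance (unpaired Student) t-test comparing the fold enrichments
#' of the two remodeller groups at one feature, two-sided, with
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param folds_g1,folds_g2 Numeric vectors of fold enrichments (length >= 2
#'   each).
#' @param feature_name Label carried into the result.
#' @return One-row tibble: `feature_name`, `mean_g1`, `mean_g2`,
#'   `t_statistic`, `df`, `p_two_sided`.
#' @export
group_mean_test <- function(folds_g1, folds_g2, feature_name = "feature") {
  if (length(folds_g1) < 2 || length(folds_g2) < 2) {
    abort("group_mean_test: need at least 2 values per group")
  }
  n1 <- length(folds_g1); n2 <- length(folds_g2)
  sp2 <- ((n1 - 1) * stats::var(folds_g1) + (n2 - 1) * stats::var(folds_g2)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    abort("group_mean_test: zero pooled variance (degenerate input)")
  }
  tt <- t.test(folds_g1, folds_g2, var.equal = TRUE)
  tibble(
    feature_name = feature_name,
    mean_g1 = mean(folds_g1), mean_g2 = mean(folds_g2),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_two_sided = tt$p.value
  )
}

#' Enrichment matrix across remodellers and features
#'
#' Runs the randomization test for every (segments, feature) pair. For each
#' remodeller, one set of `n_iter` null placements is drawn (from a
#' remodeller-specific substream of `seed`) and evaluated against every
#' feature, so the whole matrix is deterministic for a given seed.
#' Benjamini-Hochberg q-values are computed within each feature family
#' (the `family` argument maps features to families; by default each feature
#' is its own family, the analogue of adjusting per figure panel).
#'
#' @param remodeller_sets Named list of segment interval tibbles.
#' @param feature_sets Named list of annotation interval tibbles.
#' @param workspace Workspace interval tibble.
#' @param n_iter Randomization iterations per test.
#' @param seed Integer seed.
#' @param family Optional named character vector mapping feature names to
#'   BH families.
#' @return Tibble of class `chromstrat_enrichment`, one row per pair.
#' @export
enrichment_matrix <- function(remodeller_sets, feature_sets, workspace,
                              n_iter = 10000, seed = 1L, family = NULL) {
  if (length(remodeller_sets) == 0 || length(feature_sets) == 0) {
    abort("enrichment_matrix: empty input map")
  }
  workspace <- interval_merge(as_intervals(workspace))
  feature_sets <- map(feature_sets, as_intervals)
  if (is.null(family)) {
    family <- setNames(names(feature_sets), names(feature_sets))
  }
  ws_len <- workspace$end - workspace$start
  ws_goff <- c(0, cumsum(ws_len))[seq_len(nrow(workspace))]
  cfs <- map(feature_sets, conc_coverage, workspace = workspace, ws_goff = ws_goff)
  rows <- imap(remodeller_sets, function(segs, rname) {
    segs <- as_intervals(segs)
    rseed <- substream_seed(seed, paste0("enrich/", rname))
    geom <- null_geometry(segs, empty_intervals(), workspace)
    # One placement stream per remodeller, shared across features: the null
    # placements depend only on the segments and the workspace, so each
    # chunk of placements is evaluated against every annotation.
    nulls <- matrix(0, nrow = n_iter, ncol = length(cfs))
    if (geom$n_seg > 0) {
      chunk <- max(1L, as.integer(4e6 / geom$n_seg))
      withr::with_seed(rseed, {
        done <- 0L
        while (done < n_iter) {
          k <- min(chunk, n_iter - done)
          p <- draw_placements(geom, k)
          for (j in seq_along(cfs)) {
            nulls[done + seq_len(k), j] <- placement_overlaps(cfs[[j]], p, geom$n_seg)
          }
          done <- done + k
        }
      })
    }
    seg_conc <- conc_intervals(interval_merge(segs), workspace, ws_goff)
    imap(feature_sets, function(feat, fname) {
      j <- match(fname, names(feature_sets))
      observed <- sum(coverage_eval(cfs[[j]], seg_conc$ce) -
                        coverage_eval(cfs[[j]], seg_conc$cs))
      enrichment_row(observed, nulls[, j], n_iter, rseed, rname, fname)
    }) |> bind_rows()
  }) |> bind_rows()
  rows <- rows |>
    mutate(.family = family[.data$feature_name]) |>
    group_by(.data$.family) |>
    mutate(q_bh = bh_adjust(.data$p_empirical)) |>
    ungroup() |>
    select(-".family")
  class(rows) <- c("chromstrat_enrichment", class(rows))
  rows
}

#' Group contrasts across an enrichment matrix
#'
#' Applies [group_mean_test()] feature by feature, comparing the folds of
#' the two remodeller groups.
#'
#' @param enrichment Result of [enrichment_matrix()].
#' @param groups Named character vector mapping remodeller names to
#'   `"Group1"` / `"Group2"`.
#' @return Tibble with one row per feature.
#' @export
group_contrasts <- function(enrichment, groups) {
  enrichment |>
    mutate(group = groups[.data$segments_name]) |>
    group_by(.data$feature_name) |>
    group_split() |>
    map(function(d) {
      group_mean_test(d$fold[d$group == "Group1"], d$fold[d$group == "Group2"],
                      feature_name = d$feature_name[1])
    }) |>
    bind_rows()
}
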