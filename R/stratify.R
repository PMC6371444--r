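# Headline computations: algorithmic two-group stratification of
# remodellers from their enrichment profiles, expression linkage of
# promoter binding, and genome-architecture partitioning.

#' Stratify remodellers into two groups from an enrichment matrix
#'
#' Remodellers are clustered by average-linkage hierarchical clustering of
#' their log-fold enrichment profiles (Euclidean distance), cut at k = 2.
#' The cluster with the higher mean log-fold over the active features is
#' labelled Group 1, the other Group 2. Each remodeller also receives a
#' contrast score: mean log-fold at active features minus mean log-fold at
#' repressive features.
#'
#' @param enrichment Result of [enrichment_matrix()], or any tibble with
#'   `segments_name`, `feature_name`, `fold`.
#' @param active_features,repressive_features Character vectors of feature
#'   names.
#' @return Object of class `chromstrat_groups`: list with `assignments`
#'   (tibble `name`, `group`, `contrast`), `profile` (log-fold matrix) and
#'   `separation` (between-group minus within-group mean log-fold
#'   distance).
#' @export
stratify_remodellers <- function(enrichment, active_features,
                                 repressive_features) {
  if (length(active_features) == 0 || length(repressive_features) == 0) {
    abort("stratify_remodellers: both feature classes must be non-empty")
  }
  prof <- enrichment |>
    select("segments_name", "feature_name", "fold") |>
    mutate(logfold = log(.data$fold)) |>
    select(-"fold") |>
    tidyr::pivot_wider(names_from = "feature_name", values_from = "logfold")
  m <- as.matrix(prof[, -1])
  rownames(m) <- prof$segments_name
  if (nrow(m) < 2) abort("stratify_remodellers: need at least 2 remodellers")
  if (all(dist(m) == 0)) {
    abort("stratify_remodellers: all remodeller profiles identical")
  }
  missing <- setdiff(c(active_features, repressive_features), colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("stratify_remodellers: feature(s) not in matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  hc <- hclust(dist(m), method = "average")
  cl <- cutree(hc, k = 2)
  act_mean <- rowMeans(m[, active_features, drop = FALSE])
  rep_mean <- rowMeans(m[, repressive_features, drop = FALSE])
  g1_cluster <- if (mean(act_mean[cl == 1]) >= mean(act_mean[cl == 2])) 1 else 2
  group <- if_else(cl == g1_cluster, "Group1", "Group2")
  d <- as.matrix(dist(m))
  within <- mean(d[outer(group, group, "==") & upper.tri(d)])
  between <- mean(d[outer(group, group, "!=")])
  structure(list(
    assignments = tibble(name = rownames(m), group = group,
                         contrast = act_mean - rep_mean),
    profile = m,
    separation = between - within
  ), class = "chromstrat_groups")
}

#' @export
print.chromstrat_groups <- function(x, ...) {
  cat("<chromstrat_groups>\n")
  for (g in c("Group1", "Group2")) {
    cat(sprintf("  %s: %s\n", g,
                paste(x$assignments$name[x$assignments$group == g], collapse = ", ")))
  }
  cat(sprintf("  separation (between - within distance): %.3f\n", x$separation))
  invisible(x)
}

#' Transcripts per million
#'
#' `rate_i = counts_i / length_i`; `TPM_i = rate_i / sum(rate) * 1e6`.
#' Each replicate column sums to exactly 1e6.
#'
#' @param counts Non-negative count vector or matrix (genes x replicates).
#' @param lengths Positive gene lengths in bp.
#' @return Vector or matrix of TPM values matching `counts`.
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) abort("tpm: lengths must be positive")
  f <- function(cnt) {
    rate <- cnt / lengths
    s <- sum(rate)
    if (s == 0) abort("tpm: all-zero counts (TPM undefined)")
    rate / s * 1e6
  }
  if (is.matrix(counts)) apply(counts, 2, f) else f(counts)
}

#' Per-gene TPM table with replicate averaging
#'
#' @param genes Gene tibble (see [read_gene_table()]).
#' @return Tibble `gene_id`, per-replicate `tpm_*` columns, `mean_tpm`,
#'   `mean_log_tpm` (natural log of `mean_tpm`, `-Inf` when 0).
#' @export
tpm_table <- function(genes) {
  count_cols <- grep("^count_", names(genes), value = TRUE)
  m <- tpm(as.matrix(genes[, count_cols]), genes$length)
  out <- tibble(gene_id = genes$gene_id)
  for (j in seq_along(count_cols)) {
    out[[sub("^count_", "tpm_", count_cols[j])]] <- m[, j]
  }
  out$mean_tpm <- rowMeans(m)
  out$mean_log_tpm <- log(out$mean_tpm)
  out
}

#' Link promoter remodeller signal to gene expression
#'
#' For each expressed gene (mean TPM > 0), pools the per-base signal mass
#' of each group's tracks over the promoter window, assigns the gene to the
#' dominant group by the sign of the Group 1 minus Group 2 difference, and
#' tests whether Group-1-dominant genes are more highly expressed with a
#' one-tailed Wilcoxon rank-sum test on log TPM.
#'
#' @param promoters Promoter window tibble with `name` = gene id (see
#'   [promoter_windows()]).
#' @param group1_tracks,group2_tracks Lists of signal tracks.
#' @param tpm_tbl Result of [tpm_table()].
#' @param sizes Chromosome sizes tibble.
#' @return Object of class `chromstrat_expression_link`: list with
#'   `per_gene` tibble (`gene_id`, `group1_signal`, `group2_signal`,
#'   `dominant_group`, `mean_tpm`, `log_tpm`), `n_ties`, `p_one_tailed`,
#'   `statistic` and group sizes.
#' @export
link_expression <- function(promoters, group1_tracks, group2_tracks, tpm_tbl,
                            sizes) {
  pooled_mass <- function(tracks) {
    mass <- rep(0, nrow(promoters))
    off <- chrom_offsets(sizes)
    for (tr in tracks) {
      si <- signal_integral(tr, sizes)
      gs <- off[promoters$chrom] + promoters$start
      ge <- off[promoters$chrom] + promoters$end
      mass <- mass + signal_integral_eval(si, ge) - signal_integral_eval(si, gs)
    }
    mass
  }
  g1 <- pooled_mass(group1_tracks)
  g2 <- pooled_mass(group2_tracks)
  per_gene <- tibble(gene_id = promoters$name, group1_signal = g1,
                     group2_signal = g2,
                     dominant_group = dplyr::case_when(
                       g1 > g2 ~ "Group1", g1 < g2 ~ "Group2", TRUE ~ "tie")) |>
    inner_join(tpm_tbl[, c("gene_id", "mean_tpm")], by = "gene_id") |>
    filter(.data$mean_tpm > 0) |>
    mutate(log_tpm = log(.data$mean_tpm))
  n_ties <- sum(per_gene$dominant_group == "tie")
  x1 <- per_gene$log_tpm[per_gene$dominant_group == "Group1"]
  x2 <- per_gene$log_tpm[per_gene$dominant_group == "Group2"]
  if (length(x1) < 2 || length(x2) < 2) {
    abort("link_expression: fewer than 2 genes in a dominance class")
  }
  wt <- suppressWarnings(wilcox.test(x1, x2, alternative = "greater"))
  structure(list(per_gene = per_gene, n_ties = n_ties,
                 n_group1 = length(x1), n_group2 = length(x2),
                 statistic = unname(wt$statistic),
                 p_one_tailed = wt$p.value),
            class = "chromstrat_expression_link")
}

#' @export
print.chromstrat_expression_link <- function(x, ...) {
  cat("<chromstrat_expression_link>\n")
  cat(sprintf("  expressed genes: %d Group1-dominant, %d Group2-dominant, %d ties\n",
              x$n_group1, x$n_group2, x$n_ties))
  cat(sprintf("  one-tailed Wilcoxon rank-sum p = %.3g\n", x$p_one_tailed))
  invisible(x)
}

#' Pearson correlation between two expression profiles on the log scale
#'
#' @param expr_a,expr_b Named numeric vectors of expression values over the
#'   same entities (e.g. per-remodeller expression in two data sets).
#' @param exclude Optional names to exclude (recorded in the result).
#' @return Tibble `r`, `n`, `excluded`.
#' @export
expression_concordance <- function(expr_a, expr_b, exclude = NULL) {
  common <- intersect(names(expr_a), names(expr_b))
  common <- setdiff(common, exclude)
  if (length(common) < 3) abort("expression_concordance: need >= 3 paired values")
  a <- log(expr_a[common]); b <- log(expr_b[common])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("expression_concordance: zero variance")
  }
  tibble(r = cor(a, b), n = length(common),
         excluded = paste(exclude %||% character(0), collapse = ","))
}

#' Partition the genome into TADs, boundaries and unorganised chromatin
#'
#' Boundaries take precedence where they overlap TADs; the three classes
#' are disjoint and cover the genome, so the percentages sum to 100. The
#' genome size is the sum of the chromosome lengths in `sizes`.
#'
#' @param tads,boundaries Interval tibbles.
#' @param sizes Chromosome sizes tibble.
#' @return Object of class `chromstrat_partition`: list with `fractions`
#'   (tibble `class`, `bp`, `percent`) and the three class interval sets.
#' @export
partition_genome <- function(tads, boundaries, sizes) {
  genome <- genome_workspace(sizes)
  genome_bp <- sum(sizes$size)
  tads <- as_intervals(tads, sizes = sizes, what = "TADs")
  boundaries <- as_intervals(boundaries, sizes = sizes, what = "boundaries")
  b <- interval_merge(boundaries)
  t_only <- interval_subtract(tads, b)
  unorg <- interval_subtract(interval_subtract(genome, tads), b)
  fr <- tibble(
    class = c("TADs", "boundaries", "unorganised"),
    bp = c(total_bp(t_only), total_bp(b), total_bp(unorg))
  ) |> mutate(percent = .data$bp / genome_bp * 100)
  structure(list(fractions = fr, tads = t_only, boundaries = b,
                 unorganised = unorg, genome_bp = genome_bp),
            class = "chromstrat_partition")
}

#' Assign binding sites to genome-partition classes by midpoint
#'
#' Percentages per remodeller sum to 100 even for sites straddling a class
#' edge, because each site is assigned by its midpoint.
#'
#' @param sites Named list of peak interval tibbles (or one tibble).
#' @param partition Result of [partition_genome()].
#' @return Tibble `name`, `class`, `n_sites`, `percent`.
#' @export
binding_partition <- function(sites, partition) {
  if (is.data.frame(sites)) sites <- list(sites = sites)
  imap(sites, function(x, nm) {
    mid <- tibble(chrom = x$chrom,
                  start = floor((x$start + x$end) / 2),
                  end = floor((x$start + x$end) / 2) + 1)
    in_t <- overlaps_any(mid, partition$tads)
    in_b <- overlaps_any(mid, partition$boundaries)
    cls <- dplyr::case_when(in_b ~ "boundaries", in_t ~ "TADs",
                            TRUE ~ "unorganised")
    tibble(name = nm,
           class = factor(cls, levels = c("TADs", "boundaries", "unorganised"))) |>
      dplyr::count(.data$name, .data$class, .drop = FALSE, name = "n_sites") |>
      mutate(percent = .data$n_sites / nrow(x) * 100)
  }) |> bind_rows() |> mutate(class = as.character(class))
}
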