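# Group stratification, TPM, expression linkage and architecture
# partitioning.

fake_enrichment <- function(folds) {
  # folds: named list remodeller -> named numeric vector of feature folds
  purrr::imap(folds, function(v, nm) {
    tibble::tibble(segments_name = nm, feature_name = names(v), fold = unname(v))
  }) |> dplyr::bind_rows()
}

test_that("stratify_remodellers separates a perfectly split profile", {
  enr <- fake_enrichment(list(
    r1 = c(active = 3, repressive = 1),
    r2 = c(active = 3, repressive = 1),
    r3 = c(active = 1, repressive = 3),
    r4 = c(active = 1, repressive = 3)
  ))
  g <- stratify_remodellers(enr, "active", "repressive")
  expect_equal(g$assignments$group, c("Group1", "Group1", "Group2", "Group2"))
  expect_true(all(g$assignments$contrast[1:2] > 0))
  expect_true(all(g$assignments$contrast[3:4] < 0))
  # permuting input rows permutes output labels identically
  enr2 <- enr[sample(nrow(enr)), ]
  g2 <- stratify_remodellers(enr2, "active", "repressive")
  m1 <- setNames(g$assignments$group, g$assignments$name)
  m2 <- setNames(g2$assignments$group, g2$assignments$name)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
  # identical profiles are degenerate
  enr3 <- fake_enrichment(list(a = c(active = 2, repressive = 2),
                               b = c(active = 2, repressive = 2)))
  expect_error(stratify_remodellers(enr3, "active", "repressive"), "identical")
})

test_that("tpm matches hand computation and sums to 1e6", {
  expect_equal(tpm(c(10, 10, 10, 10), rep(1000, 4)), rep(2.5e5, 4))
  expect_equal(tpm(c(10, 20), c(1000, 2000)), c(5e5, 5e5))
  withr::with_seed(121, {
    cnt <- matrix(rpois(30, 50), ncol = 3)
    len <- sample(500:5000, 10)
    m <- tpm(cnt, len)
    expect_equal(colSums(m), rep(1e6, 3))
  })
  expect_error(tpm(c(0, 0), c(100, 100)), "all-zero")
  expect_error(tpm(c(1, 2), c(100, 0)), "positive")
})

test_that("tpm_table averages replicates per gene", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          tss = c(0, 10), strand = "+", length = c(1000, 2000),
                          count_1 = c(10, 20), count_2 = c(20, 40))
  tt <- tpm_table(genes)
  expect_equal(tt$tpm_1, c(5e5, 5e5))
  expect_equal(tt$mean_tpm, c(5e5, 5e5))
})

test_that("link_expression assigns dominance by sign and tests one-tailed", {
  sizes <- tibble::tibble(chrom = "chr1", size = 100000)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                          tss = seq(3000, 98000, by = 5000)[1:20], strand = "+",
                          length = 1000)
  prom <- promoter_windows(genes, sizes)
  hi <- genes$gene_id[1:10]
  mk_track <- function(weights) {
    runs <- tibble::tibble(chrom = "chr1", start = prom$start, end = prom$end,
                           value = weights)
    signal_track(runs, sizes)
  }
  g1_tracks <- list(mk_track(ifelse(genes$gene_id %in% hi, 10, 4)))
  g2_tracks <- list(mk_track(rep(6, 20)))
  withr::with_seed(131, {
    tpm_tbl <- tibble::tibble(gene_id = genes$gene_id,
                              mean_tpm = exp(rnorm(20, 2) +
                                               ifelse(genes$gene_id %in% hi, 2, 0)))
    link <- link_expression(prom, g1_tracks, g2_tracks, tpm_tbl, sizes)
    expect_equal(sort(link$per_gene$gene_id[link$per_gene$dominant_group == "Group1"]),
                 sort(hi))
    expect_lt(link$p_one_tailed, 0.05)
    # one-tailed p is at most half the two-tailed p when the effect is in
    # the hypothesised direction
    x1 <- link$per_gene$log_tpm[link$per_gene$dominant_group == "Group1"]
    x2 <- link$per_gene$log_tpm[link$per_gene$dominant_group == "Group2"]
    two <- suppressWarnings(stats::wilcox.test(x1, x2))$p.value
    expect_lte(link$p_one_tailed, two / 2 + 1e-12)
  })
})

test_that("expression_concordance computes log-scale Pearson r with exclusions", {
  a <- c(r1 = 10, r2 = 100, r3 = 1000, r4 = 5)
  expect_equal(expression_concordance(a, a)$r, 1)
  b <- setNames(rev(unname(a)), names(a))
  expect_equal(expression_concordance(a, b[c("r1", "r2", "r3")],
                                      exclude = NULL)$n, 3)
  r <- expression_concordance(a, a, exclude = "r4")
  expect_equal(r$n, 3)
  expect_equal(r$excluded, "r4")
  # perfectly anti-ordered log-spaced values give r = -1
  x <- c(a = 1, b = 10, c = 100)
  y <- c(a = 100, b = 10, c = 1)
  expect_equal(expression_concordance(x, y)$r, -1)
})

test_that("partition_genome is a disjoint, exhaustive partition", {
  sizes <- tibble::tibble(chrom = "chr1", size = 1000)
  part <- partition_genome(iv("chr1", 100, 800), iv("chr1", 800, 900), sizes)
  expect_equal(part$fractions$percent, c(70, 10, 20))
  expect_equal(sum(part$fractions$percent), 100)
  # boundaries take precedence over overlapping TADs
  part2 <- partition_genome(iv("chr1", 100, 900), iv("chr1", 800, 900), sizes)
  expect_equal(part2$fractions$percent, c(70, 10, 20))
  # no TADs
  part3 <- partition_genome(iv(character(0), double(0), double(0)),
                            iv(character(0), double(0), double(0)), sizes)
  expect_equal(part3$fractions$percent, c(0, 0, 100))
  expect_error(partition_genome(iv("chr1", 0, 2000), iv("chr1", 1, 2), sizes))
})

test_that("binding_partition assigns by midpoint and sums to 100", {
  sizes <- tibble::tibble(chrom = "chr1", size = 1000)
  part <- partition_genome(iv("chr1", 100, 800), iv("chr1", 800, 900), sizes)
  peaks <- iv("chr1", c(120, 790, 950), c(180, 850, 990))
  # midpoints 150 (TAD), 820 (boundary), 970 (unorganised)
  bp <- binding_partition(list(x = peaks), part)
  expect_equal(sum(bp$percent), 100)
  expect_equal(bp$n_sites[bp$class == "TADs"], 1L)
  expect_equal(bp$n_sites[bp$class == "boundaries"], 1L)
  expect_equal(bp$n_sites[bp$class == "unorganised"], 1L)
})
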