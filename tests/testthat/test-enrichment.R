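# Randomization test: analytic oracle agreement, saturation and extreme
# cases, p-value behaviour, BH adjustment and the group contrast.

test_that("analytic_expected_overlap matches direct enumeration", {
  ws <- 1000; L <- 100
  ann <- iv("chr1", 400, 500)
  # direct enumeration over all 901 placements
  enum <- mean(vapply(0:(ws - L), function(s) {
    max(0, min(s + L, 500) - max(s, 400))
  }, numeric(1)))
  expect_equal(analytic_expected_overlap(L, ann, ws), enum, tolerance = 1e-9)
  # saturated and empty annotations
  expect_equal(analytic_expected_overlap(L, iv("chr1", 0, ws), ws), L)
  expect_equal(analytic_expected_overlap(L, iv(character(0), double(0), double(0)), ws), 0)
  expect_error(analytic_expected_overlap(2000, ann, ws), "L > W")
})

test_that("sampler mean converges to the analytic expectation", {
  ws_tbl <- iv("chr1", 0, 1000)
  seg <- iv("chr1", 0, 100)
  ann <- iv("chr1", 400, 500)
  null <- sample_null_overlaps(seg, ann, ws_tbl, n_iter = 2000, seed = 5)
  exp_bp <- analytic_expected_overlap(100, ann, 1000)
  se <- stats::sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - exp_bp), 3 * se)
  # random geometries
  withr::with_seed(61, {
    for (rep in 1:10) {
      W <- sample(500:3000, 1)
      L <- sample(10:200, 1)
      a0 <- sort(sample(0:(W - 60), 2))
      ann_r <- interval_merge(iv("chr1", a0, pmin(a0 + sample(20:200, 2), W)))
      null_r <- sample_null_overlaps(iv("chr1", 0, L), ann_r, iv("chr1", 0, W),
                                     n_iter = 1000, seed = rep)
      mu <- analytic_expected_overlap(L, ann_r, W)
      se_r <- stats::sd(null_r) / sqrt(1000)
      expect_lt(abs(mean(null_r) - mu), max(3 * se_r, 1e-9))
    }
  })
})

test_that("saturated annotation gives every null overlap equal to segment bp", {
  segs <- iv("chr1", c(0, 500), c(100, 650))
  ws_tbl <- iv("chr1", 0, 1000)
  null <- sample_null_overlaps(segs, ws_tbl, ws_tbl, n_iter = 50, seed = 2)
  expect_true(all(null == 250))
  null0 <- sample_null_overlaps(segs, iv(character(0), double(0), double(0)),
                                ws_tbl, n_iter = 50, seed = 2)
  expect_true(all(null0 == 0))
  expect_error(sample_null_overlaps(iv("chr1", 0, 900), ws_tbl,
                                    iv("chr1", c(0, 600), c(500, 1000)), 10, 1),
               "longer than every workspace interval")
})

test_that("fold_enrichment handles saturation and extreme enrichment", {
  ws_tbl <- iv("chr1", 0, 1000)
  segs <- iv("chr1", c(0, 300), c(100, 400))
  r <- fold_enrichment(segs, ws_tbl, ws_tbl, n_iter = 100, seed = 3)
  expect_equal(r$fold, 1)
  expect_equal(r$p_empirical, 1)
  # segments inside a tiny annotation on a large workspace
  big_ws <- iv("chr1", 0, 1e6)
  segs2 <- iv("chr1", c(1000, 1200), c(1100, 1300))
  r2 <- fold_enrichment(segs2, iv("chr1", 1000, 1300), big_ws,
                        n_iter = 500, seed = 4)
  expect_gt(r2$fold, 10)
  expect_equal(r2$p_empirical, 1 / 501)
})

test_that("fold_enrichment is invariant under coordinate translation", {
  shift <- 12345
  segs <- iv("chr1", c(100, 900), c(300, 1000))
  ann <- iv("chr1", c(0, 700), c(250, 950))
  ws_tbl <- iv("chr1", 0, 5000)
  r1 <- fold_enrichment(segs, ann, ws_tbl, n_iter = 300, seed = 9)
  tr <- function(x) dplyr::mutate(x, start = start + shift, end = end + shift)
  r2 <- fold_enrichment(tr(segs), tr(ann), tr(ws_tbl), n_iter = 300, seed = 9)
  expect_equal(r1$observed_bp, r2$observed_bp)
  expect_equal(r1$expected_bp, r2$expected_bp)
  expect_equal(r1$p_empirical, r2$p_empirical)
})

test_that("empirical p is calibrated and near-uniform under the null", {
  # segments and annotation independent: upper-tail rejection ~ 5%
  withr::with_seed(71, {
    p_enrich <- replicate(300, {
      segs <- random_disjoint_segments(30, len = 50000, max_w = 300)
      a0 <- floor(runif(10, 0, 48000))
      ann <- iv("chr1", a0, a0 + pmax(1, floor(runif(10, 1, 2000))))
      r <- fold_enrichment(segs, ann, iv("chr1", 0, 50000),
                           n_iter = 200, seed = sample.int(1e6, 1))
      r$p_enrich
    })
    expect_gt(mean(p_enrich < 0.05), 0.02)
    expect_lt(mean(p_enrich < 0.05), 0.09)
    ks <- suppressWarnings(stats::ks.test(p_enrich, "punif"))
    expect_lt(unname(ks$statistic), 0.12)
  })
})

test_that("bh_adjust matches the hand-applied step-up formula", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(81, {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  })
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("group_mean_test equals the closed-form pooled t computation", {
  g1 <- c(5, 6, 7, 8); g2 <- c(1, 2, 3, 4)
  r <- group_mean_test(g1, g2)
  sp <- sqrt((3 * var(g1) + 3 * var(g2)) / 6)
  t_hand <- (mean(g1) - mean(g2)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(r$t_statistic, t_hand)
  expect_equal(r$df, 6)
  expect_equal(r$p_two_sided, 2 * stats::pt(-abs(t_hand), df = 6))
  # swapping groups negates t, preserves p
  r2 <- group_mean_test(g2, g1)
  expect_equal(r2$t_statistic, -r$t_statistic)
  expect_equal(r2$p_two_sided, r$p_two_sided)
  expect_error(group_mean_test(rep(2, 4), rep(2, 4)), "zero pooled variance")
  expect_error(group_mean_test(1, c(1, 2)), "at least 2")
})

test_that("a 1x1 enrichment matrix reduces to fold_enrichment", {
  segs <- iv("chr1", c(100, 900), c(300, 1000))
  ann <- iv("chr1", c(0, 700), c(250, 950))
  ws_tbl <- iv("chr1", 0, 5000)
  m <- enrichment_matrix(list(A = segs), list(f = ann), ws_tbl,
                         n_iter = 200, seed = 13)
  single <- fold_enrichment(segs, ann, ws_tbl, n_iter = 200,
                            seed = m$seed[1])
  expect_equal(m$observed_bp, single$observed_bp)
  expect_equal(m$expected_bp, single$expected_bp)
  expect_equal(m$fold, single$fold)
  expect_equal(m$q_bh, m$p_empirical) # single test per family
})

test_that("enrichment results are byte-identical across runs with one seed", {
  segs <- iv("chr1", c(100, 900), c(300, 1000))
  ann <- iv("chr1", c(0, 700), c(250, 950))
  ws_tbl <- iv("chr1", 0, 5000)
  a <- fold_enrichment(segs, ann, ws_tbl, n_iter = 100, seed = 99)
  b <- fold_enrichment(segs, ann, ws_tbl, n_iter = 100, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
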