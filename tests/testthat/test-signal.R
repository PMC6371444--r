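# Score matrices, profiles, correlation clustering, methylation summaries
# and sequence composition.

sizes1 <- tibble::tibble(chrom = "chr1", size = 100000)

track_of <- function(runs) signal_track(runs, sizes1)

test_that("score_matrix reproduces constant, empty and step tracks", {
  regions <- iv("chr1", c(10000, 50000), c(10400, 50400))
  const <- track_of(tibble::tibble(chrom = "chr1", start = 0, end = 100000, value = 1))
  sm <- score_matrix(const, regions, flank = 2000, n_bins = 40)
  expect_true(all(sm$matrix == 1))
  empty <- track_of(tibble::tibble(chrom = character(), start = double(),
                                   end = double(), value = double()))
  sm0 <- score_matrix(empty, regions, sizes = sizes1, flank = 2000, n_bins = 40)
  expect_true(all(sm0$matrix == 0))
  # step: 0 left of the region centre, 2 right of it (centre = 10200)
  step <- track_of(tibble::tibble(chrom = "chr1", start = 10200, end = 100000, value = 2))
  sm2 <- score_matrix(step, regions[1, ], flank = 2000, n_bins = 40)
  expect_equal(as.vector(sm2$matrix), c(rep(0, 20), rep(2, 20)))
  # per-base averaging oracle on an arbitrary window
  tr <- track_of(tibble::tibble(chrom = "chr1", start = c(9000, 10500),
                                end = c(9700, 12000), value = c(3, 0.5)))
  sm3 <- score_matrix(tr, regions[1, ], flank = 2000, n_bins = 40)
  per_base <- rep(0, 100000)
  per_base[(9000 + 1):9700] <- 3
  per_base[(10500 + 1):12000] <- 0.5
  centre <- 10200
  oracle <- vapply(seq_len(40), function(j) {
    lo <- centre - 2000 + (j - 1) * 100
    mean(per_base[(lo + 1):(lo + 100)])
  }, numeric(1))
  expect_equal(as.vector(sm3$matrix), oracle)
})

test_that("windows clipped at chromosome ends are padded with zeros", {
  tr <- track_of(tibble::tibble(chrom = "chr1", start = 0, end = 100000, value = 1))
  near_start <- iv("chr1", 100, 300) # centre 200, window [-1800, 2200)
  sm <- score_matrix(tr, near_start, flank = 2000, n_bins = 4)
  # first bin [-1800,-800) fully outside -> 0; second [-800,200) has 200 bp in
  expect_equal(as.vector(sm$matrix), c(0, 0.2, 1, 1))
})

test_that("score matrix mass is conserved and profiles average columns", {
  withr::with_seed(91, {
    runs <- tibble::tibble(chrom = "chr1",
                           start = seq(0, 99000, 1000),
                           end = seq(0, 99000, 1000) + 500,
                           value = runif(100, 0, 5))
    tr <- track_of(runs)
    regions <- iv("chr1", seq(10000, 80000, 7000), seq(10000, 80000, 7000) + 400)
    sm <- score_matrix(tr, regions, flank = 2000, n_bins = 100)
    prof <- average_profile(sm)
    expect_equal(prof$mean_signal, colMeans(sm$matrix))
    expect_equal(nrow(prof), 100)
    # total mean equals the direct per-base mean over the union of windows
    per_base <- rep(0, 100000)
    for (i in seq_len(nrow(runs))) per_base[(runs$start[i] + 1):runs$end[i]] <- runs$value[i]
    centre <- floor((regions$start + regions$end) / 2)
    win_mean <- mean(vapply(centre, function(cc) {
      mean(per_base[(cc - 2000 + 1):(cc + 2000)])
    }, numeric(1)))
    expect_equal(mean(sm$matrix), win_mean, tolerance = 1e-12)
  })
})

test_that("correlation_cluster computes Pearson r and a clustering order", {
  x <- c(1, 2, 3, 4, 5)
  cc <- correlation_cluster(list(a = x, b = x * 2, c = -x))
  expect_equal(cc$r["a", "b"], 1)
  expect_equal(cc$r["a", "c"], -1)
  expect_equal(diag(cc$r), c(a = 1, b = 1, c = 1))
  expect_error(correlation_cluster(list(a = x, b = rep(1, 5))), "zero-variance")
  # planted two-block structure separates in leaf order
  withr::with_seed(101, {
    base1 <- rnorm(200); base2 <- rnorm(200)
    sig <- list(A1 = base1 + rnorm(200, 0, .2), A2 = base1 + rnorm(200, 0, .2),
                B1 = base2 + rnorm(200, 0, .2), B2 = base2 + rnorm(200, 0, .2))
    cc2 <- correlation_cluster(sig)
    lab <- substr(cc2$labels, 1, 1)
    expect_true(identical(lab, c("A", "A", "B", "B")) ||
                  identical(lab, c("B", "B", "A", "A")))
  })
})

test_that("site_mean_methylation filters coverage strictly and averages", {
  meth <- tibble::tibble(chrom = "chr1", pos = c(150, 160, 500, 900),
                         context = "CpG",
                         methylated = c(2, 4, 5, 9), total = c(10, 10, 5, 10))
  sites <- iv("chr1", c(100, 450, 800), c(200, 550, 1000))
  r <- site_mean_methylation(meth, sites)
  expect_equal(r$mean_methylation, c(0.3, NA, 0.9))
  expect_equal(r$n_covered_sites, c(2L, 0L, 1L))
  # direct filtering-and-averaging oracle on random tables
  withr::with_seed(111, {
    tab <- tibble::tibble(chrom = "chr1", pos = sort(sample(0:9999, 400)),
                          context = "GCH", total = sample(3:20, 400, TRUE))
    tab$methylated <- vapply(tab$total, function(t) sample(0:t, 1), numeric(1))
    st <- random_intervals(30, chroms = "chr1", len = 10000)
    got <- site_mean_methylation(tab, st, min_cov = 5)
    oracle <- vapply(seq_len(nrow(st)), function(i) {
      rows <- tab[tab$pos >= st$start[i] & tab$pos < st$end[i] & tab$total > 5, ]
      if (nrow(rows) == 0) NA_real_ else mean(rows$methylated / rows$total)
    }, numeric(1))
    expect_equal(got$mean_methylation, oracle)
  })
})

test_that("sequence composition matches hand counts", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAAATATCGCGNN"))
  r <- nucleotide_density(genome, iv("chr1", 0, 4))
  expect_equal(unname(unlist(r[, c("A", "C", "G", "T")])), c(1, 0, 0, 0))
  # "ATAT": overlapping dinucleotides AT, TA, AT
  d <- dinucleotide_frequency(genome, iv("chr1", 4, 8))
  expect_equal(d$AT, 2 / 3)
  expect_equal(d$TA, 1 / 3)
  expect_equal(sum(unlist(d[, 7:22])), 1)
  # "CGCG": 2 CpG over 4 bp
  cg <- cpg_density(genome, iv("chr1", 8, 12))
  expect_equal(cg$cpg_density, 0.5)
  # N bases drop out of the nucleotide denominator
  rn <- nucleotide_density(genome, iv("chr1", 12, 14))
  expect_true(all(is.na(unlist(rn[, c("A", "C", "G", "T")]))))
  expect_error(nucleotide_density(genome, iv("chr1", 10, 20)), "beyond")
  # fractions sum to 1 whenever unambiguous sequence is present
  r2 <- nucleotide_density(genome, iv("chr1", c(0, 2), c(10, 12)))
  expect_equal(rowSums(as.matrix(r2[, c("A", "C", "G", "T")])), c(1, 1))
})
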