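# Synthetic epigenome generator: determinism, validator compliance,
# state-mark consistency and planted-parameter behaviour.

file_hashes <- function(dir) {
  fs <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  tools::md5sum(fs)
}

test_that("the same config and seed emit byte-identical files", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e5), n_peaks = 100, n_genes = 40,
                    n_islands = 25, n_loops = 10, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_epigenome(cfg, d1)
  simulate_epigenome(cfg, d2)
  h1 <- file_hashes(d1); h2 <- file_hashes(d2)
  expect_equal(basename(names(h1)), basename(names(h2)))
  expect_equal(unname(h1), unname(h2))
})

test_that("emitted files pass every reader's validation", {
  sim <- small_sim()
  sizes <- read_chrom_sizes(sim$paths$sizes)
  expect_equal(sizes$size, c(2e6, 2e6))
  expect_silent(read_bed(sim$paths$states, sizes))
  for (p in sim$paths$peaks) expect_silent(read_bed(p, sizes))
  for (p in sim$paths$marks) expect_silent(read_bed(p, sizes))
  expect_silent(read_bed(sim$paths$islands, sizes))
  expect_silent(read_bedpe(sim$paths$loops))
  expect_gt(nrow(read_methylation(sim$paths$meth_cpg, "CpG")), 0)
  expect_gt(nrow(read_methylation(sim$paths$meth_gch, "GCH")), 0)
  expect_silent(x <- read_gene_table(sim$paths$genes))
  for (p in sim$paths$signal[1:2]) expect_silent(read_bedgraph(p, sizes))
  fa <- read_genome_fasta(sim$paths$fasta)
  expect_equal(unname(Biostrings::width(fa)), sizes$size)
})

test_that("states partition the genome and marks respect the implication table", {
  sim <- small_sim()
  st <- sim$states
  expect_equal(sum(st$end - st$start), sum(sim$sizes$size))
  # disjoint states
  expect_equal(nrow(interval_intersect(st[seq(1, nrow(st), 2), ],
                                       st[seq(2, nrow(st), 2), ])), 0)
  mk <- sim$marks
  prom <- dplyr::filter(st, name == "active_promoter")
  expect_equal(overlap_bp(prom, mk$H3K4me3), sum(prom$end - prom$start))
  expect_equal(overlap_bp(prom, mk$H3K27ac), sum(prom$end - prom$start))
  biv <- dplyr::filter(st, name == "bivalent")
  expect_equal(overlap_bp(biv, mk$H3K4me3), sum(biv$end - biv$start))
  expect_equal(overlap_bp(biv, mk$H3K27me3), sum(biv$end - biv$start))
  rep_seg <- dplyr::filter(st, name == "repressive")
  expect_equal(overlap_bp(rep_seg, mk$H3K27me3) + overlap_bp(rep_seg, mk$H3K9me3),
               sum(rep_seg$end - rep_seg$start))
  # no K27ac or p300 at poised enhancers
  poised <- dplyr::filter(sim$truth$enhancers, planted == "poised")
  expect_equal(overlap_bp(poised, mk$H3K27ac), 0)
  expect_equal(overlap_bp(poised, mk$p300), 0)
})

test_that("all remodeller peaks avoid the lamina-like exclusion domains", {
  sim <- small_sim()
  for (nm in names(sim$peaks)) {
    expect_equal(overlap_bp(sim$peaks[[nm]], sim$lamin), 0)
  }
})

test_that("peaks are non-overlapping within a remodeller with planted widths", {
  sim <- small_sim()
  for (nm in c("BRG1", "CHD1")) {
    p <- sim$peaks[[nm]]
    expect_equal(nrow(p), sim$config$n_peaks)
    m <- interval_merge(p)
    # abutting peaks may merge, but no base is covered twice
    expect_equal(sum(m$end - m$start), sum(p$end - p$start))
    expect_gt(width_fraction_below(p, 750), 0.75)
  }
})

test_that("uniform odds give uniform density; planted odds shift density", {
  cfg0 <- sim_config(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6), n_peaks = 1000,
                     rho1 = 1, rho2 = 1, seed = 5)
  sim0 <- simulate_epigenome(cfg0, withr::local_tempdir(), layers = character(0))
  r0 <- planted_density_ratio(sim0$peaks$BRG1, sim0$states, cfg0$active_states,
                              exclude = sim0$lamin)
  expect_gt(r0, 0.85); expect_lt(r0, 1.18)
  sim1 <- small_sim() # rho1 = 5, rho2 = 3
  r1 <- mean(vapply(c("BRG1", "SNF2H", "CHD3", "CHD4"), function(nm) {
    planted_density_ratio(sim1$peaks[[nm]], sim1$states,
                          sim1$config$active_states, exclude = sim1$lamin)
  }, numeric(1)))
  expect_gt(r1, 3.5)
  r2 <- mean(vapply(c("BRM", "INO80", "SNF2L", "CHD1"), function(nm) {
    planted_density_ratio(sim1$peaks[[nm]], sim1$states, "repressive",
                          exclude = sim1$lamin)
  }, numeric(1)))
  expect_gt(r2, 2.3)
})

test_that("island methylation is bimodal as planted", {
  sim <- small_sim()
  meth <- sim$meth_cpg
  isl <- sim$truth$islands
  sm <- site_mean_methylation(meth, isl, min_cov = 5)
  m <- sm$mean_methylation
  expect_true(all(m[isl$planted_methylated] > 0.5))
  expect_true(all(m[!isl$planted_methylated] < 0.5))
})

test_that("accessibility is elevated at active elements", {
  sim <- small_sim()
  act <- dplyr::bind_rows(
    dplyr::filter(sim$states, name == "active_promoter"),
    dplyr::filter(sim$truth$enhancers, planted == "active"))
  rep_seg <- dplyr::filter(sim$states, name == "repressive")
  acc_a <- site_mean_methylation(sim$meth_gch, act)
  acc_r <- site_mean_methylation(sim$meth_gch, rep_seg)
  expect_gt(mean(acc_a$mean_methylation, na.rm = TRUE), 0.3)
  expect_lt(mean(acc_r$mean_methylation, na.rm = TRUE), 0.15)
})

test_that("truth_report writes one labelled row per remodeller", {
  sim <- small_sim()
  p <- truth_report(sim, dir = withr::local_tempdir())
  tr <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(nrow(tr), 8)
  expect_equal(sum(tr$group == "Group1"), 4)
  expect_equal(sum(tr$group == "Group2"), 4)
  expect_equal(unique(tr$planted_odds[tr$group == "Group1"]), sim$config$rho1)
  expect_equal(unique(tr$planted_odds[tr$group == "Group2"]), sim$config$rho2)
})

test_that("infeasible peak configurations error", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e4), n_peaks = 5000, seed = 1)
  expect_error(simulate_epigenome(cfg, withr::local_tempdir(),
                                  layers = character(0)),
               "infeasible|fit")
})
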