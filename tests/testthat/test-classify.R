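# Rule-based element classification: promoter precedence, enhancer rules,
# state collapsing, island methylation and anchor typing.

marks_fixture <- function() {
  list(
    H3K4me3 = iv("chr1", c(1000, 9000), c(2000, 9500)),
    H3K27ac = iv("chr1", 1000, 2000),
    H3K27me3 = iv("chr1", c(9000, 20000), c(9500, 21000)),
    H3K9me3 = iv("chr1", 30000, 31000)
  )
}

test_that("classify_promoters applies the mark rules with precedence", {
  m <- marks_fixture()
  w <- iv("chr1",
          c(1200, 9100, 20100, 30100, 50000),
          c(1800, 9400, 20900, 30900, 51000),
          name = c("active", "bivalent", "facultative", "constitutive", "none"))
  r <- classify_promoters(w, m)
  expect_equal(r$label, c("active", "bivalent", "facultative_repressed",
                          "constitutive_repressed", "unclassified"))
  # K4me3 + K27ac + K27me3 together: bivalency wins and is flagged
  m2 <- m
  m2$H3K27ac <- iv("chr1", 9000, 9500)
  r2 <- classify_promoters(iv("chr1", 9100, 9400), m2)
  expect_equal(r2$label, "bivalent")
  expect_true(r2$multi_mark)
  expect_error(classify_promoters(w, m[-1]), "missing mark")
})

test_that("classify_enhancers distinguishes active from poised and filters by TSS distance", {
  tss <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 1000)
  k4me1 <- iv("chr1", c(6000, 12000, 1500), c(6500, 12500, 2100))
  k27ac <- iv("chr1", 6000, 6500)
  p300 <- iv("chr1", 6200, 6400)
  dnase <- iv("chr1", 6100, 6300)
  r <- classify_enhancers(k4me1, tss, k27ac, p300, dnase)
  # the peak 500 bp from the TSS is excluded from candidacy
  expect_equal(nrow(r), 2)
  expect_equal(r$label[r$start == 6000], "active")
  expect_equal(r$label[r$start == 12000], "poised")
  # missing one of the supporting marks demotes to poised
  r2 <- classify_enhancers(k4me1, tss, k27ac, p300,
                           iv(character(0), double(0), double(0)))
  expect_true(all(r2$label == "poised"))
})

test_that("collapse_states relabels, merges and reports fractions", {
  seg <- iv("chr1", c(0, 100, 200, 600), c(100, 200, 600, 1000),
            name = c("TssA", "TssAFlnk", "Het", "Quies"))
  r <- collapse_states(seg)
  expect_equal(nrow(r$segments), 3) # abutting active_promoter segments merged
  expect_equal(sum(r$fractions$fraction), 1)
  ap <- r$segments[r$segments$name == "active_promoter", ]
  expect_equal(c(ap$start, ap$end), c(0, 200))
  expect_equal(r$fractions$fraction[r$fractions$label == "repressive"], 0.4)
  expect_error(collapse_states(iv("chr1", 0, 10, name = "NotAState")), "unmapped")
})

test_that("classify_cpg_islands bins, averages and applies the strict 50% rule", {
  island <- iv("chr1", 0, 400, name = "isl1")
  tssw <- iv("chr1", 300, 500)
  mk_meth <- function(pos, m, t) {
    tibble::tibble(chrom = "chr1", pos = pos, context = "CpG",
                   methylated = m, total = t)
  }
  # every CpG at ratio 0.9, 10x coverage -> methylated promoter island
  r <- classify_cpg_islands(island, tssw, mk_meth(seq(5, 395, 10), 9, 10))
  expect_equal(r$label, "methylated")
  expect_true(r$is_promoter_island)
  # island mean exactly 0.5 -> unmethylated (strict >)
  r2 <- classify_cpg_islands(island, tssw, mk_meth(c(50, 250), c(5, 5), c(10, 10)))
  expect_equal(r2$mean_methylation, 0.5)
  expect_equal(r2$label, "unmethylated")
  # no covered site -> no_data (coverage exactly 5 does not qualify)
  r3 <- classify_cpg_islands(island, tssw, mk_meth(50, 2, 5))
  expect_equal(r3$label, "no_data")
  # hand-built per-bin means: 40 bins of 10 bp; sites in bins 1 and 3
  meth <- mk_meth(c(2, 5, 25), c(10, 0, 4), c(10, 10, 10))
  r4 <- classify_cpg_islands(island, tssw, meth, n_bins = 40)
  # bin 1 mean = (1.0 + 0.0)/2 = 0.5; bin 3 mean = 0.4; island mean = 0.45
  expect_equal(r4$mean_methylation, 0.45)
  expect_equal(r4$n_informative_bins, 2L)
  expect_error(classify_cpg_islands(island, tssw, meth, n_bins = 0), "n_bins")
})

test_that("classify_anchors types anchors independently by active-element overlap", {
  loops <- tibble::tibble(chrom_a = "chr1", start_a = 1000, end_a = 2000,
                          chrom_b = "chr1", start_b = 50000, end_b = 51000,
                          score = NA_real_)
  act_prom <- iv("chr1", 1500, 1600)
  act_enh <- iv("chr1", 90000, 91000)
  r <- classify_anchors(loops, act_prom, act_enh)
  expect_equal(r$label, c("TypeA", "TypeB"))
  # an anchor overlapping only a poised enhancer stays TypeB
  r2 <- classify_anchors(loops, iv(character(0), double(0), double(0)),
                         iv(character(0), double(0), double(0)))
  expect_true(all(r2$label == "TypeB"))
})

test_that("classification recovers planted elements on noise-free synthetic marks", {
  sim <- small_sim()
  genes <- sim$genes
  w <- promoter_windows(genes, sim$sizes)
  pc <- classify_promoters(w, sim$marks)
  truth <- sim$truth$genes
  got <- setNames(pc$label, pc$name)[truth$gene_id]
  expected <- c(active = "active", bivalent = "bivalent",
                repressive = NA)[truth$promoter_class]
  # active and bivalent promoter windows lie wholly inside their state
  # segment, so recovery there is exact
  for (cl in c("active", "bivalent")) {
    idx <- truth$promoter_class == cl
    expect_true(all(got[idx] == cl))
  }
  # repressive-class genes must never be called active
  expect_false(any(got[truth$promoter_class == "repressive"] == "active"))

  enh <- classify_enhancers(sim$marks$H3K4me1, genes, sim$marks$H3K27ac,
                            sim$marks$p300, sim$marks$DNaseI)
  tr <- sim$truth$enhancers
  key <- paste(tr$chrom, tr$start)
  planted <- setNames(tr$planted, key)
  expect_true(all(enh$label == planted[paste(enh$chrom, enh$start)]))

  anch <- classify_anchors(sim$loops,
                           dplyr::filter(sim$states, name == "active_promoter"),
                           dplyr::filter(tr, planted == "active"))
  planted_anch <- setNames(sim$truth$anchors$planted, sim$truth$anchors$name)
  expect_true(all(anch$label == planted_anch[anch$name]))
})
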