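# Shared fixtures: small interval tables, per-base bitmask oracles, and a
# down-scaled simulation memoised across test files.

iv <- function(chrom, start, end, name = NA_character_, score = NA_real_,
               strand = NA_character_) {
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 score = score, strand = strand)
}

write_tmp <- function(lines, ext = ".bed") {
  p <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

# Per-base boolean mask of an interval set over a small genome.
bitmask <- function(x, chroms, len) {
  masks <- lapply(setNames(chroms, chroms), function(ch) {
    m <- rep(FALSE, len)
    rows <- x[x$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      m[seq(rows$start[i] + 1, rows$end[i])] <- TRUE
    }
    m
  })
  masks
}

mask_to_intervals <- function(masks) {
  out <- list()
  for (ch in names(masks)) {
    m <- masks[[ch]]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep], end = ends[keep])
    }
  }
  if (length(out) == 0) return(iv(character(0), double(0), double(0)))
  dplyr::bind_rows(out)
}

# Random interval set on a toy genome (used by round-trip / oracle tests).
random_intervals <- function(n, chroms = c("chr1", "chr2"), len = 10000,
                             max_w = 500, named = FALSE) {
  start <- floor(runif(n, 0, len - max_w))
  w <- pmax(1, floor(runif(n, 1, max_w)))
  x <- tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = pmin(start + w, len),
    name = if (named) sprintf("rec%04d", seq_len(n)) else NA_character_,
    score = if (named) round(runif(n, 0, 100), 2) else NA_real_,
    strand = if (named) sample(c("+", "-", "."), n, replace = TRUE) else NA_character_
  )
  x[order(x$chrom, x$start, x$end), ]
}

# Non-overlapping random segments (hard-core thinning of uniform draws),
# mirroring how peak sets are structured: peaks within one set never
# overlap.
random_disjoint_segments <- function(n, len = 100000, max_w = 400,
                                     chrom = "chr1") {
  s <- floor(runif(3 * n, 0, len - max_w))
  w <- pmax(1, floor(runif(3 * n, 1, max_w)))
  o <- order(s); s <- s[o]; w <- w[o]
  keep <- rep(TRUE, length(s)); last_end <- -1
  for (i in seq_along(s)) {
    if (s[i] > last_end) last_end <- s[i] + w[i] else keep[i] <- FALSE
  }
  kept <- which(keep)
  idx <- sort(sample(kept, min(n, length(kept))))
  iv(chrom, s[idx], s[idx] + w[idx])
}

# Adjusted Rand index between two label vectors (closed form over the
# pair-count contingency table).
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# The default-scale simulated study (2 x 10 Mb, 8 x 2000 peaks), memoised.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_epigenome(sim_config(seed = 1),
                                   out_dir = file.path(tempdir(), "chromstrat_default_sim"))
    }
    cache
  }
})

# Headline enrichment matrix over the default simulation, memoised: states,
# lamina domains and classified loop-anchor types, 1,000 iterations.
headline_enrichment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- default_sim()
      ws <- genome_workspace(sim$sizes)
      feats <- list()
      for (st in unique(sim$states$name)) {
        feats[[paste0("state_", st)]] <- dplyr::filter(sim$states, name == st)
      }
      feats$lamin <- sim$lamin
      anchors <- classify_anchors(
        sim$loops,
        dplyr::filter(sim$states, name == "active_promoter"),
        dplyr::filter(sim$truth$enhancers, planted == "active"))
      feats$anchors_typeA <- dplyr::filter(anchors, label == "TypeA")
      feats$anchors_typeB <- dplyr::filter(anchors, label == "TypeB")
      cache <<- list(
        sim = sim, anchors = anchors,
        enr = enrichment_matrix(sim$peaks, feats, ws, n_iter = 1000, seed = 1),
        groups_truth = setNames(sim$truth$remodellers$group,
                                sim$truth$remodellers$name)
      )
    }
    cache
  }
})

# A small simulated dataset shared across test files (computed once).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                        n_peaks = 500, n_genes = 150, n_islands = 120,
                        n_loops = 40, seed = 42)
      cache <<- simulate_epigenome(cfg, out_dir = file.path(tempdir(), "chromstrat_small_sim"))
    }
    cache
  }
})
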