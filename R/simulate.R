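# Seeded synthetic-epigenome generator. Emits a complete toy multi-layer
# dataset -- chromatin-state segmentation, histone-mark peaks consistent
# with the states, eight remodeller peak sets with planted two-group state
# preferences, bimodal CpG-island methylation, GpC accessibility elevated at
# active elements, expression elevated at Group-1-dominant promoters, and
# TAD/loop architecture with planted Type A anchors -- together with a
# ground-truth manifest for parameter-recovery tests. One global seed drives
# a named substream per layer, so generating one layer never perturbs the
# others.

#' Configuration for the synthetic epigenome
#'
#' Defaults describe a two-chromosome 2 x 10 Mb toy genome with eight
#' remodellers (four per planted group), ~2,000 peaks each with log-normal
#' widths (median ~400 bp, so well over 75% are under 750 bp), a planted
#' active-chromatin odds ratio of 5 for Group 1 and repressive odds of 3 for
#' Group 2, bimodal island methylation (beta-distributed per-site ratios
#' with means ~0.05 and ~0.85), GpC accessibility means of 0.4 at active
#' elements versus 0.1 elsewhere, a log-expression shift of 0.5 at
#' Group-1-dominant promoters, lamina-like domains from which all peaks are
#' excluded, and loop anchors of which 20% are planted Type A.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_peaks Peaks per remodeller.
#' @param rho1 Odds of a Group 1 peak landing in active states vs elsewhere.
#' @param rho2 Odds of a Group 2 peak landing in repressive states.
#' @param delta Planted log-expression shift for Group-1-dominant promoters.
#' @param n_genes,n_islands,n_loops Element counts.
#' @param typeA_frac Planted fraction of Type A loop anchors.
#' @param lamin_frac Fraction of the genome carved into lamina-like
#'   exclusion domains.
#' @param seed Integer seed driving all substreams.
#' @param ... Overrides for the remaining (documented) defaults.
#' @return A list of class `chromstrat_sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       n_peaks = 2000, rho1 = 5, rho2 = 3, delta = 0.5,
                       n_genes = 400, n_islands = 400, n_loops = 150,
                       typeA_frac = 0.2, lamin_frac = 0.10, seed = 1L, ...) {
  cfg <- list(
    chrom_lengths = chrom_lengths,
    at_fraction = 0.59,
    states = tibble::tribble(
      ~state, ~frac, ~mean_len, ~min_len,
      "active_promoter", 0.04, 3000, 2000,
      "active_enhancer", 0.06, 2500, 1500,
      "transcription", 0.15, 15000, 2000,
      "bivalent", 0.03, 3000, 2000,
      "repressive", 0.20, 15000, 2000,
      "unmarked", 0.52, 20000, 2000
    ),
    poised_enhancer_frac = 0.3,
    remodellers = tibble(
      name = c("BRG1", "SNF2H", "CHD3", "CHD4", "BRM", "INO80", "SNF2L", "CHD1"),
      group = rep(c("Group1", "Group2"), each = 4)
    ),
    n_peaks = n_peaks,
    peak_meanlog = log(400), peak_sdlog = 0.45, peak_min_width = 80,
    rho1 = rho1, rho2 = rho2,
    active_states = c("active_promoter", "active_enhancer", "transcription"),
    repressive_states = "repressive",
    lamin_frac = lamin_frac,
    n_islands = n_islands, island_min_width = 500, island_mean_width = 1000,
    cpg_spacing = 15, island_meth_frac = 0.3,
    meth_beta = c(17, 3), unmeth_beta = c(1, 19), meth_coverage_mean = 25,
    gch_spacing = 25, gch_background_n = 20000,
    gch_active_beta = c(4, 6), gch_inactive_beta = c(1, 9),
    n_genes = n_genes, n_reps = 3,
    gene_class_probs = c(active = 0.85, bivalent = 0.10, repressive = 0.05),
    expr_meanlog = c(active = 3, bivalent = 1, repressive = NA),
    expr_sdlog = 1, expr_rep_sd = 0.05,
    frac_group1_dominant = 0.6, delta = delta,
    gene_length_meanlog = log(2000), gene_length_sdlog = 0.5,
    promoter_flank = 1000,
    dominant_weight = 2, other_weight = 0.8, peak_signal_value = 1,
    tad_mean_len = 1.31e6, tad_min_len = 2e5, boundary_len = 4e4,
    gap_mean_len = 1.85e5,
    n_loops = n_loops, anchor_width = 1e4, typeA_frac = typeA_frac,
    seed = as.integer(seed)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("sim_config: unknown option(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  stopifnot(all(cfg$states$frac >= 0), sum(cfg$states$frac) <= 1 + 1e-9,
            cfg$rho1 >= 1, cfg$rho2 >= 1, cfg$n_peaks > 0)
  class(cfg) <- "chromstrat_sim_config"
  cfg
}

sim_sizes <- function(cfg) {
  tibble(chrom = names(cfg$chrom_lengths), size = as.double(cfg$chrom_lengths))
}

# Uniformly sample n integer positions within an interval space (by bp).
# Returns a tibble (chrom, pos).
sample_positions <- function(space, n) {
  if (nrow(space) == 0 || n == 0) return(tibble(chrom = character(), pos = double()))
  len <- space$end - space$start
  cum <- cumsum(len)
  u <- runif(n) * cum[length(cum)]
  i <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
  tibble(chrom = space$chrom[i], pos = floor(space$start[i] + (u - c(0, cum)[i])))
}

total_bp <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

# --- state segmentation ------------------------------------------------------

sim_states <- function(cfg) {
  w <- cfg$states$frac / cfg$states$mean_len
  out <- map(names(cfg$chrom_lengths), function(ch) {
    L <- cfg$chrom_lengths[[ch]]
    n_guess <- ceiling(L / min(cfg$states$mean_len)) + 50
    idx <- sample.int(nrow(cfg$states), n_guess, replace = TRUE, prob = w)
    len <- round(cfg$states$min_len[idx] +
                   rexp(n_guess, 1 / pmax(1, cfg$states$mean_len[idx] -
                                            cfg$states$min_len[idx])))
    ends <- cumsum(len)
    keep <- which(ends - len < L)
    idx <- idx[keep]; len <- len[keep]; ends <- ends[keep]
    tibble(chrom = ch, start = ends - len, end = pmin(ends, L),
           name = cfg$states$state[idx]) |>
      filter(.data$end > .data$start)
  })
  bind_rows(out)
}

sim_lamin <- function(cfg, states) {
  target <- cfg$lamin_frac * sum(cfg$chrom_lengths)
  un <- filter(states, .data$name == "unmarked")
  ord <- sample.int(nrow(un))
  cum <- cumsum((un$end - un$start)[ord])
  k <- which(cum >= target)[1]
  if (is.na(k)) k <- nrow(un)
  sel <- sort(ord[seq_len(k)])
  mutate(un[sel, ], name = "lamin")
}

# --- marks -------------------------------------------------------------------

sim_marks <- function(cfg, states) {
  enh <- filter(states, .data$name == "active_enhancer")
  poised <- runif(nrow(enh)) < cfg$poised_enhancer_frac
  rep_seg <- filter(states, .data$name == "repressive")
  k9 <- runif(nrow(rep_seg)) < 0.5
  prom <- filter(states, .data$name == "active_promoter")
  biv <- filter(states, .data$name == "bivalent")
  tx <- filter(states, .data$name == "transcription")
  marks <- list(
    H3K4me3 = bind_rows(prom, biv),
    H3K27ac = bind_rows(prom, enh[!poised, ]),
    H3K4me1 = enh,
    H3K27me3 = bind_rows(biv, rep_seg[!k9, ]),
    H3K9me3 = rep_seg[k9, ],
    H3K36me3 = tx,
    p300 = enh[!poised, ],
    DNaseI = bind_rows(prom, enh[!poised, ])
  )
  marks <- map(marks, function(m) sort_intervals(as_intervals(m)))
  list(marks = marks,
       enhancer_truth = mutate(enh, planted = if_else(poised, "poised", "active")))
}

# --- remodeller peaks --------------------------------------------------------

# Two-component mixture placement with odds rho for the preferred space,
# non-overlap within one remodeller enforced by rejection resampling.
sim_peaks_one <- function(cfg, preferred, other, rho, n_peaks, sizes,
                          forbidden = NULL) {
  bp_pref <- total_bp(preferred); bp_other <- total_bp(other)
  if (bp_pref + bp_other <= 0) abort("synthetic peaks: empty placement space")
  p_pref <- rho * bp_pref / (rho * bp_pref + bp_other)
  sz <- setNames(sizes$size, sizes$chrom)
  accepted <- NULL
  need <- n_peaks
  for (round in 1:200) {
    if (need <= 0) break
    n_draw <- ceiling(need * 1.2) + 10
    widths <- pmax(cfg$peak_min_width, round(rlnorm(n_draw, cfg$peak_meanlog, cfg$peak_sdlog)))
    take_pref <- runif(n_draw) < p_pref
    pos <- tibble(chrom = character(n_draw), pos = double(n_draw))
    pos[take_pref, ] <- sample_positions(preferred, sum(take_pref))
    pos[!take_pref, ] <- sample_positions(other, sum(!take_pref))
    cand <- tibble(chrom = pos$chrom, start = pos$pos,
                   end = pmin(pos$pos + widths, sz[pos$chrom]))
    cand <- filter(cand, .data$end - .data$start >= cfg$peak_min_width / 2)
    if (!is.null(forbidden) && nrow(forbidden) > 0 && nrow(cand) > 0) {
      # peak bodies (not just starts) must stay out of the exclusion domains
      cand <- cand[!overlaps_any(cand, forbidden), , drop = FALSE]
    }
    pool <- bind_rows(accepted, cand)
    g <- as_granges(pool)
    ov <- GenomicRanges::findOverlaps(g, g)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    # greedily keep earlier rows (previously accepted peaks come first)
    drop <- unique(qh[qh > sh])
    keepers <- rep(TRUE, nrow(pool))
    keepers[drop] <- FALSE
    pool <- pool[keepers, ]
    accepted <- head(pool, n_peaks)
    need <- n_peaks - nrow(accepted)
  }
  if (is.null(accepted) || nrow(accepted) < n_peaks) {
    abort("synthetic peaks do not fit: infeasible configuration")
  }
  sort_intervals(as_intervals(accepted))
}

# --- CpG islands and methylation --------------------------------------------

sim_islands <- function(cfg, states, sizes) {
  prom <- filter(states, .data$name == "active_promoter")
  n_prom_isl <- min(round(0.6 * cfg$n_islands), nrow(prom))
  n_other <- cfg$n_islands - n_prom_isl
  sz <- setNames(sizes$size, sizes$chrom)
  widths <- round(cfg$island_min_width +
                    rexp(cfg$n_islands, 1 / (cfg$island_mean_width - cfg$island_min_width)))
  sel <- sample.int(nrow(prom), n_prom_isl)
  centres_prom <- tibble(chrom = prom$chrom[sel],
                         centre = floor((prom$start[sel] + prom$end[sel]) / 2))
  other_space <- filter(states, .data$name %in% c("transcription", "unmarked"))
  pos <- sample_positions(other_space, n_other)
  centres <- bind_rows(centres_prom, tibble(chrom = pos$chrom, centre = pos$pos))
  isl <- tibble(
    chrom = centres$chrom,
    start = pmax(0, centres$centre - floor(widths / 2)),
    end = pmin(sz[centres$chrom], centres$centre + ceiling(widths / 2)),
    name = sprintf("island%03d", seq_len(cfg$n_islands)),
    from_promoter = c(rep(TRUE, n_prom_isl), rep(FALSE, n_other))
  )
  # methylated islands are rare at promoters, common elsewhere
  p_meth <- if_else(isl$from_promoter, 0.05,
                    pmin(1, (cfg$island_meth_frac - 0.05 * n_prom_isl / cfg$n_islands) /
                           max(n_other / cfg$n_islands, 1e-9)))
  isl$planted_methylated <- runif(nrow(isl)) < p_meth
  # avoid overlapping islands (drop later ones)
  g <- as_granges(isl)
  ov <- GenomicRanges::findOverlaps(g, g)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  drop <- unique(qh[qh > sh])
  if (length(drop) > 0) isl <- isl[-drop, ]
  sort_intervals(isl[, c("chrom", "start", "end", "name", "from_promoter",
                         "planted_methylated")] |>
                   mutate(score = NA_real_, strand = NA_character_))
}

sim_cpg_meth <- function(cfg, islands) {
  rows <- pmap(list(islands$chrom, islands$start, islands$end,
                    islands$planted_methylated), function(ch, s, e, meth) {
    pos <- seq(s, e - 1, by = cfg$cpg_spacing)
    ab <- if (meth) cfg$meth_beta else cfg$unmeth_beta
    ratio <- rbeta(length(pos), ab[1], ab[2])
    total <- 6 + rpois(length(pos), cfg$meth_coverage_mean - 6)
    tibble(chrom = ch, pos = pos, context = "CpG",
           methylated = rbinom(length(pos), total, ratio), total = total)
  })
  bind_rows(rows) |> arrange(.data$chrom, .data$pos)
}

sim_gch <- function(cfg, states, marks_info, sizes) {
  active <- bind_rows(
    filter(states, .data$name == "active_promoter"),
    filter(marks_info$enhancer_truth, .data$planted == "active")
  )
  act_rows <- pmap(list(active$chrom, active$start, active$end),
                   function(ch, s, e) {
    pos <- seq(s, e - 1, by = cfg$gch_spacing)
    tibble(chrom = ch, pos = pos, active = TRUE)
  })
  bg_pos <- sample_positions(
    filter(states, !.data$name %in% c("active_promoter", "active_enhancer")),
    cfg$gch_background_n)
  sites <- bind_rows(bind_rows(act_rows),
                     tibble(chrom = bg_pos$chrom, pos = bg_pos$pos, active = FALSE)) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  ab_a <- cfg$gch_active_beta; ab_i <- cfg$gch_inactive_beta
  ratio <- ifelse(sites$active,
                  rbeta(nrow(sites), ab_a[1], ab_a[2]),
                  rbeta(nrow(sites), ab_i[1], ab_i[2]))
  total <- 6 + rpois(nrow(sites), cfg$meth_coverage_mean - 6)
  tibble(chrom = sites$chrom, pos = sites$pos, context = "GCH",
         methylated = rbinom(nrow(sites), total, ratio), total = total) |>
    arrange(.data$chrom, .data$pos)
}

# --- genes and expression ----------------------------------------------------

sim_genes <- function(cfg, states) {
  class_states <- c(active = "active_promoter", bivalent = "bivalent",
                    repressive = "repressive")
  cls <- sample(names(cfg$gene_class_probs), cfg$n_genes, replace = TRUE,
                prob = cfg$gene_class_probs)
  segs <- map(names(class_states), function(k) {
    pool <- filter(states, .data$name == class_states[[k]])
    idx <- which(cls == k)
    if (length(idx) == 0) return(NULL)
    take <- sample.int(nrow(pool), min(length(idx), nrow(pool)))
    tibble(gene_idx = idx[seq_along(take)],
           chrom = pool$chrom[take],
           tss = floor((pool$start[take] + pool$end[take]) / 2),
           promoter_class = k)
  }) |> bind_rows() |> arrange(.data$gene_idx)
  n <- nrow(segs)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- pmax(200, round(rlnorm(n, cfg$gene_length_meanlog, cfg$gene_length_sdlog)))
  expressed <- segs$promoter_class != "repressive"
  base <- rep(NA_real_, n)
  base[expressed] <- rnorm(sum(expressed),
                           cfg$expr_meanlog[segs$promoter_class[expressed]],
                           cfg$expr_sdlog)
  dominant <- if_else(runif(n) < cfg$frac_group1_dominant, "Group1", "Group2")
  shift <- ifelse(expressed & dominant == "Group1", cfg$delta, 0)
  counts <- map(seq_len(cfg$n_reps), function(r) {
    mu <- ifelse(expressed, exp(base + shift + rnorm(n, 0, cfg$expr_rep_sd)) *
                   len / 1000, 0.2)
    rpois(n, mu)
  })
  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = segs$chrom, tss = segs$tss, strand = strand, length = len
  )
  for (r in seq_len(cfg$n_reps)) genes[[sprintf("count_%d", r)]] <- counts[[r]]
  truth <- tibble(
    gene_id = genes$gene_id, promoter_class = segs$promoter_class,
    expressed = expressed, base_logexpr = base, dominant_group = dominant,
    planted_shift = shift
  )
  list(genes = genes, truth = truth)
}

# --- remodeller signal tracks ------------------------------------------------

# Piled peak signal plus planted promoter dominance, flattened to
# non-overlapping runs via coverage.
sim_signal_one <- function(cfg, peaks, genes, gene_truth, group, sizes) {
  sz <- setNames(sizes$size, sizes$chrom)
  win <- tibble(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - cfg$promoter_flank),
    end = pmin(sz[genes$chrom], genes$tss + cfg$promoter_flank),
    w = if_else(gene_truth$dominant_group == group,
                cfg$dominant_weight, cfg$other_weight)
  )
  gr <- GenomicRanges::GRanges(
    seqnames = factor(c(peaks$chrom, win$chrom), levels = sizes$chrom),
    ranges = IRanges::IRanges(start = c(peaks$start, win$start) + 1,
                              end = c(peaks$end, win$end)),
    seqlengths = setNames(as.integer(sizes$size), sizes$chrom)
  )
  cov <- GenomicRanges::coverage(gr, weight = c(rep(cfg$peak_signal_value, nrow(peaks)),
                                                win$w))
  runs <- imap(as.list(cov), function(rle, ch) {
    v <- S4Vectors::runValue(rle); l <- S4Vectors::runLength(rle)
    e <- cumsum(as.double(l)); s <- e - l
    keep <- v != 0
    tibble(chrom = ch, start = s[keep], end = e[keep], value = as.double(v[keep]))
  }) |> bind_rows()
  signal_track(runs, sizes)
}

# --- architecture ------------------------------------------------------------

sim_tads <- function(cfg, sizes) {
  out <- map(seq_len(nrow(sizes)), function(i) {
    L <- sizes$size[i]; ch <- sizes$chrom[i]
    tads <- list(); bounds <- list()
    pos <- 0
    while (pos < L) {
      gap <- round(rexp(1, 1 / cfg$gap_mean_len))
      pos <- pos + gap
      if (pos >= L) break
      tad <- round(cfg$tad_min_len + rexp(1, 1 / (cfg$tad_mean_len - cfg$tad_min_len)))
      tad_end <- min(pos + tad, L)
      if (tad_end - pos >= 1e4) tads[[length(tads) + 1]] <- c(pos, tad_end)
      pos <- tad_end
      if (pos >= L) break
      b_end <- min(pos + cfg$boundary_len, L)
      if (b_end - pos >= 1e3) bounds[[length(bounds) + 1]] <- c(pos, b_end)
      pos <- b_end
    }
    list(
      tads = tibble(chrom = ch,
                    start = map_dbl(tads, 1), end = map_dbl(tads, 2)),
      bounds = tibble(chrom = ch,
                      start = map_dbl(bounds, 1), end = map_dbl(bounds, 2))
    )
  })
  list(tads = bind_rows(map(out, "tads")), boundaries = bind_rows(map(out, "bounds")))
}

sim_loops <- function(cfg, states, marks_info, lamin, sizes) {
  n_anchors <- 2 * cfg$n_loops
  n_typeA <- round(cfg$typeA_frac * n_anchors)
  typeA_slot <- rep(FALSE, n_anchors)
  typeA_slot[sample.int(n_anchors, n_typeA)] <- TRUE
  active_el <- bind_rows(
    filter(states, .data$name == "active_promoter"),
    filter(marks_info$enhancer_truth, .data$planted == "active")
  )
  w <- cfg$anchor_width
  sz <- setNames(sizes$size, sizes$chrom)
  # Type B anchors live wholly inside unmarked, non-lamin segments, so they
  # cannot touch an active element.
  un <- interval_subtract(filter(states, .data$name == "unmarked"), lamin)
  un <- filter(un, .data$end - .data$start >= w + 2)
  place_anchor <- function(typeA, chrom_want) {
    if (typeA) {
      pool <- filter(active_el, .data$chrom == chrom_want)
      i <- sample.int(nrow(pool), 1)
      c0 <- floor((pool$start[i] + pool$end[i]) / 2)
      s <- max(0, min(c0 - w / 2, sz[chrom_want] - w))
    } else {
      pool <- filter(un, .data$chrom == chrom_want, .data$end - .data$start >= w + 2)
      i <- sample.int(nrow(pool), 1)
      s <- floor(runif(1, pool$start[i], pool$end[i] - w))
    }
    c(s, s + w)
  }
  chroms <- sample(sizes$chrom, cfg$n_loops, replace = TRUE,
                   prob = sizes$size / sum(sizes$size))
  loops <- map(seq_len(cfg$n_loops), function(i) {
    ch <- chroms[i]
    a <- place_anchor(typeA_slot[2 * i - 1], ch)
    b <- place_anchor(typeA_slot[2 * i], ch)
    if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp
      typeA_slot[c(2 * i - 1, 2 * i)] <<- typeA_slot[c(2 * i, 2 * i - 1)] }
    tibble(chrom_a = ch, start_a = a[1], end_a = a[2],
           chrom_b = ch, start_b = b[1], end_b = b[2], score = NA_real_)
  }) |> bind_rows()
  anchor_truth <- tibble(
    name = as.vector(rbind(sprintf("loop%d_A", seq_len(cfg$n_loops)),
                           sprintf("loop%d_B", seq_len(cfg$n_loops)))),
    planted = if_else(typeA_slot, "TypeA", "TypeB")
  )
  list(loops = loops, anchor_truth = anchor_truth)
}

# --- sequence ----------------------------------------------------------------

sim_fasta <- function(cfg, path) {
  at <- cfg$at_fraction
  probs <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(cfg$chrom_lengths)) {
    writeLines(paste0(">", ch), con)
    L <- cfg$chrom_lengths[[ch]]
    done <- 0
    while (done < L) {
      k <- min(1e6, L - done)
      chunk <- paste0(sample(names(probs), k, replace = TRUE, prob = probs),
                      collapse = "")
      at <- seq(1, k, by = 80)
      writeLines(substring(chunk, at, pmin(at + 79, k)), con)
      done <- done + k
    }
  }
  invisible(path)
}

# --- orchestrator ------------------------------------------------------------

#' Generate a synthetic epigenome
#'
#' Emits, under `out_dir`, every file the pipeline consumes: chromosome
#' sizes, chromatin-state segmentation, histone-mark peak BEDs consistent
#' with the states, eight remodeller peak BEDs with planted group
#' preferences, lamina-like exclusion domains, CpG-island intervals with
#' CpG and GCH methylation count tables, a gene table with replicate counts,
#' per-remodeller bedGraph signal, TAD/boundary BEDs and a loop BEDPE with
#' planted Type A/B anchors. The same `(config, seed)` always produces
#' byte-identical files; each layer draws from its own named substream of
#' the seed.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param layers Optional layers to emit in addition to the core
#'   (states, marks, remodeller peaks, lamin): any of `"sequence"`,
#'   `"signal"`, `"methylation"`, `"expression"`, `"architecture"`.
#' @return An object of class `chromstrat_sim`: a list holding the emitted
#'   tables, the file paths, the ground-truth manifest (`$truth`) and the
#'   configuration.
#' @export
simulate_epigenome <- function(config = sim_config(), out_dir = tempfile("simepi"),
                               seed = config$seed,
                               layers = c("sequence", "signal", "methylation",
                                          "expression", "architecture")) {
  cfg <- config
  sizes <- sim_sizes(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ss <- function(name) substream_seed(seed, name)

  states <- withr::with_seed(ss("states"), sim_states(cfg))
  lamin <- withr::with_seed(ss("lamin"), sim_lamin(cfg, states))
  mk <- withr::with_seed(ss("marks"), sim_marks(cfg, states))

  genome <- genome_workspace(sizes)
  pref_space <- list(
    Group1 = interval_subtract(filter(states, .data$name %in% cfg$active_states), lamin),
    Group2 = interval_subtract(filter(states, .data$name %in% cfg$repressive_states), lamin)
  )
  other_space <- map(pref_space, function(p) {
    interval_subtract(interval_subtract(genome, p), lamin)
  })
  peaks <- map(seq_len(nrow(cfg$remodellers)), function(i) {
    nm <- cfg$remodellers$name[i]; grp <- cfg$remodellers$group[i]
    rho <- if (grp == "Group1") cfg$rho1 else cfg$rho2
    withr::with_seed(ss(paste0("peaks/", nm)),
                     sim_peaks_one(cfg, pref_space[[grp]], other_space[[grp]],
                                   rho, cfg$n_peaks, sizes, forbidden = lamin))
  })
  names(peaks) <- cfg$remodellers$name

  out <- list(dir = out_dir, config = cfg, sizes = sizes, states = states,
              lamin = lamin, marks = mk$marks, peaks = peaks)
  paths <- list(sizes = file.path(out_dir, "chrom.sizes"),
                states = file.path(out_dir, "states.bed"),
                lamin = file.path(out_dir, "lamin.bed"))
  write_chrom_sizes(sizes, paths$sizes)
  write_bed(as_intervals(states), paths$states)
  write_bed(as_intervals(lamin), paths$lamin)
  dir.create(file.path(out_dir, "marks"), showWarnings = FALSE)
  paths$marks <- map_chr(names(mk$marks), function(m) {
    p <- file.path(out_dir, "marks", paste0(m, ".bed"))
    write_bed(mk$marks[[m]], p); p
  })
  names(paths$marks) <- names(mk$marks)
  dir.create(file.path(out_dir, "remodellers"), showWarnings = FALSE)
  paths$peaks <- map_chr(names(peaks), function(nm) {
    p <- file.path(out_dir, "remodellers", paste0(nm, ".bed"))
    write_bed(peaks[[nm]], p); p
  })
  names(paths$peaks) <- names(peaks)

  truth <- list(
    remodellers = tibble(
      name = cfg$remodellers$name, group = cfg$remodellers$group,
      preferred_states = if_else(cfg$remodellers$group == "Group1",
                                 paste(cfg$active_states, collapse = ","),
                                 paste(cfg$repressive_states, collapse = ",")),
      planted_odds = if_else(cfg$remodellers$group == "Group1", cfg$rho1, cfg$rho2),
      n_peaks = cfg$n_peaks
    ),
    enhancers = mk$enhancer_truth
  )

  if ("methylation" %in% layers) {
    islands <- withr::with_seed(ss("islands"), sim_islands(cfg, states, sizes))
    meth_cpg <- withr::with_seed(ss("meth_cpg"), sim_cpg_meth(cfg, islands))
    meth_gch <- withr::with_seed(ss("meth_gch"), sim_gch(cfg, states, mk, sizes))
    out$islands <- islands; out$meth_cpg <- meth_cpg; out$meth_gch <- meth_gch
    truth$islands <- islands[, c("chrom", "start", "end", "name",
                                 "from_promoter", "planted_methylated")]
    paths$islands <- file.path(out_dir, "cpg_islands.bed")
    write_bed(as_intervals(islands), paths$islands)
    paths$meth_cpg <- file.path(out_dir, "meth_cpg.tsv")
    write_methylation(meth_cpg, paths$meth_cpg)
    paths$meth_gch <- file.path(out_dir, "meth_gch.tsv")
    write_methylation(meth_gch, paths$meth_gch)
  }

  if ("expression" %in% layers || "signal" %in% layers) {
    g <- withr::with_seed(ss("genes"), sim_genes(cfg, states))
    out$genes <- g$genes
    truth$genes <- g$truth
    paths$genes <- file.path(out_dir, "genes.tsv")
    write_gene_table(g$genes, paths$genes)
  }

  if ("signal" %in% layers) {
    dir.create(file.path(out_dir, "signal"), showWarnings = FALSE)
    out$tracks <- map(names(peaks), function(nm) {
      grp <- cfg$remodellers$group[cfg$remodellers$name == nm]
      sim_signal_one(cfg, peaks[[nm]], out$genes, truth$genes, grp, sizes)
    })
    names(out$tracks) <- names(peaks)
    paths$signal <- map_chr(names(out$tracks), function(nm) {
      p <- file.path(out_dir, "signal", paste0(nm, ".bedGraph"))
      write_bedgraph(out$tracks[[nm]], p); p
    })
    names(paths$signal) <- names(out$tracks)
  }

  if ("architecture" %in% layers) {
    td <- withr::with_seed(ss("tads"), sim_tads(cfg, sizes))
    lp <- withr::with_seed(ss("loops"), sim_loops(cfg, states, mk, lamin, sizes))
    out$tads <- td$tads; out$boundaries <- td$boundaries; out$loops <- lp$loops
    truth$anchors <- lp$anchor_truth
    paths$tads <- file.path(out_dir, "tads.bed")
    write_bed(as_intervals(td$tads), paths$tads)
    paths$boundaries <- file.path(out_dir, "boundaries.bed")
    write_bed(as_intervals(td$boundaries), paths$boundaries)
    paths$loops <- file.path(out_dir, "loops.bedpe")
    write_bedpe(lp$loops, paths$loops)
  }

  if ("sequence" %in% layers) {
    paths$fasta <- file.path(out_dir, "genome.fa")
    withr::with_seed(ss("fasta"), sim_fasta(cfg, paths$fasta))
  }

  out$truth <- truth
  out$paths <- paths
  out$seed <- as.integer(seed)
  class(out) <- "chromstrat_sim"
  out
}

#' Write the ground-truth manifest as TSV
#'
#' Emits the planted remodeller group labels (one labelled row per
#' remodeller, with the preferred states and planted odds), and alongside
#' it any other truth tables present (islands, genes, anchors, enhancers).
#'
#' @param sim A `chromstrat_sim` object.
#' @param dir Output directory (default: `truth/` under the simulation
#'   directory).
#' @return Path of the remodeller truth TSV, invisibly.
#' @export
truth_report <- function(sim, dir = file.path(sim$dir, "truth")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  main <- file.path(dir, "remodellers.tsv")
  readr::write_tsv(sim$truth$remodellers, main, progress = FALSE)
  for (nm in setdiff(names(sim$truth), "remodellers")) {
    readr::write_tsv(as_tibble(sim$truth[[nm]]),
                     file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  invisible(main)
}

#' Empirical peak density ratio between two state spaces
#'
#' Counts peak start positions per bp inside the preferred states versus
#' everywhere else (optionally excluding e.g. lamina domains from both
#' spaces), the direct estimator of the planted placement odds.
#'
#' @param peaks Peak interval tibble.
#' @param states State segmentation tibble (`name` holds state labels).
#' @param preferred_states Character vector of preferred state labels.
#' @param exclude Optional interval tibble removed from both spaces.
#' @return The density ratio (preferred / elsewhere).
#' @export
planted_density_ratio <- function(peaks, states, preferred_states, exclude = NULL) {
  pref <- interval_merge(filter(states, .data$name %in% preferred_states))
  rest <- interval_merge(filter(states, !.data$name %in% preferred_states))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    pref <- interval_subtract(pref, exclude)
    rest <- interval_subtract(rest, exclude)
  }
  starts <- tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$start + 1)
  n_pref <- sum(overlaps_any(starts, pref))
  n_rest <- sum(overlaps_any(starts, rest))
  (n_pref / total_bp(pref)) / (n_rest / total_bp(rest))
}

#' @export
print.chromstrat_sim <- function(x, ...) {
  cat("<chromstrat_sim>", x$dir, "\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total\n",
              nrow(x$sizes), sum(x$sizes$size) / 1e6))
  cat(sprintf("  remodellers: %d (%d peaks each), seed %d\n",
              length(x$peaks), x$config$n_peaks, x$seed))
  invisible(x)
}
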