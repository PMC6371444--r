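# End-to-end orchestration: validate -> classify -> enrich -> stratify ->
# integrate -> report, over a data directory laid out as the synthetic
# generator emits it. All numeric outputs are deterministic for a given
# config (every stochastic stage draws from a named substream of the config
# seed), and every output file embeds the tool version, a config hash and
# the seed.

#' Pipeline run configuration
#'
#' @param input_dir Data directory (layout as written by
#'   [simulate_epigenome()]: `chrom.sizes`, `states.bed`, `lamin.bed`,
#'   `marks/*.bed`, `remodellers/*.bed`, optional `signal/*.bedGraph`,
#'   `cpg_islands.bed`, `meth_cpg.tsv`, `meth_gch.tsv`, `genes.tsv`,
#'   `tads.bed`, `boundaries.bed`, `loops.bedpe`).
#' @param out_dir Output directory for stage reports.
#' @param n_iter Randomization iterations per enrichment test.
#' @param flank Promoter half-width in bp.
#' @param min_cov Coverage threshold for methylation ratios (`total >
#'   min_cov`).
#' @param island_bins Bins per CpG island for methylation classification.
#' @param alpha Significance levels annotated in reports.
#' @param seed Integer seed.
#' @return A list of class `chromstrat_run_config`.
#' @export
run_config <- function(input_dir, out_dir = file.path(input_dir, "results"),
                       n_iter = 1000, flank = 1000, min_cov = 5,
                       island_bins = 40, alpha = c(0.05, 0.001), seed = 1L) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, n_iter = n_iter,
              flank = flank, min_cov = min_cov, island_bins = island_bins,
              alpha = alpha, seed = as.integer(seed))
  class(cfg) <- "chromstrat_run_config"
  cfg
}

pipeline_files <- function(config) {
  d <- config$input_dir
  list(
    sizes = file.path(d, "chrom.sizes"),
    states = file.path(d, "states.bed"),
    lamin = file.path(d, "lamin.bed"),
    marks = list.files(file.path(d, "marks"), pattern = "\\.bed$", full.names = TRUE),
    peaks = list.files(file.path(d, "remodellers"), pattern = "\\.bed$", full.names = TRUE),
    signal = list.files(file.path(d, "signal"), pattern = "\\.bedGraph$", full.names = TRUE),
    islands = file.path(d, "cpg_islands.bed"),
    meth_cpg = file.path(d, "meth_cpg.tsv"),
    meth_gch = file.path(d, "meth_gch.tsv"),
    genes = file.path(d, "genes.tsv"),
    tads = file.path(d, "tads.bed"),
    boundaries = file.path(d, "boundaries.bed"),
    loops = file.path(d, "loops.bedpe")
  )
}

#' Validate pipeline inputs
#'
#' Checks that every required file exists and parses, and that chromosome
#' naming is consistent (verbatim names; a `chr1` vs `1` mixture is a
#' failure, not a warning) across all layers.
#'
#' @param config A [run_config()].
#' @return Tibble `file`, `ok`, `message`; one row per check.
#' @export
validate_inputs <- function(config) {
  f <- pipeline_files(config)
  rows <- list()
  note <- function(file, ok, message = "") {
    rows[[length(rows) + 1]] <<- tibble(file = file, ok = ok, message = message)
  }
  sizes <- NULL
  tryCatch({
    sizes <- read_chrom_sizes(f$sizes)
    note(f$sizes, TRUE)
  }, error = function(e) note(f$sizes, FALSE, conditionMessage(e)))
  check_read <- function(path, reader, required = TRUE) {
    if (!file.exists(path)) {
      note(path, !required, if (required) "missing file" else "absent (optional)")
      return(NULL)
    }
    tryCatch({
      x <- reader(path)
      note(path, TRUE)
      x
    }, error = function(e) { note(path, FALSE, conditionMessage(e)); NULL })
  }
  chrom_seen <- list()
  bed_reader <- function(path) {
    x <- read_bed(path)
    chrom_seen[[path]] <<- unique(x$chrom)
    # bounds are only checkable when the names resolve in the sizes table
    if (!is.null(sizes) && all(x$chrom %in% sizes$chrom)) {
      validate_intervals(x, sizes = sizes, what = path)
    }
    x
  }
  for (p in c(f$states, f$lamin, f$marks, f$peaks, f$islands, f$tads, f$boundaries)) {
    check_read(p, bed_reader, required = !p %in% c(f$islands, f$tads, f$boundaries))
  }
  check_read(f$loops, read_bedpe, required = FALSE)
  check_read(f$genes, read_gene_table, required = FALSE)
  check_read(f$meth_cpg, function(p) read_methylation(p, "CpG"), required = FALSE)
  check_read(f$meth_gch, function(p) read_methylation(p, "GCH"), required = FALSE)
  for (p in f$signal) {
    if (!is.null(sizes)) check_read(p, function(pp) read_bedgraph(pp, sizes))
  }
  if (!is.null(sizes)) {
    all_chroms <- unique(unlist(chrom_seen))
    stray <- setdiff(all_chroms, sizes$chrom)
    if (length(stray) > 0) {
      note("chromosome naming", FALSE,
           sprintf("chromosome name(s) absent from sizes table: %s",
                   paste(stray, collapse = ", ")))
    } else {
      note("chromosome naming", TRUE)
    }
  }
  bind_rows(rows)
}

# The config fingerprint covers the scientific parameters only, so a run is
# identified by what was computed, not by where its files happen to live.
run_config_hash <- function(config) {
  config_hash(config[setdiff(names(config), c("input_dir", "out_dir"))])
}

output_meta <- function(config) {
  c(sprintf("# chromstrat %s", as.character(packageVersion("chromstrat"))),
    sprintf("# config_hash %s", run_config_hash(config)),
    sprintf("# seed %d", config$seed),
    "# null model: independent uniform segment placement within the workspace")
}

write_stage_tsv <- function(x, path, config) {
  writeLines(output_meta(config), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

stars_for <- function(q, alpha) {
  dplyr::case_when(q < min(alpha) ~ "**", q < max(alpha) ~ "*", TRUE ~ "")
}

#' Run the full analysis pipeline
#'
#' Executes validation, peak statistics, element classification, the
#' enrichment matrix, two-group stratification with group contrasts,
#' methylation/accessibility summaries, expression linkage and the
#' genome-architecture partition, writing one TSV per stage plus a
#' `summary.json`. Re-running with the same config reproduces byte-identical
#' numeric outputs.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly; outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[chromstrat] stage %-16s %6.1fs", name,
                    as.double(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  vr <- stage("validate", validate_inputs(config))
  if (any(!vr$ok)) {
    bad <- vr[!vr$ok, ]
    abort(sprintf("input validation failed: %s (%s)", bad$file[1], bad$message[1]))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- pipeline_files(config)
  sizes <- read_chrom_sizes(f$sizes)
  genome_bp <- sum(sizes$size)
  workspace <- genome_workspace(sizes)
  states <- read_bed(f$states, sizes)
  lamin <- read_bed(f$lamin, sizes)
  marks <- map(f$marks, read_bed, sizes = sizes)
  names(marks) <- sub("\\.bed$", "", basename(f$marks))
  peaks <- map(f$peaks, read_bed, sizes = sizes)
  names(peaks) <- sub("\\.bed$", "", basename(f$peaks))

  # --- peak statistics (counts, widths, uniqueness, coverage) ---------------
  stats_tbl <- stage("peak_stats", {
    ov <- overlap_summary(peaks)
    u <- site_union(peaks)
    per <- imap(peaks, function(x, nm) {
      tibble(name = nm, n_sites = nrow(x),
             median_width = stats::median(x$end - x$start),
             frac_under_750bp = width_fraction_below(x, 750),
             genome_coverage_pct = coverage_fraction(x, genome_bp) * 100)
    }) |> bind_rows() |>
      left_join(ov[, c("name", "frac_shared", "frac_unique")], by = "name")
    attr(per, "n_union") <- nrow(u)
    per
  })
  write_stage_tsv(stats_tbl, file.path(config$out_dir, "peak_stats.tsv"), config)

  # --- element classification ----------------------------------------------
  have_genes <- file.exists(f$genes)
  elements <- stage("classify", {
    el <- list()
    if (have_genes) {
      genes <- read_gene_table(f$genes)
      windows <- promoter_windows(genes, sizes, flank = config$flank)
      pc <- classify_promoters(windows, marks)
      el$promoters <- pc
      el$genes <- genes
      el$windows <- windows
    }
    if (all(c("H3K4me1", "H3K27ac", "p300", "DNaseI") %in% names(marks)) && have_genes) {
      el$enhancers <- classify_enhancers(marks$H3K4me1, el$genes, marks$H3K27ac,
                                         marks$p300, marks$DNaseI)
    }
    if (file.exists(f$islands) && file.exists(f$meth_cpg) && have_genes) {
      islands <- read_bed(f$islands, sizes)
      meth <- read_methylation(f$meth_cpg, "CpG")
      el$islands <- classify_cpg_islands(islands, el$windows, meth,
                                         n_bins = config$island_bins,
                                         min_cov = config$min_cov)
    }
    if (file.exists(f$loops)) {
      loops <- read_bedpe(f$loops)
      act_prom <- if (!is.null(el$promoters))
        filter(el$promoters, .data$label == "active") else empty_intervals()
      act_enh <- if (!is.null(el$enhancers))
        filter(el$enhancers, .data$label == "active") else empty_intervals()
      el$anchors <- classify_anchors(loops, act_prom, act_enh)
    }
    el
  })
  if (!is.null(elements$promoters)) {
    write_stage_tsv(dplyr::count(elements$promoters, .data$label),
                    file.path(config$out_dir, "promoter_classes.tsv"), config)
  }

  # --- enrichment matrix ----------------------------------------------------
  features <- list()
  for (st in unique(states$name)) {
    features[[paste0("state_", st)]] <- filter(states, .data$name == st)
  }
  if (nrow(lamin) > 0) features$lamin <- lamin
  if (!is.null(elements$anchors)) {
    features$anchors_typeA <- filter(elements$anchors, .data$label == "TypeA")
    features$anchors_typeB <- filter(elements$anchors, .data$label == "TypeB")
  }
  if (!is.null(elements$islands)) {
    mi <- filter(elements$islands, .data$label == "methylated")
    ui <- filter(elements$islands, .data$label == "unmethylated")
    if (nrow(mi) > 0) features$islands_methylated <- mi
    if (nrow(ui) > 0) features$islands_unmethylated <- ui
  }
  if ("DNaseI" %in% names(marks)) features$DNaseI <- marks$DNaseI
  features <- keep(features, function(x) nrow(x) > 0)
  enr <- stage("enrich", {
    enrichment_matrix(peaks, features, workspace, n_iter = config$n_iter,
                      seed = substream_seed(config$seed, "pipeline/enrich"))
  })
  enr_out <- mutate(as_tibble(enr), signif = stars_for(.data$q_bh, config$alpha))
  write_stage_tsv(enr_out, file.path(config$out_dir, "enrichment.tsv"), config)

  # --- stratification -------------------------------------------------------
  active_feats <- intersect(c("state_active_promoter", "state_active_enhancer",
                              "state_transcription"), names(features))
  repressive_feats <- intersect("state_repressive", names(features))
  groups <- stage("stratify", {
    stratify_remodellers(enr, active_feats, repressive_feats)
  })
  gmap <- setNames(groups$assignments$group, groups$assignments$name)
  contrasts <- group_contrasts(enr, gmap)
  write_stage_tsv(groups$assignments,
                  file.path(config$out_dir, "groups.tsv"), config)
  write_stage_tsv(contrasts,
                  file.path(config$out_dir, "group_contrasts.tsv"), config)

  # --- methylation / accessibility at binding sites -------------------------
  meth_summary <- NULL
  if (file.exists(f$meth_cpg) || file.exists(f$meth_gch)) {
    meth_summary <- stage("methylation", {
      rows <- list()
      for (ctx in c("CpG", "GCH")) {
        p <- if (ctx == "CpG") f$meth_cpg else f$meth_gch
        if (!file.exists(p)) next
        tab <- read_methylation(p, ctx)
        for (nm in names(peaks)) {
          sm <- site_mean_methylation(tab, peaks[[nm]], min_cov = config$min_cov)
          rows[[paste(ctx, nm)]] <- tibble(
            context = ctx, name = nm,
            mean_ratio = mean(sm$mean_methylation, na.rm = TRUE),
            n_sites_with_data = sum(!is.na(sm$mean_methylation)))
        }
      }
      bind_rows(rows)
    })
    write_stage_tsv(meth_summary,
                    file.path(config$out_dir, "methylation.tsv"), config)
  }

  # --- expression linkage ---------------------------------------------------
  expr_link <- NULL
  if (have_genes && length(f$signal) > 0) {
    expr_link <- stage("expression", {
      tracks <- map(f$signal, read_bedgraph, sizes = sizes)
      names(tracks) <- sub("\\.bedGraph$", "", basename(f$signal))
      tpm_tbl <- tpm_table(elements$genes)
      g1 <- tracks[names(gmap)[gmap == "Group1"]]
      g2 <- tracks[names(gmap)[gmap == "Group2"]]
      link_expression(elements$windows, g1, g2, tpm_tbl, sizes)
    })
    write_stage_tsv(glance(expr_link),
                    file.path(config$out_dir, "expression_link.tsv"), config)
  }

  # --- architecture ---------------------------------------------------------
  arch <- NULL
  if (file.exists(f$tads) && file.exists(f$boundaries)) {
    arch <- stage("architecture", {
      part <- partition_genome(read_bed(f$tads, sizes),
                               read_bed(f$boundaries, sizes), sizes)
      list(partition = part, binding = binding_partition(peaks, part))
    })
    write_stage_tsv(arch$partition$fractions,
                    file.path(config$out_dir, "genome_partition.tsv"), config)
    write_stage_tsv(arch$binding,
                    file.path(config$out_dir, "binding_partition.tsv"), config)
  }

  # --- summary --------------------------------------------------------------
  summary <- list(
    tool = "chromstrat",
    version = as.character(packageVersion("chromstrat")),
    config_hash = run_config_hash(config),
    seed = config$seed,
    n_iter = config$n_iter,
    n_remodellers = length(peaks),
    n_binding_sites_union = attr(stats_tbl, "n_union"),
    groups = as.list(gmap),
    group_separation = groups$separation,
    group_contrasts = contrasts,
    partition_percent = if (!is.null(arch)) {
      setNames(as.list(arch$partition$fractions$percent),
               arch$partition$fractions$class)
    },
    expression_p_one_tailed = if (!is.null(expr_link)) expr_link$p_one_tailed
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
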