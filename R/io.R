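# Readers and writers for the plain-text genomic formats the pipeline
# consumes: BED3/BED6, BEDPE, bedGraph, FASTA, chromosome sizes, per-position
# methylation count tables and gene tables. All coordinates are 0-based,
# half-open (BED convention) everywhere in the package. Readers validate and
# refuse malformed input rather than repairing it; chromosome names are taken
# verbatim.

read_data_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

num_or_stop <- function(s, path, lineno, what) {
  x <- suppressWarnings(as.numeric(s))
  bad <- which(is.na(x) | x != floor(x))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-integer %s at line %d", path, what, lineno[bad[1]]))
  }
  x
}

#' Read genomic intervals from a BED file
#'
#' Parses BED3 or BED6 into the canonical interval tibble. `track`,
#' `browser` and `#` lines are skipped. Coordinates are kept exactly as in
#' the file (0-based, half-open); records are returned in canonical
#' (chrom, start, end) order regardless of file order.
#'
#' @param path Path to a tab-separated BED file.
#' @param sizes Optional chromosome sizes tibble; when given, records beyond
#'   a chromosome end or on unknown chromosomes are rejected.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (the last three `NA` for BED3).
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", p)
#' read_bed(p)
#' @export
read_bed <- function(path, sizes = NULL) {
  dl <- read_data_lines(path)
  if (length(dl$lines) == 0) return(empty_intervals())
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: fewer than 3 fields at line %d", path, dl$lineno[which(nf < 3)[1]]))
  }
  chrom <- map_chr(fields, 1)
  start <- num_or_stop(map_chr(fields, 2), path, dl$lineno, "start")
  end <- num_or_stop(map_chr(fields, 3), path, dl$lineno, "end")
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at line %d", path, dl$lineno[bad[1]]))
  }
  name <- ifelse(nf >= 4, map_chr(fields, function(f) f[4] %||% NA_character_), NA_character_)
  score_chr <- ifelse(nf >= 5, map_chr(fields, function(f) f[5] %||% NA_character_), NA_character_)
  score <- suppressWarnings(as.numeric(ifelse(score_chr == ".", NA, score_chr)))
  strand <- ifelse(nf >= 6, map_chr(fields, function(f) f[6] %||% NA_character_), NA_character_)
  x <- tibble(chrom = chrom, start = start, end = end,
              name = name, score = score, strand = strand)
  as_intervals(x, sizes = sizes, what = path)
}

#' Write genomic intervals to a BED file
#'
#' Writing then reading back is the identity on (`chrom`, `start`, `end`,
#' `name`, `score`, `strand`) for canonical, non-`NA` fields; `NA` optional
#' fields are written as `"."`.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @param format `"BED6"` (default) or `"BED3"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, format = c("BED6", "BED3")) {
  format <- match.arg(format)
  x <- as_intervals(x)
  if (format == "BED3" || nrow(x) == 0) {
    lines <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
    if (format == "BED6" && nrow(x) > 0) {
      lines <- paste(lines, ifelse(is.na(x$name), ".", x$name),
                     ifelse(is.na(x$score), ".", format(x$score, scientific = FALSE, trim = TRUE)),
                     ifelse(is.na(x$strand), ".", x$strand), sep = "\t")
    }
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     x$chrom, as.integer(x$start), as.integer(x$end),
                     ifelse(is.na(x$name), ".", x$name),
                     ifelse(is.na(x$score), ".", format(x$score, scientific = FALSE, trim = TRUE)),
                     ifelse(is.na(x$strand), ".", x$strand))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read chromatin-loop anchor pairs from a BEDPE file
#'
#' Each line describes one intra-chromosomal loop:
#' `chromA startA endA chromB startB endB [score]`. Inter-chromosomal pairs
#' are rejected.
#'
#' @param path Path to a tab-separated BEDPE file.
#' @return A tibble with columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `score`.
#' @export
read_bedpe <- function(path) {
  dl <- read_data_lines(path)
  if (length(dl$lines) == 0) {
    return(tibble(chrom_a = character(), start_a = double(), end_a = double(),
                  chrom_b = character(), start_b = double(), end_b = double(),
                  score = double()))
  }
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("%s: fewer than 6 fields at line %d", path, dl$lineno[which(nf < 6)[1]]))
  }
  x <- tibble(
    chrom_a = map_chr(fields, 1),
    start_a = num_or_stop(map_chr(fields, 2), path, dl$lineno, "startA"),
    end_a = num_or_stop(map_chr(fields, 3), path, dl$lineno, "endA"),
    chrom_b = map_chr(fields, 4),
    start_b = num_or_stop(map_chr(fields, 5), path, dl$lineno, "startB"),
    end_b = num_or_stop(map_chr(fields, 6), path, dl$lineno, "endB"),
    score = suppressWarnings(as.numeric(ifelse(nf >= 7, map_chr(fields, function(f) f[7] %||% NA_character_), NA)))
  )
  inter <- which(x$chrom_a != x$chrom_b)
  if (length(inter) > 0) {
    abort(sprintf("%s: inter-chromosomal pair at line %d", path, dl$lineno[inter[1]]))
  }
  bad <- which(x$start_a >= x$end_a | x$start_b >= x$end_b)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid anchor interval at line %d", path, dl$lineno[bad[1]]))
  }
  x
}

#' Write loop anchor pairs to a BEDPE file
#' @param x Loop tibble as returned by [read_bedpe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                   x$chrom_a, as.integer(x$start_a), as.integer(x$end_a),
                   x$chrom_b, as.integer(x$start_b), as.integer(x$end_b),
                   ifelse(is.na(x$score), ".", format(x$score, scientific = FALSE, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Flatten a loop table into one interval per anchor
#'
#' @param loops Loop tibble as returned by [read_bedpe()].
#' @return Interval tibble with one row per anchor; `name` records the loop
#'   index and anchor side (`"loopN_A"`, `"loopN_B"`).
#' @export
loop_anchors <- function(loops) {
  n <- nrow(loops)
  if (n == 0) return(empty_intervals())
  as_intervals(tibble(
    chrom = c(loops$chrom_a, loops$chrom_b),
    start = c(loops$start_a, loops$start_b),
    end = c(loops$end_a, loops$end_b),
    name = c(sprintf("loop%d_A", seq_len(n)), sprintf("loop%d_B", seq_len(n)))
  ))
}

#' Read a per-position methylation count table
#'
#' Tab-separated with a header; required columns `chrom`, `pos`,
#' `methylated`, `total` and optionally `context`. Counts, not ratios, are
#' stored so that coverage filters (e.g. the greater-than-5x rule) can be
#' applied downstream.
#'
#' @param path Path to the table.
#' @param context `"CpG"` (bisulphite cytosine calls) or `"GCH"` (NOMe-seq
#'   GpC accessibility calls). A `context` column in the file must agree.
#' @return Tibble `chrom`, `pos`, `context`, `methylated`, `total`.
#' @export
read_methylation <- function(path, context = c("CpG", "GCH")) {
  context <- match.arg(context)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "methylated", "total")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  if ("context" %in% names(x)) {
    if (any(x$context != context)) {
      abort(sprintf("%s: context column disagrees with requested context %s", path, context))
    }
  }
  x <- tibble(chrom = as.character(x$chrom), pos = as.double(x$pos),
              context = context,
              methylated = as.double(x$methylated), total = as.double(x$total))
  bad <- which(x$methylated > x$total)
  if (length(bad) > 0) {
    abort(sprintf("%s: methylated > total at data row %d", path, bad[1]))
  }
  if (any(x$total <= 0)) abort(sprintf("%s: non-positive total count", path))
  if (any(x$methylated < 0)) abort(sprintf("%s: negative methylated count", path))
  dup <- duplicated(x[, c("chrom", "pos")])
  if (any(dup)) {
    abort(sprintf("%s: duplicate (chrom, pos) at data row %d", path, which(dup)[1]))
  }
  arrange(x, .data$chrom, .data$pos)
}

#' Write a methylation count table
#' @param x Methylation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Runs must not overlap and must fall within chromosome bounds; bases not
#' covered by any run have value 0.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param sizes Chromosome sizes tibble (`chrom`, `size`).
#' @return A run-length signal tibble `chrom`, `start`, `end`, `value`, with
#'   the sizes table attached as attribute `"sizes"`.
#' @export
read_bedgraph <- function(path, sizes) {
  dl <- read_data_lines(path)
  if (length(dl$lines) == 0) {
    return(signal_track(tibble(chrom = character(), start = double(),
                               end = double(), value = double()), sizes))
  }
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4)) {
    abort(sprintf("%s: fewer than 4 fields at line %d", path, dl$lineno[which(nf < 4)[1]]))
  }
  x <- tibble(
    chrom = map_chr(fields, 1),
    start = num_or_stop(map_chr(fields, 2), path, dl$lineno, "start"),
    end = num_or_stop(map_chr(fields, 3), path, dl$lineno, "end"),
    value = suppressWarnings(as.numeric(map_chr(fields, 4)))
  )
  if (any(is.na(x$value) | !is.finite(x$value))) {
    abort(sprintf("%s: non-numeric value at line %d",
                  path, dl$lineno[which(is.na(x$value) | !is.finite(x$value))[1]]))
  }
  signal_track(x, sizes, what = path)
}

#' Construct a run-length signal track
#'
#' @param runs Tibble `chrom`, `start`, `end`, `value` of non-overlapping
#'   runs; uncovered bases are implicitly 0.
#' @param sizes Chromosome sizes tibble.
#' @param what Label used in error messages.
#' @return The sorted run tibble with `sizes` attached as an attribute.
#' @export
signal_track <- function(runs, sizes, what = "signal track") {
  runs <- as_tibble(runs)[, c("chrom", "start", "end", "value")]
  if (nrow(runs) > 0) {
    validate_intervals(rename(runs, score = "value"), sizes = sizes, what = what)
    runs <- runs[order(runs$chrom, runs$start, method = "radix"), ]
    same <- runs$chrom[-1] == runs$chrom[-nrow(runs)]
    if (nrow(runs) > 1 && any(same & runs$start[-1] < runs$end[-nrow(runs)])) {
      abort(sprintf("%s: overlapping runs", what))
    }
  }
  attr(runs, "sizes") <- sizes
  class(runs) <- c("chromstrat_track", class(runs))
  runs
}

#' Write a signal track as bedGraph
#' @param x Signal track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), format(x$value, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with header; columns `gene_id`, `chrom`, `tss` (0-based),
#' `strand`, `length` (bp) and one or more replicate count columns named
#' `count_*`.
#'
#' @param path Path to the table.
#' @return Tibble with one row per gene.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand", "length")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  count_cols <- grep("^count_", names(x), value = TRUE)
  if (length(count_cols) == 0) abort(sprintf("%s: no count_* columns", path))
  if (any(x$length <= 0)) {
    abort(sprintf("%s: non-positive gene length at data row %d", path, which(x$length <= 0)[1]))
  }
  counts <- as.matrix(x[, count_cols])
  if (any(counts < 0)) abort(sprintf("%s: negative count", path))
  if (any(duplicated(x$gene_id))) abort(sprintf("%s: duplicate gene_id", path))
  as_tibble(x)
}

#' Write a gene table
#' @param x Gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes table
#' @param path Path to a headerless `chrom<TAB>size` file.
#' @return Tibble `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  dl <- read_data_lines(path)
  fields <- strsplit(dl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) abort(sprintf("%s: expected 2 columns", path))
  x <- tibble(chrom = map_chr(fields, 1),
              size = num_or_stop(map_chr(fields, 2), path, dl$lineno, "size"))
  if (any(duplicated(x$chrom))) abort(sprintf("%s: duplicate chromosome", path))
  if (any(x$size <= 0)) abort(sprintf("%s: non-positive chromosome size", path))
  x
}

#' Write a chromosome sizes table
#' @param sizes Tibble `chrom`, `size`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", sizes$chrom, as.integer(sizes$size)), path)
  invisible(path)
}

#' Read genome sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(duplicated(names(seqs)))) {
    abort(sprintf("%s: duplicate FASTA header", path))
  }
  seqs
}
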