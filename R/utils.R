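# Internal helpers shared across modules.

# Canonical empty interval tibble.
empty_intervals <- function() {
  tibble(
    chrom = character(), start = double(), end = double(),
    name = character(), score = double(), strand = character()
  )
}

# Coerce a user-supplied data frame to the canonical interval layout,
# filling optional BED6 columns, and validate invariants.
as_intervals <- function(x, sizes = NULL, what = "interval set") {
  if (!is.data.frame(x)) abort(sprintf("%s must be a data frame", what))
  x <- as_tibble(x)
  if (nrow(x) == 0 && !all(c("chrom", "start", "end") %in% names(x))) {
    return(empty_intervals())
  }
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")))
  }
  if (!"name" %in% names(x)) x$name <- NA_character_
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"strand" %in% names(x)) x$strand <- NA_character_
  x <- x[, c("chrom", "start", "end", "name", "score", "strand")]
  x$chrom <- as.character(x$chrom)
  x$start <- as.double(x$start)
  x$end <- as.double(x$end)
  x$name <- as.character(x$name)
  x$score <- as.double(x$score)
  x$strand <- as.character(x$strand)
  validate_intervals(x, sizes = sizes, what = what)
  sort_intervals(x)
}

sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
}

#' Validate an interval table
#'
#' Checks the invariants every interval set in the package must satisfy:
#' non-empty chromosome names, non-negative starts, `start < end`, and --
#' when a chromosome-sizes table is supplied -- no record extending past its
#' chromosome end and no record on an unknown chromosome.
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param sizes Optional chromosome sizes tibble (`chrom`, `size`).
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x, sizes = NULL, what = "interval set") {
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(x$chrom == "")) {
    abort(sprintf("%s: empty chromosome name", what))
  }
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    abort(sprintf("%s: non-finite coordinate", what))
  }
  if (any(x$start != floor(x$start)) || any(x$end != floor(x$end))) {
    abort(sprintf("%s: non-integer coordinate", what))
  }
  if (any(x$start < 0)) abort(sprintf("%s: negative start", what))
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at record %d (%s:%g-%g)",
                  what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if ("strand" %in% names(x)) {
    ok <- is.na(x$strand) | x$strand %in% c("+", "-", ".")
    if (!all(ok)) abort(sprintf("%s: invalid strand value", what))
  }
  if (!is.null(sizes)) {
    sz <- setNames(sizes$size, sizes$chrom)
    unknown <- setdiff(unique(x$chrom), names(sz))
    if (length(unknown) > 0) {
      abort(sprintf("%s: chromosome(s) not in sizes table: %s",
                    what, paste(unknown, collapse = ", ")))
    }
    over <- which(x$end > sz[x$chrom])
    if (length(over) > 0) {
      abort(sprintf("%s: record %d extends past end of %s",
                    what, over[1], x$chrom[over[1]]))
    }
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

granges_to_tbl <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.double(GenomicRanges::start(gr) - 1),
    end = as.double(GenomicRanges::end(gr)),
    name = NA_character_, score = NA_real_, strand = NA_character_
  )
}

# Chromosome offsets for a concatenated ("global") linear coordinate system.
chrom_offsets <- function(sizes) {
  stopifnot(all(c("chrom", "size") %in% names(sizes)))
  off <- c(0, cumsum(as.double(sizes$size)))[seq_len(nrow(sizes))]
  setNames(off, sizes$chrom)
}

# Add global coordinates gstart/gend to an interval tibble.
globalize <- function(x, offsets) {
  unknown <- setdiff(unique(x$chrom), names(offsets))
  if (length(unknown) > 0) {
    abort(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  x$gstart <- x$start + offsets[x$chrom]
  x$gend <- x$end + offsets[x$chrom]
  x
}

# Step-function representation of cumulative covered bp for a merged interval
# set in global coordinates: F(x) = covered bp in [0, x).
coverage_fun <- function(gstart, gend) {
  if (length(gstart) == 0) {
    return(list(breaks = 0, cum = 0, inside = FALSE))
  }
  o <- order(gstart)
  gstart <- gstart[o]; gend <- gend[o]
  widths <- gend - gstart
  breaks <- as.double(rbind(gstart, gend))       # interleaved start,end
  cumw <- cumsum(widths)
  # cum covered bp at each break
  cum <- as.double(rbind(c(0, head(cumw, -1)), cumw))
  inside <- rep(c(TRUE, FALSE), length(gstart))
  list(breaks = breaks, cum = cum, inside = inside)
}

# Evaluate F(x) (covered bp in [0, x)) for a coverage_fun object, vectorized.
coverage_eval <- function(cf, x) {
  i <- findInterval(x, cf$breaks)
  ii <- pmax(i, 1L)
  (cf$cum[ii] + cf$inside[ii] * (x - cf$breaks[ii])) * (i > 0)
}

# Deterministic substream seed derived from a base seed and a stream name.
# Keeps results independent across named streams and below 2^31.
substream_seed <- function(seed, stream) {
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 31 + k) %% 1000003
  as.integer((as.double(seed) * 1000003 + h) %% 2147483647)
}

# Polynomial rolling hash of a string (mod 2^31 - 1), as 8 hex digits;
# used to fingerprint configs in output headers.
string_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(config) {
  string_hash(paste(deparse(config), collapse = "\n"))
}

`%||%` <- rlang::`%||%`
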