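# broom-style tidiers for the package's result objects.

#' @export
tidy.chromstrat_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.chromstrat_enrichment <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_enriched_q05 = sum(x$fold > 1 & x$q_bh < 0.05, na.rm = TRUE),
    n_depleted_q05 = sum(x$fold < 1 & x$q_bh < 0.05, na.rm = TRUE),
    n_iter = x$n_iter[1]
  )
}

#' @export
tidy.chromstrat_groups <- function(x, ...) {
  x$assignments
}

#' @export
glance.chromstrat_groups <- function(x, ...) {
  tibble(
    n_group1 = sum(x$assignments$group == "Group1"),
    n_group2 = sum(x$assignments$group == "Group2"),
    separation = x$separation
  )
}

#' @export
tidy.chromstrat_score_matrix <- function(x, ...) {
  m <- x$matrix
  tibble(
    region = rep(seq_len(nrow(m)), times = ncol(m)),
    bin = rep(seq_len(ncol(m)), each = nrow(m)),
    rel_pos = rep(x$bin_mid, each = nrow(m)),
    signal = as.vector(m)
  )
}

#' @export
tidy.chromstrat_cormat <- function(x, ...) {
  r <- x$r
  tibble(
    a = rep(rownames(r), times = ncol(r)),
    b = rep(colnames(r), each = nrow(r)),
    r = as.vector(r)
  )
}

#' @export
tidy.chromstrat_expression_link <- function(x, ...) {
  x$per_gene
}

#' @export
glance.chromstrat_expression_link <- function(x, ...) {
  tibble(n_group1 = x$n_group1, n_group2 = x$n_group2, n_ties = x$n_ties,
         statistic = x$statistic, p_one_tailed = x$p_one_tailed)
}

#' @export
tidy.chromstrat_partition <- function(x, ...) {
  x$fractions
}
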