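#' Venn comparison of two identification sets
#'
#' Summarizes the overlap between the proteins identified in two
#' conditions: set sizes, shared and condition-unique counts, the union
#' total, and each count as a percentage of the total. Percentages are
#' rounded half-up to one decimal, the convention of printed Venn reports.
#'
#' @param set_a,set_b Character vectors of accessions (duplicates ignored).
#' @param labels Two condition labels used in printing.
#' @return A `venn_summary` list with fields `n_a`, `n_b`, `shared`,
#'   `unique_a`, `unique_b`, `total`, `pct_shared`, `pct_unique_a`,
#'   `pct_unique_b`, and the accession vectors `shared_accessions`,
#'   `unique_a_accessions`, `unique_b_accessions`.
#' @examples
#' venn_compare(c("P1", "P2"), c("P2", "P3"))
#' @export
venn_compare <- function(set_a, set_b, labels = c("a", "b")) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  total <- length(set_a) + length(set_b) - length(shared)
  pct <- function(k) if (total == 0L) NA_real_ else
    round_half_up(100 * k / total, 1)
  structure(list(
    labels = labels,
    n_a = length(set_a), n_b = length(set_b),
    shared = length(shared),
    unique_a = length(set_a) - length(shared),
    unique_b = length(set_b) - length(shared),
    total = total,
    pct_shared = pct(length(shared)),
    pct_unique_a = pct(length(set_a) - length(shared)),
    pct_unique_b = pct(length(set_b) - length(shared)),
    shared_accessions = sort(shared),
    unique_a_accessions = sort(setdiff(set_a, set_b)),
    unique_b_accessions = sort(setdiff(set_b, set_a))
  ), class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("venn_summary: %d proteins in total\n", x$total))
  cat(sprintf("  %s: %d (%d unique, %.1f%%)\n", x$labels[1], x$n_a,
              x$unique_a, x$pct_unique_a))
  cat(sprintf("  %s: %d (%d unique, %.1f%%)\n", x$labels[2], x$n_b,
              x$unique_b, x$pct_unique_b))
  cat(sprintf("  shared: %d (%.1f%%)\n", x$shared, x$pct_shared))
  invisible(x)
}

#' @export
as.data.frame.venn_summary <- function(x, ...) {
  data.frame(n_a = x$n_a, n_b = x$n_b, shared = x$shared,
             unique_a = x$unique_a, unique_b = x$unique_b, total = x$total,
             pct_shared = x$pct_shared, pct_unique_a = x$pct_unique_a,
             pct_unique_b = x$pct_unique_b)
}
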