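#' Aggregate PSM rows into a protein-by-condition count matrix
#'
#' Each PSM row contributes one spectral count to exactly one protein
#' accession (no shared-peptide apportionment). Conditions may either name
#' sample labels directly (`c("normal", "stz")`) or, when several samples
#' were run per condition, map each condition to its sample labels
#' (`list(normal = c("n1", "n2"), stz = "s1")`), in which case counts are
#' pooled by summation.
#'
#' @param psm A PSM table (see [read_psm_table()]).
#' @param conditions Character vector of two condition labels, or a named
#'   list of length two mapping condition label -> sample labels.
#' @param lengths Optional named vector of protein lengths, attached for
#'   downstream NSAF computation.
#' @param allow_empty Allow a condition with zero PSM rows (default FALSE).
#' @return A `count_matrix`: list with `counts` (integer matrix, proteins x
#'   2 conditions, accessions as rownames), `conditions`, `totals` (column
#'   sums), and `lengths`.
#' @examples
#' psm <- data.frame(sample = c("normal", "normal", "stz"),
#'                   accession = c("P1", "P1", "P2"))
#' count_spectra(psm, c("normal", "stz"))
#' @export
count_spectra <- function(psm, conditions, lengths = NULL,
                          allow_empty = FALSE) {
  if (!all(c("sample", "accession") %in% names(psm)))
    stopf("psm must have 'sample' and 'accession' columns")
  if (is.list(conditions)) {
    labels <- names(conditions)
    if (is.null(labels) || length(conditions) != 2L)
      stopf("conditions must map exactly two condition labels to samples")
    map <- rep(labels, vapply(conditions, length, integer(1)))
    names(map) <- unlist(conditions)
  } else {
    if (length(conditions) != 2L)
      stopf("exactly two condition labels are required")
    labels <- conditions
    map <- stats::setNames(labels, labels)
  }
  if (anyDuplicated(labels)) stopf("condition labels must be distinct")

  cond <- map[psm$sample]
  unmapped <- is.na(cond)
  if (any(unmapped))
    warning(sprintf("ignoring %d PSM row(s) from unmapped sample(s): %s",
                    sum(unmapped),
                    paste(unique(psm$sample[unmapped]), collapse = ", ")),
            call. = FALSE)
  cond <- factor(cond[!unmapped], levels = labels)
  acc <- psm$accession[!unmapped]

  missing_cond <- labels[!labels %in% cond]
  if (length(missing_cond) && !allow_empty)
    stopf("condition '%s' has no PSM rows (set allow_empty = TRUE to permit)",
          missing_cond[1L])

  if (length(acc) == 0L) {
    counts <- matrix(0L, nrow = 0L, ncol = 2L,
                     dimnames = list(NULL, labels))
  } else {
    tab <- table(accession = acc, condition = cond)
    counts <- matrix(as.integer(tab), nrow = nrow(tab),
                     dimnames = list(rownames(tab), labels))
    counts <- counts[order(rownames(counts)), , drop = FALSE]
  }
  new_count_matrix(counts, labels, lengths)
}

new_count_matrix <- function(counts, conditions, lengths = NULL) {
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stopf("spectral counts must be nonnegative")
  if (anyDuplicated(rownames(counts)))
    stopf("every protein must appear exactly once")
  structure(list(counts = counts,
                 conditions = conditions,
                 totals = colSums(counts),
                 lengths = lengths),
            class = "count_matrix")
}

#' Build a count matrix directly from per-protein counts
#'
#' Convenience constructor for matrices not derived from PSM rows (e.g.
#' counts transcribed from a published table).
#'
#' @param counts Integer matrix (proteins x 2), accessions as rownames.
#' @param conditions Two condition labels; defaults to the column names.
#' @param lengths Optional named length vector.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts, conditions = colnames(counts),
                         lengths = NULL) {
  if (ncol(counts) != 2L) stopf("a count matrix has exactly two conditions")
  if (is.null(rownames(counts))) stopf("counts must have accession rownames")
  if (is.null(conditions)) stopf("condition labels are required")
  colnames(counts) <- conditions
  new_count_matrix(as.matrix(counts), conditions, lengths)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d proteins x 2 conditions (%s)\n",
              nrow(x$counts), paste(x$conditions, collapse = ", ")))
  cat(sprintf("total spectra: %s\n",
              paste(sprintf("%s = %d", x$conditions, x$totals),
                    collapse = ", ")))
  if (!is.null(x$lengths)) cat("protein lengths attached\n")
  invisible(x)
}

#' Identified-protein sets per condition
#'
#' A protein counts as "identified" in a condition when its spectral count
#' reaches `min_count` (default 1, i.e. at least one matched spectrum).
#'
#' @param cm A `count_matrix`.
#' @param min_count Minimum spectral count for identification (>= 1).
#' @return Named list of two character vectors of accessions.
#' @export
identified_sets <- function(cm, min_count = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.numeric(min_count) || min_count < 1L)
    stopf("min_count must be >= 1")
  out <- lapply(cm$conditions, function(cond) {
    rownames(cm$counts)[cm$counts[, cond] >= min_count]
  })
  names(out) <- cm$conditions
  out
}

#' Attach protein lengths to a count matrix
#'
#' @param cm A `count_matrix`.
#' @param lengths Named vector of protein lengths (residues).
#' @return The count matrix with lengths attached.
#' @export
set_lengths <- function(cm, lengths) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(names(lengths))) stopf("lengths must be named by accession")
  cm$lengths <- lengths
  cm
}

#' @export
as.data.frame.count_matrix <- function(x, ...) {
  df <- data.frame(accession = rownames(x$counts),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df)[2:3] <- paste0("count_", x$conditions)
  if (!is.null(x$lengths))
    df$length <- unname(x$lengths[df$accession])
  df
}
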