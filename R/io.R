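#' Read a peptide-spectrum-match (PSM) report
#'
#' Parses a delimited identification report (one row per PSM, or per
#' protein-level count when counts are later supplied by row multiplicity)
#' into the package's PSM table. Search engines export under many column
#' names, so a column mapping adapts any tab- or comma-delimited report.
#'
#' Rows with an empty sample or accession field are dropped with a warning
#' listing their file line numbers; parsing is otherwise lossless and
#' preserves row order.
#'
#' @param path Path to the report file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param columns Named list mapping the internal field names `sample`,
#'   `accession`, and optionally `peptide`, `spectrum`, `score`, to the
#'   column names used in the file header.
#' @param conditions Optional character vector of expected sample labels; if
#'   supplied, rows carrying any other label raise an error.
#' @return A `data.frame` of class `psm_table` with columns `sample`,
#'   `accession`, and any of `peptide`, `spectrum`, `score` that were mapped.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\taccession", "normal\tP1", "stz\tP1"), tf)
#' read_psm_table(tf)
#' @export
read_psm_table <- function(path, format = c("tsv", "csv"),
                           columns = list(sample = "sample",
                                          accession = "accession"),
                           conditions = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("PSM file not found: %s", path)
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  for (field in c("sample", "accession")) {
    if (is.null(columns[[field]]))
      stopf("column mapping must name a '%s' column", field)
  }
  for (field in names(columns)) {
    col <- columns[[field]]
    if (!is.null(col) && !col %in% names(raw))
      stopf("required column '%s' (mapped to field '%s') is missing from %s",
            col, field, path)
  }
  fields <- c("sample", "accession", "peptide", "spectrum", "score")
  mapped <- fields[vapply(fields, function(f) !is.null(columns[[f]]),
                          logical(1))]
  out <- raw[unlist(columns[mapped], use.names = FALSE)]
  names(out) <- mapped
  out$sample <- as.character(out$sample)
  out$accession <- as.character(out$accession)

  bad <- which(is.na(out$sample) | !nzchar(trimws(out$sample)) |
                 is.na(out$accession) | !nzchar(trimws(out$accession)))
  if (length(bad)) {
    # +1 for the header: report the actual line number in the file
    warning(sprintf("dropping %d malformed PSM row(s) at file line(s): %s",
                    length(bad), paste(bad + 1L, collapse = ", ")),
            call. = FALSE)
    out <- out[-bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stopf("no valid PSM rows in %s", path)
  if (!is.null(conditions)) {
    unknown <- setdiff(unique(out$sample), conditions)
    if (length(unknown))
      stopf("sample label(s) not among declared conditions: %s",
            paste(unknown, collapse = ", "))
  }
  rownames(out) <- NULL
  class(out) <- c("psm_table", "data.frame")
  out
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()] for the default column names; useful for
#' persisting simulated experiments.
#'
#' @param psm A PSM table (`data.frame` with `sample` and `accession`).
#' @param path Output path (tab-delimited).
#' @return The path, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  write_tsv(as.data.frame(psm), path)
}

#' Protein lengths from a FASTA file
#'
#' Reads protein sequences and returns residue counts keyed by accession,
#' the `L` term of the NSAF length normalization. The accession is taken
#' from each header by a regular expression whose first capture group is
#' the accession (default: the first whitespace-delimited token).
#'
#' @param path Path to a protein FASTA file.
#' @param accession_pattern Regex with one capture group extracting the
#'   accession from the FASTA header line (without the `>`).
#' @return Named integer vector of sequence lengths.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKTAYIAKQR"), tf)
#' read_lengths_fasta(tf)
#' @export
read_lengths_fasta <- function(path, accession_pattern = "^(\\S+)") {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stopf("no sequences in FASTA file %s", path)
  m <- regexec(accession_pattern, names(seqs))
  acc <- vapply(regmatches(names(seqs), m), function(g) {
    if (length(g) < 2L) NA_character_ else g[[2L]]
  }, character(1))
  if (anyNA(acc) || any(!nzchar(acc)))
    stopf("accession pattern failed on FASTA header(s): %s",
          paste(names(seqs)[is.na(acc) | !nzchar(acc)], collapse = ", "))
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    stopf("duplicate accession(s) in FASTA: %s", paste(dup, collapse = ", "))
  lengths <- Biostrings::width(seqs)
  names(lengths) <- acc
  lengths
}

#' Protein lengths from a two-column table
#'
#' Alternative to [read_lengths_fasta()] when sequences are unavailable:
#' a tab-delimited file with columns `accession` and `length`.
#'
#' @param path Path to the length table.
#' @return Named integer vector of lengths.
#' @export
read_lengths_table <- function(path) {
  if (!file.exists(path)) stopf("length table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "length")
  if (!all(need %in% names(tab)))
    stopf("length table must have columns 'accession' and 'length'")
  len <- as.integer(tab$length)
  if (anyNA(len) || any(len < 1L))
    stopf("protein lengths must be positive integers")
  dup <- unique(tab$accession[duplicated(tab$accession)])
  if (length(dup))
    stopf("duplicate accession(s) in length table: %s",
          paste(dup, collapse = ", "))
  names(len) <- as.character(tab$accession)
  len
}

#' Read a protein-to-category annotation table
#'
#' Two-column tab-delimited file (`accession`, `category`) assigning
#' proteins to annotation categories (e.g. GO cellular-component terms).
#' An accession may appear on several rows, one per category.
#'
#' @param path Path to the annotation TSV.
#' @return A `data.frame` with columns `accession` and `category`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "category") %in% names(ann)))
    stopf("annotation table must have columns 'accession' and 'category'")
  ann$accession <- as.character(ann$accession)
  ann$category <- as.character(ann$category)
  if (any(!nzchar(ann$category)))
    stopf("annotation categories must be non-empty strings")
  unique(ann[c("accession", "category")])
}
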