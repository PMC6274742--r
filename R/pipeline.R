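with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[%s] %s", stage, conditionMessage(e))
  })
}

#' Run the spectral-counting pipeline end to end
#'
#' Counts spectra, quantifies (Rsc, NSAF, classification), compares
#' identification sets, optionally tests category enrichment among the
#' differentially expressed proteins, and writes tab-delimited artifacts
#' plus a log that records every parameter needed to reproduce the run:
#'
#' * `counts.tsv` — protein-by-condition spectral counts and lengths;
#' * `quant.tsv` — per-protein Rsc, NSAF, class, sorted by decreasing Rsc
#'   (ties broken by accession);
#' * `venn.tsv` — identification-set overlap summary;
#' * `enrichment.tsv` — category over-representation (when annotations are
#'   given);
#' * `run.log` — package version, f, thresholds, min_count, conditions.
#'
#' Outputs are deterministic given identical inputs and configuration.
#'
#' @param psm A PSM table or a path readable by [read_psm_table()].
#' @param conditions Two condition labels (reference first) or a named
#'   list mapping labels to sample ids (see [count_spectra()]).
#' @param lengths Named length vector, or a path to a FASTA
#'   (`.fasta`/`.fa`) or two-column length table.
#' @param out_dir Output directory (created if absent).
#' @param config A [quant_config()].
#' @param annotations Optional annotation table or path for enrichment.
#' @param min_count Identification threshold for the Venn comparison.
#' @param allow_empty Permit a condition with zero PSM rows.
#' @return Invisibly, a list with the computed objects (`counts`, `quant`,
#'   `venn`, `enrichment`) and `files`, the paths written.
#' @export
run_pipeline <- function(psm, conditions, lengths = NULL, out_dir,
                         config = quant_config(), annotations = NULL,
                         min_count = 1L, allow_empty = FALSE) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  psm <- with_stage("io", {
    if (is.character(psm)) read_psm_table(psm) else psm
  })
  lengths <- with_stage("io", {
    if (is.character(lengths)) {
      if (grepl("\\.(fa|fasta|faa)$", lengths, ignore.case = TRUE))
        read_lengths_fasta(lengths)
      else read_lengths_table(lengths)
    } else lengths
  })
  annotations <- with_stage("io", {
    if (is.character(annotations)) read_annotations(annotations)
    else annotations
  })

  cm <- with_stage("counting",
                   count_spectra(psm, conditions, lengths = lengths,
                                 allow_empty = allow_empty))
  quant <- with_stage("quant", {
    if (is.null(cm$lengths))
      stopf("protein lengths are required for NSAF; supply 'lengths'")
    quantify(cm, config)
  })
  sets <- with_stage("setops", identified_sets(cm, min_count = min_count))
  venn <- with_stage("setops",
                     venn_compare(sets[[1L]], sets[[2L]],
                                  labels = cm$conditions))
  enr <- NULL
  if (!is.null(annotations)) {
    enr <- with_stage("enrichment", {
      de <- quant$accession[quant$de_class != "unchanged"]
      enrich(de, background = quant$accession, annotations = annotations)
    })
  }

  files <- c(counts = file.path(out_dir, "counts.tsv"),
             quant = file.path(out_dir, "quant.tsv"),
             venn = file.path(out_dir, "venn.tsv"),
             log = file.path(out_dir, "run.log"))
  with_stage("report", {
    write_tsv(as.data.frame(cm), files[["counts"]])
    write_tsv(as.data.frame(quant), files[["quant"]])
    write_tsv(as.data.frame(venn), files[["venn"]])
    if (!is.null(enr)) {
      files[["enrichment"]] <- file.path(out_dir, "enrichment.tsv")
      write_tsv(enr, files[["enrichment"]])
    }
    dc <- attr(quant, "de_counts")
    writeLines(c(
      sprintf("spcount version: %s",
              as.character(utils::packageVersion("spcount"))),
      sprintf("conditions: %s (reference), %s (treatment)",
              cm$conditions[1L], cm$conditions[2L]),
      sprintf("correction factor f: %g", config$f),
      sprintf("thresholds: up > %g, down < %g",
              config$up_threshold, config$down_threshold),
      sprintf("identification min_count: %d", as.integer(min_count)),
      sprintf("proteins quantified: %d", nrow(quant)),
      sprintf("differentially expressed: %d up, %d down, %d unchanged",
              dc[["up"]], dc[["down"]], dc[["unchanged"]])
    ), files[["log"]])
  })
  invisible(list(counts = cm, quant = quant, venn = venn,
                 enrichment = enr, files = files))
}
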