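#' Published extracellular-matrix protein log-ratios from a rat cornea study
#'
#' Fifteen proteins annotated "extracellular matrix" in a shotgun
#' spectral-counting comparison of normal versus streptozotocin-diabetic
#' rat cornea, with their published Rsc values (positive = higher in the
#' diabetic cornea; lumican, decorin, biglycan and prolargin among the
#' upregulated). Bundled as a worked example for the classification rule
#' and category counting.
#'
#' @return A `data.frame` with columns `accession`, `description`, `rsc`.
#' @examples
#' ecm <- cornea_ecm_proteins()
#' table(classify_rsc(ecm$rsc))
#' @export
cornea_ecm_proteins <- function() {
  utils::read.delim(system.file("extdata", "cornea_ecm.tsv",
                                package = "spcount", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Annotation table for the bundled cornea example
#'
#' Maps each accession of [cornea_ecm_proteins()] to the GO-style
#' cellular-component category "extracellular matrix".
#'
#' @return A `data.frame` with columns `accession`, `category`.
#' @export
cornea_ecm_annotations <- function() {
  read_annotations(system.file("extdata", "cornea_ecm_annotation.tsv",
                               package = "spcount", mustWork = TRUE))
}
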