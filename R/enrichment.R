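#' Category membership counts
#'
#' Counts, for each annotation category, how many of the given proteins are
#' annotated with it. Proteins without annotation contribute nothing.
#'
#' @param proteins Character vector of accessions.
#' @param annotations Annotation table (`accession`, `category`), e.g. from
#'   [read_annotations()].
#' @return Named integer vector of per-category counts (decreasing).
#' @export
category_counts <- function(proteins, annotations) {
  stopifnot(all(c("accession", "category") %in% names(annotations)))
  ann <- unique(annotations[annotations$accession %in% proteins,
                            c("accession", "category")])
  if (nrow(ann) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(ann$category)
  sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' Category over-representation among differentially expressed proteins
#'
#' For each annotation category, tests whether the differentially expressed
#' (DE) set contains more category members than expected by chance when
#' drawing from the background, using the one-sided hypergeometric upper
#' tail P(X >= k). With `ease = TRUE`, one DE member is discounted
#' (P(X >= k - 1)), a conservative variant of the score popularized by
#' web-based annotation tools. P-values are Benjamini-Hochberg adjusted
#' across the reported categories.
#'
#' @param de Character vector of DE accessions; must be a subset of
#'   `background`.
#' @param background Character vector of background accessions (typically
#'   all identified proteins).
#' @param annotations Annotation table (`accession`, `category`).
#' @param min_k Minimum number of DE proteins in a category for it to be
#'   reported (default 2).
#' @param ease Use the conservative k - 1 variant (default FALSE).
#' @return A `data.frame` with columns `category`, `k` (DE in category),
#'   `K` (background in category), `n` (DE size), `N` (background size),
#'   `p_value`, `adjusted_p`, ordered by increasing p-value.
#' @export
enrich <- function(de, background, annotations, min_k = 2L, ease = FALSE) {
  de <- unique(as.character(de))
  background <- unique(as.character(background))
  if (length(background) == 0L) stopf("background set is empty")
  extra <- setdiff(de, background)
  if (length(extra))
    stopf("DE proteins absent from background: %s",
          paste(extra, collapse = ", "))
  ann <- unique(annotations[annotations$accession %in% background,
                            c("accession", "category")])
  N <- length(background)
  n <- length(de)
  cats <- unique(ann$category)
  rows <- lapply(cats, function(cat) {
    members <- ann$accession[ann$category == cat]
    k <- sum(de %in% members)
    if (k < min_k) return(NULL)
    K <- length(members)
    k_eff <- if (ease) k - 1L else k
    p <- stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, k = k, K = K, n = n, N = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(category = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), adjusted_p = numeric(0)))
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
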