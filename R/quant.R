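#' Log2 spectral-count ratio with pseudo-count correction (Rsc)
#'
#' The fold change between two conditions is estimated from spectral counts
#' as
#' \deqn{R_{sc} = \log_2\frac{n_s + f}{n_n + f} +
#'       \log_2\frac{t_n - n_n + f}{t_s - n_s + f}}
#' where \eqn{n_n, n_s} are the protein's spectral counts in the reference
#' and treatment samples, \eqn{t_n, t_s} the total spectra over all proteins
#' in each sample, and \eqn{f} an additive correction factor (default 1.25)
#' that keeps the ratio defined when a protein has zero counts in one
#' condition. The second term corrects for unequal sampling depth. A
#' positive value indicates higher expression in the treatment sample; Rsc
#' of +1/-1 corresponds to a two-fold change up/down.
#'
#' @param n_s,n_n Spectral counts for the protein in treatment and
#'   reference samples (vectorized).
#' @param t_s,t_n Total spectral counts over all proteins in each sample.
#' @param f Positive pseudo-count correction factor (default 1.25).
#' @return Numeric vector of Rsc values (log2 units).
#' @examples
#' compute_rsc(n_s = 10, n_n = 5, t_s = 100, t_n = 100)  # ~0.925
#' @export
compute_rsc <- function(n_s, n_n, t_s, t_n, f = 1.25) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stopf("correction factor f must be a positive number")
  if (!is_count(n_s) || !is_count(n_n) || !is_count(t_s) || !is_count(t_n))
    stopf("spectral counts and totals must be finite and nonnegative")
  if (any(t_s < n_s) || any(t_n < n_n))
    stopf("totals must be at least as large as per-protein counts")
  # log2 via natural logs, one division
  (log(n_s + f) - log(n_n + f) + log(t_n - n_n + f) - log(t_s - n_s + f)) /
    log(2)
}

#' Quantitation settings
#'
#' Bundles the Rsc pseudo-count and classification thresholds. Defaults
#' follow the standard convention: f = 1.25 and a strict two-fold rule
#' (Rsc > 1 up, Rsc < -1 down).
#'
#' @param f Positive pseudo-count correction factor.
#' @param up_threshold,down_threshold Classification thresholds in log2
#'   units; `down_threshold` must be below `up_threshold`.
#' @return A `quant_config` list.
#' @export
quant_config <- function(f = 1.25, up_threshold = 1, down_threshold = -1) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stopf("f must be a positive number")
  if (!is.numeric(up_threshold) || !is.numeric(down_threshold) ||
      down_threshold >= up_threshold)
    stopf("down_threshold must be strictly below up_threshold")
  structure(list(f = f, up_threshold = up_threshold,
                 down_threshold = down_threshold),
            class = "quant_config")
}

#' Classify Rsc values as up, down, or unchanged
#'
#' Strict inequalities: a value exactly at a threshold is "unchanged",
#' matching the convention that differential expression requires Rsc > 1
#' or < -1 (i.e. strictly more than two-fold).
#'
#' @param rsc Numeric vector of Rsc values.
#' @param config A [quant_config()].
#' @return Character vector in `c("up", "down", "unchanged")`.
#' @export
classify_rsc <- function(rsc, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  ifelse(rsc > config$up_threshold, "up",
         ifelse(rsc < config$down_threshold, "down", "unchanged"))
}

#' Normalized spectral abundance factor (NSAF)
#'
#' For each protein, the spectral count divided by protein length, then
#' normalized by the sum of that quantity over all proteins in the matrix:
#' \deqn{NSAF_n = \frac{SpC_n / L_n}{\sum_i SpC_i / L_i}}
#' NSAF values are relative abundances summing to 1 within a condition; a
#' zero-count protein has NSAF 0 but still belongs to the shared protein
#' universe of the denominator.
#'
#' @param cm A `count_matrix` with lengths attached.
#' @param condition One of the matrix's condition labels.
#' @return Named numeric vector of NSAF values summing to 1.
#' @export
compute_nsaf <- function(cm, condition) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!condition %in% cm$conditions)
    stopf("unknown condition '%s'", condition)
  if (is.null(cm$lengths)) stopf("protein lengths are required for NSAF")
  acc <- rownames(cm$counts)
  len <- cm$lengths[acc]
  if (anyNA(len))
    stopf("missing protein length for accession(s): %s",
          paste(acc[is.na(len)], collapse = ", "))
  if (any(len < 1)) stopf("protein lengths must be >= 1")
  spc <- cm$counts[, condition]
  if (all(spc == 0L))
    stopf("all spectral counts are zero in condition '%s'", condition)
  saf <- spc / len
  stats::setNames(saf / sum(saf), acc)
}

#' Per-protein quantitation table
#'
#' Computes Rsc, per-condition NSAF, and the differential-expression class
#' for every protein in the matrix. The first condition of the matrix is
#' the reference and the second the treatment, so positive Rsc means
#' enriched in the second condition.
#'
#' @param cm A `count_matrix` with lengths attached.
#' @param config A [quant_config()].
#' @param sort Sort rows by decreasing Rsc, ties broken by accession
#'   (default TRUE).
#' @return A `data.frame` of class `quant_table` with columns `accession`,
#'   `count_<ref>`, `count_<trt>`, `rsc`, `nsaf_<ref>`, `nsaf_<trt>`,
#'   `de_class`; the attribute `de_counts` tallies the three classes.
#' @export
quantify <- function(cm, config = quant_config(), sort = TRUE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(config, "quant_config"))
  ref <- cm$conditions[1L]
  trt <- cm$conditions[2L]
  acc <- rownames(cm$counts)
  n_n <- cm$counts[, ref]
  n_s <- cm$counts[, trt]
  rsc <- compute_rsc(n_s = n_s, n_n = n_n,
                     t_s = cm$totals[[trt]], t_n = cm$totals[[ref]],
                     f = config$f)
  out <- data.frame(accession = acc,
                    count_ref = unname(n_n),
                    count_trt = unname(n_s),
                    rsc = unname(rsc),
                    nsaf_ref = unname(compute_nsaf(cm, ref)),
                    nsaf_trt = unname(compute_nsaf(cm, trt)),
                    de_class = unname(classify_rsc(rsc, config)),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[c(2, 3, 5, 6)] <- c(paste0("count_", c(ref, trt)),
                                 paste0("nsaf_", c(ref, trt)))
  if (sort)
    out <- out[order(-out$rsc, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "de_counts") <- c(up = sum(out$de_class == "up"),
                              down = sum(out$de_class == "down"),
                              unchanged = sum(out$de_class == "unchanged"))
  attr(out, "config") <- config
  class(out) <- c("quant_table", "data.frame")
  out
}

#' @export
print.quant_table <- function(x, ...) {
  dc <- attr(x, "de_counts")
  cat(sprintf("quant_table: %d proteins (%d up, %d down, %d unchanged)\n",
              nrow(x), dc[["up"]], dc[["down"]], dc[["unchanged"]]))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
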