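#' Configuration for the spectral-count simulator
#'
#' Describes a two-condition spectral-counting experiment: a protein
#' universe with log-uniform baseline relative abundances (spanning
#' `abundance_decades` orders of magnitude, mimicking the wide dynamic
#' range of tissue proteomes), a planted fraction of proteins whose
#' abundance is shifted by `fold_change` (direction chosen up or down with
#' equal probability), and a sequencing-style depth giving the expected
#' total spectra per condition. Defaults emulate a study identifying a few
#' hundred proteins from a few thousand spectra per condition.
#'
#' @param n_proteins Number of proteins in the universe.
#' @param depth Expected total spectral count per condition.
#' @param de_fraction Fraction of proteins with a planted abundance shift,
#'   in \[0, 1).
#' @param fold_change Planted fold change (> 1), applied multiplicatively
#'   up or down.
#' @param length_range Integer range of protein lengths (residues).
#' @param abundance_decades Orders of magnitude spanned by the log-uniform
#'   baseline abundances.
#' @param conditions Two condition labels (reference first).
#' @param seed Integer seed; every simulation is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 500L, depth = 5000L,
                             de_fraction = 0.1, fold_change = 4,
                             length_range = c(100L, 1000L),
                             abundance_decades = 3,
                             conditions = c("normal", "stz"),
                             seed = 1L) {
  if (!is.numeric(n_proteins) || n_proteins < 1L)
    stopf("n_proteins must be a positive integer")
  if (!is.numeric(depth) || depth < 1) stopf("depth must be >= 1")
  if (de_fraction < 0 || de_fraction >= 1)
    stopf("de_fraction must be in [0, 1)")
  if (fold_change <= 1) stopf("fold_change must exceed 1")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stopf("two distinct condition labels are required")
  structure(list(n_proteins = as.integer(n_proteins),
                 depth = depth, de_fraction = de_fraction,
                 fold_change = fold_change,
                 length_range = as.integer(length_range),
                 abundance_decades = abundance_decades,
                 conditions = conditions, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a two-condition spectral-counting experiment
#'
#' Protein counts per condition are drawn multinomially from the
#' condition's true relative-abundance vector, with the total itself
#' Poisson-distributed around `depth` — so within a condition the true
#' abundances sum exactly to 1 and sampling noise is pure count noise.
#' Planted proteins have their baseline weight multiplied (up) or divided
#' (down) by `fold_change` in the treatment condition before
#' renormalization. The PSM table is expanded one row per count with
#' synthetic spectrum identifiers.
#'
#' @param config A [synthetic_config()].
#' @param truth Optional truth table from a previous run (same
#'   `conditions`): reuses its abundance vectors and labels so that
#'   repeated draws under different seeds share one ground truth, as in
#'   calibration and power studies.
#' @return A list with `psm` (a `psm_table`), `lengths` (named integer
#'   vector), and `truth` (a `data.frame` with `accession`, one true
#'   abundance column per condition, and `de_label` in
#'   `c("up", "down", "null")`).
#' @examples
#' sim <- simulate_spectral_counts(synthetic_config(n_proteins = 20,
#'                                                  depth = 200, seed = 7))
#' head(sim$truth)
#' @export
simulate_spectral_counts <- function(config = synthetic_config(),
                                     truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  if (is.null(truth)) {
    n <- config$n_proteins
    acc <- sprintf("SYN%04d", seq_len(n))
    w <- 10^stats::runif(n, 0, config$abundance_decades)
    abund_ref <- w / sum(w)

    de_label <- rep("null", n)
    n_de <- round(config$de_fraction * n)
    w_trt <- w
    if (n_de > 0L) {
      idx <- sample.int(n, n_de)
      dir <- sample(c("up", "down"), n_de, replace = TRUE)
      de_label[idx] <- dir
      w_trt[idx] <- ifelse(dir == "up", w[idx] * config$fold_change,
                           w[idx] / config$fold_change)
    }
    abund_trt <- w_trt / sum(w_trt)
  } else {
    acc <- truth$accession
    n <- length(acc)
    abund_ref <- truth[[paste0("abundance_", config$conditions[1L])]]
    abund_trt <- truth[[paste0("abundance_", config$conditions[2L])]]
    de_label <- truth$de_label
    if (is.null(abund_ref) || is.null(abund_trt))
      stopf("truth table does not match conditions %s",
            paste(config$conditions, collapse = ", "))
  }
  lens <- stats::setNames(
    sample(seq(config$length_range[1L], config$length_range[2L]), n,
           replace = TRUE), acc)

  draw <- function(abund, cond) {
    total <- stats::rpois(1L, config$depth)
    counts <- as.integer(stats::rmultinom(1L, total, abund))
    k <- sum(counts)
    if (k == 0L) return(NULL)
    data.frame(sample = rep(cond, k),
               accession = rep(acc, counts),
               spectrum = sprintf("%s_scan%06d", cond, seq_len(k)),
               stringsAsFactors = FALSE)
  }
  psm <- rbind(draw(abund_ref, config$conditions[1L]),
               draw(abund_trt, config$conditions[2L]))
  rownames(psm) <- NULL
  class(psm) <- c("psm_table", "data.frame")

  truth <- data.frame(accession = acc, abund_ref, abund_trt,
                      de_label = de_label, stringsAsFactors = FALSE)
  names(truth)[2:3] <- paste0("abundance_", config$conditions)
  list(psm = psm, lengths = lens, truth = truth)
}

#' Score recovery of planted fold changes
#'
#' Compares a quantitation table against simulation ground truth:
#' * sensitivity — fraction of planted proteins classified differentially
#'   expressed with the correct sign;
#' * false-positive rate — fraction of null proteins classified
#'   differentially expressed (either sign);
#' * sign accuracy — among planted proteins classified DE, the fraction
#'   with the correct sign.
#'
#' @param quant A `quant_table` from [quantify()].
#' @param truth The `truth` component of [simulate_spectral_counts()].
#' @param proteins Optional accession subset to restrict scoring to (e.g.
#'   proteins above a minimum expected count).
#' @return Named list `sensitivity`, `false_positive_rate`,
#'   `sign_accuracy` (NA when the denominator is empty).
#' @export
evaluate_recovery <- function(quant, truth, proteins = NULL) {
  if (!all(quant$accession %in% truth$accession))
    stopf("quantitation and truth cover different protein universes")
  m <- merge(quant[c("accession", "de_class")],
             truth[c("accession", "de_label")], by = "accession")
  # proteins never observed in either condition carry no call: treat as
  # unchanged
  unseen <- truth$accession[!truth$accession %in% quant$accession]
  if (length(unseen)) {
    m <- rbind(m, data.frame(
      accession = unseen, de_class = "unchanged",
      de_label = truth$de_label[match(unseen, truth$accession)]))
  }
  if (!is.null(proteins)) m <- m[m$accession %in% proteins, , drop = FALSE]

  planted <- m$de_label != "null"
  called <- m$de_class != "unchanged"
  correct_sign <- m$de_class == m$de_label

  sens <- if (any(planted)) sum(planted & correct_sign) / sum(planted)
          else NA_real_
  fpr <- if (any(!planted)) sum(!planted & called) / sum(!planted)
         else NA_real_
  sign_acc <- if (any(planted & called))
    sum(planted & called & correct_sign) / sum(planted & called)
  else NA_real_
  list(sensitivity = sens, false_positive_rate = fpr,
       sign_accuracy = sign_acc)
}
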