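#' Corneal wound-healing percentage
#'
#' Fractional reduction of the wound area relative to the initial (time-0)
#' area, times 100:
#' \deqn{healing\% = \frac{area_0 - area_t}{area_0} \times 100}
#' Areas may be in any consistent unit (mm2, pixels): only the ratio
#' matters, so the result is invariant to rescaling all areas. The value is
#' 100 for complete closure, 0 for no change, and negative if the wound
#' grew.
#'
#' @param area_0 Initial wound area(s), strictly positive.
#' @param area_t Wound area(s) at the later time point, nonnegative.
#' @return Numeric vector of healing percentages.
#' @examples
#' healing_percent(8, 2)  # 75
#' @export
healing_percent <- function(area_0, area_t) {
  if (!is.numeric(area_0) || !is.numeric(area_t) ||
      any(!is.finite(area_0)) || any(!is.finite(area_t)))
    stopf("wound areas must be finite numbers")
  if (any(area_0 <= 0)) stopf("initial wound area must be positive")
  if (any(area_t < 0)) stopf("wound areas must be nonnegative")
  (area_0 - area_t) / area_0 * 100
}

#' Per-subject healing percentages from a long-format area table
#'
#' @param areas Long-format `data.frame` with columns `subject`, `group`,
#'   `time_h`, `area` (one row per measurement).
#' @param t Evaluation time in hours (default 25).
#' @param t0 Baseline time (default 0).
#' @return A `data.frame` with columns `subject`, `group`, `healing_pct`.
#' @export
wound_healing <- function(areas, t = 25, t0 = 0) {
  need <- c("subject", "group", "time_h", "area")
  if (!all(need %in% names(areas)))
    stopf("areas must have columns: %s", paste(need, collapse = ", "))
  subjects <- unique(areas[c("subject", "group")])
  res <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects$subject[i]
    sub <- areas[areas$subject == s, , drop = FALSE]
    a0 <- sub$area[sub$time_h == t0]
    at <- sub$area[sub$time_h == t]
    if (length(a0) != 1L)
      stopf("subject '%s' lacks a single time-%g measurement", s, t0)
    if (length(at) != 1L)
      stopf("subject '%s' lacks a single time-%g measurement", s, t)
    data.frame(subject = s, group = subjects$group[i],
               healing_pct = healing_percent(a0, at),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group summary of wound healing (mean and standard error)
#'
#' @param areas Long-format area table (see [wound_healing()]) or a result
#'   of [wound_healing()] (columns `subject`, `group`, `healing_pct`).
#' @param t Evaluation time in hours, used when `areas` is a raw table.
#' @return A `data.frame` with columns `group`, `n`, `mean_healing_pct`,
#'   `sem` (standard error of the mean, sd/sqrt(n)).
#' @export
summarize_healing <- function(areas, t = 25) {
  hp <- if ("healing_pct" %in% names(areas)) areas
        else wound_healing(areas, t = t)
  groups <- unique(hp$group)
  res <- lapply(groups, function(g) {
    v <- hp$healing_pct[hp$group == g]
    if (length(v) < 2L)
      stopf("group '%s' has fewer than 2 subjects; SEM undefined", g)
    data.frame(group = g, n = length(v), mean_healing_pct = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
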