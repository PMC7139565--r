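# Correlation of cumulative cascade enthalpies with experimental IC50.

#' Pearson product-moment correlation
#'
#' Validated wrapper around the standard product-moment correlation:
#' requires at least three finite pairs and nonzero variance in both
#' series.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("series lengths differ (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("series must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a series; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Fisher-Z confidence interval for a correlation coefficient
#'
#' `tanh(atanh(r) +/- z * / sqrt(n - 3))` with the two-sided normal
#' quantile `z* = qnorm((1 + confidence) / 2)`.
#'
#' @param r correlation coefficient, `|r| < 1`.
#' @param n number of pairs, at least 4.
#' @param confidence confidence level as a fraction (default 0.95).
#' @return named numeric vector `c(ci_low, ci_high)`.
#' @export
#' @examples
#' fisher_ci(0.9596, 6)   # upper bound 0.9957
fisher_ci <- function(r, n, confidence = 0.95) {
  if (!is.finite(r) || abs(r) >= 1) {
    stop("|r| must be < 1 for the Fisher transform", call. = FALSE)
  }
  if (n < 4L) stop("need n >= 4 for a Fisher-Z interval", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be a fraction in (0, 1)", call. = FALSE)
  }
  z <- atanh(r)
  half <- stats::qnorm((1 + confidence) / 2) / sqrt(n - 3)
  c(ci_low = tanh(z - half), ci_high = tanh(z + half))
}

#' Assemble activity records from cascade traces and IC50 data
#'
#' Joins cumulative cascade enthalpies with experimental half-maximal
#' inhibitory concentrations. IC50 values are input data from the radical-
#' scavenging assay; they are never estimated here. Cumulative ETE (and
#' hence `dh_cum`) uses the radical-coupled (net) step values.
#'
#' @param traces list of [run_cascade()] traces.
#' @param ic50 data frame with columns `compound_id` and `ic50` (micromolar,
#'   positive).
#' @return data frame with compound_id, ic50, pa_cum, ete_cum, dh_cum.
#' @export
activity_records <- function(traces, ic50) {
  if (inherits(traces, "cascade_trace")) traces <- list(traces)
  if (!all(c("compound_id", "ic50") %in% names(ic50))) {
    stop("ic50 needs columns compound_id and ic50", call. = FALSE)
  }
  if (any(!is.finite(ic50$ic50)) || any(ic50$ic50 <= 0)) {
    stop("IC50 values must be positive", call. = FALSE)
  }
  tab <- rank_compounds(traces)
  idx <- match(tab$compound_id, ic50$compound_id)
  if (any(is.na(idx))) {
    stop("no IC50 for compound(s): ",
         paste(tab$compound_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  data.frame(compound_id = tab$compound_id, ic50 = ic50$ic50[idx],
             pa_cum = tab$pa_cum, ete_cum = tab$ete_cum_net,
             dh_cum = tab$dh_cum_net, stringsAsFactors = FALSE)
}

#' Differences against a reference compound
#'
#' Subtracts the reference compound's row from every record (IC50 and all
#' enthalpy columns); the reference maps to all zeros. Applying the
#' operation twice is idempotent.
#'
#' @param records data frame as from [activity_records()].
#' @param reference_id compound id of the reference.
#' @return data frame of the same shape with differenced numeric columns.
#' @export
delta_series <- function(records, reference_id) {
  i <- match(reference_id, records$compound_id)
  if (is.na(i)) {
    stop("reference compound '", reference_id, "' not in records",
         call. = FALSE)
  }
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(col) col - col[[i]])
  records
}

#' Correlate cumulative enthalpies with IC50
#'
#' Pearson r of IC50 against each cumulative quantity (`dh_cum`, `pa_cum`,
#' `ete_cum`), each with its Fisher-Z confidence interval.
#'
#' @param records data frame as from [activity_records()].
#' @param confidence confidence level (default 0.95).
#' @return data frame with columns metric, r, n, ci_low, ci_high,
#'   confidence.
#' @export
correlate_activity <- function(records, confidence = 0.95) {
  metrics <- c("dh_cum", "pa_cum", "ete_cum")
  rows <- lapply(metrics, function(mcol) {
    r <- pearson_r(records[[mcol]], records$ic50)
    n <- nrow(records)
    ci <- fisher_ci(r, n, confidence)
    data.frame(metric = mcol, r = r, n = n,
               ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
               confidence = confidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
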