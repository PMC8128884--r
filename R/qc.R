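# Proliferation metrics (population doublings, doubling time),
# threshold-based screening of substandard cultures, and the
# motion-vs-proliferation correlation statistic.

#' Culture cell-count record
#'
#' @param n0 Inoculated cell count (> 0).
#' @param n Harvested cell count (> 0).
#' @param days_in_culture Days in culture between inoculation and
#'   harvest (> 0).
#' @return Object of class `culture_count`.
#' @export
culture_count <- function(n0, n, days_in_culture) {
  if (!is.numeric(n0) || n0 <= 0) stop("`n0` must be > 0", call. = FALSE)
  if (!is.numeric(n) || n <= 0) stop("`n` must be > 0", call. = FALSE)
  if (!is.numeric(days_in_culture) || days_in_culture <= 0) {
    stop("`days_in_culture` must be > 0", call. = FALSE)
  }
  structure(list(n0 = n0, n = n, days_in_culture = days_in_culture),
            class = "culture_count")
}

#' Population doublings
#'
#' `PD = log2(N / N0)`: the number of times the population doubled
#' between inoculation (`N0`) and harvest (`N`).  Negative when cells
#' were lost.  Additive over consecutive culture intervals.
#'
#' @param counts A [culture_count()], or the harvested count `N` when
#'   `n0` is also given.
#' @param n0 Inoculated count (only when `counts` is a plain number).
#' @return PD (dimensionless).
#' @examples
#' population_doublings(culture_count(1.25e5, 5e5, 4))  # 2
#' @export
population_doublings <- function(counts, n0 = NULL) {
  if (inherits(counts, "culture_count")) {
    return(log2(counts$n / counts$n0))
  }
  if (is.null(n0)) stop("supply a culture_count or both `counts` and `n0`",
                        call. = FALSE)
  if (any(counts <= 0) || any(n0 <= 0)) {
    stop("cell counts must be positive", call. = FALSE)
  }
  log2(counts / n0)
}

#' Population doubling time
#'
#' `PDT = I / PD`, days per doubling over `I` days in culture.  A
#' non-positive PD means the culture did not grow; the PDT is then
#' undefined and returned as `NA` with a warning.
#'
#' @param pd Population doublings (from [population_doublings()]).
#' @param days_in_culture Days in culture, `I`.
#' @return PDT in days, or `NA` when `pd <= 0`.
#' @export
doubling_time <- function(pd, days_in_culture) {
  if (any(days_in_culture <= 0)) stop("`days_in_culture` must be > 0",
                                      call. = FALSE)
  out <- days_in_culture / pd
  bad <- pd <= 0
  if (any(bad)) {
    warning("non-positive PD: culture did not grow, PDT undefined")
    out[bad] <- NA_real_
  }
  out
}

#' Screen a culture by its motion index
#'
#' A culture is SUBSTANDARD when its MMS is strictly below the
#' threshold.  The default threshold of 40 um/h is the lowest MMS
#' observed among healthy standard-protocol keratinocyte cultures in the
#' system the method was developed on; it is culture-system specific and
#' therefore configurable.
#'
#' @param mms Mean motion speed in um/h (>= 0).
#' @param threshold Screening threshold in um/h (>= 0).
#' @param pdt Optional PDT (days) carried along in the result.
#' @param protocol_label Optional protocol description.
#' @return Object of class `qc_result` with fields `mms`, `threshold`,
#'   `verdict` ("ACCEPTABLE"/"SUBSTANDARD"), `pdt`, `protocol_label`.
#' @examples
#' classify_culture(39.9)$verdict  # "SUBSTANDARD"
#' classify_culture(40.0)$verdict  # "ACCEPTABLE"
#' @export
classify_culture <- function(mms, threshold = 40, pdt = NULL,
                             protocol_label = "") {
  if (!is.numeric(threshold) || threshold < 0) {
    stop("`threshold` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(mms) || any(mms < 0)) {
    stop("`mms` must be non-negative", call. = FALSE)
  }
  structure(
    list(mms = mms, threshold = threshold,
         verdict = ifelse(mms < threshold, "SUBSTANDARD", "ACCEPTABLE"),
         pdt = pdt, protocol_label = protocol_label),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: MMS %.2f um/h vs threshold %.2f um/h -> %s\n",
              x$mms[1], x$threshold, x$verdict[1]))
  invisible(x)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Rank-based correlation (average ranks for ties), with a two-sided p
#' value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` and a confidence interval
#' from the Fisher z transform of rho with standard error
#' `1.03 / sqrt(n - 3)` (the slightly inflated variance conventional for
#' rank correlations, as printed by common biostatistics software).
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`, no missing values.
#' @param conf_level Confidence level of the interval.
#' @return List with `rho`, `p_value`, `ci_lower`, `ci_upper`, `n`,
#'   `conf_level`.
#' @examples
#' spearman_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho  # 0.7
#' @export
spearman_correlation <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ",
                                   call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  if (n > 3 && abs(rho) < 1) {
    z <- atanh(rho)
    se <- 1.03 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else {
    ci <- c(rho, rho)
  }
  list(rho = rho, p_value = p, ci_lower = ci[1], ci_upper = ci[2],
       n = n, conf_level = conf_level)
}

#' Cohort scatter report of MMS versus PDT
#'
#' Builds the tidy table behind the motion-vs-proliferation scatterplot:
#' one row per sample with its MMS, PDT, protocol group and threshold
#' verdict.  Empty protocol labels are grouped under "unlabelled".
#'
#' @param samples `data.frame` (or list coercible to one) with columns
#'   `mms`, `pdt` and optionally `protocol` and `sample`.
#' @param threshold Screening threshold in um/h.
#' @return `data.frame` of class `scatter_report` with columns `sample`,
#'   `mms`, `pdt`, `protocol`, `verdict`; the threshold is kept in
#'   attribute `"threshold"`.
#' @export
scatter_report <- function(samples, threshold = 40) {
  samples <- as.data.frame(samples)
  if (nrow(samples) < 1) stop("need at least one sample", call. = FALSE)
  if (!all(c("mms", "pdt") %in% names(samples))) {
    stop("`samples` needs columns `mms` and `pdt`", call. = FALSE)
  }
  protocol <- if ("protocol" %in% names(samples)) {
    as.character(samples$protocol)
  } else rep("", nrow(samples))
  protocol[is.na(protocol) | !nzchar(protocol)] <- "unlabelled"
  id <- if ("sample" %in% names(samples)) samples$sample else
    seq_len(nrow(samples))
  out <- data.frame(
    sample = id, mms = samples$mms, pdt = samples$pdt, protocol = protocol,
    verdict = ifelse(samples$mms < threshold, "SUBSTANDARD", "ACCEPTABLE"),
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("scatter_report", class(out))
  out
}

#' @export
plot.scatter_report <- function(x, ...) {
  groups <- factor(x$protocol)
  graphics::plot(x$mms, x$pdt, col = as.integer(groups), pch = 19,
                 xlab = "MMS (um/h)", ylab = "PDT (days)", ...)
  graphics::abline(v = attr(x, "threshold"), lty = 2, col = "grey40")
  graphics::legend("topright", legend = levels(groups), pch = 19,
                   col = seq_along(levels(groups)), bty = "n")
  invisible(x)
}
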