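# Robust per-element summary battery and the log-median transform used as
# clustering input.

#' Summarize one element's concentrations
#'
#' Computes the nine-statistic battery used in frond-survey reporting:
#' min, max, mean, SD (n-1 denominator), relative SD in percent
#' (100 * sd / mean), first and third quartiles, median, and the
#' *unscaled* MAD (median of absolute deviations from the median, no
#' 1.4826 consistency factor — its natural scale relative to the
#' quartiles in such tables). RSD is `NA` when the mean is zero.
#'
#' @param values Numeric vector of concentrations (>= 2 finite values).
#' @param quartile_type Quantile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation). Other software uses other
#'   conventions, so this is configurable.
#' @return A one-row tibble: `n`, `min`, `max`, `mean`, `sd`, `rsd_pct`,
#'   `q1`, `median`, `q3`, `mad`.
#' @export
#' @examples
#' summarize_element(c(1, 2, 3))
summarize_element <- function(values, quartile_type = 7L) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("summarize_element() needs at least 2 finite values")
  }
  m <- mean(values)
  s <- sd(values)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = quartile_type))
  tibble::tibble(
    n = length(values),
    min = min(values),
    max = max(values),
    mean = m,
    sd = s,
    rsd_pct = if (m > 0) 100 * s / m else NA_real_,
    q1 = q[1],
    median = q[2],
    q3 = q[3],
    mad = median(abs(values - q[2]))
  )
}

#' Summarize every element of a concentration table
#'
#' Applies [summarize_element()] per element (after replicate aggregation
#' if a replicate column is still present) and returns rows in the input's
#' element order.
#'
#' @param x Long concentration tibble (one compartment).
#' @inheritParams summarize_element
#' @param rule Replicate-aggregation rule if replicates are present.
#' @return A tibble with `element` plus the summary columns.
#' @export
summarize_elements <- function(x, quartile_type = 7L, rule = "median") {
  if (!all(is.na(x$replicate))) x <- aggregate_replicates(x, rule)
  dplyr::reframe(
    dplyr::group_by(x, .data$element),
    summarize_element(.data$value_mg_kg, quartile_type)
  )
}

#' Robust coefficient of variation
#'
#' `100 * mad / median`, with the unscaled MAD — the robust analogue of
#' the RSD, appropriate when a distribution is tight but non-normal (for
#' example structural carbon, which varies by ~1% across sites). Returns
#' `NA` with a warning when the median is not positive.
#'
#' @param values Numeric vector.
#' @return Percent (scalar).
#' @export
#' @examples
#' robust_cv(c(1, 2, 3)) # 50
robust_cv <- function(values) {
  values <- values[is.finite(values)]
  med <- median(values)
  if (!isTRUE(med > 0)) {
    warn("robust_cv(): median <= 0, returning NA")
    return(NA_real_)
  }
  100 * median(abs(values - med)) / med
}

#' Log10-median matrix for clustering
#'
#' Builds the matrix fed into correlation-distance clustering: per
#' (site, element) medians over replicates, log10-transformed. The default
#' reading of "log-transformed medians" is log10 of the median; setting
#' `median_of_logs = TRUE` gives the alternative (median of log10 values)
#' — identical when replicates are already aggregated.
#'
#' Concentrations must be strictly positive: detection-limit substitution
#' (never zero) is the upstream censoring policy's job, and a zero or
#' negative value reaching this point is an error.
#'
#' @param x Long concentration tibble (one compartment).
#' @param mode `"by_element"` (rows = elements, the layout for clustering
#'   elements) or `"by_site"` (rows = sites).
#' @param median_of_logs See above.
#' @return A numeric matrix with informative dimnames.
#' @export
log10_medians <- function(x, mode = c("by_element", "by_site"),
                          median_of_logs = FALSE) {
  mode <- match.arg(mode)
  if (any(!is.na(x$value_mg_kg) & x$value_mg_kg <= 0)) {
    abort("log10_medians(): nonpositive concentration; censor upstream")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(x, .data$site_id, .data$element),
    value = if (median_of_logs) {
      median(log10(.data$value_mg_kg), na.rm = TRUE)
    } else {
      log10(median(.data$value_mg_kg, na.rm = TRUE))
    },
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(agg,
    names_from = "element", values_from = "value"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide$site_id)
  if (mode == "by_element") t(m) else m
}
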