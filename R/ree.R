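# Shale normalization of REE concentrations and cerium anomalies by
# geometric extrapolation.

#' Shale-normalize REE concentrations
#'
#' Divides measured concentrations elementwise by a named shale reference
#' composition (see [ree_reference()]). Every requested element must be
#' present in the reference — a missing one (e.g. Pm) is an error naming
#' it — and all concentrations must be positive.
#'
#' @param conc Named numeric vector (names = element symbols), or a tibble
#'   with columns `element` and a single value column.
#' @param ref A reference tibble from [ree_reference()].
#' @return Named numeric vector of normalized values, with attribute
#'   `"reference"`.
#' @export
#' @examples
#' ree_normalize(c(Ce = 19.1, Pr = 2.46, Nd = 8.22), ree_reference())
ree_normalize <- function(conc, ref = ree_reference()) {
  if (is.data.frame(conc)) {
    value_col <- setdiff(names(conc), "element")[1]
    conc <- setNames(conc[[value_col]], conc$element)
  }
  if (is.null(names(conc)) || any(names(conc) == "")) {
    abort("ree_normalize(): concentrations must be named by element")
  }
  missing <- setdiff(names(conc), ref$element)
  if (length(missing) > 0) {
    abort(paste0(
      "Element(s) absent from reference '",
      attr(ref, "reference") %||% "?", "': ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(conc <= 0, na.rm = TRUE)) {
    abort("ree_normalize(): concentrations must be positive")
  }
  denom <- setNames(ref$value_mg_kg, ref$element)[names(conc)]
  out <- conc / denom
  attr(out, "reference") <- attr(ref, "reference")
  out
}

#' Cerium anomaly by geometric extrapolation
#'
#' The theoretical, anomaly-free normalized cerium value is extrapolated
#' geometrically from its lighter neighbours: Ce* = Pr_N^2 / Nd_N, so
#'
#' \deqn{Ce/Ce^{*} = Ce_N \cdot Nd_N / Pr_N^2.}
#'
#' The ratio is < 1 for a negative anomaly (Ce depleted relative to its
#' neighbours, typical when plants take up REE from oxidizing solutions in
#' which Ce(III) has been removed as insoluble Ce(IV)) and > 1 for a
#' positive anomaly. Invariant to a common multiplicative factor on the
#' raw REE vector and to rescaling the reference; homogeneous of degree 1
#' in Ce_N alone.
#'
#' @param ce_n,pr_n,nd_n Shale-normalized Ce, Pr, Nd values (> 0).
#' @return Numeric ratio(s) Ce/Ce*.
#' @export
#' @examples
#' ce_anomaly(1, 1, 1) # flat pattern, no anomaly
ce_anomaly <- function(ce_n, pr_n, nd_n) {
  if (any(c(ce_n, pr_n, nd_n) <= 0, na.rm = TRUE)) {
    abort("ce_anomaly(): normalized values must be positive")
  }
  ce_n * nd_n / pr_n^2
}

#' Call an anomaly from a Ce/Ce* ratio
#'
#' "Significantly different from 1" is operationalized as a symmetric
#' band: ratios below `1 - band` are negative anomalies, above `1 + band`
#' positive, anything else `"none"`. The default band of 0.10 is
#' deliberately wider than typical analytical uncertainty on the ratio;
#' it is a configuration field, not a constant.
#'
#' @param ce_ratio Ce/Ce* ratio(s) (> 0).
#' @param band Nonnegative half-width of the "no anomaly" band.
#' @return Factor with levels `negative`, `none`, `positive`.
#' @export
#' @examples
#' call_anomaly(c(0.84, 1.0, 1.38))
call_anomaly <- function(ce_ratio, band = 0.10) {
  stopifnot(band >= 0)
  if (any(ce_ratio <= 0, na.rm = TRUE)) {
    abort("call_anomaly(): ratio must be positive")
  }
  factor(
    dplyr::case_when(
      ce_ratio < 1 - band ~ "negative",
      ce_ratio > 1 + band ~ "positive",
      TRUE ~ "none"
    ),
    levels = c("negative", "none", "positive")
  )
}

#' Per-site REE patterns and cerium anomalies
#'
#' Normalizes each site's REE concentrations (La, Ce, Pr, Nd and Y where
#' present; Ce, Pr, Nd required) against a named shale reference and
#' computes Ce*, Ce/Ce* and the anomaly call.
#'
#' @param frond Aggregated frond concentration tibble.
#' @param reference Reference name (see [list_ree_references()]).
#' @param band Anomaly band for [call_anomaly()].
#' @return Tibble with one row per site: normalized values (`la_n`,
#'   `ce_n`, `pr_n`, `nd_n`, `y_n` as available), `ce_star`, `ce_ratio`,
#'   `anomaly`, `reference`.
#' @export
ce_anomaly_table <- function(frond, reference = "PAAS-P2012", band = 0.10) {
  ref <- ree_reference(reference)
  if (!all(is.na(frond$replicate))) frond <- aggregate_replicates(frond)
  ree <- dplyr::filter(frond, .data$element %in% ref$element)
  missing <- setdiff(c("Ce", "Pr", "Nd"), unique(ree$element))
  if (length(missing) > 0) {
    abort(paste0(
      "ce_anomaly_table(): missing element(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  denom <- setNames(ref$value_mg_kg, ref$element)
  norm <- dplyr::mutate(ree,
    normalized = .data$value_mg_kg / denom[.data$element],
    element = paste0(tolower(.data$element), "_n")
  )
  wide <- tidyr::pivot_wider(norm,
    id_cols = "site_id", names_from = "element", values_from = "normalized"
  )
  dplyr::mutate(wide,
    ce_star = .data$pr_n^2 / .data$nd_n,
    ce_ratio = ce_anomaly(.data$ce_n, .data$pr_n, .data$nd_n),
    anomaly = call_anomaly(.data$ce_ratio, band),
    reference = reference
  )
}
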