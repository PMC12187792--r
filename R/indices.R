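# Bioconcentration factors, Al-normalized enrichment factors, the
# six-class enrichment scale, median aggregation and nutrient
# stoichiometry.

#' Bioconcentration factor
#'
#' BcF = c_frond / c_substrate for one element measured in the same units
#' in plant tissue and a substrate horizon. Unit-free and invariant under
#' a common rescaling of both concentrations. A zero substrate
#' concentration yields `NA` with a warning (never infinity).
#'
#' @param c_frond Frond concentration(s), >= 0.
#' @param c_substrate Substrate concentration(s), >= 0.
#' @return Numeric ratio(s).
#' @export
#' @examples
#' bcf(10, 100) # 0.1
bcf <- function(c_frond, c_substrate) {
  if (any(c_frond < 0, na.rm = TRUE) || any(c_substrate < 0, na.rm = TRUE)) {
    abort("bcf(): concentrations must be nonnegative")
  }
  zero <- !is.na(c_substrate) & c_substrate == 0
  if (any(zero)) {
    warn("bcf(): zero substrate concentration, returning NA")
  }
  ifelse(zero, NA_real_, c_frond / c_substrate)
}

#' Aluminium-normalized enrichment factor
#'
#' EF = (E/Al)_frond / (E/Al)_substrate, with Al as the conservative
#' lithogenic normalizer: it discounts the element pool attributable to
#' mineral dust or soil particles. EF of Al itself is identically 1, and
#' EF is invariant under unit changes applied to all four concentrations.
#' A zero Al or substrate concentration yields `NA` with a warning.
#'
#' @param e_frond,al_frond Element and Al concentration in the frond.
#' @param e_substrate,al_substrate Element and Al concentration in the
#'   substrate horizon.
#' @return Numeric ratio(s).
#' @export
#' @examples
#' ef(2, 1, 1, 1) # 2
ef <- function(e_frond, al_frond, e_substrate, al_substrate) {
  args <- list(e_frond, al_frond, e_substrate, al_substrate)
  if (any(vapply(args, function(a) any(a < 0, na.rm = TRUE), logical(1)))) {
    abort("ef(): concentrations must be nonnegative")
  }
  zero <- (!is.na(al_frond) & al_frond == 0) |
    (!is.na(al_substrate) & al_substrate == 0) |
    (!is.na(e_substrate) & e_substrate == 0)
  if (any(zero)) {
    warn("ef(): zero Al or substrate concentration, returning NA")
  }
  ifelse(zero, NA_real_,
    (e_frond / al_frond) / (e_substrate / al_substrate)
  )
}

.ef_labels <- c(
  "not_enriched", "slight", "moderate", "severe", "highly_severe", "extreme"
)
.ef_breaks <- c(0, 1.5, 2, 5, 20, 40, Inf)

#' The six-class enrichment scale
#'
#' Classes and their half-open intervals `[a, b)`: not_enriched [0, 1.5),
#' slight [1.5, 2), moderate [2, 5), severe [5, 20), highly_severe
#' [20, 40), extreme [40, Inf). Published interval notation shares
#' endpoints between adjacent classes; assigning each shared endpoint to
#' the upper class makes the scale a true partition of `[0, Inf)` (the
#' ">= 40" top class anchors that convention).
#'
#' @return A tibble with `label`, `lower`, `upper` (upper exclusive).
#' @export
ef_classes <- function() {
  tibble::tibble(
    label = .ef_labels,
    lower = .ef_breaks[-length(.ef_breaks)],
    upper = .ef_breaks[-1]
  )
}

#' Classify an enrichment factor
#'
#' Maps nonnegative EF values onto the six-class scale (see
#' [ef_classes()]). Monotone: a larger EF never gets a lower class.
#'
#' @param value Numeric EF value(s), >= 0 (NA passes through).
#' @return Ordered factor with levels from `not_enriched` to `extreme`.
#' @export
#' @examples
#' classify_ef(c(1, 3, 40))
classify_ef <- function(value) {
  if (any(value < 0, na.rm = TRUE)) {
    abort("classify_ef(): negative enrichment factor")
  }
  cut(value,
    breaks = .ef_breaks, labels = .ef_labels,
    right = FALSE, include.lowest = TRUE, ordered_result = TRUE
  )
}

#' Compute per-site accumulation indices
#'
#' Builds the long table of BcF or EF values for every
#' (site, element, horizon) from a replicate-aggregated frond table and
#' one or more substrate tables. For EF the element Al must be present in
#' frond and substrate. EF rows carry their enrichment class; BcF rows
#' have `ef_class = NA` (the class scale is defined for EF only).
#'
#' @param frond Aggregated frond concentration tibble.
#' @param substrates Named list of aggregated substrate tibbles; names
#'   must be among `"humus"`, `"topsoil"`, `"subsoil"`.
#' @param kind `"BcF"`, `"EF"`, or both (default).
#' @return Tibble with `site_id`, `element`, `horizon`, `index_kind`,
#'   `value`, `ef_class`.
#' @export
compute_indices <- function(frond, substrates, kind = c("BcF", "EF")) {
  kind <- match.arg(kind, several.ok = TRUE)
  stopifnot(all(names(substrates) %in% .horizons))
  if (!all(is.na(frond$replicate))) frond <- aggregate_replicates(frond)
  f <- dplyr::select(frond, "site_id", "element", f_value = "value_mg_kg")
  out <- purrr::map(names(substrates), function(h) {
    s <- substrates[[h]]
    if (!all(is.na(s$replicate))) s <- aggregate_replicates(s)
    s <- dplyr::select(s, "site_id", "element", s_value = "value_mg_kg")
    joined <- dplyr::inner_join(f, s, by = c("site_id", "element"))
    al <- dplyr::filter(joined, .data$element == "Al")
    al <- dplyr::select(al, "site_id",
      al_f = "f_value", al_s = "s_value"
    )
    res <- list()
    if ("BcF" %in% kind) {
      res$bcf <- dplyr::transmute(joined,
        site_id = .data$site_id, element = .data$element, horizon = h,
        index_kind = "BcF",
        value = bcf(.data$f_value, .data$s_value),
        ef_class = factor(NA, levels = .ef_labels, ordered = TRUE)
      )
    }
    if ("EF" %in% kind) {
      if (nrow(al) == 0) {
        abort(paste0("compute_indices(): Al missing for horizon ", h))
      }
      withal <- dplyr::inner_join(joined, al, by = "site_id")
      res$ef <- dplyr::transmute(withal,
        site_id = .data$site_id, element = .data$element, horizon = h,
        index_kind = "EF",
        value = ef(.data$f_value, .data$al_f, .data$s_value, .data$al_s),
        ef_class = classify_ef(.data$value)
      )
    }
    dplyr::bind_rows(res)
  })
  dplyr::bind_rows(out)
}

#' Median index across sites
#'
#' Aggregates a per-site index table to the median per
#' (element, horizon, index kind), dropping `NA` values but always
#' reporting how many sites contributed (`n_sites`) and how many were
#' dropped (`n_na`). The median EF additionally carries its enrichment
#' class.
#'
#' @param indices Output of [compute_indices()].
#' @return Tibble with `element`, `horizon`, `index_kind`, `value`,
#'   `n_sites`, `n_na`, `ef_class`.
#' @export
median_index <- function(indices) {
  out <- dplyr::summarise(
    dplyr::group_by(
      indices, .data$element, .data$horizon, .data$index_kind
    ),
    n_sites = sum(!is.na(.data$value)),
    n_na = sum(is.na(.data$value)),
    value = if (sum(!is.na(.data$value)) > 0) {
      median(.data$value, na.rm = TRUE)
    } else {
      NA_real_
    },
    .groups = "drop"
  )
  dplyr::mutate(out,
    ef_class = classify_ef(
      dplyr::if_else(.data$index_kind == "EF", .data$value, NA_real_)
    )
  )
}

#' Nutrient stoichiometry and limitation flags
#'
#' Mass ratios C:N, N:P and C:P from frond concentrations (all mg/kg),
#' with N- and P-limitation flags from the N:P ratio: below `np_low` the
#' stand is N-limited, above `np_high` P-limited (defaults 14 and 16, the
#' conventional wetland-ecology thresholds; between them neither flag is
#' set, so the flags are mutually exclusive).
#'
#' @param c,n,p Carbon, nitrogen, phosphorus concentrations (mg/kg, > 0).
#' @param np_low,np_high N:P thresholds.
#' @return Tibble with `cn_ratio`, `np_ratio`, `cp_ratio`, `n_limited`,
#'   `p_limited`.
#' @export
#' @examples
#' stoichiometry(449229, 25889, 1913)
stoichiometry <- function(c, n, p, np_low = 14, np_high = 16) {
  if (any(c(c, n, p) <= 0, na.rm = TRUE)) {
    abort("stoichiometry(): concentrations must be positive")
  }
  np <- n / p
  tibble::tibble(
    cn_ratio = c / n,
    np_ratio = np,
    cp_ratio = c / p,
    n_limited = np < np_low,
    p_limited = np > np_high
  )
}

#' Per-site stoichiometry from a frond table
#'
#' @param frond Aggregated frond concentration tibble containing C, N, P.
#' @inheritParams stoichiometry
#' @return Tibble with `site_id` plus the [stoichiometry()] columns.
#' @export
stoichiometry_table <- function(frond, np_low = 14, np_high = 16) {
  if (!all(is.na(frond$replicate))) frond <- aggregate_replicates(frond)
  wide <- tidyr::pivot_wider(
    dplyr::filter(frond, .data$element %in% c("C", "N", "P")),
    id_cols = "site_id", names_from = "element", values_from = "value_mg_kg"
  )
  missing <- setdiff(c("C", "N", "P"), names(wide))
  if (length(missing) > 0) {
    abort(paste0(
      "stoichiometry_table(): missing element(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  dplyr::bind_cols(
    dplyr::select(wide, "site_id"),
    stoichiometry(wide$C, wide$N, wide$P, np_low, np_high)
  )
}

#' Accumulation / exclusion verdict per element
#'
#' Applies the operational cut-offs used to summarize a survey: an element
#' is an **excluder** when its median BcF is below `bcf_excluder`
#' (default 0.1) in every horizon, and **accumulated** when its median EF
#' reaches `ef_accumulated` (default 10) in any horizon; otherwise
#' `"intermediate"`.
#'
#' @param med Output of [median_index()] containing both index kinds.
#' @param bcf_excluder,ef_accumulated Cut-offs (see above).
#' @return Tibble with `element`, `verdict`, `max_median_bcf`,
#'   `max_median_ef`.
#' @export
accumulation_verdict <- function(med, bcf_excluder = 0.1,
                                 ef_accumulated = 10) {
  wide <- dplyr::summarise(
    dplyr::group_by(med, .data$element),
    max_median_bcf = suppressWarnings(
      max(.data$value[.data$index_kind == "BcF"], na.rm = TRUE)
    ),
    max_median_ef = suppressWarnings(
      max(.data$value[.data$index_kind == "EF"], na.rm = TRUE)
    ),
    .groups = "drop"
  )
  wide$max_median_bcf[!is.finite(wide$max_median_bcf)] <- NA_real_
  wide$max_median_ef[!is.finite(wide$max_median_ef)] <- NA_real_
  dplyr::mutate(wide,
    verdict = dplyr::case_when(
      !is.na(.data$max_median_bcf) & .data$max_median_bcf < bcf_excluder ~
        "excluder",
      !is.na(.data$max_median_ef) & .data$max_median_ef >= ef_accumulated ~
        "accumulated",
      TRUE ~ "intermediate"
    ),
    .after = "element"
  )
}
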