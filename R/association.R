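# Spearman correlation screening of frond chemistry against substrate
# chemistry and site factors.

.p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Spearman screen of target variables against predictors
#'
#' Computes Spearman's rho and a two-sided p-value for every
#' (target, predictor) pair over complete cases, with an optional
#' multiplicity adjustment across the whole screen (default
#' Benjamini-Hochberg; raw p-values are always kept). Categorical bedrock
#' enters as 0/1 indicators (see [bedrock_indicators()]) so rho's sign
#' reads as enrichment on that bedrock. A constant variable has undefined
#' rho and is reported `NA`; pairs with fewer than 3 complete cases are
#' dropped. P-values use the large-sample t approximation, adequate for
#' survey-scale n and continuous variables.
#'
#' @param frame Data frame holding all variables (one row per site).
#' @param targets,predictors Character vectors of column names.
#' @param adjust Method for [stats::p.adjust()] (`"none"` to skip).
#' @return Tibble with `target`, `predictor`, `rho`, `p_value`,
#'   `adjusted_p`, `n`, `stars` (conventional `*`/`**`/`***` flags on the
#'   raw p).
#' @export
spearman_screen <- function(frame, targets, predictors, adjust = "BH") {
  missing <- setdiff(c(targets, predictors), names(frame))
  if (length(missing) > 0) {
    abort(paste0(
      "spearman_screen(): missing column(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  grid <- tidyr::expand_grid(target = targets, predictor = predictors)
  grid <- dplyr::filter(grid, .data$target != .data$predictor)
  res <- purrr::pmap(grid, function(target, predictor) {
    x <- frame[[target]]
    y <- frame[[predictor]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3) {
      return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warn(paste0(
        "spearman_screen(): constant variable in pair ",
        target, " ~ ", predictor, "; rho undefined"
      ))
      return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out <- dplyr::filter(out, .data$n >= 3)
  out$adjusted_p <- if (adjust == "none") {
    out$p_value
  } else {
    p.adjust(out$p_value, method = adjust)
  }
  dplyr::mutate(out, stars = .p_stars(.data$p_value))
}

#' Correlation distance matrix (1 - Pearson r)
#'
#' Computes the dissimilarity d(i, j) = 1 - cor(row_i, row_j) between the
#' rows of a matrix: 0 for perfectly correlated profiles, 1 for
#' uncorrelated, 2 for perfectly anticorrelated. A row with zero variance
#' has no defined correlation and is an error naming the row.
#'
#' @param m Numeric matrix, items as rows (>= 2 columns).
#' @return A [stats::dist] object with the row names as labels and
#'   attribute `"method"` set to `"1-pearson"`.
#' @export
pearson_distance <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    abort("pearson_distance(): need at least 2 variables per item")
  }
  sds <- apply(m, 1, sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- rownames(m)[which(sds == 0 | is.na(sds))]
    if (is.null(bad)) bad <- which(sds == 0 | is.na(sds))
    abort(paste0(
      "pearson_distance(): zero-variance item(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  d <- stats::as.dist(1 - cor(t(m)))
  attr(d, "method") <- "1-pearson"
  d
}
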