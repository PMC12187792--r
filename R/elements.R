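# Element metadata and shipped reference resources.

# Recognized IUPAC element symbols (H..U plus a few transuranics); used only
# to warn on unknown column names, never to drop data.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu"
)

# Element groupings that drive defaults of the synthetic generator and the
# reporting order. REEs here are the light lanthanides measured in frond
# surveys plus chemically analogous Y.
.ree_elements <- c("La", "Ce", "Pr", "Nd", "Y")
.granite_affine <- c("Rb", "Cs", "Be", "Tl", "U")
.deposition_affected <- c("Cd", "Hg", "Bi", "Cu", "Mo", "Pb", "Sb", "Sn")
.macro_elements <- c("C", "N", "P", "K", "Ca", "Mg", "S", "Fe", "Si")

#' Catalog of elements handled by the default survey design
#'
#' Returns one row per element of the default 47-element analyte set
#' (46 solution/combustion analytes of a full frond survey plus Si), with
#' the groupings used throughout the package: macroelement vs. trace,
#' membership in the rare-earth set (La, Ce, Pr, Nd and yttrium), affinity
#' for granitic bedrock, and susceptibility to atmospheric-deposition
#' enrichment of the humus layer.
#'
#' @return A tibble with columns `element`, `group` (`"macro"`/`"trace"`),
#'   `ree`, `granite_affine`, `deposition_affected` (logicals).
#' @export
#' @examples
#' element_catalog()
element_catalog <- function() {
  stats <- frond_reference_stats()
  tibble::tibble(
    element = stats$element,
    group = ifelse(stats$element %in% .macro_elements, "macro", "trace"),
    ree = stats$element %in% .ree_elements,
    granite_affine = stats$element %in% .granite_affine,
    deposition_affected = stats$element %in% .deposition_affected
  )
}

#' Published summary statistics for lady-fern frond element contents
#'
#' A transcription of the per-element summary battery (n = 35 composite
#' frond samples, mg/kg dry mass) from a national survey of
#' *Athyrium filix-femina* fronds: minimum, maximum, mean, SD, relative SD,
#' quartiles, median and unscaled MAD. The table is kept verbatim as
#' printed; a handful of rows are internally inconsistent as published
#' (e.g. a mean exceeding the maximum) and [flag_summary_consistency()]
#' marks them rather than repairing them. Note these are summary rows
#' only — no per-sample concentrations are distributed with the package,
#' so any statistic of per-sample derived quantities (for example the
#' cohort distribution of Ce/Ce*) cannot be recomputed from this resource.
#'
#' @return A tibble with columns `element`, `n`, `min`, `max`, `mean`,
#'   `sd`, `rsd_pct`, `q1`, `median`, `q3`, `mad`.
#' @export
#' @examples
#' frond_reference_stats()
frond_reference_stats <- function() {
  path <- system.file("extdata", "frond_reference_stats.csv",
    package = "phytoaccum", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Flag internally inconsistent summary rows
#'
#' Checks each row of an element-summary table for the order constraints a
#' valid summary must satisfy (min <= q1 <= median <= q3 <= max and
#' min <= mean <= max). Inconsistent rows — which occur in published
#' tables through typesetting errors — are flagged, never altered.
#'
#' @param stats A tibble shaped like [frond_reference_stats()].
#' @return The input with an added logical column `consistent`.
#' @export
#' @examples
#' dplyr::filter(flag_summary_consistency(frond_reference_stats()), !consistent)
flag_summary_consistency <- function(stats) {
  dplyr::mutate(
    stats,
    consistent = .data$min <= .data$q1 & .data$q1 <= .data$median &
      .data$median <= .data$q3 & .data$q3 <= .data$max &
      .data$mean >= .data$min & .data$mean <= .data$max
  )
}

#' Shale reference compositions for REE normalization
#'
#' The package ships named, versioned Post-Archean Australian Shale (PAAS)
#' compositions for the elements needed by the cerium-anomaly calculation
#' (La, Ce, Pr, Nd, Y). Swapping the reference is an explicit configuration
#' change: every normalized output records which reference produced it.
#'
#' @param name Reference name; see [list_ree_references()].
#' @return For `ree_reference()`, a tibble with columns `element` and
#'   `value_mg_kg` plus attributes `reference` and `source`. For
#'   `list_ree_references()`, a character vector of available names.
#' @export
#' @examples
#' ree_reference()
#' list_ree_references()
ree_reference <- function(name = "PAAS-P2012") {
  all <- .read_ree_references()
  if (!name %in% all$reference) {
    abort(paste0(
      "Unknown REE reference '", name, "'. Available: ",
      paste(unique(all$reference), collapse = ", ")
    ))
  }
  ref <- dplyr::filter(all, .data$reference == name)
  stopifnot(all(ref$value_mg_kg > 0))
  out <- dplyr::select(ref, "element", "value_mg_kg")
  attr(out, "reference") <- name
  attr(out, "source") <- ref$source[[1]]
  out
}

#' @rdname ree_reference
#' @export
list_ree_references <- function() {
  unique(.read_ree_references()$reference)
}

.read_ree_references <- function() {
  path <- system.file("extdata", "ree_references.csv",
    package = "phytoaccum", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
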