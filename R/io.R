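# Reading, validation and writing of concentration and site-factor tables.
#
# Canonical in-memory layout is long: one row per
# (site_id, element, compartment, replicate) with `value_mg_kg` and a
# `censored` flag for values reported below a detection limit.

.compartments <- c("frond", "humus", "topsoil", "subsoil")
.horizons <- c("humus", "topsoil", "subsoil")

.read_delim <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}

# Parse concentration strings that may carry "<x" detection-limit marks.
# policy: "half" substitutes x/2, "limit" substitutes x, "na" drops to NA.
.parse_censored <- function(x, policy = c("half", "limit", "na")) {
  policy <- match.arg(policy)
  x <- stringr::str_trim(as.character(x))
  cens <- stringr::str_detect(x, "^<")
  cens[is.na(cens)] <- FALSE
  num <- suppressWarnings(as.numeric(stringr::str_remove(x, "^<\\s*")))
  bad <- !is.na(x) & x != "" & is.na(num)
  if (any(bad)) {
    abort(paste0(
      "Non-numeric concentration value(s): ",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  sub <- switch(policy,
    half = num / 2,
    limit = num,
    na = NA_real_
  )
  list(value = ifelse(cens, sub, num), censored = cens)
}

.validate_conc <- function(tbl) {
  neg <- which(!is.na(tbl$value_mg_kg) & tbl$value_mg_kg < 0)
  if (length(neg) > 0) {
    first <- tbl[neg[1], ]
    abort(paste0(
      "Negative concentration for element ", first$element,
      " at site ", first$site_id, " (", first$value_mg_kg, " mg/kg)"
    ))
  }
  dup <- dplyr::count(
    tbl, .data$site_id, .data$element, .data$compartment, .data$replicate
  )
  dup <- dplyr::filter(dup, .data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (site, element, replicate) entries, e.g. site ",
      dup$site_id[1], ", element ", dup$element[1]
    ))
  }
  unknown <- setdiff(unique(tbl$element), .element_symbols)
  if (length(unknown) > 0) {
    warn(paste0(
      "Unknown element symbol(s) retained: ",
      paste(unknown, collapse = ", ")
    ))
  }
  invisible(tbl)
}

.as_conc_tbl <- function(site_id, element, compartment, replicate, value,
                         censored = FALSE) {
  tibble::tibble(
    site_id = as.integer(site_id),
    element = as.character(element),
    compartment = as.character(compartment),
    replicate = as.integer(replicate),
    value_mg_kg = as.double(value),
    censored = as.logical(censored)
  )
}

#' Read a concentration table
#'
#' Reads element concentrations for one compartment (frond, humus, topsoil
#' or subsoil) from CSV/TSV in either layout:
#'
#' * **long** — columns `site_id`, `element`, `value_mg_kg` (or `value`
#'   plus a `unit` column holding `"mg/kg"` or `"g/kg"`), optionally
#'   `replicate` and `compartment`;
#' * **wide** — a `site_id` column, optionally `replicate`, and one column
#'   per element symbol.
#'
#' Values below a detection limit may be written as strings like `"<0.01"`;
#' they are substituted according to `dl_policy` and flagged in the
#' `censored` column. Negative concentrations and duplicate
#' (site, element, replicate) rows are hard errors; unrecognized element
#' symbols are retained with a warning. C and N are frequently reported in
#' g/kg: pass `units = "g_kg"` (wide) or a `unit` column (long) and values
#' are converted so that everything is stored in mg/kg.
#'
#' @param path CSV (`,`) or TSV (`\t`) file path, UTF-8.
#' @param compartment One of `"frond"`, `"humus"`, `"topsoil"`, `"subsoil"`.
#' @param layout `"long"` or `"wide"`.
#' @param units Unit of all values in a wide file (`"mg_kg"` default).
#' @param dl_policy Detection-limit substitution: `"half"` (x/2, default),
#'   `"limit"` (x) or `"na"`.
#' @return A long tibble with columns `site_id`, `element`, `compartment`,
#'   `replicate`, `value_mg_kg`, `censored`.
#' @seealso [write_concentration_table()], [aggregate_replicates()]
#' @export
read_concentration_table <- function(path, compartment,
                                     layout = c("long", "wide"),
                                     units = c("mg_kg", "g_kg"),
                                     dl_policy = c("half", "limit", "na")) {
  layout <- match.arg(layout)
  units <- match.arg(units)
  dl_policy <- match.arg(dl_policy)
  compartment <- match.arg(compartment, .compartments)
  raw <- .read_delim(path)

  if (layout == "long") {
    value_col <- if ("value_mg_kg" %in% names(raw)) "value_mg_kg" else "value"
    need <- c("site_id", "element", value_col)
    missing <- setdiff(need, names(raw))
    if (length(missing) > 0) {
      abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
    }
    if ("compartment" %in% names(raw) &&
      !all(raw$compartment %in% compartment)) {
      abort("File contains rows for a different compartment")
    }
    parsed <- .parse_censored(raw[[value_col]], dl_policy)
    scale <- if ("unit" %in% names(raw)) {
      u <- stringr::str_replace_all(tolower(raw$unit), "[ /]", "_")
      ifelse(u %in% c("g_kg", "g_kg_dm"), 1000, 1)
    } else if (value_col == "value" && units == "g_kg") 1000 else 1
    rep <- if ("replicate" %in% names(raw)) raw$replicate else NA_integer_
    tbl <- .as_conc_tbl(
      raw$site_id, raw$element, compartment, rep,
      parsed$value * scale, parsed$censored
    )
  } else {
    if (!"site_id" %in% names(raw)) abort("Wide layout needs a site_id column")
    id_cols <- intersect(c("site_id", "replicate"), names(raw))
    long <- tidyr::pivot_longer(raw,
      cols = -dplyr::all_of(id_cols),
      names_to = "element", values_to = "raw_value"
    )
    parsed <- .parse_censored(long$raw_value, dl_policy)
    scale <- if (units == "g_kg") 1000 else 1
    rep <- if ("replicate" %in% id_cols) long$replicate else NA_integer_
    tbl <- .as_conc_tbl(
      long$site_id, long$element, compartment, rep,
      parsed$value * scale, parsed$censored
    )
  }
  .validate_conc(tbl)
  tbl
}

#' Write a concentration table
#'
#' Inverse of [read_concentration_table()]: writes the canonical long
#' layout, or a wide sites-by-elements table (one compartment, values in
#' mg/kg). `write` then `read` is value-identical in both layouts.
#'
#' @param x Long concentration tibble.
#' @param path Output CSV path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(x, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (layout == "long") {
    readr::write_csv(
      dplyr::select(
        x, "site_id", "element", "compartment", "replicate", "value_mg_kg"
      ),
      path, progress = FALSE
    )
  } else {
    stopifnot(length(unique(x$compartment)) == 1)
    id_cols <- c("site_id", if (!all(is.na(x$replicate))) "replicate")
    wide <- tidyr::pivot_wider(
      dplyr::select(x, dplyr::all_of(id_cols), "element", "value_mg_kg"),
      names_from = "element", values_from = "value_mg_kg"
    )
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Aggregate analytical replicates
#'
#' Collapses replicate measurements to one value per
#' (site, element, compartment). The default rule is the median, robust to
#' a single failed digestion; the mean is available. A single replicate
#' passes through unchanged, and mixed replicate counts are aggregated
#' over whatever is available with a warning.
#'
#' @param x Long concentration tibble.
#' @param rule `"median"` (default) or `"mean"`.
#' @return A tibble with one row per (site, element, compartment);
#'   `replicate` is `NA`, `n_reps` records how many values contributed,
#'   `censored` is `TRUE` if any contributing value was censored. The
#'   aggregation rule is recorded in attribute `"replicate_rule"`.
#' @export
aggregate_replicates <- function(x, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  fun <- if (rule == "median") stats::median else base::mean
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$site_id, .data$element, .data$compartment),
    n_reps = sum(!is.na(.data$value_mg_kg)),
    censored = any(.data$censored, na.rm = TRUE),
    value_mg_kg = fun(.data$value_mg_kg, na.rm = TRUE),
    .groups = "drop"
  )
  out <- dplyr::relocate(out, "value_mg_kg", .after = "compartment")
  if (length(unique(out$n_reps)) > 1) {
    warn("Mixed replicate counts; aggregated over available replicates")
  }
  out <- dplyr::mutate(out, replicate = NA_integer_, .after = "compartment")
  attr(out, "replicate_rule") <- rule
  out
}

#' Midpoint of a potential-evaporation class
#'
#' Evaporation is reported as 50 mm/y classes such as `"550-600"`. For
#' correlation work each class is scored by its midpoint; the parser is
#' insensitive to the dash variant (`-`, en dash, em dash) and to
#' whitespace, and requires lower < upper.
#'
#' @param x Character vector of interval strings.
#' @return Numeric vector of midpoints (mm/y).
#' @export
#' @examples
#' evaporation_midpoint(c("550-600", "500–550"))
evaporation_midpoint <- function(x) {
  parts <- stringr::str_match(
    stringr::str_trim(x),
    "^([0-9]+(?:\\.[0-9]+)?)\\s*[-–—;]\\s*([0-9]+(?:\\.[0-9]+)?)$"
  )
  if (anyNA(parts[!is.na(x), 1])) {
    abort(paste0(
      "Unparseable evaporation class: ",
      paste(unique(x[is.na(parts[, 1]) & !is.na(x)]), collapse = ", ")
    ))
  }
  lo <- as.numeric(parts[, 2])
  hi <- as.numeric(parts[, 3])
  if (any(!is.na(lo) & lo >= hi)) {
    abort("Evaporation class lower bound must be below upper bound")
  }
  (lo + hi) / 2
}

.bedrock_classes <- c("SAND", "PHYL", "GRA", "PAR", "BAS")

#' Validate a site-factor table
#'
#' Checks and normalizes a table of per-site explanatory factors:
#' `site_id`, `latitude`, `longitude`, `elevation_m` (> 0),
#' `bedrock_class` (one of SAND, PHYL, GRA, PAR, BAS — sandstones,
#' phyllites/greywackes, granitoids, paragneisses, basic rocks),
#' `climate_zone`, `evaporation_class` (interval string), and optional
#' `humus_pH` / `topsoil_pH`. Adds `evaporation_mid` (class midpoint).
#'
#' @param x Data frame of site factors.
#' @return Validated tibble with `evaporation_mid` appended.
#' @export
as_site_factors <- function(x) {
  need <- c(
    "site_id", "latitude", "longitude", "elevation_m", "bedrock_class",
    "climate_zone", "evaporation_class"
  )
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing site-factor column(s): ", paste(missing, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)
  if (any(duplicated(x$site_id))) abort("Duplicate site_id in site factors")
  if (any(x$elevation_m <= 0)) abort("Elevation must be positive")
  bad <- setdiff(unique(x$bedrock_class), .bedrock_classes)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown bedrock class(es): ", paste(bad, collapse = ", "),
      " (expected ", paste(.bedrock_classes, collapse = ", "), ")"
    ))
  }
  dplyr::mutate(x,
    site_id = as.integer(.data$site_id),
    evaporation_mid = evaporation_midpoint(.data$evaporation_class)
  )
}

#' Read a site-factor table from CSV/TSV
#'
#' @inheritParams read_concentration_table
#' @return See [as_site_factors()].
#' @export
read_site_factors <- function(path) {
  raw <- .read_delim(path)
  num <- intersect(
    c("site_id", "latitude", "longitude", "elevation_m", "humus_pH",
      "topsoil_pH"),
    names(raw)
  )
  raw[num] <- lapply(raw[num], as.numeric)
  as_site_factors(raw)
}

#' Join concentrations with site factors
#'
#' Attaches the per-site explanatory factors to every concentration row.
#' Every `site_id` in the concentration table must appear in the
#' site-factor table; unmatched ids are a hard error listing the ids.
#'
#' @param x Long concentration tibble.
#' @param sites Site-factor table (see [as_site_factors()]).
#' @return The joined analysis frame.
#' @export
join_site_factors <- function(x, sites) {
  sites <- as_site_factors(sites)
  unmatched <- setdiff(unique(x$site_id), sites$site_id)
  if (length(unmatched) > 0) {
    abort(paste0(
      "site ", paste(sort(unmatched), collapse = ", "),
      " unmatched in site-factor table"
    ))
  }
  dplyr::left_join(x, sites, by = "site_id")
}

#' Expand bedrock class into 0/1 indicator columns
#'
#' Correlation screens treat the categorical bedrock class as one binary
#' indicator per class (`bedrock_GRA`, ...), so that a positive rho reads
#' as "higher on that bedrock".
#'
#' @param sites Site-factor table.
#' @return The input with five indicator columns appended.
#' @export
bedrock_indicators <- function(sites) {
  for (cls in .bedrock_classes) {
    sites[[paste0("bedrock_", cls)]] <- as.integer(sites$bedrock_class == cls)
  }
  sites
}
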