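# Seeded synthetic survey generator.
#
# Emulates the statistical structure the analysis assumes — log-normal
# element concentrations, bedrock-stratified shifts for granite-affine
# elements, mutually coherent REEs, humus enrichment of
# deposition-affected metals, frond-substrate coupling at a configurable
# true BcF, and injectable Ce anomalies — so the whole pipeline is
# testable end to end without any external data. Distributional defaults
# are seeded from the shipped frond reference statistics back-solved
# through the default coupling strengths; they are illustrative study
# conditions, not ground truth about any real landscape.

#' Synthetic survey configuration
#'
#' All knobs of the generator, with defaults emulating a 35-site,
#' 47-element fern-frond survey:
#'
#' * `n_sites` (35), `seed` (1; the seed fully determines all output),
#' * `elements` and `element_params` — per element the frond geometric
#'   mean `frond_gm` (defaults: the shipped reference medians), the true
#'   coupling `bcf_true` (frond = bcf_true x reference-horizon
#'   concentration x noise) and the subsoil geometric SD `gsd_subsoil`
#'   (default 1.8, a typical geochemical spread),
#' * `bedrock_probs` — mixture over SAND/PHYL/GRA/PAR/BAS (defaults
#'   7/6/9/10/3 out of 35, the composition of the emulated survey),
#' * `granite_mult` (4) applied to Rb, Cs, Be, Tl, U on granitic sites,
#' * `topsoil_mult` (0.9) and `humus_mult` (0.7) horizon profiles,
#'   `deposition_mult` (3) extra humus enrichment for Cd, Hg, Bi, Cu, Mo,
#'   Pb, Sb, Sn (atmospheric deposition), `humus_al_mult` (0.4) for the
#'   low Al content of organic horizons, `horizon_gsd` (1.15),
#' * `ree_rho` (0.9) — common latent factor giving La/Ce/Pr/Nd/Y their
#'   strong mutual correlation,
#' * `frond_gsd` (1.3) — lognormal noise of the frond-substrate coupling;
#'   `replicate_gsd` (1.02) — analytical replicate noise (3 replicates),
#' * `ce_multiplier` (1) — multiplies frond Ce to inject an anomaly,
#' * `reference_horizon` (`"topsoil"`) — the horizon fronds couple to
#'   (plants forage mineral horizons below the humus),
#' * site-factor model: `elevation_range` (275-925 m), potential
#'   evaporation decreasing with elevation (`evap_intercept` 780 mm/y,
#'   `evap_slope` -0.3 per m, `evap_noise_sd` 25) binned into
#'   `evap_bin` = 50 mm/y classes, and a humus pH model (`ph_base` 4.0,
#'   per-bedrock offsets, `ph_noise_sd` 0.3).
#'
#' @param ... Named overrides of any field above.
#' @return A list of class `"synth_config"`.
#' @export
#' @examples
#' cfg <- synth_config(n_sites = 10, seed = 42)
synth_config <- function(...) {
  stats <- frond_reference_stats()
  params <- tibble::tibble(
    element = stats$element,
    frond_gm = stats$median,
    bcf_true = .default_bcf(stats$element),
    gsd_subsoil = 1.8
  )
  cfg <- list(
    n_sites = 35L,
    seed = 1L,
    elements = stats$element,
    element_params = params,
    bedrock_probs = c(SAND = 7, PHYL = 6, GRA = 9, PAR = 10, BAS = 3) / 35,
    granite_mult = 4,
    granite_elements = .granite_affine,
    deposition_mult = 3,
    deposition_elements = .deposition_affected,
    topsoil_mult = 0.9,
    humus_mult = 0.7,
    humus_al_mult = 0.4,
    horizon_gsd = 1.15,
    ree_rho = 0.9,
    ree_elements = .ree_elements,
    frond_gsd = 1.3,
    replicate_gsd = 1.02,
    n_replicates = 3L,
    ce_multiplier = 1,
    reference_horizon = "topsoil",
    elevation_range = c(275, 925),
    evap_intercept = 780,
    evap_slope = -0.3,
    evap_noise_sd = 25,
    evap_bin = 50,
    ph_base = 4.0,
    ph_bedrock_offset = c(SAND = -0.3, PHYL = 0, GRA = -0.2, PAR = 0,
      BAS = 0.8),
    ph_noise_sd = 0.3,
    latitude_range = c(48.8, 51.0),
    longitude_range = c(12.1, 18.8)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown synth_config field(s): ", paste(unknown, collapse = ", ")
    ))
  }
  cfg <- modifyList(cfg, dots)
  if ("elements" %in% names(dots) && !"element_params" %in% names(dots)) {
    cfg$element_params <- dplyr::filter(
      params, .data$element %in% cfg$elements
    )
  }
  .validate_synth_config(structure(cfg, class = "synth_config"))
}

# Plausible coupling strengths used only to seed defaults: excluded
# lithogenic elements well below 0.1, mobile nutrients above 1, the rest
# intermediate.
.default_bcf <- function(elements) {
  excluded <- c(
    "Na", "As", "Bi", "Pb", "Sb", "Sn", "Th", "Tl", "W", "Al", "Fe",
    "Cr", "Li", "U", "V", "Ag"
  )
  mobile <- c("K", "Mg", "Cd", "Cu", "Hg", "Mn", "Rb", "Zn")
  dplyr::case_when(
    elements %in% excluded ~ 0.03,
    elements %in% mobile ~ 1.5,
    elements == "C" ~ 8,
    elements == "N" ~ 10,
    elements %in% c("P", "S") ~ 2,
    elements %in% c("Ca", "B", "Ba", "Sr") ~ 0.8,
    elements == "Si" ~ 0.5,
    TRUE ~ 0.3
  )
}

.validate_synth_config <- function(cfg) {
  if (cfg$n_sites < 2) abort("synth_config: n_sites must be >= 2")
  if (abs(sum(cfg$bedrock_probs) - 1) > 1e-8) {
    abort("synth_config: bedrock_probs must sum to 1")
  }
  if (diff(cfg$elevation_range) <= 0) {
    abort("synth_config: degenerate elevation range")
  }
  mults <- c(
    cfg$granite_mult, cfg$deposition_mult, cfg$topsoil_mult,
    cfg$humus_mult, cfg$humus_al_mult, cfg$ce_multiplier,
    cfg$element_params$bcf_true
  )
  if (any(mults <= 0)) abort("synth_config: multipliers must be positive")
  gsds <- c(
    cfg$horizon_gsd, cfg$frond_gsd, cfg$replicate_gsd,
    cfg$element_params$gsd_subsoil
  )
  if (any(gsds < 1)) abort("synth_config: geometric SDs must be >= 1")
  if (cfg$ree_rho < 0 || cfg$ree_rho > 1) {
    abort("synth_config: ree_rho must be in [0, 1]")
  }
  missing <- setdiff(cfg$elements, cfg$element_params$element)
  if (length(missing) > 0) {
    abort(paste0(
      "synth_config: element(s) lacking parameters: ",
      paste(missing, collapse = ", ")
    ))
  }
  cfg
}

# Correlated standard-normal noise: REEs share a latent site factor with
# loading sqrt(rho); everything else is independent.
.element_noise <- function(n_sites, elements, ree_elements, rho) {
  z <- matrix(rnorm(n_sites * length(elements)), n_sites, length(elements),
    dimnames = list(NULL, elements)
  )
  ree <- intersect(elements, ree_elements)
  if (length(ree) > 0 && rho > 0) {
    common <- rnorm(n_sites)
    z[, ree] <- sqrt(rho) * common + sqrt(1 - rho) * z[, ree]
  }
  z
}

.matrix_to_conc <- function(m, compartment, replicate = NA_integer_) {
  tbl <- tibble::as_tibble(m)
  tbl$site_id <- seq_len(nrow(m))
  long <- tidyr::pivot_longer(tbl, -"site_id",
    names_to = "element", values_to = "value_mg_kg"
  )
  .as_conc_tbl(
    long$site_id, long$element, compartment, replicate,
    long$value_mg_kg, FALSE
  )
}

#' Generate synthetic site records
#'
#' Draws `n_sites` site-factor records: coordinates and elevation uniform
#' over their ranges, bedrock classes from the configured mixture, a
#' potential-evaporation class decreasing with elevation (negative slope
#' plus noise, binned into 50 mm/y classes), a climate-zone code tied to
#' elevation, and humus/topsoil pH from a bedrock-offset model.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A validated site-factor tibble (see [as_site_factors()]).
#' @export
generate_sites <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sites
  elevation <- runif(n, cfg$elevation_range[1], cfg$elevation_range[2])
  bedrock <- sample(names(cfg$bedrock_probs), n,
    replace = TRUE, prob = cfg$bedrock_probs
  )
  evap_raw <- cfg$evap_intercept + cfg$evap_slope * elevation +
    rnorm(n, 0, cfg$evap_noise_sd)
  lo <- floor(evap_raw / cfg$evap_bin) * cfg$evap_bin
  zone_letter <- dplyr::case_when(
    elevation > 750 ~ "C",
    elevation < 400 ~ "W",
    TRUE ~ "MW"
  )
  humus_pH <- cfg$ph_base + cfg$ph_bedrock_offset[bedrock] +
    rnorm(n, 0, cfg$ph_noise_sd)
  as_site_factors(tibble::tibble(
    site_id = seq_len(n),
    latitude = round(runif(n, cfg$latitude_range[1], cfg$latitude_range[2]),
      4
    ),
    longitude = round(
      runif(n, cfg$longitude_range[1], cfg$longitude_range[2]), 4
    ),
    elevation_m = round(elevation),
    bedrock_class = bedrock,
    climate_zone = paste0(zone_letter, sample(1:11, n, replace = TRUE)),
    evaporation_class = sprintf("%d-%d", lo, lo + cfg$evap_bin),
    humus_pH = round(unname(humus_pH), 2),
    topsoil_pH = round(unname(humus_pH) + 0.3 + rnorm(n, 0, 0.2), 2)
  ))
}

#' Generate synthetic substrate tables
#'
#' Subsoil concentrations are log-normal per element (geometric mean
#' back-solved from the configured frond medians and couplings, geometric
#' SD `gsd_subsoil`) times a bedrock multiplier for granite-affine
#' elements on granitic sites, with REEs sharing a common latent factor.
#' Topsoil and humus apply the horizon profile multipliers, humus
#' additionally the deposition enrichment for Cd, Hg, Bi, Cu, Mo, Pb, Sb,
#' Sn and the low-Al factor. Deterministic given `cfg$seed`.
#'
#' @param sites Site-factor tibble from [generate_sites()].
#' @param cfg A [synth_config()].
#' @return Named list of three long concentration tibbles: `humus`,
#'   `topsoil`, `subsoil`.
#' @export
generate_substrate <- function(sites, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(sites)
  params <- cfg$element_params[
    match(cfg$elements, cfg$element_params$element),
  ]
  elems <- params$element
  # geometric mean of the reference horizon back-solves the frond medians
  subsoil_gm <- params$frond_gm / params$bcf_true /
    if (cfg$reference_horizon == "topsoil") cfg$topsoil_mult else 1

  z_sub <- .element_noise(n, elems, cfg$ree_elements, cfg$ree_rho)
  sigma <- matrix(log(params$gsd_subsoil), n, length(elems), byrow = TRUE)
  bed_mult <- matrix(1, n, length(elems), dimnames = list(NULL, elems))
  gran <- intersect(elems, cfg$granite_elements)
  bed_mult[sites$bedrock_class == "GRA", gran] <- cfg$granite_mult

  subsoil <- matrix(subsoil_gm, n, length(elems), byrow = TRUE) *
    bed_mult * exp(sigma * z_sub)
  colnames(subsoil) <- elems

  h_sigma <- log(cfg$horizon_gsd)
  z_top <- .element_noise(n, elems, cfg$ree_elements, cfg$ree_rho)
  z_hum <- .element_noise(n, elems, cfg$ree_elements, cfg$ree_rho)
  topsoil <- subsoil * cfg$topsoil_mult * exp(h_sigma * z_top)
  hum_mult <- rep(cfg$humus_mult, length(elems))
  names(hum_mult) <- elems
  dep <- intersect(elems, cfg$deposition_elements)
  hum_mult[dep] <- hum_mult[dep] * cfg$deposition_mult
  if ("Al" %in% elems) hum_mult["Al"] <- hum_mult["Al"] * cfg$humus_al_mult
  humus <- subsoil * matrix(hum_mult, n, length(elems), byrow = TRUE) *
    exp(h_sigma * z_hum)

  list(
    humus = .matrix_to_conc(humus, "humus"),
    topsoil = .matrix_to_conc(topsoil, "topsoil"),
    subsoil = .matrix_to_conc(subsoil, "subsoil")
  )
}

#' Generate synthetic frond concentrations
#'
#' Encodes the uptake model behind the bioconcentration factor: each
#' frond concentration is `bcf_true` times the concentration in the
#' configured reference horizon, times log-normal noise of geometric SD
#' `frond_gsd` (REEs again share a latent factor, giving them coherent
#' frond patterns). The Ce anomaly multiplier scales frond Ce only. Each
#' site gets `n_replicates` analytical replicates with small
#' multiplicative noise (`replicate_gsd`). Deterministic given
#' `cfg$seed`.
#'
#' @param substrates Output of [generate_substrate()].
#' @param cfg A [synth_config()].
#' @return Long frond concentration tibble with replicates.
#' @export
generate_fronds <- function(substrates, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  ref <- substrates[[cfg$reference_horizon]]
  if (is.null(ref)) {
    abort(paste0(
      "generate_fronds(): reference horizon ", cfg$reference_horizon,
      " not in substrates"
    ))
  }
  params <- cfg$element_params[
    match(cfg$elements, cfg$element_params$element),
  ]
  missing <- setdiff(unique(ref$element), params$element)
  if (length(missing) > 0) {
    abort(paste0(
      "generate_fronds(): no coupling for element(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  wide <- dplyr::arrange(
    tidyr::pivot_wider(ref,
      id_cols = "site_id", names_from = "element",
      values_from = "value_mg_kg"
    ),
    .data$site_id
  )
  m <- as.matrix(wide[params$element])
  n <- nrow(m)
  z <- .element_noise(n, params$element, cfg$ree_elements, cfg$ree_rho)
  base <- m *
    matrix(params$bcf_true, n, ncol(m), byrow = TRUE) *
    exp(log(cfg$frond_gsd) * z)
  if ("Ce" %in% colnames(base)) {
    base[, "Ce"] <- base[, "Ce"] * cfg$ce_multiplier
  }
  reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    noise <- exp(log(cfg$replicate_gsd) *
      matrix(rnorm(length(base)), nrow(base), ncol(base)))
    .matrix_to_conc(base * noise, "frond", replicate = r)
  })
  dplyr::arrange(
    dplyr::bind_rows(reps), .data$site_id, .data$element, .data$replicate
  )
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_sites()],
#' [generate_substrate()] and [generate_fronds()].
#'
#' @param cfg A [synth_config()].
#' @return List with `sites`, `humus`, `topsoil`, `subsoil`, `frond`,
#'   `config`.
#' @export
#' @examples
#' study <- generate_study(synth_config(n_sites = 5, seed = 7))
generate_study <- function(cfg = synth_config()) {
  sites <- generate_sites(cfg)
  sub <- generate_substrate(sites, cfg)
  frond <- generate_fronds(sub, cfg)
  c(list(sites = sites), sub, list(frond = frond, config = cfg))
}
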