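# Guideline and toxicity-factor registry, hazard-index screening.
# Internal concentration unit is ug/m3 throughout; registry files may carry
# values in mg/m3 and are converted once at load.

.unit_factors <- c(ug_m3 = 1, mg_m3 = 1000)

#' Convert an air concentration between mg/m3 and ug/m3
#'
#' @param x numeric concentration(s).
#' @param from,to units, one of `"ug_m3"` or `"mg_m3"`.
#' @return concentration(s) expressed in `to` units.
#' @examples
#' convert_concentration(0.10, "mg_m3", "ug_m3")  # 100
#' @export
convert_concentration <- function(x, from, to) {
  from <- match.arg(from, names(.unit_factors))
  to <- match.arg(to, names(.unit_factors))
  x * .unit_factors[[from]] / .unit_factors[[to]]
}

.norm_units <- function(u) {
  u <- gsub("[/^]", "_", tolower(u))
  u <- sub("m_?3$", "m3", u)
  match.arg(u, names(.unit_factors))
}

#' Load the guideline-concentration registry
#'
#' Reads a registry of reference concentrations (RfCs, RELs, indoor air
#' quality standards) and converts all thresholds to ug/m3. The packaged
#' default covers formaldehyde and benzene under GB/T 18883-2002, OEHHA
#' (acute and chronic reference exposure levels) and U.S. EPA IRIS.
#'
#' @param path CSV with columns `compound, source, effect_class, value, units`.
#'   Defaults to the packaged registry.
#' @return data.frame with columns `compound`, `source`, `effect_class`,
#'   `threshold` (ug/m3).
#' @export
load_guidelines <- function(path = system.file("extdata", "guidelines.csv",
                                               package = "iaqrisk")) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "source", "effect_class", "value", "units")
  if (!all(need %in% names(reg)))
    stop("guideline registry must have columns: ", paste(need, collapse = ", "))
  if (any(reg$value <= 0)) stop("guideline thresholds must be positive")
  key <- paste(reg$compound, reg$source, reg$effect_class)
  if (anyDuplicated(key))
    stop("duplicate (compound, source, effect_class) in guideline registry")
  reg$threshold <- mapply(function(v, u) convert_concentration(v, .norm_units(u), "ug_m3"),
                          reg$value, reg$units)
  reg[c("compound", "source", "effect_class", "threshold")]
}

#' Load the inhalation-unit-risk registry
#'
#' Inhalation unit risks (IURs) express lifetime (70-year) excess cancer risk
#' per ug/m3 of continuous exposure. Each (compound, source) pair has exactly
#' one `default` row; alternates (e.g. the lower IRIS benzene value) carry
#' `variant = "alternate"`.
#'
#' @param path CSV with columns `compound, source, variant, iur`.
#' @return data.frame with columns `compound`, `source`, `variant`, `iur`.
#' @export
load_toxicity_factors <- function(path = system.file("extdata", "toxicity.csv",
                                                     package = "iaqrisk")) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "source", "variant", "iur")
  if (!all(need %in% names(reg)))
    stop("toxicity registry must have columns: ", paste(need, collapse = ", "))
  if (any(reg$iur <= 0)) stop("inhalation unit risks must be positive")
  def <- reg[reg$variant == "default", ]
  if (anyDuplicated(paste(def$compound, def$source)))
    stop("more than one default IUR for a (compound, source)")
  reg[need]
}

#' Look up a guideline concentration
#'
#' @param compound e.g. `"formaldehyde"` or `"benzene"`.
#' @param source issuing body: `"GB/T 18883-2002"`, `"OEHHA"` or
#'   `"U.S. EPA IRIS"`.
#' @param effect_class `"acute"`, `"chronic"` or `"iaq_standard"`.
#' @param registry registry data.frame; defaults to the packaged one.
#' @return one-row data.frame (`compound`, `source`, `effect_class`,
#'   `threshold` in ug/m3).
#' @examples
#' get_guideline("formaldehyde", "OEHHA", "acute")$threshold  # 55
#' @export
get_guideline <- function(compound, source, effect_class,
                          registry = load_guidelines()) {
  hit <- registry[registry$compound == compound & registry$source == source &
                    registry$effect_class == effect_class, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop(sprintf("no guideline for compound '%s', source '%s', effect class '%s'",
                 compound, source, effect_class))
  row.names(hit) <- NULL
  hit
}

#' Look up an inhalation unit risk
#'
#' @inheritParams get_guideline
#' @param variant `"default"` (the study value) or `"alternate"`.
#' @param registry toxicity registry data.frame.
#' @return one-row data.frame with the `iur` (per ug/m3).
#' @export
get_toxicity_factor <- function(compound, source, variant = "default",
                                registry = load_toxicity_factors()) {
  hit <- registry[registry$compound == compound & registry$source == source &
                    registry$variant == variant, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop(sprintf("no IUR for compound '%s', source '%s', variant '%s'",
                 compound, source, variant))
  row.names(hit) <- NULL
  hit
}

#' Hazard index for non-carcinogenic screening
#'
#' HI = C_exp / RfC. An index above 1 flags potential non-cancer toxicity;
#' below 1 the exposure is considered unlikely to pose that risk.
#'
#' @param c_exp exposure concentration(s), ug/m3, non-negative.
#' @param guideline one-row data.frame from [get_guideline()], or a single
#'   positive threshold in ug/m3.
#' @return data.frame with columns `value` (the ratio) and `flagged`
#'   (`value > 1`).
#' @examples
#' hazard_index(131, get_guideline("formaldehyde", "GB/T 18883-2002",
#'                                 "iaq_standard"))
#' @export
hazard_index <- function(c_exp, guideline) {
  if (any(!is.finite(c_exp)) || any(c_exp < 0))
    stop("exposure concentrations must be finite and non-negative")
  threshold <- if (is.data.frame(guideline)) guideline$threshold else guideline
  if (length(threshold) != 1L || threshold <= 0)
    stop("guideline must supply a single positive threshold")
  data.frame(value = c_exp / threshold, flagged = c_exp / threshold > 1)
}

#' Concentration equivalent to a target lifetime cancer risk
#'
#' Inverts the linear risk model: the concentration sustaining a lifetime
#' risk of `target_risk` excess cases per million is
#' `target_risk * 1e-6 / iur`. Example: 100 per million under the IRIS
#' formaldehyde IUR of 1.3e-5 corresponds to about 8 ug/m3.
#'
#' @param target_risk positive risk, excess cases per million.
#' @param factor one-row data.frame from [get_toxicity_factor()], or a single
#'   positive IUR (per ug/m3).
#' @return concentration in ug/m3.
#' @export
risk_equivalent_concentration <- function(target_risk, factor) {
  if (any(!is.finite(target_risk)) || any(target_risk <= 0))
    stop("target risk must be positive")
  iur <- if (is.data.frame(factor)) factor$iur else factor
  if (length(iur) != 1L || iur <= 0) stop("factor must supply a single positive IUR")
  target_risk * 1e-6 / iur
}
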