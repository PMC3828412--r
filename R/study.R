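# Full study pipeline: generate -> fit -> screen -> simulate -> assess ->
# report, driven by one scenario configuration and one root seed.

#' Screen concentration records against guidelines
#'
#' Computes a hazard index for every record against every applicable
#' guideline, and per-stratum exceedance fractions.
#'
#' @param records data.frame with columns `building_id`, `building_type`,
#'   `compound`, `concentration_ug_m3` (one row per building x compound,
#'   rooms already averaged).
#' @param guidelines registry from [load_guidelines()].
#' @return list with `hazard_table` (per building x guideline HI and flag)
#'   and `exceedance` (per stratum x guideline empirical fraction).
#' @export
screen_concentrations <- function(records, guidelines = load_guidelines()) {
  need <- c("building_id", "building_type", "compound", "concentration_ug_m3")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$concentration_ug_m3 <= 0))
    stop("non-positive concentrations in records")
  hz <- merge(records, guidelines, by = "compound")
  hi <- hz$concentration_ug_m3 / hz$threshold
  hazard_table <- data.frame(
    building_id = hz$building_id, building_type = hz$building_type,
    compound = hz$compound, source = hz$source,
    effect_class = hz$effect_class, hazard_index = hi, flagged = hi > 1)
  hazard_table <- hazard_table[order(hazard_table$building_id,
                                     hazard_table$source), ]
  agg <- stats::aggregate(
    flagged ~ building_type + compound + source + effect_class,
    data = hazard_table, FUN = mean)
  names(agg)[names(agg) == "flagged"] <- "fraction_exceeding"
  list(hazard_table = hazard_table, exceedance = agg)
}

.require_stratum <- function(summaries, building_type, compound, stage) {
  hit <- summaries[summaries$building_type == building_type &
                     summaries$compound == compound, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop(sprintf("stage '%s': missing stratum (%s, %s) in scenario summaries",
                 stage, building_type, compound))
  hit
}

# stable content hash of the configuration (polynomial rolling hash over
# its serialization; doubles keep exact integers below 2^53)
.config_hash <- function(config) {
  bytes <- as.numeric(serialize(config, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full risk-assessment study
#'
#' Orchestrates the pipeline: synthetic building records, lognormal fits per
#' stratum, guideline screening (analytic and empirical exceedance),
#' Monte Carlo personal-exposure simulation per compound, cancer risk under
#' every default inhalation-unit-risk set, microenvironment disaggregation
#' and the long-term concentration-decay scenario. All randomness flows
#' from `config$seed`; re-running with the same config reproduces identical
#' numbers.
#'
#' @param config a [scenario_config()].
#' @param guidelines registry from [load_guidelines()].
#' @param toxicity registry from [load_toxicity_factors()].
#' @param decay named vector of retained long-term concentration fractions
#'   per compound (defaults: formaldehyde 0.35, benzene 0.25).
#' @param keep_draws retain per-draw exposure/risk matrices in the result
#'   (needed by [plot.iaq_study()]).
#' @return object of class `iaq_study` with elements `fits`,
#'   `exceedance_table`, `exposure_summaries`, `risk_summary`, `risk_table`,
#'   `decay_table`, `records`, and a reproducibility `manifest`.
#' @export
run_study <- function(config, guidelines = load_guidelines(),
                      toxicity = load_toxicity_factors(),
                      decay = c(formaldehyde = 0.35, benzene = 0.25),
                      keep_draws = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  t0 <- Sys.time()
  s <- config$summaries
  compounds <- unique(s$compound)

  # stage: synthetic records
  records <- generate_building_records(config)

  # stage: per-stratum lognormal fits (method of moments on the summary)
  fits <- list()
  for (i in seq_len(nrow(s))) {
    med <- if ("median" %in% names(s) && is.finite(s$median[i])) s$median[i]
    fits[[paste(s$building_type[i], s$compound[i], sep = ".")]] <-
      fit_lognormal_mom(s$mean[i], s$sd[i], median = med)
  }

  # stage: guideline exceedance, analytic (from fits) and empirical (records)
  exc <- list()
  for (g in seq_len(nrow(guidelines))) {
    for (bt in unique(s$building_type)) {
      key <- paste(bt, guidelines$compound[g], sep = ".")
      if (is.null(fits[[key]])) next
      rec <- records[records$building_type == bt &
                       records$compound == guidelines$compound[g], ]
      exc[[length(exc) + 1L]] <- data.frame(
        building_type = bt, compound = guidelines$compound[g],
        source = guidelines$source[g], effect_class = guidelines$effect_class[g],
        threshold = guidelines$threshold[g],
        analytic = exceedance_analytic(fits[[key]], guidelines$threshold[g]),
        empirical = exceedance_empirical(rec$concentration_ug_m3,
                                         guidelines$threshold[g]))
    }
  }
  exceedance_table <- do.call(rbind, exc)

  # stage: exposure simulation per compound
  draws <- list()
  exposure_summaries <- list()
  for (cp in compounds) {
    .require_stratum(s, "dwelling", cp, "exposure")
    .require_stratum(s, "office", cp, "exposure")
    d <- simulate_personal_exposure(
      fits[[paste("dwelling", cp, sep = ".")]],
      fits[[paste("office", cp, sep = ".")]],
      config$time_use, n_trials = config$n_trials,
      seed = (config$seed + match(cp, compounds) * 7919L) %% 2147483647L,
      compound = cp)
    draws[[cp]] <- d
    es <- summary(d)
    exposure_summaries[[cp]] <- cbind(compound = cp, es)
  }
  exposure_summaries <- do.call(rbind, exposure_summaries)
  row.names(exposure_summaries) <- NULL

  # stage: cancer risk per compound x default IUR source
  defaults <- toxicity[toxicity$variant == "default", ]
  risk_rows <- list(); part_rows <- list(); decay_rows <- list()
  for (cp in compounds) {
    for (src in unique(defaults$source[defaults$compound == cp])) {
      fac <- get_toxicity_factor(cp, src, registry = toxicity)
      rk <- cancer_risk(draws[[cp]], fac)
      sm <- summary(rk)
      risk_rows[[length(risk_rows) + 1L]] <- sm
      for (part in c("home", "office")) {
        col <- paste0("r_", part)
        part_rows[[length(part_rows) + 1L]] <- cbind(
          data.frame(compound = cp, iur_source = src, microenvironment = part),
          .summary_row(rk[[col]]),
          data.frame(share = unname(disaggregate(rk)[paste0(part, "_share")])))
      }
      if (cp %in% names(decay)) {
        dsm <- decay_scenario(sm, decay[[cp]])
        dsm$retained_fraction <- decay[[cp]]
        decay_rows[[length(decay_rows) + 1L]] <- dsm
      }
    }
  }
  risk_summary <- do.call(rbind, risk_rows); row.names(risk_summary) <- NULL
  risk_table <- do.call(rbind, part_rows); row.names(risk_table) <- NULL
  decay_table <- do.call(rbind, decay_rows); row.names(decay_table) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("iaqrisk")),
    config_hash = .config_hash(config), seed = config$seed,
    n_trials = config$n_trials,
    n_records = nrow(records),
    stages = c("records", "fits", "screen", "exposure", "risk", "decay"),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(config = config, fits = fits, records = records,
                 exceedance_table = exceedance_table,
                 exposure_summaries = exposure_summaries,
                 risk_summary = risk_summary, risk_table = risk_table,
                 decay_table = decay_table,
                 draws = if (keep_draws) draws,
                 manifest = manifest),
            class = "iaq_study")
}

#' @export
print.iaq_study <- function(x, ...) {
  cat("Indoor air toxics risk-assessment study\n")
  cat(sprintf("  %d building records, %d Monte Carlo trials, seed %d (config %s)\n",
              nrow(x$records), x$config$n_trials, x$config$seed,
              x$manifest$config_hash))
  cat("\nCancer risk (excess cases per million):\n")
  print(x$risk_summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.iaq_study <- function(object, ...) {
  list(exceedance = object$exceedance_table,
       exposure = object$exposure_summaries,
       risk = object$risk_summary,
       decay = object$decay_table)
}

#' Histogram / ECDF displays of the simulated risk distributions
#'
#' @param x an `iaq_study` run with `keep_draws = TRUE`.
#' @param which `"hist"` or `"ecdf"`.
#' @param ... passed to the graphics call.
#' @export
plot.iaq_study <- function(x, which = c("hist", "ecdf"), ...) {
  which <- match.arg(which)
  if (is.null(x$draws)) stop("study was run with keep_draws = FALSE")
  old <- graphics::par(mfrow = c(1, length(x$draws)))
  on.exit(graphics::par(old))
  for (cp in names(x$draws)) {
    e <- x$draws[[cp]]$e_total
    if (which == "hist")
      graphics::hist(e, breaks = 50, main = cp,
                     xlab = "indoor personal exposure (ug/m3)", ...)
    else
      graphics::plot(stats::ecdf(e), main = cp,
                     xlab = "indoor personal exposure (ug/m3)", ...)
  }
  invisible(x)
}

.pct <- function(x) sprintf("%.1f%%", 100 * x)
.int_fmt <- function(x) formatC(round(x), format = "d", big.mark = ",")

#' Render a human-readable study report
#'
#' Markdown summary with exceedance percentages to one decimal and risk
#' statistics as integers with thousands separators.
#'
#' @param study an `iaq_study` object.
#' @return character vector of markdown lines (invisibly printed with
#'   `cat` when interactive use wants it: `cat(report(study), sep = "\n")`).
#' @export
report <- function(study) {
  if (!inherits(study, "iaq_study")) stop("report() needs an iaq_study object")
  for (el in c("exceedance_table", "exposure_summaries", "risk_summary"))
    if (is.null(study[[el]]) || nrow(study[[el]]) == 0L)
      stop("incomplete study: missing ", el)
  out <- c("# Indoor air toxics risk assessment",
           "",
           sprintf("Seed %d, %d trials, config %s.", study$config$seed,
                   study$config$n_trials, study$manifest$config_hash),
           "", "## Guideline exceedance (fitted lognormal tail)")
  ex <- study$exceedance_table
  for (g in unique(paste(ex$source, ex$effect_class))) {
    sub <- ex[paste(ex$source, ex$effect_class) == g, ]
    out <- c(out, "", sprintf("### %s", g))
    out <- c(out, sprintf("- %s, %s (> %g ug/m3): %s", sub$building_type,
                          sub$compound, sub$threshold, .pct(sub$analytic)))
  }
  out <- c(out, "", "## Cancer risk (excess cases per million)", "")
  rs <- study$risk_summary
  out <- c(out, sprintf(
    "- %s (%s): mean %s, median %s, 95th pct %s; home share %s",
    rs$compound, rs$iur_source, .int_fmt(rs$mean), .int_fmt(rs$median),
    .int_fmt(rs$p95), .pct(rs$home_share)))
  if (!is.null(study$decay_table) && nrow(study$decay_table)) {
    dt <- study$decay_table
    out <- c(out, "", "## Long-term decay scenario", "")
    out <- c(out, sprintf(
      "- %s (%s), retained fraction %.2f: median %s",
      dt$compound, dt$iur_source, dt$retained_fraction, .int_fmt(dt$median)))
  }
  out
}

#' Write study outputs to a directory
#'
#' CSV tables (UTF-8, header row) plus a JSON manifest; byte-identical
#' across runs with the same config and seed.
#'
#' @param study an `iaq_study`.
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest file path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "iaq_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  w(study$records, "records.csv")
  w(study$exceedance_table, "exceedance.csv")
  w(study$exposure_summaries, "exposure_summary.csv")
  w(study$risk_summary, "risk_summary.csv")
  w(study$risk_table, "risk_by_microenvironment.csv")
  w(study$decay_table, "decay_scenario.csv")
  writeLines(report(study), file.path(dir, "report.md"))
  man <- study$manifest
  man$finished <- NULL; man$started <- NULL  # timestamps break byte-identity
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
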