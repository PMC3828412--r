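# Lifetime inhalation cancer risk from exposure draws. risk = E * IUR,
# reported as excess cases per million population (x 1e6). Risk is linear
# in concentration, so decay scenarios scale draws and summaries alike.

#' Per-draw lifetime cancer risk
#'
#' Multiplies each exposure draw by the inhalation unit risk and scales to
#' excess cases per million. The home and office components are scaled
#' identically so risk can be disaggregated by microenvironment.
#'
#' @param draws an `exposure_draws` object.
#' @param factor one-row data.frame from [get_toxicity_factor()]; its
#'   `compound` must match the draws'.
#' @param per_million report per-million risks (default) or raw lifetime
#'   probabilities.
#' @return object of class `risk_draws`: data.frame with `r_home`,
#'   `r_office`, `r_total`, plus attributes `compound`, `iur_source`.
#' @export
cancer_risk <- function(draws, factor, per_million = TRUE) {
  stopifnot(inherits(draws, "exposure_draws"))
  if (!is.data.frame(factor) || !all(c("compound", "iur") %in% names(factor)))
    stop("factor must be a toxicity-factor row with compound and iur")
  if (!identical(factor$compound, attr(draws, "compound")))
    stop(sprintf("toxicity factor is for '%s' but draws are for '%s'",
                 factor$compound, attr(draws, "compound")))
  k <- factor$iur * if (per_million) 1e6 else 1
  structure(
    data.frame(r_home = draws$e_home * k, r_office = draws$e_office * k,
               r_total = draws$e_total * k),
    compound = factor$compound, iur_source = factor$source,
    per_million = per_million,
    class = c("risk_draws", "data.frame"))
}

#' Summarize a risk distribution
#'
#' @param object a `risk_draws` object with >= 2 draws.
#' @param ... unused.
#' @return one-row data.frame: `compound`, `iur_source`, `mean`, `sd`,
#'   `median`, `p95` (95th percentile of the simulated distribution),
#'   `home_share`, `office_share`.
#' @export
summary.risk_draws <- function(object, ...) {
  if (nrow(object) < 2L) stop("need at least 2 draws to summarize")
  sh <- disaggregate(object)
  cbind(data.frame(compound = attr(object, "compound"),
                   iur_source = attr(object, "iur_source")),
        .summary_row(object$r_total),
        data.frame(home_share = sh[["home_share"]],
                   office_share = sh[["office_share"]]))
}

#' @export
print.risk_draws <- function(x, ...) {
  unit <- if (attr(x, "per_million")) "excess cases per million" else
    "lifetime probability"
  cat(sprintf("Cancer risk draws: %s, IUR source %s (%s)\n",
              attr(x, "compound"), attr(x, "iur_source"), unit))
  print(summary(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Disaggregate cumulative risk by microenvironment
#'
#' Shares are ratios of mean risk components: share_home =
#' mean(r_home) / mean(r_total); the two shares sum to one.
#'
#' @param risks a `risk_draws` object.
#' @return named numeric vector `c(home_share, office_share)`.
#' @export
disaggregate <- function(risks) {
  stopifnot(inherits(risks, "risk_draws"))
  total <- mean(risks$r_total)
  if (total <= 0) stop("total risk is zero; shares undefined")
  c(home_share = mean(risks$r_home) / total,
    office_share = mean(risks$r_office) / total)
}

#' Post-remodeling concentration-decay scenario
#'
#' Indoor emission-driven concentrations decline after remodeling (for
#' instance to ~35% of initial formaldehyde and ~25% of initial benzene
#' within months to years). Because risk is linear in concentration, a
#' long-term scenario simply multiplies every draw or summary statistic by
#' the retained fraction.
#'
#' @param x a `risk_draws` object, a `summary.risk_draws` row, or a bare
#'   numeric of risk statistics.
#' @param retained_fraction long-term concentration as a fraction of the
#'   initial level, in (0, 1].
#' @return same shape as `x`, scaled. Shares are unchanged (scale-free).
#' @export
decay_scenario <- function(x, retained_fraction) {
  if (!is.numeric(retained_fraction) || length(retained_fraction) != 1L ||
      retained_fraction <= 0 || retained_fraction > 1)
    stop("retained_fraction must be a single value in (0, 1]")
  if (inherits(x, "risk_draws")) {
    x[c("r_home", "r_office", "r_total")] <-
      x[c("r_home", "r_office", "r_total")] * retained_fraction
    return(x)
  }
  if (is.data.frame(x)) {
    for (col in intersect(c("mean", "sd", "median", "p95"), names(x)))
      x[[col]] <- x[[col]] * retained_fraction
    return(x)
  }
  x * retained_fraction
}
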