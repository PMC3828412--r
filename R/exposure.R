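# Monte Carlo simulation of time-weighted indoor personal exposure.
# For person i, E_i = C_home,i * f_home,i + C_office,i * f_office,i where
# the f are fractions of TOTAL time (all microenvironments), so f_home +
# f_office deliberately stays below 1: E is the indoor (home + office)
# share of total personal exposure, never renormalized.

#' Simulate time-weighted indoor personal exposure
#'
#' Draws per-person home and office concentrations from the fitted stratum
#' lognormals (independently by default), pairs them with time-use
#' fractions, and returns the per-draw microenvironment contributions.
#'
#' @param home_fit,office_fit `lognormal_fit` objects for the compound's
#'   dwelling and office strata.
#' @param time_use a [time_use_model()].
#' @param n_trials number of simulated persons (>= 1).
#' @param seed integer seed, mandatory.
#' @param compound label carried through to risk computation.
#' @return object of class `exposure_draws`: data.frame with columns
#'   `e_home`, `e_office`, `e_total` (ug/m3) plus attributes `compound`,
#'   `n_trials`, `seed`.
#' @export
simulate_personal_exposure <- function(home_fit, office_fit, time_use,
                                       n_trials = 5000, seed,
                                       compound = "compound") {
  stopifnot(inherits(home_fit, "lognormal_fit"),
            inherits(office_fit, "lognormal_fit"),
            inherits(time_use, "time_use_model"), n_trials >= 1)
  if (missing(seed)) stop("a seed is required")
  tu <- sample_time_use(time_use, n_trials, seed = .stage_seed(seed, "time_use"))
  set.seed(.stage_seed(seed, "conc_home"))
  c_home <- stats::rlnorm(n_trials, home_fit$mu, home_fit$sigma)
  set.seed(.stage_seed(seed, "conc_office"))
  c_office <- stats::rlnorm(n_trials, office_fit$mu, office_fit$sigma)
  e_home <- c_home * tu$f_home
  e_office <- c_office * tu$f_office
  if (any(!is.finite(e_home)) || any(!is.finite(e_office)))
    stop("non-finite exposure draws")
  structure(
    data.frame(e_home = e_home, e_office = e_office,
               e_total = e_home + e_office),
    compound = compound, n_trials = as.integer(n_trials),
    seed = as.integer(seed),
    class = c("exposure_draws", "data.frame"))
}

.summary_row <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.95), type = 7, names = FALSE)
  data.frame(mean = mean(x), sd = stats::sd(x), median = q[1], p95 = q[2])
}

#' Summarize exposure draws per microenvironment
#'
#' @param object an `exposure_draws` object with at least 2 draws.
#' @param ... unused.
#' @return data.frame with rows `home`, `office`, `total` and columns
#'   `mean`, `sd`, `median`, `p95` (ug/m3). Quantiles use linear
#'   interpolation between order statistics (type 7).
#' @export
summary.exposure_draws <- function(object, ...) {
  if (nrow(object) < 2L) stop("need at least 2 draws to summarize")
  out <- rbind(.summary_row(object$e_home), .summary_row(object$e_office),
               .summary_row(object$e_total))
  out <- cbind(microenvironment = c("home", "office", "total"), out)
  attr(out, "compound") <- attr(object, "compound")
  out
}

#' @export
print.exposure_draws <- function(x, ...) {
  cat(sprintf("Personal exposure draws: %s, %d trials (seed %d)\n",
              attr(x, "compound"), attr(x, "n_trials"), attr(x, "seed")))
  print(summary(x), row.names = FALSE, digits = 3)
  invisible(x)
}
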