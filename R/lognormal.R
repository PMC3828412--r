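# Lognormal concentration model: descriptive statistics, method-of-moments
# fitting from printed summary statistics, and guideline-exceedance tails.

#' Descriptive summary of concentration records
#'
#' Produces the Mean (arithmetic), sample SD (n-1 denominator) and median
#' used to report a stratum of building-level measurements.
#'
#' @param records numeric vector of concentrations, ug/m3, all positive.
#' @return data.frame with columns `n`, `mean`, `sd` (NA for a single
#'   record), `median`.
#' @export
summarize_concentrations <- function(records) {
  if (length(records) == 0L) stop("no concentration records supplied")
  bad <- which(!is.finite(records) | records <= 0)
  if (length(bad))
    stop("non-positive or non-finite concentrations at index ",
         paste(utils::head(bad, 5L), collapse = ", "))
  data.frame(n = length(records), mean = mean(records),
             sd = stats::sd(records), median = stats::median(records))
}

#' Fit a lognormal concentration model by the method of moments
#'
#' Chooses log-scale parameters (mu, sigma) so that the lognormal's
#' arithmetic mean and SD equal the supplied values exactly:
#' sigma^2 = log(1 + (sd/mean)^2), mu = log(mean) - sigma^2 / 2.
#' This is the natural estimator when only a printed "mean +/- SD" summary
#' of a stratum is available.
#'
#' If a reported `median` is supplied, the fitted geometric mean exp(mu) is
#' checked against it; a deviation beyond `median_tol` (default 15%) raises a
#' model-adequacy warning, not an error.
#'
#' @param mean arithmetic mean, ug/m3, positive.
#' @param sd arithmetic SD, ug/m3, positive.
#' @param median optional reported median for the adequacy check.
#' @param median_tol relative tolerance for that check.
#' @return object of class `lognormal_fit`: list with `mu`, `sigma`, and the
#'   input `mean`, `sd`.
#' @examples
#' fit_lognormal_mom(131, 90)   # mu ~ 4.68, sigma ~ 0.62
#' @export
fit_lognormal_mom <- function(mean, sd, median = NULL, median_tol = 0.15) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be a positive number")
  if (!is.finite(sd) || sd <= 0) stop("sd must be a positive number")
  sigma2 <- log1p((sd / mean)^2)  # log1p keeps precision as sd/mean -> 0
  fit <- structure(
    list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2),
         mean = mean, sd = sd, method = "moments"),
    class = "lognormal_fit")
  if (!is.null(median)) {
    rel <- abs(exp(fit$mu) - median) / median
    if (rel > median_tol)
      warning(sprintf(paste0("fitted median %.3g deviates %.0f%% from the ",
                             "reported median %.3g: lognormal may fit poorly"),
                      exp(fit$mu), 100 * rel, median))
  }
  fit
}

#' Fit a lognormal model to raw records by maximum likelihood
#'
#' Closed-form MLE: mu and sigma are the mean and (n-denominator) SD of the
#' log records. Offered for raw data; [fit_lognormal_mom()] is the default
#' route because the study strata are available only as printed moments.
#'
#' @param records positive concentrations, ug/m3, length >= 2.
#' @return `lognormal_fit` object (its `mean`/`sd` are the implied
#'   lognormal moments, not the sample moments).
#' @export
fit_lognormal_mle <- function(records) {
  if (length(records) < 2L) stop("need at least two records")
  if (any(!is.finite(records) | records <= 0))
    stop("records must be positive and finite")
  lx <- log(records)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma <= 0) stop("records are constant; lognormal spread undefined")
  structure(list(mu = mu, sigma = sigma,
                 mean = exp(mu + sigma^2 / 2),
                 sd = exp(mu + sigma^2 / 2) * sqrt(expm1(sigma^2)),
                 method = "mle"),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("Lognormal concentration model (%s fit)\n", x$method))
  cat(sprintf("  mu = %.4f, sigma = %.4f  (log ug/m3 scale)\n", x$mu, x$sigma))
  cat(sprintf("  implied mean = %.4g, sd = %.4g, median = %.4g ug/m3\n",
              x$mean, x$sd, exp(x$mu)))
  invisible(x)
}

#' @export
mean.lognormal_fit <- function(x, ...) exp(x$mu + x$sigma^2 / 2)

#' @export
median.lognormal_fit <- function(x, na.rm = FALSE, ...) exp(x$mu)

#' @export
quantile.lognormal_fit <- function(x, probs = c(0.05, 0.5, 0.95), ...)
  stats::qlnorm(probs, x$mu, x$sigma)

#' Analytic guideline-exceedance fraction
#'
#' Upper-tail probability of the fitted lognormal at a guideline threshold:
#' P(X > t) = 1 - Phi((log t - mu) / sigma).
#'
#' @param fit `lognormal_fit` object.
#' @param threshold positive concentration(s), ug/m3.
#' @return fraction(s) in \\[0, 1\\].
#' @examples
#' exceedance_analytic(fit_lognormal_mom(131, 90), 55)  # ~0.86
#' @export
exceedance_analytic <- function(fit, threshold) {
  stopifnot(inherits(fit, "lognormal_fit"))
  if (any(!is.finite(threshold) | threshold <= 0))
    stop("threshold must be positive")
  stats::plnorm(threshold, fit$mu, fit$sigma, lower.tail = FALSE)
}

#' Empirical guideline-exceedance fraction
#'
#' Fraction of records strictly above the threshold; ties count as
#' compliant, matching the "above the guideline" reading.
#'
#' @param records numeric concentrations, ug/m3.
#' @param threshold positive threshold, ug/m3.
#' @return fraction in \\[0, 1\\].
#' @export
exceedance_empirical <- function(records, threshold) {
  if (length(records) == 0L) stop("no concentration records supplied")
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be positive")
  mean(records > threshold)
}
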