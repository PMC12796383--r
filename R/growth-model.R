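#' Construct or validate a volume series
#'
#' A volume series is a data frame with columns \code{time_h} (h AEL),
#' \code{volume} (> 0) and \code{replicate}.
#'
#' @param x data frame with the three columns above.
#' @return \code{x} with class \code{"volume_series"} prepended.
#' @export
volume_series <- function(x) {
  need <- c("time_h", "volume", "replicate")
  if (!all(need %in% names(x)))
    stop("a volume series needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(x$time_h)) || any(!is.finite(x$volume)))
    stop("times and volumes must be finite")
  if (any(x$volume <= 0)) stop("all volumes must be positive")
  if (!inherits(x, "volume_series"))
    class(x) <- c("volume_series", class(x))
  x
}

#' Normalise volumes to the mean initial volume
#'
#' Divides every volume by the mean volume at the earliest observed
#' timepoint, yielding dimensionless fold-of-initial volumes (the mean at
#' the earliest timepoint becomes exactly 1). Idempotent.
#'
#' @param series a \code{\link{volume_series}}.
#' @return the normalised series, flagged with
#'   \code{attr(, "dimensionless")}.
#' @export
normalize_volumes <- function(series) {
  series <- volume_series(series)
  t0 <- min(series$time_h)
  v0 <- series$volume[series$time_h == t0]
  if (length(v0) == 0) stop("no observations at the earliest timepoint")
  series$volume <- series$volume / mean(v0)
  attr(series, "dimensionless") <- TRUE
  series
}

# Self-start for the 3-parameter logistic: Asym0 slightly above the largest
# observation, then a logit-linear regression for tmid0 and scal0.
logistic_selfstart <- function(t, v, asym_factor = 1.05) {
  asym0 <- asym_factor * max(v)
  p <- pmin(pmax(v / asym0, 1e-6), 1 - 1e-6)
  z <- log(p / (1 - p))              # z = (t - tmid)/scal under the model
  fit <- stats::lm(z ~ t)
  slope <- stats::coef(fit)[["t"]]
  if (!is.finite(slope) || slope <= 0) {
    scal0 <- diff(range(t)) / 4
    tmid0 <- stats::median(t)
  } else {
    scal0 <- 1 / slope
    tmid0 <- -stats::coef(fit)[["(Intercept)"]] * scal0
  }
  list(Asym = asym0, tmid = tmid0, scal = scal0)
}

#' Fit the logistic growth model to a disc-volume time course
#'
#' Fits \code{V(t) = Asym / (1 + exp((tmid - t) / scal))} by nonlinear least
#' squares. Starting values are computed automatically (self-start):
#' \code{Asym0} is \code{asym_factor} times the largest observed volume, and
#' \code{tmid0}, \code{scal0} come from regressing \code{logit(V / Asym0)}
#' on time. \code{\link[stats]{nls}} performs the refinement, with a
#' Levenberg-Marquardt fallback (\code{\link[minpack.lm]{nlsLM}}) if the
#' Gauss-Newton iteration fails.
#'
#' @param series a \code{\link{volume_series}} with at least 4 distinct
#'   timepoints and positive, non-constant volumes.
#' @param asym_factor self-start inflation factor for \code{Asym0}; any
#'   value > 1 works.
#' @return an object of class \code{"logistic_fit"}: components
#'   \code{Asym}, \code{tmid}, \code{scal}, \code{residual_sse},
#'   \code{converged}, \code{n_obs}, the data, and the underlying
#'   \code{nls} object.
#' @seealso \code{\link{relative_growth_rate}},
#'   \code{\link{bootstrap_growth_rate}}
#' @export
fit_logistic <- function(series, asym_factor = 1.05) {
  series <- volume_series(series)
  if (length(unique(series$time_h)) < 4)
    stop("at least 4 distinct timepoints are required")
  if (stats::sd(series$volume) == 0)
    stop("degenerate data: all volumes are equal")
  if (asym_factor <= 1) stop("'asym_factor' must exceed 1")
  t <- series$time_h; v <- series$volume
  start <- logistic_selfstart(t, v, asym_factor)
  dat <- data.frame(t = t, v = v)
  form <- v ~ Asym / (1 + exp((tmid - t) / scal))
  fit <- tryCatch(
    stats::nls(form, data = dat, start = start,
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = c(Asym = 0, tmid = -Inf, scal = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  if (is.null(fit))
    stop("logistic fit failed to converge")
  cf <- stats::coef(fit)
  if (cf[["Asym"]] <= 0 || cf[["scal"]] <= 0)
    stop("logistic fit converged to non-positive Asym or scal")
  structure(
    list(Asym = cf[["Asym"]], tmid = cf[["tmid"]], scal = cf[["scal"]],
         coefficients = cf,
         residual_sse = sum(stats::residuals(fit)^2),
         converged = TRUE, n_obs = nrow(series),
         data = series, nls = fit, call = match.call()),
    class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
fitted.logistic_fit <- function(object, ...)
  logistic_volume(object$data$time_h, object$Asym, object$tmid, object$scal)

#' @export
residuals.logistic_fit <- function(object, ...)
  object$data$volume - fitted(object)

#' Predicted volumes from a logistic fit
#'
#' @param object a \code{"logistic_fit"}.
#' @param times times (h AEL) at which to evaluate the curve; defaults to
#'   the observed times.
#' @param ... unused.
#' @return predicted volumes.
#' @export
predict.logistic_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  logistic_volume(times, object$Asym, object$tmid, object$scal)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic growth fit: V(t) = Asym / (1 + exp((tmid - t)/scal))\n")
  cat(sprintf("  Asym = %.4g   tmid = %.4g h   scal = %.4g h\n",
              x$Asym, x$tmid, x$scal))
  cat(sprintf("  n = %d observations, residual SSE = %.4g\n",
              x$n_obs, x$residual_sse))
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  s <- summary(object$nls)
  rate <- relative_growth_rate(object,
                               times = range(object$data$time_h))
  structure(list(fit = object, nls_summary = s, rate_endpoints = rate),
            class = "summary.logistic_fit")
}

#' @export
print.summary.logistic_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates:\n")
  stats::printCoefmat(x$nls_summary$coefficients)
  r <- x$rate_endpoints
  cat(sprintf(
    "\nRelative growth rate: %.3f /h at %g h AEL -> %.3f /h at %g h AEL\n",
    r$rate_per_h[1], r$time_h[1], r$rate_per_h[2], r$time_h[2]))
  invisible(x)
}

#' @export
plot.logistic_fit <- function(x, ...) {
  d <- x$data
  grid <- seq(min(d$time_h), max(d$time_h), length.out = 200)
  plot(d$time_h, d$volume, xlab = "time (h AEL)", ylab = "volume",
       main = "Logistic growth fit", ...)
  graphics::lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate volume tables from a fitted logistic model
#'
#' Draws new replicate tables at the observed design, with multiplicative
#' log-normal noise whose scale is estimated from the fit's log-residuals
#' (parametric bootstrap style).
#'
#' @param object a \code{"logistic_fit"}.
#' @param nsim number of simulated tables.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of \code{nsim} \code{\link{volume_series}} objects.
#' @export
simulate.logistic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sdlog <- stats::sd(log(object$data$volume) - log(mu))
  lapply(seq_len(nsim), function(i) {
    out <- object$data
    out$volume <- mu * exp(stats::rnorm(length(mu), 0, sdlog))
    out
  })
}

#' Relative growth rate of a fitted logistic curve
#'
#' The relative growth rate is \code{(dV/dt) / V}. For the logistic law it
#' has the closed form \code{(1/scal) * (1 - V(t)/Asym)} — the exact
#' derivative divided by the instantaneous volume, computed analytically
#' rather than by numeric differentiation. It is strictly positive and
#' strictly decreasing in time, from a plateau of \code{1/scal} at early
#' times, through \code{1/(2*scal)} at \code{tmid}, towards 0.
#'
#' @param fit a \code{"logistic_fit"}.
#' @param times evaluation grid in h AEL; defaults to 0.5 h steps over the
#'   observed time range.
#' @return data frame of class \code{"growth_rate_series"} with columns
#'   \code{time_h} and \code{rate_per_h}.
#' @export
relative_growth_rate <- function(fit, times = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (is.null(times))
    times <- seq(min(fit$data$time_h), max(fit$data$time_h), by = 0.5)
  v <- logistic_volume(times, fit$Asym, fit$tmid, fit$scal)
  out <- data.frame(time_h = times,
                    rate_per_h = (1 / fit$scal) * (1 - v / fit$Asym))
  class(out) <- c("growth_rate_series", "data.frame")
  out
}

#' Bootstrap uncertainty ribbon for the relative growth rate
#'
#' Case-resamples the observations with replacement \emph{within each
#' timepoint} (stratified resampling, preserving the unequal per-timepoint
#' design), refits the logistic model to each resample, evaluates the
#' relative growth rate on the grid and reports the per-time standard
#' deviation across successful refits.
#'
#' Resampling n-from-n within a stratum deflates the bootstrap variance by
#' the factor (n - 1)/n; with the small per-timepoint cohorts typical of
#' disc volumetry (5-6 discs) this bias is material, so the reported SD
#' carries the standard finite-sample rescaling sqrt(n/(n - 1)), using the
#' mean stratum size.
#'
#' @param series a \code{\link{volume_series}} on which
#'   \code{\link{fit_logistic}} succeeds.
#' @param times evaluation grid; default as in
#'   \code{\link{relative_growth_rate}}.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for reproducible ribbons.
#' @return a \code{"growth_rate_series"} with an extra \code{boot_sd}
#'   column; attributes \code{n_boot} and \code{n_failed} record the
#'   resampling outcome.
#' @export
bootstrap_growth_rate <- function(series, times = NULL, n_boot = 500,
                                  seed = NULL) {
  series <- volume_series(series)
  fit0 <- fit_logistic(series)
  if (is.null(times))
    times <- seq(min(series$time_h), max(series$time_h), by = 0.5)
  if (!is.null(seed)) set.seed(seed)
  strata <- split(seq_len(nrow(series)), series$time_h)
  rates <- matrix(NA_real_, length(times), n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]))
    refit <- tryCatch(fit_logistic(series[idx, , drop = FALSE]),
                      error = function(e) NULL)
    if (is.null(refit)) { n_failed <- n_failed + 1L; next }
    rates[, b] <- relative_growth_rate(refit, times)$rate_per_h
  }
  if (n_failed > 0.2 * n_boot)
    stop(sprintf(
      "bootstrap failed: %d of %d refits did not converge", n_failed,
      n_boot))
  out <- relative_growth_rate(fit0, times)
  n_bar <- mean(lengths(strata))
  rescale <- if (n_bar > 1) sqrt(n_bar / (n_bar - 1)) else 1
  out$boot_sd <- rescale * apply(rates, 1, stats::sd, na.rm = TRUE)
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- n_failed
  out
}
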