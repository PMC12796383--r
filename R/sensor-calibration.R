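#' Normalise reporter intensities to their normoxia controls
#'
#' Divides every intensity by the mean intensity of the normoxia group
#' (20.9 percent O2 by default), so the normalised normoxia mean is exactly
#' 1. If a \code{batch} column is present (or \code{batch} names one), each
#' batch is normalised to its own normoxia controls.
#'
#' @param table data frame with columns \code{o2_percent},
#'   \code{intensity} and optionally \code{replicate}, \code{batch}.
#' @param normoxia_o2 oxygen level of the reference group, percent.
#' @param batch optional name of a batch column; default uses
#'   \code{"batch"} if present.
#' @return the table with normalised intensities, class
#'   \code{"oxygen_response"}.
#' @export
normalize_to_normoxia <- function(table, normoxia_o2 = 20.9,
                                  batch = NULL) {
  if (!all(c("o2_percent", "intensity") %in% names(table)))
    stop("need columns 'o2_percent' and 'intensity'")
  if (is.null(batch) && "batch" %in% names(table)) batch <- "batch"
  norm_one <- function(d) {
    ref <- d$intensity[abs(d$o2_percent - normoxia_o2) < 1e-9]
    if (length(ref) == 0)
      stop(sprintf("no normoxia (%.1f%% O2) group to normalise to",
                   normoxia_o2))
    if (mean(ref) <= 0) stop("normoxia group has non-positive mean")
    d$intensity <- d$intensity / mean(ref)
    d
  }
  out <- if (is.null(batch)) norm_one(table) else {
    parts <- split(table, table[[batch]])
    do.call(rbind, lapply(parts, norm_one))
  }
  rownames(out) <- NULL
  if (!inherits(out, "oxygen_response"))
    class(out) <- c("oxygen_response", class(out))
  out
}

#' Fit the two-regime (segmented) oxygen-response calibration
#'
#' Calibrates a hypoxia reporter from a normalised dose-response table by
#' fitting two regimes: an ordinary least-squares line \code{I = m*O2 + k}
#' over the responsive oxygen range, and a zero-slope plateau \code{I = c}
#' (the plain mean) over the upper range. The boundary level (18.0 percent
#' by default) belongs to both regimes, matching the stated ranges of the
#' calibration protocol; set \code{boundary_shared = FALSE} for exclusive
#' assignment to the plateau. By default the regression runs on per-level
#' mean intensities (\code{per_level_mean = TRUE}); set it to \code{FALSE}
#' to regress on individual replicate points.
#'
#' The derived \emph{sensitivity breakpoint} is the oxygen level where the
#' two regimes intersect, \code{(c - k)/m}: the mildest hypoxia the sensor
#' resolves. The \emph{dynamic range} is the fold-increase of the
#' responsive line at \code{floor_o2} over the plateau,
#' \code{(m*floor_o2 + k)/c}.
#'
#' A non-responsive fit (\code{m >= 0}) is flagged with a warning and the
#' derived quantities are withheld as \code{NA}.
#'
#' @param table an \code{"oxygen_response"} data frame (see
#'   \code{\link{normalize_to_normoxia}}).
#' @param responsive_range inclusive O2 interval (percent) of the linear
#'   regime; needs >= 2 distinct levels.
#' @param plateau_range inclusive O2 interval of the flat regime; needs
#'   >= 1 level.
#' @param per_level_mean regress on per-level means (default) rather than
#'   per-replicate points.
#' @param boundary_shared include a level on the shared boundary of the two
#'   ranges in both fits.
#' @param floor_o2 oxygen level at which the dynamic range is evaluated.
#' @return object of class \code{"piecewise_calibration"} with components
#'   \code{m}, \code{k}, \code{c}, \code{breakpoint}, \code{dynamic_range},
#'   \code{responsive}, the ranges, point counts and the underlying
#'   \code{lm} fit.
#' @export
fit_piecewise <- function(table, responsive_range = c(5.0, 18.0),
                          plateau_range = c(18.0, 20.9),
                          per_level_mean = TRUE, boundary_shared = TRUE,
                          floor_o2 = 5.0) {
  if (!all(c("o2_percent", "intensity") %in% names(table)))
    stop("need columns 'o2_percent' and 'intensity'")
  stopifnot(length(responsive_range) == 2, length(plateau_range) == 2)
  pts <- data.frame(o2 = table$o2_percent, I = table$intensity)
  if (per_level_mean) {
    agg <- stats::aggregate(I ~ o2, data = pts, FUN = mean)
    pts <- agg
  }
  eps <- 1e-9
  in_resp <- pts$o2 >= responsive_range[1] - eps &
    pts$o2 <= responsive_range[2] + eps
  in_plat <- pts$o2 >= plateau_range[1] - eps &
    pts$o2 <= plateau_range[2] + eps
  if (!boundary_shared) {
    on_boundary <- abs(pts$o2 - responsive_range[2]) < eps &
      abs(pts$o2 - plateau_range[1]) < eps
    in_resp <- in_resp & !on_boundary
  }
  resp <- pts[in_resp, , drop = FALSE]
  plat <- pts[in_plat, , drop = FALSE]
  if (length(unique(resp$o2)) < 2)
    stop("need >= 2 distinct O2 levels in the responsive range")
  if (nrow(plat) < 1)
    stop("need >= 1 observation in the plateau range")
  line <- stats::lm(I ~ o2, data = resp)
  m <- stats::coef(line)[["o2"]]
  k <- stats::coef(line)[["(Intercept)"]]
  cc <- mean(plat$I)
  responsive <- is.finite(m) && m < 0
  if (!responsive)
    warning("fitted slope m >= 0: sensor is non-responsive; ",
            "breakpoint and dynamic range withheld")
  structure(
    list(m = m, k = k, c = cc,
         breakpoint = if (responsive) (cc - k) / m else NA_real_,
         dynamic_range = if (responsive) (m * floor_o2 + k) / cc
                         else NA_real_,
         responsive = responsive,
         responsive_range = responsive_range,
         plateau_range = plateau_range, floor_o2 = floor_o2,
         n_responsive = nrow(resp), n_plateau = nrow(plat),
         per_level_mean = per_level_mean, lm = line,
         call = match.call()),
    class = "piecewise_calibration")
}

#' @export
coef.piecewise_calibration <- function(object, ...)
  c(m = object$m, k = object$k, c = object$c)

#' Predicted normalised intensity of a calibrated sensor
#'
#' @param object a \code{"piecewise_calibration"}.
#' @param o2 environmental oxygen percentages.
#' @param ... unused.
#' @return predicted intensities: the responsive line below the breakpoint,
#'   the plateau at and above it.
#' @export
predict.piecewise_calibration <- function(object, o2, ...) {
  if (!object$responsive)
    stop("non-responsive fit: no piecewise prediction")
  ifelse(o2 < object$breakpoint, object$m * o2 + object$k, object$c)
}

#' @export
print.piecewise_calibration <- function(x, ...) {
  cat("Two-regime oxygen-response calibration\n")
  cat(sprintf("  responsive line: I = %.4g * O2 + %.4g  (%g-%g%% O2)\n",
              x$m, x$k, x$responsive_range[1], x$responsive_range[2]))
  cat(sprintf("  plateau:         I = %.4g  (%g-%g%% O2)\n",
              x$c, x$plateau_range[1], x$plateau_range[2]))
  if (x$responsive) {
    cat(sprintf("  sensitivity breakpoint: %.2f%% O2\n", x$breakpoint))
    cat(sprintf("  dynamic range: %.2f-fold at %g%% O2\n",
                x$dynamic_range, x$floor_o2))
  } else cat("  sensor flagged non-responsive (m >= 0)\n")
  invisible(x)
}

#' @export
plot.piecewise_calibration <- function(x, ...) {
  d <- x$lm$model
  grid <- seq(x$responsive_range[1], x$plateau_range[2], length.out = 200)
  plot(d$o2, d$I, xlab = "environmental O2 (%)",
       ylab = "normalised intensity", main = "Sensor calibration", ...)
  if (x$responsive)
    graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Sensitivity breakpoint of a calibrated sensor
#'
#' The mildest hypoxia the sensor resolves: the oxygen level where the
#' responsive line meets the plateau, \code{(c - k)/m}. By construction the
#' responsive line evaluated there equals the plateau constant.
#'
#' @param fit a responsive \code{"piecewise_calibration"}.
#' @return breakpoint in percent O2.
#' @export
sensitivity <- function(fit) {
  stopifnot(inherits(fit, "piecewise_calibration"))
  if (!fit$responsive) stop("sensor is non-responsive (m >= 0)")
  (fit$c - fit$k) / fit$m
}

#' Dynamic range of a calibrated sensor
#'
#' Fold-increase of the responsive line at \code{floor_o2} over the plateau
#' constant: \code{(m*floor_o2 + k)/c}. Exceeds 1 for any responsive
#' sensor evaluated below its breakpoint.
#'
#' @param fit a responsive \code{"piecewise_calibration"}.
#' @param floor_o2 evaluation level, percent O2; must lie below the
#'   breakpoint.
#' @return dimensionless fold-change.
#' @export
dynamic_range <- function(fit, floor_o2 = 5.0) {
  stopifnot(inherits(fit, "piecewise_calibration"))
  if (!fit$responsive) stop("sensor is non-responsive (m >= 0)")
  if (floor_o2 >= sensitivity(fit))
    stop("'floor_o2' must lie below the sensitivity breakpoint")
  (fit$m * floor_o2 + fit$k) / fit$c
}

#' Bootstrap confidence interval for the sensitivity breakpoint
#'
#' Resamples replicates with replacement within each oxygen level, refits
#' the two-regime calibration and returns percentile quantiles of the
#' breakpoint. This interval is an extension beyond the plain calibration
#' protocol.
#'
#' @param table an \code{"oxygen_response"} table.
#' @param n_boot number of resamples.
#' @param seed RNG seed.
#' @param probs quantiles to report.
#' @param ... passed to \code{\link{fit_piecewise}}.
#' @return named numeric vector of breakpoint quantiles, with the number of
#'   failed refits in \code{attr(, "n_failed")}.
#' @export
bootstrap_breakpoint <- function(table, n_boot = 1000, seed = NULL,
                                 probs = c(0.025, 0.975), ...) {
  if (!is.null(seed)) set.seed(seed)
  strata <- split(seq_len(nrow(table)), table$o2_percent)
  bps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]))
    f <- tryCatch(
      suppressWarnings(fit_piecewise(table[idx, , drop = FALSE], ...)),
      error = function(e) NULL)
    if (!is.null(f) && f$responsive) bps[b] <- f$breakpoint
  }
  out <- stats::quantile(bps, probs, na.rm = TRUE)
  attr(out, "n_failed") <- sum(is.na(bps))
  out
}
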