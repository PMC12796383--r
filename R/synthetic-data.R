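#' Simulation configuration
#'
#' Bundles the design of a simulated experiment: the RNG seed, the
#' coefficient of variation of the multiplicative (log-normal) noise, the
#' sampling timepoints in hours after egg laying (h AEL) and the number of
#' biological replicates at each timepoint.
#'
#' The default design is the bulk RNA-seq time course used throughout the
#' package: seven timepoints from 80 to 118 h AEL with three biological
#' replicates each, except two replicates at 80 h.
#'
#' All generators draw their noise as \code{exp(e)} with
#' \code{e ~ N(0, sqrt(log(1 + cv^2)))}, so the multiplicative factor has
#' coefficient of variation exactly \code{noise_cv}. Fluorescence and volume
#' measurements are positive and heteroscedastic, which this noise model
#' respects.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 switches noise off entirely).
#' @param timepoints strictly increasing vector of times in h AEL.
#' @param replicates_per_timepoint integer vector aligned to
#'   \code{timepoints}.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       noise_cv = 0.1,
                       timepoints = c(80, 88, 96, 104, 112, 116, 118),
                       replicates_per_timepoint = c(2L, rep(3L, 6))) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("'noise_cv' must be a single non-negative number")
  if (any(diff(timepoints) <= 0))
    stop("'timepoints' must be strictly increasing")
  if (length(replicates_per_timepoint) != length(timepoints))
    stop("'replicates_per_timepoint' must align with 'timepoints'")
  if (any(replicates_per_timepoint < 1))
    stop("each timepoint needs at least one replicate")
  structure(
    list(seed = as.integer(seed), noise_cv = noise_cv,
         timepoints = as.numeric(timepoints),
         replicates_per_timepoint = as.integer(replicates_per_timepoint)),
    class = "sim_config")
}

#' Default design for simulated disc-volume cohorts
#'
#' Volume time courses are sampled every 4 h from 72 h AEL (L2-L3
#' transition) to 116 h plus a final point at 118 h, with six discs per
#' timepoint except five at 84 h — the design of the volumetric growth
#' study this package models.
#'
#' @inheritParams sim_config
#' @return a \code{"sim_config"}.
#' @export
volume_sim_config <- function(seed = 1L, noise_cv = 0.05) {
  tp <- c(seq(72, 116, by = 4), 118)
  reps <- ifelse(tp == 84, 5L, 6L)
  sim_config(seed = seed, noise_cv = noise_cv, timepoints = tp,
             replicates_per_timepoint = reps)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Multiplicative log-normal factors with coefficient of variation `cv`.
mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sigma))
}

#' Logistic volume curve
#'
#' Evaluates \code{Asym / (1 + exp((tmid - t) / scal))}, the three-parameter
#' logistic growth law used for wing-disc volumes.
#'
#' @param t time(s) in h AEL.
#' @param Asym asymptotic maximum volume.
#' @param tmid time at which the volume reaches \code{Asym/2}.
#' @param scal steepness scale in hours.
#' @return volumes at \code{t}.
#' @export
logistic_volume <- function(t, Asym, tmid, scal) {
  Asym / (1 + exp((tmid - t) / scal))
}

#' Simulate a disc-volume time course
#'
#' Draws replicate disc volumes around a planted logistic growth curve with
#' multiplicative log-normal noise. The default planted parameters
#' (\code{Asym = 21.5}, \code{tmid = 104}, \code{scal = 10.6}, volumes on a
#' dimensionless fold-of-initial scale) give a relative growth rate that
#' declines from about 9 percent per hour at 72 h AEL to about 2 percent per
#' hour at 118 h AEL, the deceleration observed over the third larval
#' instar.
#'
#' @param config a \code{\link{sim_config}}; defaults to
#'   \code{\link{volume_sim_config}()}.
#' @param Asym,tmid,scal planted logistic parameters (\code{Asym > 0},
#'   \code{scal > 0}).
#' @return a data frame of class \code{"volume_series"} with columns
#'   \code{time_h}, \code{volume}, \code{replicate}, carrying the planted
#'   truth in \code{attr(, "truth")}.
#' @export
gen_volume_series <- function(config = volume_sim_config(),
                              Asym = 21.5, tmid = 104, scal = 10.6) {
  stopifnot(inherits(config, "sim_config"))
  if (Asym <= 0 || scal <= 0)
    stop("'Asym' and 'scal' must be positive")
  tp <- rep(config$timepoints, config$replicates_per_timepoint)
  rep_id <- unlist(lapply(config$replicates_per_timepoint, seq_len))
  v_true <- logistic_volume(tp, Asym, tmid, scal)
  fac <- with_seed(config$seed, mult_noise(length(tp), config$noise_cv))
  out <- data.frame(time_h = tp, volume = v_true * fac,
                    replicate = rep_id)
  attr(out, "truth") <- list(Asym = Asym, tmid = tmid, scal = scal,
                             noise_cv = config$noise_cv,
                             seed = config$seed)
  class(out) <- c("volume_series", "data.frame")
  out
}

#' Simulate a gene-by-replicate expression time course with planted classes
#'
#' Generates a normalised expression matrix in which \emph{tracking} genes
#' are positive affine transforms of a growth-rate profile, \emph{anti-
#' tracking} genes are negative affine transforms, and \emph{null} genes are
#' drawn independently of it, all with multiplicative log-normal replicate
#' noise. Expression values represent post-normalisation abundances (the
#' matrix a differential-expression pipeline would emit), not raw counts.
#'
#' Null genes are redrawn while the Pearson correlation of their noiseless
#' profile with \code{rate_profile} reaches \code{null_r_guard} in absolute
#' value, so the planted class labels are unambiguous even without noise.
#' Only the extreme tail of the null distribution (about 2 percent of draws
#' at the default guard) is resampled.
#'
#' @param config a \code{\link{sim_config}} giving timepoints, replicates,
#'   noise and seed.
#' @param n_tracking,n_anti,n_null numbers of genes in each planted class
#'   (total must be >= 1).
#' @param rate_profile growth rate evaluated at \code{config$timepoints};
#'   same length as the timepoints.
#' @param base_level median expression level around which genes are scaled.
#' @param null_r_guard absolute-correlation bound enforced on noiseless
#'   null profiles.
#' @return numeric matrix (genes x replicate columns, named
#'   \code{"<timepoint>_rep<k>"}) with \code{attr(, "truth")}: a data frame
#'   of gene and planted class, plus the rate profile used.
#' @export
gen_expression_timecourse <- function(config = sim_config(),
                                      n_tracking = 100L, n_anti = 100L,
                                      n_null = 800L, rate_profile,
                                      base_level = 100,
                                      null_r_guard = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  n_tracking <- as.integer(n_tracking); n_anti <- as.integer(n_anti)
  n_null <- as.integer(n_null)
  if (any(c(n_tracking, n_anti, n_null) < 0) ||
      n_tracking + n_anti + n_null < 1L)
    stop("gene counts must be non-negative and total at least 1")
  tp <- config$timepoints
  if (length(rate_profile) != length(tp))
    stop("'rate_profile' must have one value per timepoint")
  if (stats::sd(rate_profile) == 0)
    stop("'rate_profile' must not be constant")

  n_tp <- length(tp)
  reps <- config$replicates_per_timepoint
  # affine map of the rate profile onto [0.5, 1.5] x gene level: positive
  # everywhere, slope sign carries the class
  unit <- (rate_profile - min(rate_profile)) / diff(range(rate_profile))
  with_seed(config$seed, {
    classes <- rep(c("tracking", "anti_tracking", "null"),
                   c(n_tracking, n_anti, n_null))
    n_genes <- length(classes)
    levels_g <- base_level * exp(stats::rnorm(n_genes, 0, 0.5))
    profiles <- matrix(NA_real_, n_genes, n_tp)
    for (g in seq_len(n_genes)) {
      profiles[g, ] <- switch(classes[g],
        tracking = levels_g[g] * (0.5 + unit),
        anti_tracking = levels_g[g] * (1.5 - unit),
        null = {
          repeat {
            p <- levels_g[g] * exp(stats::rnorm(n_tp, 0, 0.4))
            if (stats::sd(p) > 0 &&
                abs(stats::cor(p, rate_profile)) < null_r_guard) break
          }
          p
        })
    }
    values <- profiles[, rep(seq_len(n_tp), reps), drop = FALSE]
    values <- values * matrix(mult_noise(length(values), config$noise_cv),
                              nrow = n_genes)
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    rownames(values) <- genes
    colnames(values) <- unlist(lapply(seq_len(n_tp), function(i)
      sprintf("%g_rep%d", tp[i], seq_len(reps[i]))))
    # columns grouped by timepoint
    ord <- order(rep(seq_len(n_tp), reps))
    values <- values[, ord, drop = FALSE]
    attr(values, "timepoints") <- tp
    attr(values, "truth") <- list(
      classes = data.frame(gene = genes, class = classes,
                           stringsAsFactors = FALSE),
      rate_profile = rate_profile)
    values
  })
}

#' Simulate a two-regime oxygen dose-response table
#'
#' Emulates the calibration experiment of a hypoxia-activated fluorescent
#' reporter: below the sensitivity breakpoint the normalised intensity
#' follows the responsive line \code{I = m * O2 + k} (with \code{m < 0}:
#' intensity rises as oxygen falls); at and above the breakpoint it sits on
#' the plateau \code{I = c}. Replicates carry multiplicative log-normal
#' noise.
#'
#' The default planted parameters reproduce a sensor with a sensitivity
#' breakpoint at 17.09 percent O2 and a 4-fold intensity increase at
#' 5 percent O2 relative to the normoxic plateau (\code{c = 1}).
#'
#' @param config a \code{\link{sim_config}} (only seed and noise are used).
#' @param m slope of the responsive regime, intensity per percent O2
#'   (must be negative).
#' @param k intercept of the responsive regime.
#' @param c_plateau plateau intensity at and above the breakpoint.
#' @param levels tested environmental oxygen percentages; must straddle the
#'   planted breakpoint \code{(c_plateau - k) / m}.
#' @param reps replicates per oxygen level.
#' @return data frame of class \code{"oxygen_response"} with columns
#'   \code{o2_percent}, \code{intensity}, \code{replicate}; planted truth in
#'   \code{attr(, "truth")}.
#' @export
gen_oxygen_response <- function(config = sim_config(noise_cv = 0.05),
                                m = -3 / 12.09, k = 4 - 5 * (-3 / 12.09),
                                c_plateau = 1,
                                levels = c(5, 8, 11, 14, 18, 20.9),
                                reps = 6L) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  if (m >= 0) stop("'m' must be negative: intensity rises as O2 falls")
  bp <- (c_plateau - k) / m
  if (bp <= min(levels) || bp >= max(levels))
    stop(sprintf(
      "planted breakpoint %.3f%% O2 lies outside the tested levels", bp))
  o2 <- rep(levels, each = reps)
  mu <- ifelse(o2 < bp, m * o2 + k, c_plateau)
  fac <- with_seed(config$seed, mult_noise(length(o2), config$noise_cv))
  out <- data.frame(o2_percent = o2, intensity = mu * fac,
                    replicate = rep(seq_len(reps), times = length(levels)))
  attr(out, "truth") <- list(m = m, k = k, c = c_plateau, breakpoint = bp,
                             dynamic_range = (m * 5 + k) / c_plateau,
                             noise_cv = config$noise_cv)
  class(out) <- c("oxygen_response", "data.frame")
  out
}

#' Simulate a two-compartment disc image with masks and planted truth
#'
#' Builds a single-plane intensity image of an elliptical "wing pouch"
#' split into anterior (A, left) and posterior (P, right) compartments.
#' All A pixels carry signal at \code{a_mean}; a fixed fraction of P pixels
#' (chosen at seeded random positions, count rounded to the nearest pixel)
#' carry signal at \code{p_mean}; everything else sits at
#' \code{background}. Multiplicative log-normal noise is applied per pixel.
#'
#' @param config a \code{\link{sim_config}} (seed and noise only).
#' @param shape image dimensions in pixels, \code{c(rows, cols)}; both
#'   must be at least 8.
#' @param a_mean,p_mean planted signal intensities of the A and P
#'   compartments (must exceed \code{background}).
#' @param background intensity outside signal regions (>= 0).
#' @param positive_fraction_p fraction of P-compartment pixels carrying
#'   signal, in [0, 1].
#' @return list of class \code{"disc_image"}: \code{image} (numeric
#'   matrix), logical masks \code{mask_a}, \code{mask_p}, \code{mask_pouch},
#'   and \code{truth}.
#' @export
gen_disc_image <- function(config = sim_config(noise_cv = 0),
                           shape = c(128L, 128L),
                           a_mean = 100, p_mean = 200, background = 10,
                           positive_fraction_p = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (length(shape) != 2L || any(shape < 8))
    stop("'shape' must give at least 8 x 8 pixels")
  if (background < 0 || a_mean <= background || p_mean <= background)
    stop("compartment means must exceed a non-negative background")
  if (positive_fraction_p < 0 || positive_fraction_p > 1)
    stop("'positive_fraction_p' must lie in [0, 1]")
  nr <- shape[1]; nc <- shape[2]
  row_i <- matrix(seq_len(nr), nr, nc)
  col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # elliptical pouch centred in the frame
  pouch <- ((row_i - (nr + 1) / 2) / (0.4 * nr))^2 +
    ((col_i - (nc + 1) / 2) / (0.4 * nc))^2 <= 1
  mask_a <- pouch & col_i <= nc / 2
  mask_p <- pouch & col_i > nc / 2
  img <- matrix(background, nr, nc)
  img[mask_a] <- a_mean
  with_seed(config$seed, {
    p_idx <- which(mask_p)
    n_pos <- round(positive_fraction_p * length(p_idx))
    pos <- if (n_pos > 0) sample(p_idx, n_pos) else integer(0)
    img[pos] <- p_mean
    img <- img * matrix(mult_noise(length(img), config$noise_cv), nr, nc)
  })
  structure(
    list(image = img, mask_a = mask_a, mask_p = mask_p, mask_pouch = pouch,
         truth = list(a_mean = a_mean, p_mean = p_mean,
                      background = background,
                      positive_fraction_p = positive_fraction_p,
                      n_positive_p = round(positive_fraction_p *
                                             sum(mask_p)),
                      noise_cv = config$noise_cv)),
    class = "disc_image")
}

#' Simulate cumulative pupariation counts
#'
#' Draws individual pupariation times from a logistic distribution centred
#' at \code{t50_true} (any sigmoid would do; the logistic has closed-form
#' quantiles) and tallies the cumulative number of pupariated larvae at each
#' observation time, emulating 4-hourly scoring of larval cohorts.
#'
#' @param config a \code{\link{sim_config}} (seed only).
#' @param n_larvae cohort size (> 0).
#' @param t50_true time at which half the cohort has pupariated, h AEL.
#' @param spread scale of the logistic pupariation-time distribution in
#'   hours; 0 collapses all larvae onto \code{t50_true}.
#' @param observation_times increasing scoring times in h AEL.
#' @return data frame of class \code{"pupariation_table"} with columns
#'   \code{time_h} and \code{pupariated}; cohort size and truth in
#'   attributes.
#' @export
gen_pupariation_counts <- function(config = sim_config(),
                                   n_larvae = 210L, t50_true = 120,
                                   spread = 3,
                                   observation_times = seq(96, 160, by = 4)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_larvae <= 0) stop("'n_larvae' must be positive")
  if (any(diff(observation_times) <= 0))
    stop("'observation_times' must be strictly increasing")
  if (spread < 0) stop("'spread' must be non-negative")
  times <- with_seed(config$seed, {
    if (spread == 0) rep(t50_true, n_larvae)
    else stats::rlogis(n_larvae, location = t50_true, scale = spread)
  })
  counts <- vapply(observation_times,
                   function(tt) sum(times <= tt), integer(1))
  out <- data.frame(time_h = observation_times, pupariated = counts)
  attr(out, "n_larvae") <- as.integer(n_larvae)
  attr(out, "truth") <- list(t50 = t50_true, spread = spread)
  class(out) <- c("pupariation_table", "data.frame")
  out
}
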