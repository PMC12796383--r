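#' Background-exclusion threshold for a pixel set
#'
#' Resolves a \code{threshold_mode} argument to a numeric cutoff: either a
#' fixed value, or \code{"otsu"} for an automatic Otsu threshold on the
#' ROI's own intensity histogram (via \code{\link[EBImage]{otsu}}). A
#' constant ROI has no histogram valley; its threshold is placed just below
#' the constant so every pixel counts as signal.
#'
#' @param values numeric vector of pixel intensities (e.g. the ROI pixels).
#' @param threshold_mode \code{"otsu"} or a single numeric cutoff.
#' @return the numeric threshold; pixels strictly above it are signal.
#' @export
resolve_threshold <- function(values, threshold_mode = "otsu") {
  if (is.numeric(threshold_mode)) {
    stopifnot(length(threshold_mode) == 1L, is.finite(threshold_mode))
    return(threshold_mode)
  }
  if (!identical(threshold_mode, "otsu"))
    stop("'threshold_mode' must be \"otsu\" or a numeric cutoff")
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1] - abs(rng[1]) * 1e-9 - 1e-12)
  EBImage::otsu(matrix(values, ncol = 1L), range = rng)
}

#' Mean fluorescence intensity over a thresholded ROI
#'
#' Applies a background-exclusion threshold inside a region of interest to
#' form a binary signal mask, then reports the mean intensity over the
#' signal pixels — the single-confocal-plane quantification rule used for
#' wing-pouch and compartment intensities. If no pixel clears the
#' threshold the mean is undefined and the result is flagged.
#'
#' @param image 2-D numeric intensity matrix (single plane).
#' @param roi_mask logical matrix of the same shape, \code{TRUE} inside the
#'   ROI; must be non-empty.
#' @param threshold_mode \code{"otsu"} (default) or a fixed numeric cutoff;
#'   see \code{\link{resolve_threshold}}.
#' @return list of class \code{"roi_quantification"}: \code{n_pixels},
#'   \code{n_signal}, \code{mean_intensity}, \code{area_fraction_pct},
#'   \code{threshold} and \code{flagged} (no signal pixels).
#' @export
roi_mean_intensity <- function(image, roi_mask, threshold_mode = "otsu") {
  image <- as.matrix(image); roi_mask <- as.matrix(roi_mask)
  if (!identical(dim(image), dim(roi_mask)))
    stop("image and mask shapes differ")
  roi_mask <- roi_mask > 0
  if (!any(roi_mask)) stop("empty ROI")
  px <- image[roi_mask]
  thr <- resolve_threshold(px, threshold_mode)
  signal <- px > thr
  flagged <- !any(signal)
  if (flagged)
    warning("no pixels above threshold in ROI; mean intensity undefined")
  structure(
    list(n_pixels = length(px), n_signal = sum(signal),
         mean_intensity = if (flagged) NA_real_ else mean(px[signal]),
         area_fraction_pct = 100 * sum(signal) / length(px),
         threshold = thr, flagged = flagged),
    class = "roi_quantification")
}

#' @export
print.roi_quantification <- function(x, ...) {
  cat(sprintf(
    "ROI: %d px, %d signal px (%.1f%%), mean intensity %.4g (thr %.4g)\n",
    x$n_pixels, x$n_signal, x$area_fraction_pct, x$mean_intensity,
    x$threshold))
  invisible(x)
}

#' Posterior-to-anterior compartment intensity ratio
#'
#' Normalises the perturbed posterior (P) compartment's mean intensity to
#' the internal-control anterior (A) compartment of the same disc.
#'
#' @param quant_a,quant_p \code{"roi_quantification"} results for the A and
#'   P compartments.
#' @return list of class \code{"compartment_ratio"}: \code{value} (P/A),
#'   \code{a_mean}, \code{p_mean}.
#' @export
pa_ratio <- function(quant_a, quant_p) {
  stopifnot(inherits(quant_a, "roi_quantification"),
            inherits(quant_p, "roi_quantification"))
  if (quant_a$flagged || quant_p$flagged)
    stop("undefined compartment mean: cannot form P/A ratio")
  if (!(quant_a$mean_intensity > 0))
    stop("A-compartment mean must be positive")
  structure(list(value = quant_p$mean_intensity / quant_a$mean_intensity,
                 a_mean = quant_a$mean_intensity,
                 p_mean = quant_p$mean_intensity),
            class = "compartment_ratio")
}

#' @export
print.compartment_ratio <- function(x, ...) {
  cat(sprintf("P/A intensity ratio: %.4g (P = %.4g, A = %.4g)\n",
              x$value, x$p_mean, x$a_mean))
  invisible(x)
}

#' Fluorescence-positive area fraction of a compartment
#'
#' Percentage of the compartment area occupied by fluorescence-positive
#' pixels, after background-exclusion thresholding within the compartment.
#'
#' @inheritParams roi_mean_intensity
#' @param compartment_mask logical matrix delimiting the compartment.
#' @return area fraction in percent (0-100).
#' @export
area_fraction <- function(image, compartment_mask,
                          threshold_mode = "otsu") {
  q <- roi_mean_intensity(image, compartment_mask, threshold_mode)
  q$area_fraction_pct
}

#' Per-nucleus red-to-green intensity ratio
#'
#' Quantifies a ratiometric maturation-based oxygen readout: nuclei are
#' isolated as connected components of a thresholded nuclear mask
#' (touching nuclei are not split), and each nucleus contributes the ratio
#' of its mean red to mean green intensity. Nuclei with zero green signal
#' are flagged and excluded from the cohort summary.
#'
#' @param red,green congruent 2-D intensity matrices for the two channels.
#' @param nuclei_mask logical matrix marking nuclear pixels; non-empty.
#' @return list of class \code{"ratio_quantification"}:
#'   \code{per_nucleus} data frame (label, n_pixels, red_mean, green_mean,
#'   ratio, excluded) and \code{summary_mean} over included nuclei.
#' @export
red_green_ratio <- function(red, green, nuclei_mask) {
  red <- as.matrix(red); green <- as.matrix(green)
  nuclei_mask <- as.matrix(nuclei_mask) > 0
  if (!identical(dim(red), dim(green)) ||
      !identical(dim(red), dim(nuclei_mask)))
    stop("channel and mask shapes differ")
  if (!any(nuclei_mask)) stop("empty nuclei mask")
  labels <- EBImage::bwlabel(nuclei_mask)
  labels <- as.matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  per <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    rg <- mean(red[sel]); gg <- mean(green[sel])
    data.frame(label = id, n_pixels = sum(sel), red_mean = rg,
               green_mean = gg,
               ratio = if (gg > 0) rg / gg else NA_real_,
               excluded = !(gg > 0))
  }))
  if (any(per$excluded))
    warning(sum(per$excluded),
            " nucleus/nuclei with zero green signal excluded")
  structure(list(per_nucleus = per,
                 summary_mean = mean(per$ratio[!per$excluded])),
            class = "ratio_quantification")
}

#' Trichome density from four inter-vein ROI counts
#'
#' Averages trichome-socket counts over the four equally sized inter-vein
#' ROIs of an adult wing and divides by the ROI area. The four-ROI design
#' is part of the protocol; a different number of ROIs must be authorised
#' explicitly with \code{allow_any_count}.
#'
#' @param counts trichome-socket counts, one per ROI (length 4 unless
#'   overridden).
#' @param roi_area area of each ROI, in the unit the density is to be
#'   expressed per.
#' @param allow_any_count permit a deviating number of ROIs.
#' @return trichomes per unit area.
#' @export
trichome_density <- function(counts, roi_area, allow_any_count = FALSE) {
  if (!allow_any_count && length(counts) != 4L)
    stop("the protocol uses exactly four inter-vein ROIs; pass ",
         "'allow_any_count = TRUE' to deviate explicitly")
  if (length(counts) == 0) stop("no ROI counts")
  if (!(roi_area > 0)) stop("'roi_area' must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  mean(counts) / roi_area
}

#' Pupariation T50 from cumulative counts
#'
#' The developmental-timing summary of a larval cohort: the time at which
#' half the population has pupariated. If an observation hits the 0.5
#' fraction exactly, its time is returned; otherwise T50 is linearly
#' interpolated between the bracketing observations. A cohort that never
#' reaches 50 percent is censored and yields \code{NA} with a warning.
#'
#' @param table a \code{"pupariation_table"} (columns \code{time_h},
#'   \code{pupariated}) or any data frame shaped like one.
#' @param n_larvae cohort size; taken from \code{attr(table, "n_larvae")}
#'   when absent.
#' @return T50 in hours, or \code{NA} if censored.
#' @export
t50_pupariation <- function(table, n_larvae = NULL) {
  if (!all(c("time_h", "pupariated") %in% names(table)))
    stop("need columns 'time_h' and 'pupariated'")
  if (is.null(n_larvae)) n_larvae <- attr(table, "n_larvae")
  if (is.null(n_larvae) || !(n_larvae > 0))
    stop("cohort size 'n_larvae' must be supplied (or attached)")
  if (is.unsorted(table$time_h, strictly = TRUE))
    stop("'time_h' must be strictly increasing")
  if (any(diff(table$pupariated) < 0))
    stop("cumulative counts must be non-decreasing")
  if (max(table$pupariated) > n_larvae)
    stop("counts exceed the cohort size")
  frac <- table$pupariated / n_larvae
  eps <- 1e-12
  hit <- which(abs(frac - 0.5) < eps)
  if (length(hit)) return(table$time_h[hit[1]])
  above <- which(frac > 0.5)
  if (!length(above)) {
    warning("cohort never reaches 50% pupariation: T50 censored")
    return(NA_real_)
  }
  j <- above[1]
  if (j == 1) return(table$time_h[1])
  t0 <- table$time_h[j - 1]; t1 <- table$time_h[j]
  f0 <- frac[j - 1]; f1 <- frac[j]
  t0 + (0.5 - f0) / (f1 - f0) * (t1 - t0)
}
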