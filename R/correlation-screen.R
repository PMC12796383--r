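#' Average replicate columns of an expression matrix per timepoint
#'
#' Collapses a gene x replicate matrix whose columns are named
#' \code{"<timepoint>_rep<k>"} (the layout written by
#' \code{\link{gen_expression_timecourse}} and expected from expression
#' CSV/TSV input) to one arithmetic mean per gene and timepoint.
#'
#' @param matrix gene x replicate numeric matrix with
#'   \code{"<timepoint>_rep<k>"} column names.
#' @return gene x timepoint matrix of replicate means, columns named by
#'   timepoint and ordered by increasing time.
#' @export
summarise_replicates <- function(matrix) {
  if (is.null(colnames(matrix)))
    stop("expression matrix must have '<timepoint>_rep<k>' column names")
  tp_chr <- sub("_rep.*$", "", colnames(matrix))
  tp <- suppressWarnings(as.numeric(tp_chr))
  if (any(is.na(tp)))
    stop("malformed column names (expected '<timepoint>_rep<k>'): ",
         paste(unique(colnames(matrix)[is.na(tp)]), collapse = ", "))
  levels_tp <- sort(unique(tp))
  out <- vapply(levels_tp, function(x)
    rowMeans(matrix[, tp == x, drop = FALSE]), numeric(nrow(matrix)))
  out <- base::matrix(out, nrow = nrow(matrix),
                      dimnames = list(rownames(matrix),
                                      format(levels_tp, trim = TRUE)))
  attr(out, "timepoints") <- levels_tp
  out
}

#' Correlate each gene's time course with the growth-rate profile
#'
#' Computes the Pearson product-moment correlation between every gene's
#' (replicate-mean) expression profile and the relative growth rate
#' evaluated at the same timepoints. Genes whose profile has zero variance
#' have no defined correlation; they are flagged \code{undefined} rather
#' than propagating \code{NaN}.
#'
#' @param profiles gene x timepoint matrix (one value per timepoint, e.g.
#'   from \code{\link{summarise_replicates}}).
#' @param rate_profile growth rate at the matrix's timepoints, from
#'   \code{\link{relative_growth_rate}} evaluated on the continuous fit —
#'   same length as \code{ncol(profiles)}, at least 3.
#' @return data frame of class \code{"screen_result"} with columns
#'   \code{gene}, \code{r}, \code{undefined}.
#' @export
correlate_with_growth_rate <- function(profiles, rate_profile) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(rate_profile))
    stop("'rate_profile' length must equal the number of timepoints")
  if (ncol(profiles) < 3)
    stop("at least 3 timepoints are required for a correlation")
  if (stats::sd(rate_profile) == 0)
    stop("'rate_profile' is constant; correlations are undefined")
  sds <- apply(profiles, 1, stats::sd)
  undefined <- sds == 0
  r <- rep(NA_real_, nrow(profiles))
  if (any(!undefined))
    r[!undefined] <- as.vector(
      stats::cor(t(profiles[!undefined, , drop = FALSE]), rate_profile))
  genes <- rownames(profiles)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(nrow(profiles)))
  out <- data.frame(gene = genes, r = r, undefined = undefined,
                    stringsAsFactors = FALSE)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Classify genes by their correlation with the growth rate
#'
#' Applies the selection rule of the screen: genes with \code{r} strictly
#' greater than \code{threshold} are \code{positive} (expression tracks the
#' declining growth rate, i.e. decreases over time), genes with \code{r}
#' strictly below \code{-threshold} are \code{negative} (expression rises as
#' growth slows); \code{r} exactly at the threshold is \code{unselected}.
#' Zero-variance profiles stay \code{undefined}. The four classes partition
#' the gene list.
#'
#' @param result a \code{"screen_result"} from
#'   \code{\link{correlate_with_growth_rate}}.
#' @param threshold absolute-correlation cutoff in (0, 1); default 0.8.
#' @return the input with a \code{class} column added (factor with levels
#'   positive, negative, unselected, undefined).
#' @export
classify_genes <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "screen_result"))
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly inside (0, 1)")
  cls <- ifelse(result$undefined, "undefined",
         ifelse(result$r > threshold, "positive",
         ifelse(result$r < -threshold, "negative", "unselected")))
  result$class <- factor(cls, levels = c("positive", "negative",
                                         "unselected", "undefined"))
  attr(result, "threshold") <- threshold
  result
}

#' Normalise each gene's profile to its maximum
#'
#' Divides every row by its maximum so each profile lies in [0, 1] with row
#' maximum exactly 1 — the normalisation used for time-course heatmap
#' display. Idempotent; rows whose maximum is not positive are rejected by
#' name.
#'
#' @param profiles gene x timepoint matrix with all values >= 0.
#' @return matrix of the same shape with unit row maxima.
#' @export
max_normalize <- function(profiles) {
  profiles <- as.matrix(profiles)
  m <- apply(profiles, 1, max)
  bad <- which(!(m > 0))
  if (length(bad))
    stop("rows with non-positive maximum cannot be max-normalised: ",
         paste(utils::head(rownames(profiles)[bad], 5), collapse = ", "))
  sweep(profiles, 1, m, "/")
}

#' Hierarchically cluster max-normalised expression profiles
#'
#' Clusters gene profiles by Euclidean distance under Ward's
#' minimum-variance criterion in its D2 form (the Lance-Williams recurrence
#' applied to unsquared Euclidean distances), the standard ordering step
#' before heatmap display.
#'
#' @param profiles gene x timepoint matrix, typically from
#'   \code{\link{max_normalize}}; at least 2 genes, all values finite.
#' @return object of class \code{"clustered_heatmap"}: the input
#'   \code{matrix}, the dendrogram leaf \code{order}, the \code{merge} tree
#'   and merge \code{height}s, and the underlying \code{hclust} object.
#' @export
cluster_genes <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("at least 2 genes are required")
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  h <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                     method = "ward.D2")
  structure(list(matrix = profiles, order = h$order, merge = h$merge,
                 height = h$height, hclust = h),
            class = "clustered_heatmap")
}

#' @export
print.clustered_heatmap <- function(x, ...) {
  cat(sprintf(
    "Clustered heatmap: %d genes x %d timepoints (ward.D2, Euclidean)\n",
    nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  merge heights: %.3g .. %.3g\n",
              min(x$height), max(x$height)))
  invisible(x)
}

#' @export
plot.clustered_heatmap <- function(x, ...) {
  stats::heatmap(x$matrix, Rowv = stats::as.dendrogram(x$hclust),
                 Colv = NA, scale = "none",
                 col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' Tests each gene set for over-representation among the selected genes
#' with the one-sided hypergeometric tail P(X >= overlap), an explicit
#' stand-in for web-service pathway enrichment. Gene sets are intersected
#' with the universe before testing. The EASE variant (overlap decremented
#' by one before taking the tail, so sets overlapping in at most one gene
#' get p = 1) is available because some enrichment services default to it.
#' Benjamini-Hochberg adjusted values are reported alongside the raw p,
#' and sets are flagged as retained at raw p < 0.05.
#'
#' @param selected character vector of selected genes (must be a subset of
#'   \code{universe}).
#' @param universe character vector of all genes eligible for selection.
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param ease use the conservative EASE-score variant.
#' @param alpha retention threshold on the raw p-value.
#' @return data frame of class \code{"enrichment_result"}: one row per gene
#'   set with overlap, set_size, list_size, universe_size, p, q (BH) and
#'   retained flag.
#' @export
enrich <- function(selected, universe, gene_sets, ease = FALSE,
                   alpha = 0.05) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(universe) == 0) stop("'universe' is empty")
  if (!all(selected %in% universe))
    stop("selected genes outside the universe: ",
         paste(utils::head(setdiff(selected, universe), 5), collapse = ", "))
  if (length(gene_sets) == 0) stop("no gene sets to test")
  if (is.null(names(gene_sets)))
    stop("'gene_sets' must be a named list")
  N <- length(universe); k <- length(selected)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    s <- length(set)
    ov <- length(intersect(set, selected))
    eff <- if (ease) ov - 1L else ov
    p <- if (eff <= 0) 1 else
      stats::phyper(eff - 1L, s, N - s, k, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = s, list_size = k,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$retained <- out$p < alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}
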