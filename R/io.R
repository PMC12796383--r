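#' Read and write the pipeline's tabular inputs
#'
#' Plain-text interchange for the four tabular inputs: disc-volume time
#' courses (\code{time_h}, \code{volume}, \code{replicate}), gene x
#' replicate expression matrices (genes as rows, columns
#' \code{"<timepoint>_rep<k>"}), oxygen dose-response tables
#' (\code{o2_percent}, \code{intensity}, \code{replicate}, optional
#' \code{batch}) and cumulative pupariation counts (\code{time_h},
#' \code{pupariated}, with the cohort size in a \code{n_larvae} comment or
#' supplied on read).
#'
#' @param path file path.
#' @param x object to write.
#' @name disc_io
NULL

#' @rdname disc_io
#' @export
read_volume_csv <- function(path) {
  volume_series(utils::read.csv(path))
}

#' @rdname disc_io
#' @export
write_volume_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname disc_io
#' @param sep field separator; \code{"\t"} for TSV.
#' @export
read_expression_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname disc_io
#' @export
write_expression_matrix <- function(x, path, sep = ",") {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname disc_io
#' @export
read_oxygen_csv <- function(path) {
  out <- utils::read.csv(path)
  if (!all(c("o2_percent", "intensity") %in% names(out)))
    stop("need columns 'o2_percent' and 'intensity'")
  class(out) <- c("oxygen_response", class(out))
  out
}

#' @rdname disc_io
#' @export
write_oxygen_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname disc_io
#' @param n_larvae cohort size to attach on read.
#' @export
read_pupariation_csv <- function(path, n_larvae) {
  out <- utils::read.csv(path)
  attr(out, "n_larvae") <- as.integer(n_larvae)
  class(out) <- c("pupariation_table", class(out))
  out
}

#' @rdname disc_io
#' @export
write_pupariation_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over \code{\link[fgsea]{gmtPathways}}: one gene set per
#' line, tab-separated, name and description followed by member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description column (recycled).
#' @return the path, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  if (is.null(names(gene_sets))) stop("'gene_sets' must be named")
  description <- rep_len(description, length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], description[i], gene_sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a planted-truth sidecar file
#'
#' Serialises the \code{truth} attribute (or component) of a generated
#' dataset to JSON next to the dataset itself, so every simulation carries
#' its ground truth.
#'
#' @param x a generated object carrying truth.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(x, path) {
  truth <- if (!is.null(attr(x, "truth"))) attr(x, "truth") else x$truth
  if (is.null(truth)) stop("no planted truth attached to this object")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
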