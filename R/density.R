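# Histogram-based probability density estimation along the gene-number axis
# and the log10 genome-size axis. The estimator is a pure histogram density:
# counts divided by (class width x total number of genomes), so values are
# comparable across datasets of different size.

.new_binned_density <- function(axis, interval, class_labels, counts, n_total) {
  structure(list(
    axis = axis,
    interval = interval,
    class_labels = class_labels,
    counts = as.integer(counts),
    density = counts / (interval * n_total),
    n_total = as.integer(n_total)
  ), class = "binned_density")
}

#' Bin genomes into gene-number classes and estimate the density
#'
#' Genomes are grouped into classes of \code{interval} genes. Class labels
#' follow the minimal-multiple convention: class 0 covers gene counts in
#' \eqn{[0, i]}, class \eqn{k \ge 1} (label \eqn{k i}) covers
#' \eqn{(k i, (k+1) i]}. The density per gene in class \eqn{j} is
#' \eqn{f_g[j] = \mathrm{count}_j / (i \times N)} where \eqn{N} counts every
#' input genome, including those above \code{max_genes} (which are excluded
#' from the classes but retained in the normalization, so the binned masses
#' sum to the binned fraction of the dataset).
#'
#' @param records a \code{genome_records} data frame.
#' @param interval class width in genes (default 500).
#' @param max_genes upper end of the binned range (default 100,000); must be
#'   a multiple of \code{interval}.
#' @return A \code{binned_density} object with fields \code{class_labels},
#'   \code{counts}, \code{density} (per gene) and \code{n_total}.
#' @examples
#' rec <- genome_records("a", "x", c(500, 501), c(400, 400), c(0, 0),
#'                       c(1e6, 1e6))
#' bin_gene_numbers(rec)$counts[1:2]
#' @export
bin_gene_numbers <- function(records, interval = 500L, max_genes = 100000L) {
  if (length(interval) != 1L || !is.finite(interval) || interval < 1 ||
      interval != round(interval))
    stop("interval must be a positive integer number of genes")
  if (max_genes %% interval != 0)
    stop("max_genes must be a multiple of interval")
  if (nrow(records) == 0L) stop("no genome records to bin")
  g <- records$total_genes
  lab <- interval * pmax(0, ceiling(g / interval) - 1)
  grid <- seq(0, max_genes - interval, by = interval)
  keep <- g <= max_genes
  counts <- tabulate(match(lab[keep], grid), nbins = length(grid))
  .new_binned_density("gene_number", interval, grid, counts, nrow(records))
}

#' Bin genomes into log10 genome-size classes and estimate the density
#'
#' Total sequence lengths are log-transformed (base 10) and binned into
#' classes of \code{interval} decades (default 0.1). The class label is the
#' minimal multiple of \code{interval} the class covers; a size of
#' \eqn{10^6} bp with the default interval falls into the class labelled 6.0.
#' The density is per decade: counts divided by
#' \code{interval} \eqn{\times N}; when every genome is binned the densities
#' times \code{interval} sum to 1.
#'
#' @param records a \code{genome_records} data frame with positive
#'   \code{size_bp}.
#' @param interval class width in decades of genome size (default 0.1).
#' @return A \code{binned_density} object on the \code{log10_size} axis.
#' @export
bin_log_sizes <- function(records, interval = 0.1) {
  if (length(interval) != 1L || !is.finite(interval) || interval <= 0)
    stop("interval must be a positive number of decades")
  if (nrow(records) == 0L) stop("no genome records to bin")
  s <- records$size_bp
  if (any(!is.finite(s) | s < 1)) stop("non-positive genome size encountered")
  x <- log10(s)
  j <- floor(x / interval + 1e-9)
  grid <- seq(min(j), max(j))
  counts <- tabulate(match(j, grid), nbins = length(grid))
  .new_binned_density("log10_size", interval, grid * interval, counts,
                      nrow(records))
}

#' Rice rule for the number of histogram bins
#'
#' Returns \eqn{2 n^{1/3}} rounded to the nearest integer; for the reference
#' collection of 25,975 genomes this gives 59 bins.
#'
#' @param n number of data points.
#' @return Integer number of bins.
#' @export
rice_rule <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a positive integer")
  as.integer(round(2 * n^(1 / 3)))
}

#' Freedman--Diaconis bin width
#'
#' Returns \eqn{2\,(Q_3 - Q_1)\, n^{-1/3}}, the interquartile-range-based
#' histogram bin width.
#'
#' @param q1,q3 first and third quartiles of the data.
#' @param n number of data points.
#' @return Bin width (same units as the quartiles).
#' @export
freedman_diaconis <- function(q1, q3, n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a positive integer")
  if (q3 < q1) stop("q3 must not be smaller than q1")
  2 * (q3 - q1) * n^(-1 / 3)
}

#' Export a binned density as a tab-separated table
#'
#' @param density a \code{binned_density} object.
#' @param path output path; columns are \code{class_label}, \code{count},
#'   \code{density}.
#' @return Invisibly, \code{path}.
#' @export
write_density <- function(density, path) {
  stopifnot(inherits(density, "binned_density"))
  out <- data.frame(class_label = density$class_labels,
                    count = density$counts,
                    density = density$density)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.binned_density <- function(x, ...) {
  cat(sprintf(
    "Binned density on the %s axis: %d classes of width %g, %d genomes (%d binned)\n",
    x$axis, length(x$class_labels), x$interval, x$n_total, sum(x$counts)))
  invisible(x)
}
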