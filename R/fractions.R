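# Cumulative extensive/intensive gene fractions over an ordered genome
# series. Genomes are arranged by increasing gene number (size as the
# second sort key); walking up the series, each increment of dg genes
# between consecutive genomes contributes dg * (extensive fraction at the
# previous genome's model size) extensive genes. Model sizes come from the
# closed-form size curve, not the observed sizes.

#' Cumulative extensive and intensive gene fractions
#'
#' For every genome \eqn{k} in the series sorted by (gene number, size),
#' the predicted fraction of its genes that were added as extensive genes:
#' \deqn{g_e/g[g_k] = \frac{\sum_{j \le k} (1 - l_e(s_{j-1})/l_{emax})
#'   (g_j - g_{j-1})}{g_k}}
#' with \eqn{(g_0, s_0)} the model's minimal genome and
#' \eqn{s_j = s(g_j)} the model size. The intensive fraction is the
#' complement. When \code{count_baseline_as_extensive} is \code{TRUE}
#' (default) the minimal genome's own \eqn{g_0} genes count as extensive,
#' which makes the series start near 1 at small gene numbers.
#'
#' @param records a \code{genome_records} data frame; all gene counts must
#'   be at least \code{params$g0}.
#' @param params a \code{size_model_params} object.
#' @param count_baseline_as_extensive count the first \eqn{g_0} genes as
#'   extensive?
#' @return A data frame of class \code{fraction_series}, sorted by gene
#'   number, with columns \code{gene_number}, \code{ge_over_g},
#'   \code{gi_over_g}, \code{empirical_pc_ps}, \code{empirical_nc}.
#' @export
cumulative_extensive_fraction <- function(records, params,
                                          count_baseline_as_extensive = TRUE) {
  if (nrow(records) == 0L) stop("no genome records")
  o <- order(records$total_genes, records$size_bp)
  rec <- records[o, , drop = FALSE]
  g <- as.numeric(rec$total_genes)
  if (any(g < params$g0))
    stop("all gene counts must be >= the model's minimal genome g0")
  g_prev <- c(params$g0, g[-length(g)])
  s_prev <- s_of_g(g_prev, params)
  incr <- dge_fraction(s_prev, params) * (g - g_prev)
  num <- cumsum(incr) + if (count_baseline_as_extensive) params$g0 else 0
  ge <- pmin(pmax(num / g, 0), 1)
  out <- data.frame(
    gene_number = g,
    ge_over_g = ge,
    gi_over_g = 1 - ge,
    empirical_pc_ps = (rec$pc_genes + rec$ps_genes) / rec$total_genes,
    empirical_nc = rec$nc_genes / rec$total_genes
  )
  class(out) <- c("fraction_series", "data.frame")
  out
}

#' Empirical gene-type fractions per genome
#'
#' The observed shares of protein-coding, pseudogene and non-coding genes
#' in each genome; the protein-coding + pseudogene share is the empirical
#' counterpart of the predicted extensive fraction, the non-coding share of
#' the intensive fraction.
#'
#' @param records a \code{genome_records} data frame.
#' @return A data frame with columns \code{gene_number}, \code{pc},
#'   \code{ps}, \code{nc} and \code{pc_ps}; genomes with zero total genes
#'   are excluded and listed in the \code{"excluded"} attribute.
#' @export
empirical_fractions <- function(records) {
  zero <- records$total_genes == 0L
  rec <- records[!zero, , drop = FALSE]
  out <- data.frame(
    gene_number = rec$total_genes,
    pc = rec$pc_genes / rec$total_genes,
    ps = rec$ps_genes / rec$total_genes,
    nc = rec$nc_genes / rec$total_genes,
    pc_ps = (rec$pc_genes + rec$ps_genes) / rec$total_genes
  )
  attr(out, "excluded") <- which(zero)
  out
}

#' Compare predicted and empirical gene-type fractions
#'
#' Per-genome differences between the model's extensive fraction and the
#' empirical protein-coding + pseudogene share (and between the intensive
#' fraction and the non-coding share), with summary statistics.
#'
#' @param series a \code{fraction_series} from
#'   [cumulative_extensive_fraction()].
#' @return A list with \code{per_genome} (one row per genome:
#'   \code{diff_extensive}, \code{diff_intensive}) and \code{summary}
#'   (mean, mean absolute difference and quartiles of each).
#' @export
compare_predicted_vs_empirical <- function(series) {
  stopifnot(inherits(series, "fraction_series"))
  d_e <- series$ge_over_g - series$empirical_pc_ps
  d_i <- series$gi_over_g - series$empirical_nc
  qs <- function(x) c(mean = mean(x), mean_abs = mean(abs(x)),
                      stats::quantile(x, c(0.25, 0.5, 0.75)))
  list(
    per_genome = data.frame(gene_number = series$gene_number,
                            diff_extensive = d_e, diff_intensive = d_i),
    summary = rbind(extensive = qs(d_e), intensive = qs(d_i))
  )
}

#' Export a fraction series as a tab-separated table
#'
#' @param series a \code{fraction_series}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_fraction_series <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
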