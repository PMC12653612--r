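# Synthetic genome-table generator. Gene counts are drawn from the
# gene-number mixture (a generative reading of the density model), genome
# sizes follow the closed-form size curve with multiplicative log-normal
# scatter, and each genome's genes are split into protein-coding +
# pseudogene vs non-coding parts consistent with the model's cumulative
# extensive/intensive fractions. Genomes are i.i.d. draws; phylogenetic
# correlation and the within-class placement of real annotations are not
# emulated.

#' Configuration for the synthetic genome generator
#'
#' @param n_genomes number of genomes to draw.
#' @param mixture gene-number mixture parameters (default: the reference
#'   fit, [default_mixture_params()]).
#' @param size_params genome-size model parameters (default:
#'   [default_size_params()]).
#' @param size_noise_sigma standard deviation of the log10 multiplicative
#'   scatter applied to model sizes (decades; default 0.15).
#' @param fraction_noise_sigma standard deviation of the additive noise on
#'   the extensive share used for the gene-type split (default 0.05).
#' @param ps_share share of the extensive (protein-coding + pseudogene)
#'   genes annotated as pseudogenes (default 0.05).
#' @param seed integer seed; every sampling routine is deterministic given
#'   it.
#' @param interval gene-number class width in genes (default 500).
#' @param min_genes smallest gene count drawn in class 0 (default 149, the
#'   reference collection's minimal genome).
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genomes = 25975L,
                              mixture = default_mixture_params(),
                              size_params = default_size_params(),
                              size_noise_sigma = 0.15,
                              fraction_noise_sigma = 0.05,
                              ps_share = 0.05,
                              seed = 1L,
                              interval = 500L,
                              min_genes = 149L) {
  stopifnot(n_genomes >= 1, size_noise_sigma >= 0, fraction_noise_sigma >= 0,
            ps_share >= 0, ps_share <= 1)
  structure(list(n_genomes = as.integer(n_genomes), mixture = mixture,
                 size_params = size_params,
                 size_noise_sigma = size_noise_sigma,
                 fraction_noise_sigma = fraction_noise_sigma,
                 ps_share = ps_share, seed = as.integer(seed),
                 interval = as.integer(interval),
                 min_genes = as.integer(min_genes)),
            class = "simulation_config")
}

# Draw one class index from a single mixture component.
.sample_component_class <- function(id, n, mixture) {
  if (id == "bg") return(sample.int(mixture$L, n, replace = TRUE) - 1L)
  if (id == "S") {
    st <- mixture$step
    p_plateau <- st$L_s / (st$L_s + 1 / (1 - exp(-st$gamma)))
    tail <- stats::runif(n) >= p_plateau
    k <- integer(n)
    k[!tail] <- st$k_start +
      sample.int(st$L_s, sum(!tail), replace = TRUE) - 1L
    k[tail] <- st$k_start + st$L_s +
      stats::rgeom(sum(tail), 1 - exp(-st$gamma))
    return(k)
  }
  i <- as.integer(sub("^P", "", id))
  mixture$poisson$k0[i] + stats::rpois(n, mixture$poisson$lambda[i])
}

#' Sample gene counts from the gene-number mixture
#'
#' A component is chosen with probability proportional to its coefficient
#' (coefficients are renormalized to sum to 1 for sampling), a class is
#' drawn from that component's mass, and the gene count is placed uniformly
#' within the class's gene range (class 0 from \code{min_genes} to
#' \code{interval}, respecting the observed minimal genome).
#'
#' @param config a \code{simulation_config}.
#' @return Integer vector of gene counts; deterministic given
#'   \code{config$seed}.
#' @export
sample_gene_counts <- function(config) {
  mx <- config$mixture
  ids <- .component_ids(nrow(mx$poisson), !is.null(mx$step))
  w <- c(mx$a_bg, mx$poisson$a, if (!is.null(mx$step)) mx$step$a_s)
  if (sum(w) <= 0) stop("all mixture coefficients are zero")
  set.seed(config$seed)
  comp <- sample(ids, config$n_genomes, replace = TRUE, prob = w / sum(w))
  k <- integer(config$n_genomes)
  for (id in unique(comp)) {
    sel <- comp == id
    k[sel] <- .sample_component_class(id, sum(sel), mx)
  }
  i <- config$interval
  g <- k * i + sample.int(i, config$n_genomes, replace = TRUE)
  zero <- k == 0L
  if (any(zero))
    g[zero] <- sample(seq(config$min_genes, i), sum(zero), replace = TRUE)
  g
}

#' Sample genome sizes around the model size curve
#'
#' Sizes are the closed-form model size at each gene count multiplied by
#' \eqn{10^\epsilon}, \eqn{\epsilon \sim N(0, \sigma)} with
#' \eqn{\sigma =} \code{size_noise_sigma}; draws below the minimal genome
#' size \eqn{s_0} are redrawn.
#'
#' @param gene_counts integer gene counts, all at least the model's
#'   \eqn{g_0}.
#' @param config a \code{simulation_config}.
#' @return Numeric vector of sizes in bp; deterministic given
#'   \code{config$seed}.
#' @export
sample_sizes <- function(gene_counts, config) {
  sp <- config$size_params
  if (any(gene_counts < sp$g0))
    stop("gene counts below the model's minimal genome g0")
  set.seed(config$seed + 1L)
  mu <- s_of_g(gene_counts, sp)
  s <- mu * 10^stats::rnorm(length(mu), 0, config$size_noise_sigma)
  for (it in 1:100) {
    low <- s < sp$s0
    if (!any(low)) break
    s[low] <- mu[low] * 10^stats::rnorm(sum(low), 0, config$size_noise_sigma)
  }
  s[s < sp$s0] <- sp$s0
  round(s)
}

#' Split gene totals into protein-coding, pseudogene and non-coding parts
#'
#' The extensive share of each genome's genes is taken from the cumulative
#' extensive-fraction series (model sizes, genomes ordered by gene number
#' then size), perturbed by additive normal noise and clamped to
#' \eqn{[0, 1]}; that share becomes protein-coding + pseudogene genes (a
#' fixed proportion \code{ps_share} of it annotated as pseudogenes), the
#' remainder non-coding. Counts are integers summing exactly to the total.
#'
#' @param gene_counts integer gene counts.
#' @param sizes genome sizes in bp (used as the secondary sort key).
#' @param config a \code{simulation_config}.
#' @return A data frame with columns \code{pc}, \code{ps}, \code{nc} in the
#'   input order.
#' @export
split_gene_types <- function(gene_counts, sizes, config) {
  sp <- config$size_params
  n <- length(gene_counts)
  o <- order(gene_counts, sizes)
  g <- as.numeric(gene_counts[o])
  g_prev <- c(sp$g0, g[-n])
  incr <- dge_fraction(s_of_g(g_prev, sp), sp) * (g - g_prev)
  ge <- (cumsum(incr) + sp$g0) / g
  frac <- numeric(n)
  frac[o] <- ge
  set.seed(config$seed + 2L)
  frac <- pmin(pmax(frac + stats::rnorm(n, 0, config$fraction_noise_sigma),
                    0), 1)
  pc_ps <- round(frac * gene_counts)
  ps <- round(config$ps_share * pc_ps)
  data.frame(pc = as.integer(pc_ps - ps), ps = as.integer(ps),
             nc = as.integer(gene_counts - pc_ps))
}

#' Simulate a full set of genome records
#'
#' Draws gene counts, sizes and gene-type splits, and assembles them into a
#' \code{genome_records} data frame in the same dialect produced by real
#' genome summary tables.
#'
#' @param config a \code{simulation_config}.
#' @return A \code{genome_records} data frame with \code{n_genomes} rows.
#' @examples
#' rec <- simulate_genome_records(simulation_config(n_genomes = 100, seed = 7))
#' head(rec)
#' @export
simulate_genome_records <- function(config) {
  g <- sample_gene_counts(config)
  s <- sample_sizes(g, config)
  split <- split_gene_types(g, s, config)
  genome_records(
    assembly_name = sprintf("SYN%06d", seq_along(g)),
    organism_name = sprintf("synthetic genome %d", seq_along(g)),
    total_genes = g, pc_genes = split$pc, ps_genes = split$ps,
    size_bp = s, domain = "unknown"
  )
}

#' Generate a synthetic genome summary table on disk
#'
#' @param config a \code{simulation_config}.
#' @param path output path for the tab-separated table; readable by
#'   [read_genome_table()].
#' @return Invisibly, the generated \code{genome_records}.
#' @export
generate_table <- function(config, path) {
  rec <- simulate_genome_records(config)
  write_genome_table(rec, path)
  invisible(rec)
}
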