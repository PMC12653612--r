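# Shared fixtures: small record sets built in code, and a binned density
# evaluated exactly from a mixture parameter set (a noise-free
# "observation" for fitting tests).

make_records <- function(total, pc = NULL, ps = NULL, size = NULL,
                         domain = "unknown") {
  n <- length(total)
  if (is.null(pc)) pc <- round(0.9 * total)
  if (is.null(ps)) ps <- round(0.02 * total)
  if (is.null(size)) size <- 1000 * total
  genome_records(
    assembly_name = sprintf("ASM%03d", seq_len(n)),
    organism_name = sprintf("organism %d", seq_len(n)),
    total_genes = total, pc_genes = pc, ps_genes = ps,
    size_bp = size, domain = domain
  )
}

# A binned_density carrying an exactly known density curve (n_total and
# counts are placeholders; only the density enters the fitting objective).
exact_density <- function(params, kmax = 199L, interval = 500L) {
  k <- 0:kmax
  structure(list(
    axis = "gene_number", interval = interval,
    class_labels = k * interval,
    counts = rep(1L, length(k)),
    density = predict_mixture_density(params, k * interval, interval),
    n_total = 1L
  ), class = "binned_density")
}

ref_mixture <- default_mixture_params()
ref_size <- default_size_params()
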