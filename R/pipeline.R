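# Pipeline configuration and stage runner tying the analysis together:
# simulate (or read) a genome table, estimate the densities, fit the
# mixture and size models, compute the gene fractions, and report the
# reference-parameter identities. Each stage writes plain-text artifacts
# into an output directory and appends to a run log, so a run is
# reproducible from the configuration and seed alone.

#' Pipeline configuration
#'
#' @param input path to a genome summary table; \code{NULL} to use the
#'   table generated by the \code{"simulate"} stage.
#' @param out_dir output directory for stage artifacts.
#' @param interval gene-number class width in genes.
#' @param max_genes upper end of the binned gene-number range.
#' @param log_size_interval log-size class width in decades.
#' @param seed integer seed for every stochastic stage.
#' @param n_genomes number of genomes for the \code{"simulate"} stage.
#' @param restarts optimizer restarts for the fitting stages.
#' @param n_poisson,use_step mixture structure for the fitting stages.
#' @param warm_start use the reference mixture parameters as the fitting
#'   warm start instead of the staged build-up?
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, out_dir = "genedensity-run",
                            interval = 500L, max_genes = 100000L,
                            log_size_interval = 0.1, seed = 1L,
                            n_genomes = 25975L, restarts = 10L,
                            n_poisson = 5L, use_step = TRUE,
                            warm_start = FALSE) {
  stopifnot(interval >= 1, log_size_interval > 0)
  structure(list(input = input, out_dir = out_dir,
                 interval = as.integer(interval),
                 max_genes = as.integer(max_genes),
                 log_size_interval = log_size_interval,
                 seed = as.integer(seed),
                 n_genomes = as.integer(n_genomes),
                 restarts = as.integer(restarts),
                 n_poisson = as.integer(n_poisson),
                 use_step = use_step,
                 warm_start = warm_start),
            class = "pipeline_config")
}

.log_line <- function(config, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  message(msg)
  cat(msg, "\n", file = file.path(config$out_dir, "run.log"),
      append = TRUE)
}

.stage_input <- function(config) {
  path <- config$input
  if (is.null(path)) path <- file.path(config$out_dir, "genomes.tsv")
  if (!file.exists(path))
    stop("input table not found: ", path,
         " (run the \"simulate\" stage first or set input=)")
  read_genome_table(path)
}

#' Run one pipeline stage
#'
#' Stages: \code{"simulate"} writes a synthetic genome table;
#' \code{"density"} writes the gene-number and log-size density tables;
#' \code{"fit-mixture"} fits the mixture and writes its parameter report;
#' \code{"fit-size"} fits the size model and writes fitted and derived
#' parameters; \code{"fractions"} writes the cumulative
#' extensive/intensive fraction series; \code{"validate-holdout"} runs the
#' hold-out protocol; \code{"report"} evaluates the built-in reference
#' parameter sets (derived identities, worked-example shares) without any
#' fitting.
#'
#' @param stage stage name.
#' @param config a \code{pipeline_config}.
#' @return Invisibly, a list of the stage's artifact paths and main
#'   objects.
#' @export
run_stage <- function(stage = c("simulate", "density", "fit-mixture",
                                "fit-size", "fractions",
                                "validate-holdout", "report"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_line(config, "stage %s (seed %d)", stage, config$seed)

  if (stage == "simulate") {
    path <- file.path(config$out_dir, "genomes.tsv")
    rec <- generate_table(simulation_config(n_genomes = config$n_genomes,
                                            interval = config$interval,
                                            seed = config$seed), path)
    .log_line(config, "wrote %d genomes to %s", nrow(rec), path)
    return(invisible(list(path = path, records = rec)))
  }

  if (stage == "density") {
    rec <- .stage_input(config)
    fg <- bin_gene_numbers(rec, config$interval, config$max_genes)
    fs <- bin_log_sizes(rec, config$log_size_interval)
    p1 <- file.path(config$out_dir, "density-genes.tsv")
    p2 <- file.path(config$out_dir, "density-logsize.tsv")
    write_density(fg, p1)
    write_density(fs, p2)
    .log_line(config, "densities written to %s, %s", p1, p2)
    return(invisible(list(gene_density = fg, size_density = fs,
                          paths = c(p1, p2))))
  }

  if (stage == "fit-mixture") {
    rec <- .stage_input(config)
    fg <- bin_gene_numbers(rec, config$interval, config$max_genes)
    fit <- fit_mixture(fg, n_poisson = config$n_poisson,
                       use_step = config$use_step, seed = config$seed,
                       restarts = config$restarts,
                       init = if (config$warm_start)
                         default_mixture_params() else NULL)
    path <- file.path(config$out_dir, "mixture-fit.txt")
    write_mixture_params(fit$params, path)
    cat(sprintf("rmse = %.8g\nrelative_error = %.8g\n",
                fit$rmse, fit$relative_error),
        file = path, append = TRUE)
    .log_line(config, "mixture fit rmse %.4g (relative %.1f%%) -> %s",
              fit$rmse, 100 * fit$relative_error, path)
    return(invisible(list(fit = fit, path = path)))
  }

  if (stage == "fit-size") {
    rec <- .stage_input(config)
    fit <- fit_size_model(rec, seed = config$seed,
                          restarts = config$restarts)
    path <- file.path(config$out_dir, "size-fit.txt")
    write_size_params(fit$params, path)
    .log_line(config, "size fit rmse %.4g -> %s", fit$rmse, path)
    return(invisible(list(fit = fit, path = path)))
  }

  if (stage == "fractions") {
    rec <- .stage_input(config)
    series <- cumulative_extensive_fraction(rec, default_size_params())
    path <- file.path(config$out_dir, "fractions.tsv")
    write_fraction_series(series, path)
    .log_line(config, "fraction series (%d genomes) -> %s",
              nrow(series), path)
    return(invisible(list(series = series, path = path)))
  }

  if (stage == "validate-holdout") {
    rec <- .stage_input(config)
    hv <- holdout_validate(rec, seed = config$seed,
                           interval = config$interval,
                           max_genes = config$max_genes,
                           n_poisson = config$n_poisson,
                           use_step = config$use_step,
                           restarts = config$restarts,
                           init = if (config$warm_start)
                             default_mixture_params() else NULL)
    path <- file.path(config$out_dir, "holdout.txt")
    writeLines(c(
      sprintf("mean_relative_error_on_excluded = %.8g",
              hv$mean_relative_error_on_excluded),
      sprintf("refit_rmse = %.8g", hv$refit$rmse)), path)
    .log_line(config, "hold-out mean relative error %.1f%% -> %s",
              100 * hv$mean_relative_error_on_excluded, path)
    return(invisible(list(holdout = hv, path = path)))
  }

  # stage == "report": constants-only evaluation of the reference presets.
  mx <- default_mixture_params()
  sp <- default_size_params()
  shares <- decompose_mixture(10L, mx)[1L, ]
  shares <- 100 * shares / sum(shares)
  s250 <- le_of_s(2.5e8, sp) / sp$lemax
  lines <- c(
    sprintf("rice_rule_n25975 = %d", rice_rule(25975)),
    sprintf("b = %.15g", sp$b),
    sprintf("c = %.15g", sp$c),
    sprintf("le0 = %.15g", sp$le0),
    sprintf("lemax = %.15g", sp$lemax),
    sprintf("s_at_g0 = %.15g", s_of_g(sp$g0, sp)),
    sprintf("share_P1_class10_pct = %.6g", shares[["P1"]]),
    sprintf("share_P3_class10_pct = %.6g", shares[["P3"]]),
    sprintf("share_P4_class10_pct = %.6g", shares[["P4"]]),
    sprintf("p1_group_genomes = %.6g", mx$poisson$a[1L] * 25975),
    sprintf("le_ratio_s2.5e8 = %.6g", s250),
    sprintf("dge_fraction_s2.5e8 = %.6g", 1 - s250),
    sprintf("step_mean_classes = %.6g", step_mean(mx$step)))
  path <- file.path(config$out_dir, "report.txt")
  writeLines(lines, path)
  .log_line(config, "reference-parameter report -> %s", path)
  invisible(list(path = path, lines = lines))
}
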