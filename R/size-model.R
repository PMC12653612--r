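# Genome-size evolution model. New genes split into extensive genes (each
# adds, on average, l_e base pairs) and intensive genes (no size change);
# the extensive share shrinks as l_e approaches a ceiling l_emax, and l_e
# itself grows linearly with genome size. These assumptions give the
# logistic-type ODE
#     s'(g) = a ((s - s0) + b) (1 - c ((s - s0) + b))
# whose solution is
#     s(g) = A e^{a(g - g0)} / (1 + B e^{a(g - g0)}) - A/(1 + B) + s0
# with A = b/(1 - bc), B = bc/(1 - bc), b = le0/a, c = a/lemax.

#' Construct genome-size evolution model parameters
#'
#' Fills the derived parameters from the fitted ones:
#' \eqn{b = A/(1+B)}, \eqn{c = B/A}, \eqn{l_{e0} = a b} (average extensive
#' gene length in the minimal genome) and \eqn{l_{emax} = a/c} (its
#' model-imposed ceiling). The boundary condition \eqn{(g_0, s_0)} is the
#' minimal genome's gene count and size.
#'
#' @param A size scale, bp.
#' @param B dimensionless shape parameter; must be positive (at
#'   \eqn{B = 0} the ceiling \eqn{l_{emax}} is infinite and the model
#'   degenerates).
#' @param a per-gene rate, 1/genes.
#' @param g0 minimal gene number, genes.
#' @param s0 minimal genome size, bp.
#' @return An object of class \code{size_model_params} with fields
#'   \code{A, B, a, g0, s0} and derived \code{b, c, le0, lemax}.
#' @seealso [default_size_params()] for the reference fit.
#' @export
size_model_params <- function(A, B, a, g0, s0) {
  if (!is.finite(A) || A <= 0) stop("A must be positive")
  if (!is.finite(B) || B <= 0)
    stop("domain error: B must be positive (B = 0 gives an infinite l_emax)")
  if (!is.finite(a) || a <= 0) stop("a must be positive")
  b <- A / (1 + B)
  cc <- B / A
  if (b * cc >= 1) stop("domain error: b*c must be below 1")
  structure(list(A = A, B = B, a = a, g0 = g0, s0 = s0,
                 b = b, c = cc, le0 = a * b, lemax = a / cc),
            class = "size_model_params")
}

#' Reference parameter set for the genome-size model
#'
#' Values fitted to the unclassified (gene number, genome size) pairs of the
#' 1 May 2025 NCBI reference collection; the boundary condition is that
#' collection's minimal genome (149 genes, 137,475.095 bp).
#'
#' @return A \code{size_model_params} object.
#' @export
default_size_params <- function() {
  size_model_params(A = 5000000.26632, B = 0.00202752763471099,
                    a = 0.000202289166662222,
                    g0 = 149, s0 = 137475.095259792)
}

#' Genome size as a function of gene number (closed form)
#'
#' The closed-form solution of the size-evolution ODE. Evaluated through
#' the logistic function \code{plogis} so large gene numbers do not
#' overflow: \eqn{s(g) = (A/B)\,\sigma(a (g - g_0) + \log B) - A/(1+B) +
#' s_0}. Strictly increasing in \eqn{g} and bounded above by
#' \eqn{s_0 + A/B - A/(1+B)}.
#'
#' @param g gene numbers (vectorized), \code{g >= g0}.
#' @param params a \code{size_model_params} object.
#' @return Genome sizes in bp.
#' @examples
#' s_of_g(149, default_size_params())  # the minimal genome's size
#' @export
s_of_g <- function(g, params) {
  if (any(!is.finite(g)) || any(g < params$g0))
    stop("gene numbers must satisfy g >= g0")
  with(params, A / B * stats::plogis(a * (g - g0) + log(B)) -
                 A / (1 + B) + s0)
}

#' Average extensive-gene length at a given genome size
#'
#' The linear law \eqn{l_e(s) = a (s - s_0) + l_{e0}}. With
#' \code{clamp = TRUE} (default) the value is capped at \eqn{l_{emax}}, so
#' the extensive fraction \eqn{1 - l_e/l_{emax}} never goes negative for
#' sizes beyond the model's validity range.
#'
#' @param s genome sizes in bp (vectorized), \code{s >= s0}.
#' @param params a \code{size_model_params} object.
#' @param clamp cap the value at \code{lemax}?
#' @return Lengths in bp per extensive gene.
#' @export
le_of_s <- function(s, params, clamp = TRUE) {
  if (any(!is.finite(s)) || any(s < params$s0))
    stop("sizes must satisfy s >= s0")
  le <- params$a * (s - params$s0) + params$le0
  if (clamp) le <- pmin(le, params$lemax)
  le
}

#' Extensive fraction of newly added genes
#'
#' The share of new genes that are extensive at genome size \eqn{s}:
#' \eqn{dg_e/dg = 1 - l_e(s)/l_{emax}}, with \eqn{l_e} clamped at
#' \eqn{l_{emax}} so the result stays in \eqn{[0, 1]}. The intensive
#' complement is \eqn{dg_i/dg = l_e/l_{emax}}.
#'
#' @param s genome sizes in bp (vectorized), \code{s >= s0}.
#' @param params a \code{size_model_params} object.
#' @return Fractions in \eqn{[0, 1]}.
#' @export
dge_fraction <- function(s, params) {
  1 - le_of_s(s, params, clamp = TRUE) / params$lemax
}

#' Fit the genome-size model to (gene number, size) pairs
#'
#' Bounded nonlinear least squares (Levenberg--Marquardt on
#' log-transformed positive parameters) of the closed-form size curve to
#' unclassified per-genome data. The boundary condition \eqn{(g_0, s_0)}
#' defaults to the dataset's minimal genome (ties on gene number broken by
#' size) and can be overridden. Multi-start over a grid of initial shape
#' parameters \eqn{B} plus seeded random perturbations makes the fit
#' reproducible for a given seed.
#'
#' @param records a \code{genome_records} data frame (needs
#'   \code{total_genes} and \code{size_bp}).
#' @param seed integer seed for the multi-start perturbations.
#' @param g0,s0 optional boundary-condition overrides.
#' @param loss fit on raw sizes (\code{"raw"}, default) or log10 sizes
#'   (\code{"log"}; appropriate when scatter is multiplicative).
#' @param restarts number of random restarts added to the deterministic
#'   initial grid.
#' @return A list of class \code{size_model_fit} with elements
#'   \code{params} (a \code{size_model_params}), \code{rmse} (in the loss
#'   units), \code{converged} and \code{seed}.
#' @export
fit_size_model <- function(records, seed = 1L, g0 = NULL, s0 = NULL,
                           loss = c("raw", "log"), restarts = 10L) {
  loss <- match.arg(loss)
  g <- as.numeric(records$total_genes)
  s <- as.numeric(records$size_bp)
  ok <- is.finite(g) & is.finite(s) & s >= 1
  g <- g[ok]; s <- s[ok]
  if (length(unique(paste(g, s))) < 5L)
    stop("need at least 5 distinct (gene number, size) pairs")
  o <- order(g, s)
  if (is.null(g0)) g0 <- g[o][1L]
  if (is.null(s0)) s0 <- s[o][1L]
  use <- g >= g0
  g <- g[use]; s <- s[use]

  resid_fn <- function(p) {
    A <- exp(p[1L]); B <- exp(p[2L]); a <- exp(p[3L])
    pred <- A / B * stats::plogis(a * (g - g0) + log(B)) - A / (1 + B) + s0
    if (loss == "log") log10(pmax(pred, 1)) - log10(s) else pred - s
  }

  # Initial guesses: the upper asymptote is roughly s0 + A/B and the
  # initial slope a*A/(1+B)^2 is roughly the small-genome bp-per-gene.
  asym <- max(s) - s0
  small <- g <= stats::quantile(g, 0.25)
  slope0 <- if (sum(small) >= 2L)
    max(stats::coef(stats::lm(s[small] ~ g[small]))[2L], 10) else 1000
  inits <- lapply(c(0.001, 0.01, 0.1, 1), function(B0) {
    A0 <- asym * B0
    c(log(A0), log(B0), log(slope0 * (1 + B0)^2 / A0))
  })
  set.seed(seed)
  if (restarts > 0L)
    inits <- c(inits, lapply(seq_len(restarts), function(i)
      inits[[(i - 1L) %% 4L + 1L]] + stats::rnorm(3L, 0, 0.5)))

  best <- NULL
  for (p0 in inits) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r2 <- sum(fit$fvec^2)
    if (is.null(best) || r2 < best$r2)
      best <- list(par = fit$par, r2 = r2, info = fit$info)
  }
  if (is.null(best)) stop("size-model fit failed from every start")
  params <- size_model_params(exp(best$par[1L]), exp(best$par[2L]),
                              exp(best$par[3L]), g0, s0)
  structure(list(params = params,
                 rmse = sqrt(best$r2 / length(g)),
                 loss = loss,
                 converged = best$info %in% 1:4,
                 n = length(g),
                 seed = as.integer(seed)),
            class = "size_model_fit")
}

#' Transform a gene-number density into a predicted log-size density
#'
#' The point transform \eqn{g \to s = p_1 g}, \eqn{f_g \to f_s = p_2 f_g},
#' mapping each gene-number class (label and per-gene density) to a point
#' on the log10 genome-size axis. \eqn{p_1} (bp per gene) is supplied, not
#' fitted; \eqn{p_2} rescales the density and can be calibrated by matching
#' maxima with [calibrate_p2()]. Classes with non-positive labels have no
#' log-size image and are dropped.
#'
#' @param gene_numbers gene-number class labels (genes), or a
#'   \code{binned_density} on the gene-number axis.
#' @param density densities per gene at those labels (ignored when a
#'   \code{binned_density} is supplied).
#' @param p1 bp per gene (default 1000).
#' @param p2 density scale factor (default 1).
#' @return A data frame with columns \code{gene_number}, \code{size_bp},
#'   \code{log10_size} and \code{density}.
#' @export
transform_density <- function(gene_numbers, density = NULL, p1 = 1000,
                              p2 = 1) {
  if (inherits(gene_numbers, "binned_density")) {
    density <- gene_numbers$density
    gene_numbers <- gene_numbers$class_labels
  }
  if (p1 <= 0 || p2 <= 0) stop("p1 and p2 must be positive")
  keep <- gene_numbers > 0
  data.frame(gene_number = gene_numbers[keep],
             size_bp = p1 * gene_numbers[keep],
             log10_size = log10(p1 * gene_numbers[keep]),
             density = p2 * density[keep])
}

#' Calibrate the density scale factor by maximum matching
#'
#' Single-point calibration of \eqn{p_2}: the ratio of the maximum of the
#' observed log-size density to the maximum of the (unscaled) transformed
#' gene-number density.
#'
#' @param predicted_density unscaled predicted densities (the transform
#'   with \code{p2 = 1}).
#' @param observed_density observed log-size densities.
#' @return The scalar \eqn{p_2}.
#' @export
calibrate_p2 <- function(predicted_density, observed_density) {
  if (inherits(predicted_density, "data.frame"))
    predicted_density <- predicted_density$density
  if (inherits(observed_density, "binned_density"))
    observed_density <- observed_density$density
  max(observed_density) / max(predicted_density)
}

#' Write size-model parameters to a flat key-value file
#'
#' @param params a \code{size_model_params} object.
#' @param path output path; fitted parameters (\code{A, B, a, g0, s0}) and
#'   derived ones (\code{b, c, le0, lemax}) are labelled as such.
#' @return Invisibly, \code{path}.
#' @export
write_size_params <- function(params, path) {
  lines <- c(
    sprintf("%s = %.15g  # fitted", c("A", "B", "a", "g0", "s0"),
            unlist(params[c("A", "B", "a", "g0", "s0")])),
    sprintf("%s = %.15g  # derived", c("b", "c", "le0", "lemax"),
            unlist(params[c("b", "c", "le0", "lemax")])))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.size_model_params <- function(x, ...) {
  cat("Genome-size evolution model\n")
  cat(sprintf("  fitted:  A = %.6g, B = %.6g, a = %.6g, g0 = %g, s0 = %.6g\n",
              x$A, x$B, x$a, x$g0, x$s0))
  cat(sprintf("  derived: b = %.6g, c = %.6g, le0 = %.6g bp, lemax = %.6g bp\n",
              x$b, x$c, x$le0, x$lemax))
  invisible(x)
}

#' @export
print.size_model_fit <- function(x, ...) {
  cat(sprintf("Size-model fit on %d genomes (%s loss): rmse = %.6g, %s\n",
              x$n, x$loss, x$rmse,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}
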