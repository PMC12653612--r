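# The bg5Ps density model for the gene-number axis: a uniform background
# over the first L classes, five shifted Poisson components, and a step
# input with exponential decay. Classes are integer indices k = g / i of
# gene-number classes of width i (i = 500 genes throughout the reference
# analysis); the per-gene density is the class mass divided by the width.

.component_ids <- function(n_poisson, use_step) {
  c("bg", if (n_poisson > 0) paste0("P", seq_len(n_poisson)),
    if (use_step) "S")
}

#' Construct bg5Ps mixture parameters
#'
#' @param a_bg background coefficient (mass attributed to a uniform
#'   background over classes \eqn{0 \le k < L}).
#' @param L background support length in classes.
#' @param poisson data frame with one row per shifted Poisson component and
#'   columns \code{a} (coefficient), \code{lambda} (rate, in classes) and
#'   \code{k0} (integer start class).
#' @param step \code{NULL}, or a list with \code{a_s} (coefficient),
#'   \code{k_start} (first plateau class), \code{L_s} (plateau length in
#'   classes; decay starts at \code{k_start + L_s}) and \code{gamma}
#'   (exponential decay rate per class).
#' @return An object of class \code{mixture_params}.
#' @seealso [default_mixture_params()] for the reference fit.
#' @export
mixture_params <- function(a_bg, L, poisson = NULL, step = NULL) {
  if (a_bg < 0 || L < 1) stop("background requires a_bg >= 0 and L >= 1")
  if (!is.null(poisson)) {
    poisson <- as.data.frame(poisson)
    stopifnot(all(c("a", "lambda", "k0") %in% names(poisson)))
    if (nrow(poisson) > 0) {
      if (any(poisson$a < 0)) stop("Poisson coefficients must be >= 0")
      if (any(poisson$lambda <= 0)) stop("Poisson rates must be positive")
      if (any(poisson$k0 < 0 | poisson$k0 != round(poisson$k0)))
        stop("Poisson start classes must be non-negative integers")
    }
  } else {
    poisson <- data.frame(a = numeric(), lambda = numeric(), k0 = integer())
  }
  if (!is.null(step)) {
    stopifnot(all(c("a_s", "k_start", "L_s", "gamma") %in% names(step)))
    if (step$a_s < 0) stop("step coefficient must be >= 0")
    if (step$gamma <= 0) stop("step decay rate gamma must be positive")
    if (step$L_s < 1) stop("step plateau length must be >= 1")
    step$k_decay <- step$k_start + step$L_s
  }
  structure(list(a_bg = a_bg, L = as.integer(L), poisson = poisson,
                 step = step),
            class = "mixture_params")
}

#' Reference parameter set for the gene-number mixture
#'
#' The bg5Ps parameter values estimated from the 1 May 2025 NCBI reference
#' collection of 25,975 genomes, binned into 500-gene classes: background
#' over the first 200 classes with coefficient 0.007, five shifted Poisson
#' components starting at classes 0, 2, 4, 6 and 44, and a step input with a
#' 29-class plateau starting at class 30 followed by exponential decay.
#' The coefficients sum to about 0.9923 (the residual is fitting error; they
#' are used as printed, not renormalized).
#'
#' @return A \code{mixture_params} object.
#' @export
default_mixture_params <- function() {
  mixture_params(
    a_bg = 0.007, L = 200L,
    poisson = data.frame(
      a      = c(0.531584, 0.074895, 0.153836, 0.161564, 0.004509),
      lambda = c(6.133813, 23.092150, 9.513952, 2.071796, 16.900607),
      k0     = c(0L, 2L, 4L, 6L, 44L)
    ),
    step = list(a_s = 0.058909, k_start = 30L, L_s = 29L, gamma = 0.045683)
  )
}

.check_classes <- function(k) {
  if (any(!is.finite(k)) || any(k != round(k)))
    stop("class indices k must be integers")
  as.integer(round(k))
}

#' Shifted Poisson component mass
#'
#' Probability mass of a Poisson distribution with rate \code{lambda}
#' shifted to start at class \code{k0}: zero below \code{k0}, otherwise the
#' Poisson mass at \code{k - k0}. Evaluated on the log scale internally so
#' large classes do not overflow.
#'
#' @param k integer class (vectorized).
#' @param lambda positive rate, in classes.
#' @param k0 integer start class.
#' @return Probability mass at each \code{k}.
#' @export
poisson_component <- function(k, lambda, k0 = 0L) {
  k <- .check_classes(k)
  if (lambda <= 0) stop("lambda must be positive")
  out <- numeric(length(k))
  on_support <- k >= k0
  out[on_support] <- stats::dpois(k[on_support] - k0, lambda)
  out
}

#' Step-with-exponential-decay component mass
#'
#' Zero below the plateau start; the constant plateau value
#' \eqn{1/(L_s + 1/\gamma)} on classes
#' \eqn{k_\mathrm{start} \le k < k_\mathrm{decay}}; exponential decay
#' \eqn{e^{-\gamma (k - k_\mathrm{decay})}/(L_s + 1/\gamma)} from the decay
#' start onward (continuous at the decay start). The normalizer
#' \eqn{L_s + 1/\gamma} is the continuous-time normalization; the discrete
#' sum over the support differs from 1 by about 1 percent.
#'
#' @param k integer class (vectorized).
#' @param step step parameter list as in [mixture_params()].
#' @return Probability mass at each \code{k}.
#' @export
step_component <- function(k, step) {
  k <- .check_classes(k)
  if (step$gamma <= 0) stop("gamma must be positive")
  k_decay <- step$k_start + step$L_s
  plateau <- 1 / (step$L_s + 1 / step$gamma)
  out <- numeric(length(k))
  mid <- k >= step$k_start & k < k_decay
  tail <- k >= k_decay
  out[mid] <- plateau
  out[tail] <- plateau * exp(-step$gamma * (k[tail] - k_decay))
  out
}

# Uniform background: mass 1/L on classes 0 <= k < L, zero elsewhere.
background_component <- function(k, L) {
  k <- .check_classes(k)
  ifelse(k >= 0 & k < L, 1 / L, 0)
}

#' Decompose the mixture into per-component contributions
#'
#' @param k integer class (vectorized).
#' @param params a \code{mixture_params} object.
#' @return A matrix with one row per class and one column per component
#'   (\code{bg}, \code{P1}..., \code{S}); rows sum exactly to the mixture
#'   class mass.
#' @export
decompose_mixture <- function(k, params) {
  k <- .check_classes(k)
  np <- nrow(params$poisson)
  ids <- .component_ids(np, !is.null(params$step))
  m <- matrix(0, length(k), length(ids), dimnames = list(NULL, ids))
  m[, "bg"] <- params$a_bg * background_component(k, params$L)
  for (i in seq_len(np))
    m[, paste0("P", i)] <- params$poisson$a[i] *
      poisson_component(k, params$poisson$lambda[i], params$poisson$k0[i])
  if (!is.null(params$step))
    m[, "S"] <- params$step$a_s * step_component(k, params$step)
  m
}

#' Evaluate the mixture density
#'
#' The class mass is the coefficient-weighted sum of the background, the
#' shifted Poisson components and the step input; the per-gene density is
#' the class mass divided by the class width in genes.
#'
#' @param k integer class (vectorized, \code{k >= 0}).
#' @param params a \code{mixture_params} object.
#' @param interval class width in genes used to convert class mass to a
#'   per-gene density (default 500).
#' @return A data frame with columns \code{k}, \code{class_mass} and
#'   \code{density_per_gene}.
#' @examples
#' evaluate_mixture(10, default_mixture_params())
#' @export
evaluate_mixture <- function(k, params, interval = 500) {
  k <- .check_classes(k)
  if (any(k < 0)) stop("class indices must be non-negative")
  mass <- rowSums(decompose_mixture(k, params))
  data.frame(k = k, class_mass = mass, density_per_gene = mass / interval)
}

#' Dominant mixture component per class
#'
#' The component contributing the largest share of the class mass; ties are
#' broken by the fixed component order \code{bg}, \code{P1}...\code{P5},
#' \code{S}.
#'
#' @param k integer class (vectorized).
#' @param params a \code{mixture_params} object.
#' @return Character vector of component ids.
#' @export
dominant_component <- function(k, params) {
  m <- decompose_mixture(k, params)
  colnames(m)[apply(m, 1L, which.max)]
}

#' Mean class offset of the step input
#'
#' \eqn{\mu_s = (L_s^2/2 + 1/\gamma) / (L_s + 1/\gamma)}, the mean offset
#' (in classes) of the step-with-exponential-decay distribution under its
#' continuous normalization.
#'
#' @param step step parameter list as in [mixture_params()].
#' @return Mean offset in classes.
#' @export
step_mean <- function(step) {
  if (step$gamma <= 0) stop("gamma must be positive")
  (step$L_s^2 / 2 + 1 / step$gamma) / (step$L_s + 1 / step$gamma)
}

#' Geometric (naive) density model
#'
#' The baseline model \eqn{f_g[k] = f_{g0}\, q^k} in which every genome in a
#' class seeds \eqn{q} genomes in the next class; with \eqn{q > 1} it grows
#' without bound, which is why the mixture model replaces it.
#'
#' @param k integer class (vectorized).
#' @param f_g0 initial density.
#' @param q per-class ratio.
#' @return Density at each class.
#' @export
geometric_model <- function(k, f_g0, q) {
  if (f_g0 <= 0 || q <= 0) stop("f_g0 and q must be positive")
  f_g0 * q^k
}

#' Component rates ordered by start class
#'
#' The Poisson rates \eqn{\lambda_i} and the step input's mean offset
#' \eqn{\mu_s}, ordered by the class at which each component starts.
#'
#' @param params a \code{mixture_params} object.
#' @return A data frame with columns \code{component}, \code{start_class}
#'   and \code{rate}.
#' @export
rate_summary <- function(params) {
  np <- nrow(params$poisson)
  out <- data.frame(
    component = paste0("P", seq_len(np)),
    start_class = params$poisson$k0,
    rate = params$poisson$lambda,
    stringsAsFactors = FALSE
  )
  if (!is.null(params$step))
    out <- rbind(out, data.frame(component = "S",
                                 start_class = params$step$k_start,
                                 rate = step_mean(params$step)))
  out <- out[order(out$start_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write mixture parameters to a flat key-value file
#'
#' @param params a \code{mixture_params} object.
#' @param path output path; keys are \code{a_bg}, \code{L}, \code{a_i},
#'   \code{lambda_i}, \code{k0_i} per component, and \code{a_s},
#'   \code{k_start}, \code{L_s}, \code{gamma} for the step.
#' @return Invisibly, \code{path}.
#' @export
write_mixture_params <- function(params, path) {
  kv <- c(a_bg = params$a_bg, L = params$L)
  for (i in seq_len(nrow(params$poisson))) {
    kv[paste0("a_", i)] <- params$poisson$a[i]
    kv[paste0("lambda_", i)] <- params$poisson$lambda[i]
    kv[paste0("k0_", i)] <- params$poisson$k0[i]
  }
  if (!is.null(params$step))
    kv <- c(kv, a_s = params$step$a_s, k_start = params$step$k_start,
            L_s = params$step$L_s, gamma = params$step$gamma)
  writeLines(sprintf("%s = %.17g", names(kv), unname(kv)), path)
  invisible(path)
}

#' Read mixture parameters from a flat key-value file
#'
#' @param path a file written by [write_mixture_params()].
#' @return A \code{mixture_params} object.
#' @export
read_mixture_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "=", fixed = TRUE)
  kv <- stats::setNames(as.numeric(trimws(vapply(parts, `[`, "", 2L))),
                        trimws(vapply(parts, `[`, "", 1L)))
  ip <- sort(as.integer(sub("^a_", "", grep("^a_[0-9]+$", names(kv),
                                            value = TRUE))))
  poisson <- if (length(ip)) data.frame(
    a = unname(kv[paste0("a_", ip)]),
    lambda = unname(kv[paste0("lambda_", ip)]),
    k0 = as.integer(unname(kv[paste0("k0_", ip)]))) else NULL
  step <- if ("a_s" %in% names(kv)) list(
    a_s = kv[["a_s"]], k_start = as.integer(kv[["k_start"]]),
    L_s = as.integer(kv[["L_s"]]), gamma = kv[["gamma"]]) else NULL
  mixture_params(a_bg = kv[["a_bg"]], L = as.integer(kv[["L"]]),
                 poisson = poisson, step = step)
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("Gene-number density mixture (bg + shifted Poissons + step)\n")
  cat(sprintf("  background: a_bg = %.6f over L = %d classes\n", x$a_bg, x$L))
  for (i in seq_len(nrow(x$poisson)))
    cat(sprintf("  P%d: a = %.6f, lambda = %.6f, k0 = %d\n", i,
                x$poisson$a[i], x$poisson$lambda[i], x$poisson$k0[i]))
  if (!is.null(x$step))
    cat(sprintf("  S: a_s = %.6f, plateau %d..%d, gamma = %.6f\n",
                x$step$a_s, x$step$k_start, x$step$k_decay - 1L,
                x$step$gamma))
  invisible(x)
}
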