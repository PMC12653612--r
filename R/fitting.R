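# Fitting of the gene-number density models by RMSE minimization.
# Continuous parameters (coefficients, Poisson rates, step decay rate) are
# optimized by bounded Levenberg-Marquardt least squares; integer start
# classes are refined by a local coordinate search; components are added in
# stages (background, then Poisson components one at a time, then the step
# input), each stage initialized from the previous solution so the achieved
# RMSE never increases along the staged sequence.

#' Root-mean-square error between an observed and a predicted density
#'
#' @param observed a \code{binned_density}, or a numeric density vector.
#' @param predicted numeric vector of predicted densities on the same class
#'   grid (same length and order).
#' @return The RMSE, in density units.
#' @export
rmse_objective <- function(observed, predicted) {
  y <- if (inherits(observed, "binned_density")) observed$density
       else as.numeric(observed)
  if (length(y) != length(predicted))
    stop("observed and predicted are on different class grids")
  sqrt(mean((y - predicted)^2))
}

#' Predict the mixture density on a class-label grid
#'
#' @param params a \code{mixture_params} object.
#' @param class_labels gene-number class labels (multiples of
#'   \code{interval}).
#' @param interval class width in genes.
#' @return Densities per gene at each label.
#' @export
predict_mixture_density <- function(params, class_labels, interval = 500) {
  k <- class_labels / interval
  evaluate_mixture(k, params, interval)$density_per_gene
}

# --- internal parameter packing -------------------------------------------

# Continuous parameter vector: a_bg, then (a_i, lambda_i) per Poisson
# component, then (a_s, gamma) if the step is present. Integer geometry
# (k0_i, k_start, L_s) is held fixed during continuous optimization.
.mx_pack <- function(params) {
  np <- nrow(params$poisson)
  par <- params$a_bg
  lower <- 0
  for (i in seq_len(np)) {
    par <- c(par, params$poisson$a[i], params$poisson$lambda[i])
    lower <- c(lower, 0, 1e-3)
  }
  if (!is.null(params$step)) {
    par <- c(par, params$step$a_s, params$step$gamma)
    lower <- c(lower, 0, 1e-4)
  }
  list(par = par, lower = lower,
       k0 = params$poisson$k0,
       step_geom = if (is.null(params$step)) NULL
                   else params$step[c("k_start", "L_s")],
       L = params$L)
}

.mx_unpack <- function(par, pk) {
  np <- length(pk$k0)
  poisson <- if (np > 0) data.frame(
    a = par[2 * seq_len(np)],
    lambda = par[2 * seq_len(np) + 1],
    k0 = pk$k0) else NULL
  step <- if (!is.null(pk$step_geom)) list(
    a_s = par[2 * np + 2], k_start = pk$step_geom$k_start,
    L_s = pk$step_geom$L_s, gamma = par[2 * np + 3]) else NULL
  mixture_params(a_bg = max(par[1], 0), L = pk$L,
                 poisson = poisson, step = step)
}

# Continuous bounded least squares at fixed integer geometry.
.mx_refine <- function(y, k, pk, interval, maxiter = 100) {
  fn <- function(par) {
    par <- pmax(par, pk$lower)
    predict_mixture_density(.mx_unpack(par, pk), k * interval, interval) - y
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(pk$par, lower = pk$lower, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(pk)
  pk$par <- pmax(fit$par, pk$lower)
  pk$rmse <- sqrt(mean(fit$fvec^2))
  pk$converged <- fit$info %in% 1:4
  pk
}

# Local integer search: move each start class (and the step geometry)
# within +/- `radius` classes, keeping any move that lowers the RMSE.
.mx_integer_search <- function(y, k, pk, interval, radius = 3L,
                               sweeps = 2L) {
  pk <- .mx_refine(y, k, pk, interval)
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    for (i in seq_along(pk$k0)) {
      for (d in setdiff(-radius:radius, 0L)) {
        cand <- pk
        cand$k0[i] <- pk$k0[i] + d
        if (cand$k0[i] < 0) next
        cand <- .mx_refine(y, k, cand, interval, maxiter = 50)
        if (!is.null(cand$rmse) && cand$rmse < pk$rmse - 1e-15) {
          pk <- cand; improved <- TRUE
        }
      }
    }
    if (!is.null(pk$step_geom)) {
      for (fld in c("k_start", "L_s")) {
        for (d in setdiff(-radius:radius, 0L)) {
          cand <- pk
          cand$step_geom[[fld]] <- pk$step_geom[[fld]] + d
          if (cand$step_geom$k_start < 0 || cand$step_geom$L_s < 1) next
          cand <- .mx_refine(y, k, cand, interval, maxiter = 50)
          if (!is.null(cand$rmse) && cand$rmse < pk$rmse - 1e-15) {
            pk <- cand; improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  pk
}

# Place a new shifted Poisson component on the positive residual: start
# class and rate from the residual's local mean and variance (for a Poisson
# the variance equals the rate and the mean is k0 + rate).
.mx_place_poisson <- function(resid, k) {
  w <- pmax(resid, 0)
  if (sum(w) <= 0) return(list(a = 1e-4, lambda = 2, k0 = max(k[1], 0)))
  peak <- k[which.max(w)]
  win <- abs(k - peak) <= 15
  ww <- w[win]; kk <- k[win]
  mu <- sum(ww * kk) / sum(ww)
  v <- sum(ww * (kk - mu)^2) / sum(ww)
  lambda <- min(max(v, 0.5), 50)
  list(lambda = lambda, k0 = max(0L, as.integer(round(mu - lambda))))
}

# Place the step input on the positive residual: plateau spanning the bulk
# of the residual mass beyond its first substantial class.
.mx_place_step <- function(resid, k) {
  w <- pmax(resid, 0)
  if (sum(w) <= 0) return(list(a_s = 1e-4, k_start = 30L, L_s = 29L,
                               gamma = 0.05))
  cw <- cumsum(w) / sum(w)
  k_start <- k[which(cw >= 0.10)[1L]]
  k_decay <- k[which(cw >= 0.60)[1L]]
  L_s <- max(1L, as.integer(k_decay - k_start))
  list(a_s = 1e-3, k_start = as.integer(k_start), L_s = L_s, gamma = 0.05)
}

#' Fit the background + shifted-Poisson + step mixture to a binned density
#'
#' Minimizes the RMSE between the observed per-gene density and the mixture
#' prediction. Components are added in stages: the constant background
#' (closed-form fit), then \code{n_poisson} shifted Poisson components one
#' at a time (each placed at the largest positive residual), then the step
#' input. Each stage starts from the previous stage's solution, so RMSE is
#' non-increasing along the staged sequence. At every stage the continuous
#' parameters are refined by bounded Levenberg--Marquardt least squares,
#' integer start classes by a local coordinate search (\eqn{\pm 3} classes),
#' and \code{restarts} seeded multiplicative perturbations of the continuous
#' parameters guard against local minima.
#'
#' @param observed a \code{binned_density} on the gene-number axis.
#' @param n_poisson number of shifted Poisson components, 0--5.
#' @param use_step include the step-with-exponential-decay input?
#' @param seed integer seed (the fit is deterministic given it).
#' @param restarts number of perturbed restarts at the final stage.
#' @param init optional \code{mixture_params} warm start (e.g. the
#'   reference fit from [default_mixture_params()]); skips the staged
#'   build-up and keeps the warm start's integer start classes fixed,
#'   refining only the continuous parameters.
#' @param L background support length in classes; defaults to the number of
#'   classes in \code{observed}.
#' @return A list of class \code{mixture_fit}: \code{params},
#'   \code{rmse}, \code{relative_error} (RMSE over the mean observed
#'   density), \code{n_components}, \code{converged}, \code{seed}.
#' @export
fit_mixture <- function(observed, n_poisson = 5L, use_step = TRUE,
                        seed = 1L, restarts = 10L, init = NULL, L = NULL) {
  stopifnot(inherits(observed, "binned_density"))
  if (length(observed$class_labels) == 0L) stop("no classes to fit")
  if (n_poisson < 0L || n_poisson > 5L)
    stop("n_poisson must be between 0 and 5")
  interval <- observed$interval
  k <- observed$class_labels / interval
  if (any(k != round(k)))
    stop("class labels must be multiples of the interval")
  k <- as.integer(round(k))
  y <- observed$density
  if (is.null(L)) L <- max(k) + 1L
  set.seed(as.integer(seed))

  if (is.null(init)) {
    # Stage 0: background only, closed form (least-squares constant).
    a_bg <- mean(y) * L * interval
    params <- mixture_params(a_bg = a_bg, L = L)
    if (n_poisson > 0L || use_step) {
      # Add Poisson components one at a time, then the step.
      for (i in seq_len(n_poisson)) {
        resid <- y - predict_mixture_density(params, k * interval, interval)
        np <- .mx_place_poisson(resid, k)
        np$a <- max(sum(pmax(resid, 0)) * interval, 1e-4)
        params$poisson <- rbind(params$poisson,
                                data.frame(a = np$a, lambda = np$lambda,
                                           k0 = np$k0))
        pk <- .mx_pack(params)
        pk <- .mx_integer_search(y, k, pk, interval)
        params <- .mx_unpack(pk$par, pk)
      }
      if (use_step) {
        resid <- y - predict_mixture_density(params, k * interval, interval)
        st <- .mx_place_step(resid, k)
        st$a_s <- max(sum(pmax(resid, 0)) * interval, 1e-4)
        params$step <- st
        params <- mixture_params(params$a_bg, params$L, params$poisson,
                                 params$step)
        pk <- .mx_pack(params)
        pk <- .mx_integer_search(y, k, pk, interval)
        params <- .mx_unpack(pk$par, pk)
      }
    }
  } else {
    params <- init
    if (nrow(params$poisson) != n_poisson ||
        is.null(params$step) == use_step)
      stop("init does not match the requested model structure")
    params <- mixture_params(params$a_bg, L, params$poisson, params$step)
  }

  pk <- .mx_pack(params)
  pk <- .mx_refine(y, k, pk, interval)
  best <- pk
  # Multi-start: perturb the continuous parameters multiplicatively.
  for (r in seq_len(restarts)) {
    cand <- pk
    cand$par <- pk$par * exp(stats::rnorm(length(pk$par), 0, 0.2))
    cand <- .mx_refine(y, k, cand, interval)
    if (!is.null(cand$rmse) && cand$rmse < best$rmse) best <- cand
  }
  # A warm start fixes the integer geometry; only blind fits keep
  # searching the start classes at the end.
  if (is.null(init))
    best <- .mx_integer_search(y, k, best, interval, sweeps = 1L)

  params <- .mx_unpack(best$par, best)
  structure(list(
    params = params,
    rmse = best$rmse,
    relative_error = best$rmse / mean(y),
    n_components = 1L + n_poisson + as.integer(use_step),
    converged = isTRUE(best$converged),
    seed = as.integer(seed)
  ), class = "mixture_fit")
}

#' Fit the geometric (naive) density model
#'
#' Least-squares fit of \eqn{f_g[k] = f_{g0} q^k}, initialized by
#' log-linear regression on the positive densities and refined by
#' Levenberg--Marquardt on the raw densities.
#'
#' @param observed a \code{binned_density} on the gene-number axis with at
#'   least two classes.
#' @return A list of class \code{geometric_fit}: \code{f_g0}, \code{q},
#'   \code{rmse}, \code{relative_error}, \code{converged}.
#' @export
fit_geometric <- function(observed) {
  stopifnot(inherits(observed, "binned_density"))
  k <- observed$class_labels / observed$interval
  y <- observed$density
  if (length(k) < 2L) stop("need at least two classes")
  pos <- y > 0
  if (sum(pos) < 2L) stop("need at least two positive densities")
  cf <- stats::coef(stats::lm(log(y[pos]) ~ k[pos]))
  p0 <- c(cf[[1L]], cf[[2L]])  # log f_g0, log q
  fit <- minpack.lm::nls.lm(p0, fn = function(p)
    exp(p[1L]) * exp(p[2L])^k - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(
    f_g0 = exp(fit$par[1L]), q = exp(fit$par[2L]),
    rmse = sqrt(mean(fit$fvec^2)),
    relative_error = sqrt(mean(fit$fvec^2)) / mean(y),
    converged = fit$info %in% 1:4
  ), class = "geometric_fit")
}

# Subset a binned density to a set of class indices (keeps n_total, so the
# densities remain globally normalized).
.subset_density <- function(bd, keep) {
  bd$class_labels <- bd$class_labels[keep]
  bd$counts <- bd$counts[keep]
  bd$density <- bd$density[keep]
  bd
}

#' Hold-out validation of the mixture fit
#'
#' Removes the classes covering a gene-number range, refits the mixture on
#' the remaining classes, and scores the refit model's predictions on the
#' held-out classes by mean relative error. The reference protocol excludes
#' the range 3001--4500 genes (classes 6, 7 and 8 of the 500-gene grid),
#' i.e. the neighbourhood of the density maximum.
#'
#' @param records a \code{genome_records} data frame.
#' @param exclude_range \code{c(lo, hi)} gene-number range to hold out,
#'   aligned to class boundaries (\code{lo - 1} and \code{hi} multiples of
#'   \code{interval}); \code{NULL} excludes nothing.
#' @param seed integer seed passed to [fit_mixture()].
#' @param interval,max_genes binning settings, as in [bin_gene_numbers()].
#' @param ... further arguments passed to [fit_mixture()] (e.g.
#'   \code{n_poisson}, \code{restarts}, \code{init}).
#' @return A list with \code{refit} (the \code{mixture_fit} on the reduced
#'   grid), \code{mean_relative_error_on_excluded}, and \code{excluded}, a
#'   data frame of per-class observed and predicted densities.
#' @export
holdout_validate <- function(records, exclude_range = c(3001, 4500),
                             seed = 1L, interval = 500L,
                             max_genes = 100000L, ...) {
  bd <- bin_gene_numbers(records, interval = interval,
                         max_genes = max_genes)
  if (is.null(exclude_range)) {
    refit <- fit_mixture(bd, seed = seed, ...)
    return(list(refit = refit, mean_relative_error_on_excluded = NA_real_,
                excluded = NULL))
  }
  lo <- exclude_range[1L]; hi <- exclude_range[2L]
  if ((lo - 1) %% interval != 0 || hi %% interval != 0)
    stop("exclude_range must be aligned to class boundaries")
  excluded_labels <- seq(lo - 1, hi - interval, by = interval)
  out <- bd$class_labels %in% excluded_labels
  if (all(out)) stop("exclusion empties the training grid")
  train <- .subset_density(bd, !out)
  refit <- fit_mixture(train, seed = seed, ...)
  obs <- bd$density[out]
  pred <- predict_mixture_density(refit$params, bd$class_labels[out],
                                  interval)
  rel <- abs(pred - obs) / ifelse(obs > 0, obs, NA_real_)
  list(refit = refit,
       mean_relative_error_on_excluded = mean(rel, na.rm = TRUE),
       excluded = data.frame(class_label = bd$class_labels[out],
                             observed = obs, predicted = pred,
                             relative_error = rel))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Mixture fit: %d components, rmse = %.4g (relative error %.1f%%), %s\n",
    x$n_components, x$rmse, 100 * x$relative_error,
    if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf(
    "Geometric fit: f_g0 = %.4g, q = %.4g, rmse = %.4g (relative error %.1f%%)\n",
    x$f_g0, x$q, x$rmse, 100 * x$relative_error))
  invisible(x)
}
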