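#' @title Distribution fitting for expression values
#' @description Expression levels across genes are well described by
#' heavy-tailed laws (power-law, lognormal and relatives). This module fits
#' six candidate families by maximum likelihood and ranks them by the Akaike
#' information criterion, so the user can judge which law their data follow
#' and, via the power-law tail, where a low signal-to-noise cutoff sits.
#' @name distfit
NULL

#' The six supported distribution families
#' @export
dist_families <- c("lognormal", "pareto", "loglogistic", "gamma",
                   "weibull", "burr")

# free-parameter counts entering the AIC
dist_n_params <- c(lognormal = 2L, pareto = 2L, loglogistic = 2L,
                   gamma = 2L, weibull = 2L, burr = 3L)

# log-likelihood given a named parameter vector
dist_loglik <- function(x, family, params) {
  ll <- switch(family,
    lognormal   = stats::dlnorm(x, params[["meanlog"]], params[["sdlog"]], log = TRUE),
    pareto      = dpareto(x, params[["shape"]], params[["minimum"]], log = TRUE),
    loglogistic = dloglogis(x, params[["shape"]], params[["scale"]], log = TRUE),
    gamma       = stats::dgamma(x, shape = params[["shape"]], rate = params[["rate"]], log = TRUE),
    weibull     = stats::dweibull(x, params[["shape"]], params[["scale"]], log = TRUE),
    burr        = dburr(x, params[["shape1"]], params[["shape2"]], params[["scale"]], log = TRUE),
    tt_stop("unknown family '%s'", family))
  sum(ll)
}

# moment-based starting values on the optimizer's scale (see dist_trans)
dist_start <- function(x, family) {
  lx <- log(x)
  mlx <- mean(lx)
  slx <- max(stats::sd(lx), 1e-3)
  switch(family,
    lognormal = c(mlx, log(slx)),
    # minimum profiled out at min(x); only log(shape) is free
    pareto = log(max(length(x) / sum(lx - log(min(x))), 1e-3)),
    # log X is logistic with scale 1/shape: sd = pi / (sqrt(3) shape)
    loglogistic = c(log(pi / (sqrt(3) * slx)), log(stats::median(x))),
    gamma = {
      m <- mean(x); v <- max(stats::var(x), 1e-12)
      log(c(m^2 / v, m / v))
    },
    # log X is Gumbel with scale 1/shape: sd = pi / (sqrt(6) shape)
    weibull = {
      sh <- pi / (sqrt(6) * slx)
      log(c(sh, exp(mlx + 0.5772156649 / sh)))
    },
    burr = c(log(pi / (sqrt(3) * slx)), 0, log(stats::median(x))))
}

# map optimizer coordinates to named natural parameters
dist_trans <- function(theta, family, x) {
  switch(family,
    lognormal   = c(meanlog = theta[1], sdlog = exp(theta[2])),
    pareto      = c(shape = exp(theta[1]), minimum = min(x)),
    loglogistic = c(shape = exp(theta[1]), scale = exp(theta[2])),
    gamma       = c(shape = exp(theta[1]), rate = exp(theta[2])),
    weibull     = c(shape = exp(theta[1]), scale = exp(theta[2])),
    burr        = c(shape1 = exp(theta[1]), shape2 = exp(theta[2]),
                    scale = exp(theta[3])))
}

# central-difference gradient of f at x
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

new_distribution_fit <- function(family, params, loglik, n, n_zero,
                                 converged, degenerate = FALSE,
                                 grad_norm = NA_real_, method = "closed_form") {
  k <- dist_n_params[[family]]
  structure(list(family = family, params = params, loglik = loglik,
                 aic = 2 * k - 2 * loglik, n_params = k, n = n,
                 n_zero_dropped = n_zero, converged = converged,
                 degenerate = degenerate, grad_norm = grad_norm,
                 method = method),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("distribution_fit: %s (n = %d%s)\n", x$family, x$n,
              if (x$n_zero_dropped > 0)
                sprintf(", %d zeros dropped", x$n_zero_dropped) else ""))
  cat("  params:", paste(sprintf("%s = %.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  loglik = %.4f, AIC = %.4f, converged = %s%s\n",
              x$loglik, x$aic, x$converged,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Fit one distribution family by maximum likelihood
#'
#' Zeros are excluded before fitting (all six supports are strictly
#' positive) and their count reported in the result. Lognormal and Pareto
#' have closed-form estimators (lognormal: mean and population sd of the
#' logs; Pareto: location fixed at the sample minimum, shape `n / sum
#' log(x/xmin)`), used by default; the other families are optimized
#' numerically on log-parameters with three fixed starting points
#' (Nelder-Mead, relative tolerance 1e-8), because the Burr likelihood in
#' particular can be multi-modal on skewed data.
#'
#' The Pareto counts 2 free parameters in the AIC even though the minimum is
#' profiled at the sample minimum, following standard practice.
#'
#' @param values positive expression values (zeros tolerated and dropped).
#' @param family one of `r paste(dist_families, collapse = ", ")`.
#' @param method `"auto"` (closed form where it exists, else numerical),
#'   `"closed_form"`, or `"numerical"`.
#' @return object of class `distribution_fit` with elements `family`,
#'   `params`, `loglik`, `aic`, `n`, `n_zero_dropped`, `converged`,
#'   `degenerate`, `grad_norm`, `method`.
#' @export
fit_family <- function(values, family = dist_families,
                       method = c("auto", "closed_form", "numerical")) {
  family <- match.arg(family)
  method <- match.arg(method)
  x <- prep_positive(values)
  n <- length(x)
  n_zero <- attr(x, "n_zero")
  if (n < 30)
    tt_warn("only %d positive values; MLE fits below n = 30 are unreliable", n)

  has_closed <- family %in% c("lognormal", "pareto")
  if (method == "closed_form" && !has_closed)
    tt_stop("no closed-form estimator for family '%s'", family)
  use_closed <- has_closed && method != "numerical"

  if (length(unique(x)) == 1L) {
    # all mass at a point: parameters run to a boundary
    params <- dist_trans(dist_start(c(x, x * 1.000001), family), family, x)
    if (family == "lognormal") params <- c(meanlog = mean(log(x)), sdlog = 0)
    return(new_distribution_fit(family, params, loglik = Inf, n = n,
                                n_zero = n_zero, converged = FALSE,
                                degenerate = TRUE, method = "degenerate"))
  }

  if (use_closed) {
    if (family == "lognormal") {
      mu <- mean(log(x))
      sigma <- sqrt(mean((log(x) - mu)^2))   # MLE divides by n
      params <- c(meanlog = mu, sdlog = sigma)
    } else {
      xmin <- min(x)
      alpha <- n / sum(log(x / xmin))
      params <- c(shape = alpha, minimum = xmin)
    }
    ll <- dist_loglik(x, family, params)
    return(new_distribution_fit(family, params, ll, n, n_zero,
                                converged = TRUE, method = "closed_form"))
  }

  nll <- function(theta) {
    p <- dist_trans(theta, family, x)
    # extreme probe points can overflow the densities; they are rejected
    v <- -suppressWarnings(dist_loglik(x, family, p))
    if (!is.finite(v)) 1e300 else v
  }
  th0 <- dist_start(x, family)
  starts <- list(th0, th0 + log(2), th0 - log(2))
  if (family == "lognormal") {
    starts <- list(th0, th0 + c(0.5, log(2)), th0 - c(0.5, log(2)))
  }
  best <- NULL
  for (s in starts) {
    fit <- if (length(s) == 1L) {
      o <- stats::optimize(nll, interval = c(s - 20, s + 20), tol = 1e-10)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      nm <- stats::optim(s, nll, method = "Nelder-Mead",
                         control = list(reltol = 1e-8, maxit = 5000))
      # quasi-Newton polish: NM's simplex stalls short of full precision
      qn <- tryCatch(
        stats::optim(nm$par, nll, method = "BFGS",
                     control = list(reltol = 1e-14, maxit = 1000)),
        error = function(e) nm)
      if (qn$value <= nm$value) qn else nm
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  params <- dist_trans(theta, family, x)
  ll <- -best$value
  gn <- sqrt(sum(num_grad(nll, theta)^2))
  converged <- best$convergence == 0 && is.finite(ll)
  new_distribution_fit(family, params, ll, n, n_zero, converged,
                       grad_norm = gn, method = "numerical")
}

# drop zeros with a recorded count; error if nothing positive remains
prep_positive <- function(values) {
  if (!is.numeric(values)) tt_stop("'values' must be numeric")
  values <- values[is.finite(values)]
  if (any(values < 0)) tt_stop("negative values are outside every supported family")
  x <- values[values > 0]
  if (length(x) == 0) tt_stop("no positive values to fit")
  attr(x, "n_zero") <- sum(values == 0)
  x
}

#' Fit several families and rank them by AIC
#'
#' All requested families are fitted by [fit_family()]; fits that fail to
#' converge are excluded from the ranking (but kept in `$fits`). Ties in AIC
#' are broken toward the family with fewer parameters.
#'
#' @inheritParams fit_family
#' @param families character vector, a subset of [dist_families].
#' @return object of class `fit_comparison`: list with `fits` (all fits, by
#'   family), `table` (ranking data.frame) and `best` (family name with the
#'   lowest AIC).
#' @export
compare_fits <- function(values, families = dist_families) {
  families <- match.arg(families, dist_families, several.ok = TRUE)
  fits <- lapply(families, function(f) fit_family(values, f))
  names(fits) <- families
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(ok)) tt_stop("no family converged; nothing to compare")
  tab <- data.frame(
    family = families,
    n_params = vapply(fits, function(f) f$n_params, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = ok,
    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[ok, , drop = FALSE]
  tab <- tab[order(tab$aic, tab$n_params), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab, best = tab$family[1]),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("fit_comparison — best family:", x$best, "\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Empirical cumulative distribution of positive expression values
#'
#' Zeros are excluded (their count is reported with a warning) because the
#' fitted families all have strictly positive support; the ECDF is the
#' right-continuous step function reaching 1 at the maximum.
#'
#' @param values expression values; at least 2 must be positive.
#' @return list of class `ecdf_result` with `support` (sorted unique
#'   values), `probs` (cumulative probabilities), `fun` (vectorized step
#'   function) and `n_zero_dropped`.
#' @export
ecdf_positive <- function(values) {
  x <- prep_positive(values)
  n_zero <- attr(x, "n_zero")
  if (length(x) < 2) tt_stop("need at least 2 positive values")
  if (n_zero > 0)
    tt_warn("%d zero values excluded from the ECDF", n_zero)
  f <- stats::ecdf(x)
  structure(list(support = sort(unique(as.numeric(x))),
                 probs = f(sort(unique(as.numeric(x)))),
                 fun = f, n_zero_dropped = n_zero),
            class = "ecdf_result")
}

#' Power-law low-expression cutoff report
#'
#' Expression below a signal-to-noise threshold (default 10, on the FPKM
#' scale) is often unreliable. This reports the fraction of values strictly
#' below the threshold and the Pareto (power-law) fit restricted to values
#' at or above it, so the user can judge how well the reliable tail follows
#' a power law.
#'
#' @param values positive expression values.
#' @param threshold cutoff on the expression scale; strict comparison (`<`).
#' @return list of class `cutoff_report`: `threshold`, `n_total`, `n_below`,
#'   `fraction_below`, `tail_fit` (a `distribution_fit`).
#' @export
powerlaw_cutoff <- function(values, threshold = 10) {
  x <- prep_positive(values)
  if (!is_scalar_number(threshold) || threshold < 0)
    tt_stop("'threshold' must be a non-negative number")
  if (threshold > max(x))
    tt_stop("threshold %g exceeds the largest value %g", threshold, max(x))
  n_below <- sum(x < threshold)
  tail <- x[x >= threshold]
  structure(list(threshold = threshold,
                 n_total = length(x),
                 n_below = n_below,
                 fraction_below = n_below / length(x),
                 tail_fit = fit_family(as.numeric(tail), "pareto")),
            class = "cutoff_report")
}
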