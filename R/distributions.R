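# Density / distribution / quantile / random generation for the three
# heavy-tailed families not shipped with base R. Parameterizations:
#   Pareto (type I):  f(x) = a * m^a / x^(a+1), x >= m (shape a, minimum m)
#   log-logistic:     f(x) = (b/a) (x/a)^(b-1) / (1 + (x/a)^b)^2
#                     (scale a, shape b)
#   Burr type XII:    f(x) = (c k / l) (x/l)^(c-1) [1 + (x/l)^c]^(-(k+1))
#                     (shape1 c, shape2 k, scale l); the log-logistic is the
#                     k = 1 special case

#' Pareto (power-law), log-logistic and Burr XII distributions
#'
#' Standard d/p/q/r quadruples for the heavy-tailed families used in
#' expression-distribution fitting. Parameterizations are stated in the
#' package vignette; the Burr density is type XII with two shape parameters
#' and one scale, of which the log-logistic (`shape2 = 1`) is a special
#' case.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param shape,scale,minimum,shape1,shape2 family parameters, all > 0.
#' @param log,log.p logical; return log-density / log-probability.
#' @name heavy-tails
NULL

#' @rdname heavy-tails
#' @export
dpareto <- function(x, shape, minimum = 1, log = FALSE) {
  ld <- ifelse(x >= minimum,
               log(shape) + shape * log(minimum) - (shape + 1) * log(x),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname heavy-tails
#' @export
ppareto <- function(q, shape, minimum = 1) {
  ifelse(q < minimum, 0, 1 - (minimum / q)^shape)
}

#' @rdname heavy-tails
#' @export
qpareto <- function(p, shape, minimum = 1) {
  minimum * (1 - p)^(-1 / shape)
}

#' @rdname heavy-tails
#' @export
rpareto <- function(n, shape, minimum = 1) {
  qpareto(stats::runif(n), shape, minimum)
}

#' @rdname heavy-tails
#' @export
dloglogis <- function(x, shape, scale = 1, log = FALSE) {
  ld <- ifelse(x > 0,
               log(shape) - log(scale) +
                 (shape - 1) * (log(x) - log(scale)) -
                 2 * log1p((x / scale)^shape),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname heavy-tails
#' @export
ploglogis <- function(q, shape, scale = 1) {
  ifelse(q <= 0, 0, 1 / (1 + (q / scale)^(-shape)))
}

#' @rdname heavy-tails
#' @export
qloglogis <- function(p, shape, scale = 1) {
  scale * (p / (1 - p))^(1 / shape)
}

#' @rdname heavy-tails
#' @export
rloglogis <- function(n, shape, scale = 1) {
  qloglogis(stats::runif(n), shape, scale)
}

#' @rdname heavy-tails
#' @export
dburr <- function(x, shape1, shape2, scale = 1, log = FALSE) {
  ld <- ifelse(x > 0,
               log(shape1) + log(shape2) - log(scale) +
                 (shape1 - 1) * (log(x) - log(scale)) -
                 (shape2 + 1) * log1p((x / scale)^shape1),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname heavy-tails
#' @export
pburr <- function(q, shape1, shape2, scale = 1) {
  ifelse(q <= 0, 0, 1 - (1 + (q / scale)^shape1)^(-shape2))
}

#' @rdname heavy-tails
#' @export
qburr <- function(p, shape1, shape2, scale = 1) {
  scale * ((1 - p)^(-1 / shape2) - 1)^(1 / shape1)
}

#' @rdname heavy-tails
#' @export
rburr <- function(n, shape1, shape2, scale = 1) {
  qburr(stats::runif(n), shape1, shape2, scale)
}
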