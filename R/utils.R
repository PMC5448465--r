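# Internal numerical helpers: Box-Cox transforms, Gauss-Hermite quadrature,
# survey-weighted quantiles, reproducible sub-stream seeding, and the
# exact-fraction sampler used for salt-use assignment.

#' Box-Cox transformation
#'
#' Forward power transform \eqn{g(y) = (y^\lambda - 1)/\lambda} (natural log
#' for \eqn{\lambda = 0}).
#'
#' @param y positive numeric vector.
#' @param lambda transformation parameter.
#' @return transformed values.
#' @keywords internal
#' @noRd
box_cox <- function(y, lambda) {
  if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
}

#' Inverse Box-Cox; arguments outside the domain (lambda*z + 1 <= 0 for
#' lambda > 0) map to 0, since a daily intake cannot be negative.
#' @noRd
inv_box_cox <- function(z, lambda) {
  if (abs(lambda) < 1e-8) return(exp(z))
  base <- lambda * z + 1
  out <- numeric(length(z))
  ok <- base > 0
  out[ok] <- base[ok]^(1 / lambda)
  if (lambda < 0 && any(!is.finite(out))) {
    stop("inverse Box-Cox produced non-finite values; ",
         "refit with a lambda floor (lambda >= 0)", call. = FALSE)
  }
  out
}

#' Gauss-Hermite nodes and weights (Golub-Welsch, physicists' convention:
#' integrates f against exp(-x^2)).
#' @noRd
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

#' Expectation of h(mu + e), e ~ Normal(0, sigma2), by Gauss-Hermite
#' quadrature. `mu` may be a vector; returns one value per element.
#' @noRd
gh_expect <- function(h, mu, sigma2, order = 15L) {
  if (sigma2 <= 0) return(h(mu))
  gh <- gauss_hermite(order)
  s <- sqrt(2 * sigma2)
  out <- numeric(length(mu))
  for (k in seq_along(gh$nodes)) {
    out <- out + gh$weights[k] * h(mu + s * gh$nodes[k])
  }
  out / sqrt(pi)
}

#' Survey-weighted quantile by inversion of the right-continuous weighted
#' empirical distribution function: the smallest x with F_w(x) >= p.
#'
#' @param x numeric values.
#' @param w positive weights, same length.
#' @param probs probabilities in (0, 1).
#' @return numeric vector, one quantile per element of `probs`.
#' @keywords internal
#' @noRd
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(is.finite(w)))
  if (length(x) == 0L) stop("empty distribution", call. = FALSE)
  if (any(probs <= 0 | probs >= 1)) {
    stop("probs must lie strictly between 0 and 1", call. = FALSE)
  }
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Weighted mean fraction of values satisfying a predicate.
#' @noRd
weighted_prop <- function(flag, w) {
  sum(w[flag]) / sum(w)
}

#' Evaluate an expression under a temporary RNG state derived from a seed,
#' restoring the caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive the sub-stream seed for one Monte Carlo iteration from a root seed.
#' Counter-based: seed and iteration are mixed by a fixed linear congruence
#' so that any iteration is reproducible in isolation.
#' @noRd
iteration_seed <- function(seed, iteration) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
              as.numeric(iteration) * 16807) %% 2147483629)
}

#' Sample an exact fraction of a set: round(p * n) elements (round half to
#' even, as base round() does), drawn without replacement.
#'
#' Returns a logical vector marking the selected elements. Mirrors a
#' fixed-proportion survey draw rather than independent Bernoulli trials.
#' @noRd
draw_exact_fraction <- function(n, p) {
  stopifnot(p >= 0, p <= 1)
  k <- round(p * n)
  sel <- logical(n)
  if (k > 0) sel[sample.int(n, k)] <- TRUE
  sel
}

#' Convert added sodium (mg per 100 g food) to added salt (g per 100 g food).
#'
#' Salt (NaCl) is about 2.5 times its sodium mass; 1000 converts mg to g.
#'
#' @param sodium_mg_100g numeric, added sodium in mg per 100 g of food.
#' @return added salt in g per 100 g of food.
#' @export
#' @examples
#' sodium_to_salt(400) # 1 g salt per 100 g
sodium_to_salt <- function(sodium_mg_100g) {
  sodium_mg_100g * 2.5 / 1000
}
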