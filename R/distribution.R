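# Survey-weighted intake distributions: a set of per-individual habitual
# intake values with survey weights, representing a population
# distribution, with percentile and prevalence queries.

#' Construct an intake distribution
#'
#' @param df data frame with columns `habitual` (ug/d) and `weight`
#'   (positive, finite); optionally `subject_id`, `age`, `sex` (needed for
#'   band-level evaluation).
#' @return object of class `intake_dist` (a data frame).
#' @export
intake_dist <- function(df) {
  stopifnot(all(c("habitual", "weight") %in% names(df)))
  if (nrow(df) == 0L) fail("intake_dist: empty distribution")
  if (any(!is.finite(df$weight) | df$weight <= 0)) {
    fail("intake_dist: weights must be positive and finite")
  }
  if (any(!is.finite(df$habitual))) {
    fail("intake_dist: non-finite habitual values")
  }
  class(df) <- c("intake_dist", "data.frame")
  df
}

#' Survey-weighted quantiles of an intake distribution
#'
#' Inverts the weighted empirical distribution function; monotone in `probs`.
#'
#' @param x an `intake_dist`.
#' @param probs probabilities in (0, 1).
#' @param ... unused.
#' @return named numeric vector of quantiles (ug/d).
#' @export
quantile.intake_dist <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                 ...) {
  q <- weighted_quantile(x$habitual, x$weight, probs)
  names(q) <- paste0("p", probs * 100)
  q
}

#' @export
mean.intake_dist <- function(x, ...) {
  sum(x$habitual * x$weight) / sum(x$weight)
}

#' @export
print.intake_dist <- function(x, ...) {
  q <- quantile(x)
  cat(sprintf(
    "Weighted intake distribution: n = %d, mean = %.1f ug/d\n", nrow(x),
    mean(x)))
  print(round(q, 1))
  invisible(x)
}

#' Prevalence of inadequate and excessive intake
#'
#' The EAR cut-point method: the prevalence of inadequate intake is the
#' weighted fraction of the habitual distribution below the estimated
#' average requirement; excess is the weighted fraction above the tolerable
#' upper intake level.
#'
#' @param dist an `intake_dist`.
#' @param ear estimated average requirement (ug/d).
#' @param ul tolerable upper intake level (ug/d); `Inf` to skip.
#' @return named vector `c(below_ear, above_ul)` of weighted fractions.
#' @export
prevalence <- function(dist, ear, ul = Inf) {
  stopifnot(inherits(dist, "intake_dist"))
  c(below_ear = weighted_prop(dist$habitual < ear, dist$weight),
    above_ul = weighted_prop(dist$habitual > ul, dist$weight))
}

#' Per-band prevalence and percentiles against a DRI table
#'
#' Evaluates an intake distribution within each age-sex band of a DRI
#' table: weighted percentiles, weighted mean, P(< EAR) and P(> UL).
#'
#' @param dist an `intake_dist` with `age` and `sex` columns.
#' @param dri validated DRI table.
#' @param probs percentile probabilities.
#' @return data frame, one row per band.
#' @export
evaluate_bands <- function(dist, dri, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(all(c("age", "sex") %in% names(dist)))
  bi <- band_index(dri, dist$age, dist$sex)
  rows <- lapply(seq_len(nrow(dri)), function(i) {
    sel <- which(bi == i)
    if (!length(sel)) {
      fail("evaluate_bands: no individuals in band ", band_label(dri)[i])
    }
    d <- intake_dist(dist[sel, , drop = FALSE])
    pr <- prevalence(d, dri$ear[i], dri$ul[i])
    q <- quantile(d, probs)
    out <- data.frame(band = band_label(dri)[i], sex = dri$sex[i],
                      age_low = dri$age_low[i], age_high = dri$age_high[i],
                      n = nrow(d), mean = mean(d), stringsAsFactors = FALSE)
    for (k in seq_along(q)) out[[names(q)[k]]] <- q[k]
    out$below_ear <- pr[["below_ear"]]
    out$above_ul <- pr[["above_ul"]]
    out
  })
  do.call(rbind, rows)
}
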