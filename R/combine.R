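# Combination of the four source-specific habitual distributions by Monte
# Carlo simulation ("first shrink then add"): each simulated individual
# draws an age-sex stratum by survey weight and then one habitual value
# per source conditional on that stratum, independently across sources
# given the stratum. Ensemble summaries quantify the spread induced by the
# repeated salt-use assignments.

#' Combine source-specific habitual distributions by Monte Carlo
#'
#' @param dists list of `intake_dist` objects (typically the four sources:
#'   natural, manufacturer salt, discretionary salt, supplements), each
#'   with `age` and `sex` columns and covering every stratum.
#' @param strata data frame `age_low`, `age_high`, `sex` defining the
#'   age-sex strata (e.g. the DRI table).
#' @param mc_size number of simulated individuals.
#' @param seed integer seed; deterministic given the seed.
#' @param by_person if `TRUE`, draw whole persons instead: one subject per
#'   simulated individual, summing that subject's values across all
#'   distributions (requires matching subject ids). Retains any
#'   person-level correlation between sources; the default assumes
#'   conditional independence given the stratum.
#' @return an `intake_dist` of `mc_size` simulated individuals (weight 1).
#' @export
combine_sources <- function(dists, strata, mc_size = 1e5, seed = 1L,
                            by_person = FALSE) {
  stopifnot(length(dists) >= 1)
  for (d in dists) {
    stopifnot(inherits(d, "intake_dist"))
    if (nrow(d) == 0L) fail("combine_sources: empty source distribution")
  }
  if (by_person) {
    base <- dists[[1]]
    tot <- base$habitual
    for (d in dists[-1]) {
      idx <- match(base$subject_id, d$subject_id)
      if (anyNA(idx)) fail("combine_sources: by_person requires matching ",
                           "subject ids across sources")
      tot <- tot + d$habitual[idx]
    }
    persons <- data.frame(age = base$age, sex = base$sex, habitual = tot,
                          weight = base$weight, stringsAsFactors = FALSE)
    return(with_seed(seed, {
      pick <- sample.int(nrow(persons), mc_size, replace = TRUE,
                         prob = persons$weight / sum(persons$weight))
      intake_dist(data.frame(age = persons$age[pick],
                             sex = persons$sex[pick],
                             habitual = persons$habitual[pick], weight = 1,
                             stringsAsFactors = FALSE))
    }))
  }
  ns <- nrow(strata)
  idx_by_stratum <- lapply(dists, function(d) {
    bi <- band_index(strata, d$age, d$sex)
    lapply(seq_len(ns), function(s) which(bi == s))
  })
  # a stratum absent from every source simply carries no population; a
  # stratum populated in one source but empty in another is an error
  pop <- vapply(seq_len(ns), function(s) {
    any(vapply(idx_by_stratum, function(ix) length(ix[[s]]) > 0, logical(1)))
  }, logical(1))
  for (k in seq_along(dists)) {
    empty <- which(pop & !vapply(idx_by_stratum[[k]], length, integer(1)))
    if (length(empty)) {
      fail("combine_sources: source ", k, " has no individuals in ",
           "stratum ", paste(band_label(strata)[empty], collapse = ", "))
    }
  }
  # stratum probabilities from the first source's weights
  wsum <- vapply(seq_len(ns), function(s) {
    if (!pop[s]) return(0)
    sum(dists[[1]]$weight[idx_by_stratum[[1]][[s]]])
  }, numeric(1))
  with_seed(seed, {
    strat <- sample.int(ns, mc_size, replace = TRUE, prob = wsum / sum(wsum))
    total <- numeric(mc_size)
    age <- integer(mc_size)
    sex <- character(mc_size)
    for (s in seq_len(ns)) {
      who <- which(strat == s)
      if (!length(who)) next
      for (k in seq_along(dists)) {
        rows <- idx_by_stratum[[k]][[s]]
        w <- dists[[k]]$weight[rows]
        pick <- rows[sample.int(length(rows), length(who), replace = TRUE,
                                prob = w / sum(w))]
        total[who] <- total[who] + dists[[k]]$habitual[pick]
        if (k == 1L) {
          age[who] <- dists[[1]]$age[pick]
          sex[who] <- dists[[1]]$sex[pick]
        }
      }
    }
    intake_dist(data.frame(age = age, sex = sex, habitual = total,
                           weight = 1, stringsAsFactors = FALSE))
  })
}

#' Average source contributions to total intake
#'
#' For each individual (matched across sources by subject id) the fraction
#' of total habitual intake contributed by each source is computed; the
#' survey-weighted mean and SD of these fractions are reported per source.
#' Individuals with zero total are excluded with a warning.
#'
#' @param dists named list of `intake_dist` objects over the same subjects.
#' @return data frame `source`, `mean_share`, `sd_share` (fractions; means
#'   sum to 1), with attribute `n_excluded`.
#' @export
source_shares <- function(dists) {
  stopifnot(length(dists) >= 1, !is.null(names(dists)))
  base <- dists[[1]]
  vals <- vapply(dists, function(d) {
    idx <- match(base$subject_id, d$subject_id)
    if (anyNA(idx)) fail("source_shares: sources cover different subjects")
    d$habitual[idx]
  }, numeric(nrow(base)))
  vals <- matrix(vals, nrow = nrow(base),
                 dimnames = list(NULL, names(dists)))
  total <- rowSums(vals)
  keep <- total > 0
  n_excl <- sum(!keep)
  if (n_excl == nrow(vals)) fail("source_shares: all totals are zero")
  if (n_excl > 0) {
    warning(n_excl, " individual(s) with zero total intake excluded from ",
            "source shares", call. = FALSE)
  }
  sh <- vals[keep, , drop = FALSE] / total[keep]
  w <- base$weight[keep]
  m <- colSums(sh * w) / sum(w)
  s <- sqrt(colSums(t(t(sh) - m)^2 * w) / sum(w))
  structure(data.frame(source = names(dists), mean_share = m, sd_share = s,
                       row.names = NULL, stringsAsFactors = FALSE),
            n_excluded = n_excl)
}

#' Summarise an ensemble of per-iteration statistics
#'
#' For every numeric statistic reported per iteration (band percentiles,
#' prevalences, source shares, ...), computes the median, SD and central
#' 2.5-97.5 percent range across iterations.
#'
#' @param per_iteration list of data frames of identical layout, one per
#'   iteration; non-numeric columns are treated as grouping keys.
#' @return data frame with one row per (key, statistic): `median`, `sd`,
#'   `q2.5`, `q97.5`, `min`, `max`.
#' @export
summarise_ensemble <- function(per_iteration) {
  stopifnot(length(per_iteration) >= 1)
  tmpl <- per_iteration[[1]]
  num_cols <- names(tmpl)[vapply(tmpl, is.numeric, logical(1))]
  key_cols <- setdiff(names(tmpl), num_cols)
  rows <- list()
  for (r in seq_len(nrow(tmpl))) {
    for (cl in num_cols) {
      v <- vapply(per_iteration, function(d) d[[cl]][r], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        key = if (length(key_cols)) {
          paste(unlist(tmpl[r, key_cols]), collapse = "|")
        } else as.character(r),
        statistic = cl,
        median = stats::median(v), sd = stats::sd(v),
        q2.5 = unname(stats::quantile(v, 0.025, type = 1)),
        q97.5 = unname(stats::quantile(v, 0.975, type = 1)),
        min = min(v), max = max(v),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$sd[is.na(out$sd)] <- 0  # single iteration
  out
}
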