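# The habitual-intake measurement-error model (one-part).
#
# Daily intakes y_ij (subject i, recall day j) are modelled on a Box-Cox
# transformed scale as
#
#   g(y_ij; lambda) = f(age_i) + b_i + e_ij,
#   b_i ~ N(0, sigma_b^2),  e_ij ~ N(0, sigma_w^2)  (independent),
#
# with f a spline age trend fitted separately by sex. lambda is estimated
# by profile maximum likelihood on the pooled daily data (or fixed by the
# caller); the variance components by (survey-weight pseudo-) REML, which
# is cheap here because the fixed-effect design is constant within subject.
# The habitual (long-run average) intake of subject i is
#
#   H_i = E_e[ g^{-1}(f(age_i) + b*_i + e) ],
#
# a Gauss-Hermite integral over the within-person noise, where b*_i is the
# subject's shrunken person effect rescaled so that the set of person
# effects has variance sigma_b^2 (variance-preserving shrinkage, as in
# classical usual-intake estimation): plain best-linear-unbiased-predictor
# shrinkage would understate the spread of the habitual distribution and
# bias its outer percentiles inward.

make_basis <- function(age, df_spline = 3L) {
  ua <- sort(unique(age))
  if (length(ua) >= 7L && length(age) >= 30L) {
    nk <- max(1L, min(df_spline, length(ua) - 4L))
    knots <- stats::quantile(age, probs = seq_len(nk) / (nk + 1L),
                             type = 1, names = FALSE)
    bnd <- range(ua)
    list(type = "spline", knots = unique(knots), boundary = bnd, degree = 3L)
  } else if (length(ua) >= 2L) {
    list(type = "linear")
  } else {
    list(type = "intercept")
  }
}

eval_basis <- function(basis, age) {
  switch(basis$type,
    spline = {
      # clamp ages outside the fitted range to the boundary
      a <- pmin(pmax(age, basis$boundary[1]), basis$boundary[2])
      cbind(1, splines::bs(a, knots = basis$knots, degree = basis$degree,
                           Boundary.knots = basis$boundary))
    },
    linear = cbind(1, age),
    intercept = matrix(1, length(age), 1L)
  )
}

# Profile log-likelihood for the Box-Cox parameter on pooled daily data
# (weighted least squares on the age basis, clustering ignored at this
# stage; lambda only needs the marginal fit).
profile_lambda <- function(y, X, w, interval = c(-0.5, 2)) {
  sw <- sum(w)
  neg_ll <- function(lam) {
    z <- box_cox(y, lam)
    fit <- stats::lm.wfit(X, z, w)
    rss <- sum(w * fit$residuals^2)
    if (!is.finite(rss) || rss <= 0) return(Inf)
    sw / 2 * log(rss / sw) - (lam - 1) * sum(w * log(y))
  }
  stats::optimize(neg_ll, interval = interval)$minimum
}

# Survey-weight pseudo-REML for the two variance components, exploiting the
# within-subject-constant design: beta solves a weighted regression of the
# subject mean on the age basis with weights w_i * n_i / (1 + phi n_i).
fit_variance_components <- function(zbar, ssw, n_days, Xs, w) {
  N <- sum(w * n_days)
  p <- qr(Xs)$rank
  crit <- function(phi) {
    d <- n_days / (1 + phi * n_days)
    fit <- stats::lm.wfit(Xs, zbar, w * d)
    m <- fit$residuals
    Q <- sum(w * (ssw + d * m^2))
    s2w <- Q / (N - p)
    if (!is.finite(s2w) || s2w <= 0) return(list(obj = Inf))
    A <- crossprod(Xs * sqrt(w * d))
    obj <- (N - p) * log(s2w) + sum(w * log1p(phi * n_days)) +
      determinant(A, logarithm = TRUE)$modulus
    list(obj = as.numeric(obj), beta = fit$coefficients, m = m, s2w = s2w)
  }
  # profile over phi = sigma_b^2 / sigma_w^2, including the boundary phi = 0
  opt <- stats::optimize(function(phi) crit(phi)$obj,
                         interval = c(1e-8, 1e3))
  cand <- if (crit(0)$obj <= opt$objective) 0 else opt$minimum
  res <- crit(cand)
  beta <- res$beta
  beta[is.na(beta)] <- 0
  list(phi = cand, beta = beta, resid_mean = res$m,
       sigma2_w = res$s2w, sigma2_b = cand * res$s2w)
}

fit_one_group <- function(daily, lambda, df_spline, weighted, gh_order) {
  sid <- daily$subject_id
  ord <- order(sid, daily$day)
  daily <- daily[ord, , drop = FALSE]
  y <- daily$intake

  shift <- 0
  if (any(y <= 0)) {
    pos <- y[y > 0]
    if (!length(pos)) fail("hab_fit: all intakes are zero")
    shift <- min(pos) / 2
    y <- y + shift
  }

  sub <- daily[!duplicated(daily$subject_id),
               c("subject_id", "age", "sex", "survey_weight")]
  si <- match(daily$subject_id, sub$subject_id)
  n_days <- tabulate(si, nbins = nrow(sub))
  if (!any(n_days >= 2L)) {
    fail("hab_fit: no subject has 2 recall days; ",
         "within-person variance is not identifiable")
  }
  w_sub <- if (weighted) sub$survey_weight else rep(1, nrow(sub))
  w_sub <- w_sub * sum(n_days) / sum(w_sub * n_days)  # mean obs weight 1
  w_obs <- w_sub[si]

  basis <- make_basis(sub$age, df_spline)
  X <- eval_basis(basis, daily$age)
  Xs <- eval_basis(basis, sub$age)

  degenerate <- stats::var(y) < 1e-20 || length(y) < 2L
  if (is.null(lambda)) {
    lambda <- if (degenerate) 1 else profile_lambda(y, X, w_obs)
    lambda_estimated <- TRUE
  } else {
    lambda_estimated <- FALSE
  }

  z <- box_cox(y, lambda)
  zbar <- as.numeric(tapply(z, si, mean))
  ssw <- as.numeric(tapply(z, si, function(v) sum((v - mean(v))^2)))

  if (degenerate) {
    fit0 <- stats::lm.wfit(Xs, zbar, w_sub)
    beta <- fit0$coefficients
    beta[is.na(beta)] <- 0
    vc <- list(phi = 0, beta = beta, resid_mean = fit0$residuals,
               sigma2_w = 0, sigma2_b = 0)
  } else {
    vc <- fit_variance_components(zbar, ssw, n_days, Xs, w_sub)
  }

  # variance-preserving shrinkage of the person effect
  s2b <- vc$sigma2_b
  s2w <- vc$sigma2_w
  scale_i <- if (s2b > 0) sqrt(s2b) / sqrt(s2b + s2w / n_days) else
    rep(0, nrow(sub))
  b_star <- scale_i * vc$resid_mean
  mu <- as.numeric(Xs %*% vc$beta) + b_star

  habitual <- if (abs(lambda - 1) < 1e-8 || s2w == 0) {
    inv_box_cox(mu, lambda)
  } else {
    gh_expect(function(v) inv_box_cox(v, lambda), mu, s2w, gh_order)
  }
  habitual <- pmax(habitual - shift, 0)

  list(lambda = lambda, lambda_estimated = lambda_estimated, shift = shift,
       basis = basis, beta = vc$beta, phi = vc$phi,
       sigma2_b = s2b, sigma2_w = s2w,
       subjects = data.frame(sub,
                             n_days = n_days,
                             resid_mean = vc$resid_mean,
                             b_star = b_star,
                             mu = mu,
                             habitual = habitual,
                             stringsAsFactors = FALSE),
       n_obs = length(y))
}

#' Fit the one-part habitual-intake model
#'
#' Estimates the habitual (long-run average, within-person-variation-free)
#' intake distribution from repeated daily intakes: Box-Cox transformation,
#' spline age trend, between- and within-person normal variance components,
#' and Gauss-Hermite back-transformation of variance-preserving shrunken
#' person effects. Fitted separately by sex when each sex has enough
#' subjects to support its own age trend.
#'
#' @param daily data frame with `subject_id`, `day`, `intake` (ug/d; one
#'   row per subject-day).
#' @param subjects subjects table (for `age`, `sex`, `survey_weight`).
#' @param lambda Box-Cox parameter; `NULL` (default) estimates it by
#'   profile maximum likelihood on the pooled daily data.
#' @param df_spline number of interior knots of the cubic B-spline age
#'   trend (reduced automatically for small or age-homogeneous data).
#' @param by_sex fit separately per sex (default); falls back to a pooled
#'   fit when a sex has fewer than 30 subjects.
#' @param weighted use survey weights in estimation (default `TRUE`).
#' @param gh_order Gauss-Hermite quadrature order for the back-transform.
#' @param require_two_days error unless every subject has exactly 2 days
#'   (the standard recall design). Set `FALSE` for unbalanced data such as
#'   the positive-day amounts of a two-part model.
#' @return an object of class `hab_fit`; see [habitual()],
#'   [predict.hab_fit()], [coef.hab_fit()].
#' @seealso [hab_fit2()] for episodic sources with never-consumers.
#' @export
#' @examples
#' dat <- simulate_survey(150, gt_preset("lognormal"), seed = 42)
#' nat <- natural_iodine(dat$consumption, dat$composition, dat$subjects)
#' fit <- hab_fit(nat, dat$subjects)
#' fit
#' quantile(habitual(fit), c(0.05, 0.5, 0.95))
hab_fit <- function(daily, subjects, lambda = NULL, df_spline = 3L,
                    by_sex = TRUE, weighted = TRUE, gh_order = 15L,
                    require_two_days = TRUE) {
  stopifnot(all(c("subject_id", "day", "intake") %in% names(daily)))
  keep <- c("subject_id", "age", "sex", "survey_weight")
  daily <- merge(daily[, c("subject_id", "day", "intake")],
                 subjects[, keep], by = "subject_id")
  if (!nrow(daily)) fail("hab_fit: no daily intake data")
  nd <- table(daily$subject_id)
  if (require_two_days && any(nd != 2L)) {
    fail("hab_fit: every subject needs exactly 2 recall days; offending ",
         "subject_id: ", paste(utils::head(names(nd)[nd != 2L], 5),
                               collapse = ", "))
  }
  split_sex <- by_sex && length(unique(daily$sex)) > 1L &&
    all(table(unique(daily[, c("subject_id", "sex")])$sex) >= 30L)
  groups <- if (split_sex) split(daily, daily$sex) else list(all = daily)
  fits <- lapply(groups, fit_one_group, lambda = lambda,
                 df_spline = df_spline, weighted = weighted,
                 gh_order = gh_order)
  structure(list(fits = fits, by_sex = split_sex, weighted = weighted,
                 gh_order = gh_order, call = match.call()),
            class = "hab_fit")
}

#' Habitual intake distribution of a fitted model
#'
#' Extracts the per-subject habitual intakes and survey weights as an
#' [intake_dist] object.
#'
#' @param fit a `hab_fit`, `hab_fit2` or `suppl_fit` object.
#' @param ... unused.
#' @return an `intake_dist`.
#' @export
habitual <- function(fit, ...) UseMethod("habitual")

#' @export
habitual.hab_fit <- function(fit, ...) {
  sub <- do.call(rbind, lapply(fit$fits, `[[`, "subjects"))
  intake_dist(data.frame(subject_id = sub$subject_id, age = sub$age,
                         sex = sub$sex, habitual = sub$habitual,
                         weight = sub$survey_weight,
                         stringsAsFactors = FALSE))
}

#' @export
print.hab_fit <- function(x, ...) {
  cat("Habitual intake model (one-part)\n")
  for (g in names(x$fits)) {
    f <- x$fits[[g]]
    cat(sprintf(
      "  %s: n = %d subjects, lambda = %.3f%s, sigma_b = %.3f, sigma_w = %.3f\n",
      g, nrow(f$subjects), f$lambda,
      if (f$lambda_estimated) " (estimated)" else " (fixed)",
      sqrt(f$sigma2_b), sqrt(f$sigma2_w)))
  }
  d <- habitual(x)
  q <- quantile(d, c(0.05, 0.5, 0.95))
  cat(sprintf("  habitual P5/P50/P95: %.1f / %.1f / %.1f ug/d\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' @export
coef.hab_fit <- function(object, ...) {
  t(vapply(object$fits, function(f) {
    c(lambda = f$lambda, sigma_b = sqrt(f$sigma2_b),
      sigma_w = sqrt(f$sigma2_w), shift = f$shift)
  }, numeric(4)))
}

#' @export
summary.hab_fit <- function(object, ...) {
  d <- habitual(object)
  structure(list(coef = coef.hab_fit(object),
                 quantiles = quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95)),
                 mean = mean(d), n = nrow(d)),
            class = "summary.hab_fit")
}

#' @export
print.summary.hab_fit <- function(x, ...) {
  cat("Habitual intake model: parameter estimates\n")
  print(round(x$coef, 4))
  cat(sprintf("\nWeighted habitual distribution (n = %d):\n  mean %.1f ug/d\n",
              x$n, x$mean))
  print(round(x$quantiles, 1))
  invisible(x)
}

#' Predict from a habitual-intake model
#'
#' `type = "habitual"` returns the per-subject habitual intakes of the
#' fitted population (shrinkage requires the subjects' own recall data, so
#' `newdata` is not used). `type = "mean"` returns the model's
#' back-transformed population age curve
#' `E[g^{-1}(f(age) + b + e)]` over both noise components for the ages and
#' sexes in `newdata`.
#'
#' @param object a `hab_fit`.
#' @param newdata data frame with `age` and `sex` (for `type = "mean"`).
#' @param type see above.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.hab_fit <- function(object, newdata = NULL,
                            type = c("habitual", "mean"), ...) {
  type <- match.arg(type)
  if (type == "habitual") return(habitual(object)$habitual)
  if (is.null(newdata)) fail("predict: newdata required for type = 'mean'")
  out <- numeric(nrow(newdata))
  for (g in names(object$fits)) {
    f <- object$fits[[g]]
    sel <- if (object$by_sex) newdata$sex == g else rep(TRUE, nrow(newdata))
    if (!any(sel)) next
    mu <- as.numeric(eval_basis(f$basis, newdata$age[sel]) %*% f$beta)
    tot <- f$sigma2_b + f$sigma2_w
    v <- if (tot > 0) {
      gh_expect(function(x) inv_box_cox(x, f$lambda), mu, tot,
                object$gh_order)
    } else inv_box_cox(mu, f$lambda)
    out[sel] <- pmax(v - f$shift, 0)
  }
  out
}

#' @export
residuals.hab_fit <- function(object, ...) {
  unlist(lapply(object$fits, function(f) {
    r <- f$subjects$resid_mean
    names(r) <- f$subjects$subject_id
    r
  }), use.names = TRUE)
}

#' Simulate recall data from a fitted habitual-intake model
#'
#' Parametric bootstrap: draws new person effects and day errors from the
#' fitted model for the fitted population and back-transforms, giving
#' `nsim` replicate 2-day datasets.
#'
#' @param object a `hab_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` data frames (`subject_id`, `day`, `intake`).
#' @export
simulate.hab_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    parts <- lapply(object$fits, function(f) {
      n <- nrow(f$subjects)
      mu_f <- f$subjects$mu - f$subjects$b_star
      b <- stats::rnorm(n, 0, sqrt(f$sigma2_b))
      out <- lapply(1:2, function(day) {
        e <- stats::rnorm(n, 0, sqrt(f$sigma2_w))
        data.frame(subject_id = f$subjects$subject_id, day = day,
                   intake = pmax(inv_box_cox(mu_f + b + e, f$lambda) -
                                   f$shift, 0),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    })
    reps[[r]] <- do.call(rbind, parts)
  }
  reps
}

#' @export
plot.hab_fit <- function(x, ...) {
  d <- habitual(x)
  graphics::plot(d$age, d$habitual, col = ifelse(d$sex == "male", 4, 2),
                 pch = 16, cex = 0.5, xlab = "age (years)",
                 ylab = "habitual intake (ug/d)",
                 main = "Habitual intake by age", ...)
  ages <- seq(min(d$age), max(d$age))
  for (s in unique(d$sex)) {
    nd <- data.frame(age = ages, sex = s)
    graphics::lines(ages, predict(x, nd, type = "mean"),
                    col = ifelse(s == "male", 4, 2), lwd = 2)
  }
  invisible(x)
}
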