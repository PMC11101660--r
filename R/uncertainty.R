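#' Beta parameterisation of penetrance uncertainty
#'
#' The uncertainty in a penetrance estimate \eqn{p} with precision \eqn{n}
#' is modelled as \eqn{\mathrm{Beta}(\alpha, \beta)} with
#' \eqn{\alpha = n p} and \eqn{\beta = n (1 - p)} --- the posterior one
#' would obtain from a hypothetical trial of \eqn{n} carriers with a flat
#' improper prior, so the mean reproduces \eqn{p} exactly and larger
#' \eqn{n} means a tighter distribution.
#'
#' @param penetrance Penetrance estimate in \[0, 1\].
#' @param precision Positive effective trial size \eqn{n}.
#' @return A list of class `beta_uncertainty` with elements `alpha`,
#'   `beta` and `point_mass` (`TRUE` when the penetrance is exactly 0 or
#'   1, in which case no Beta distribution is fit and downstream summaries
#'   treat the penetrance as known exactly; `alpha`/`beta` are then `NA`
#'   and the degenerate value is kept in `value`).
#' @examples
#' beta_params(0.2, 100)   # Beta(20, 80)
#' @export
beta_params <- function(penetrance, precision) {
  check_probability(penetrance, "penetrance")
  check_positive(precision, "precision")
  if (penetrance == 0 || penetrance == 1) {
    return(structure(list(alpha = NA_real_, beta = NA_real_,
                          point_mass = TRUE, value = penetrance),
                     class = "beta_uncertainty"))
  }
  structure(list(alpha = precision * penetrance,
                 beta = precision * (1 - penetrance),
                 point_mass = FALSE, value = penetrance),
            class = "beta_uncertainty")
}

pair_beta <- function(pair) beta_params(pair$penetrance, pair$precision)

#' Equal-tailed credible interval for a penetrance
#'
#' Exact Beta quantiles at \eqn{(1-\mathrm{level})/2} and
#' \eqn{1-(1-\mathrm{level})/2}; no normal approximation is used, which
#' matters at small precision where the Beta is strongly skewed.
#'
#' @inheritParams net_utility_pair
#' @param level Interval mass in (0, 1), e.g. 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
penetrance_interval <- function(pair, level = 0.95) {
  pair <- as_pair_fields(pair)
  check_level(level)
  bu <- pair_beta(pair)
  if (bu$point_mass) {
    return(c(lower = bu$value, upper = bu$value))
  }
  q <- stats::qbeta(c((1 - level) / 2, 1 - (1 - level) / 2),
                    bu$alpha, bu$beta)
  c(lower = q[1], upper = q[2])
}

check_level <- function(level) {
  if (length(level) != 1 || !is.numeric(level) || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  invisible(level)
}

#' Probability that a pair's net utility is positive
#'
#' Net utility is increasing in the penetrance, so
#' \eqn{\Pr(\Delta > 0)} equals the Beta upper-tail probability beyond the
#' cut point
#' \deqn{c = \frac{\delta_{G+D-} - K/\Pr(G=1)}{\delta_{G+D-} +
#'   \delta_{G-D+}},}
#' computed analytically from the Beta survival function. A cut below 0
#' gives probability 1, above 1 gives 0. For a point-mass penetrance the
#' result is the indicator of a positive plug-in net utility.
#'
#' @inheritParams net_utility_pair
#' @return A probability in \[0, 1\].
#' @export
prob_positive_pair <- function(pair, d) {
  pair <- as_pair_fields(pair)
  stopifnot(inherits(d, "disutility_spec"))
  bu <- pair_beta(pair)
  k <- pair$test_disutility
  if (k != 0 && pair$carrier_prevalence == 0) {
    stop("carrier_prevalence must be > 0 when test_disutility is nonzero",
         call. = FALSE)
  }
  adj <- if (k == 0) 0 else k / pair$carrier_prevalence
  cut <- (d$delta_gpos_dneg - adj) /
    (d$delta_gpos_dneg + d$delta_gneg_dpos)
  if (bu$point_mass) {
    return(as.numeric(bu$value > cut))
  }
  if (cut < 0) return(1)
  if (cut > 1) return(0)
  stats::pbeta(cut, bu$alpha, bu$beta, lower.tail = FALSE)
}

#' Credible interval for the break-even threshold of one pair
#'
#' The threshold is strictly monotone in the penetrance, so exact interval
#' endpoints come from the monotone transform of the Beta quantiles: the
#' lower threshold bound is the threshold evaluated at the upper penetrance
#' quantile and vice versa. No sampling is involved.
#'
#' @inheritParams utility_threshold_pair
#' @inheritParams penetrance_interval
#' @return A list of class `threshold_result` with elements `estimate`,
#'   `ci_lower`, `ci_upper`, `level`.
#' @export
threshold_interval_pair <- function(pair, delta_gpos_dneg = 1,
                                    level = 0.95) {
  pair <- as_pair_fields(pair)
  check_strictly_positive(delta_gpos_dneg, "delta_gpos_dneg")
  check_level(level)
  est <- threshold_core(pair$carrier_prevalence, pair$penetrance,
                        pair$test_disutility, delta_gpos_dneg)
  bu <- pair_beta(pair)
  if (bu$point_mass) {
    lo <- hi <- as.numeric(est)
  } else {
    q <- stats::qbeta(c((1 - level) / 2, 1 - (1 - level) / 2),
                      bu$alpha, bu$beta)
    at_q <- vapply(q, function(p) {
      as.numeric(threshold_core(pair$carrier_prevalence, p,
                                pair$test_disutility, delta_gpos_dneg))
    }, numeric(1))
    lo <- min(at_q)
    hi <- max(at_q)
  }
  structure(list(estimate = as.numeric(est), ci_lower = lo, ci_upper = hi,
                 level = level,
                 always_beneficial = isTRUE(attr(est, "always_beneficial"))),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> estimate %.4g, %d%% CI (%.4g, %.4g)\n",
              x$estimate, round(100 * x$level), x$ci_lower, x$ci_upper))
  if (isTRUE(x$always_beneficial)) {
    cat("  (negative threshold: testing beneficial at every ratio)\n")
  }
  invisible(x)
}

#' Draw penetrance samples for every pair in a panel
#'
#' Independent Beta draws per pair from a single RNG stream, columns filled
#' in declared panel order, so results are exactly reproducible given the
#' seed. Point-mass penetrances (0 or 1) give constant columns.
#'
#' @inheritParams aggregate_utility
#' @param n_samples Number of draws (rows), at least 1.
#' @param seed Integer seed; required, since every Monte-Carlo summary in
#'   the package must be reproducible.
#' @return Numeric matrix, `n_samples` rows by one column per pair, column
#'   names from the pair labels.
#' @export
sample_penetrances <- function(panel, n_samples = 100000, seed) {
  stopifnot(inherits(panel, "gene_panel"))
  if (missing(seed)) {
    stop("seed is required for penetrance sampling (reproducibility)",
         call. = FALSE)
  }
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be >= 1", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  pairs <- panel$pairs
  out <- matrix(NA_real_, nrow = n_samples, ncol = nrow(pairs),
                dimnames = list(NULL, pair_labels(pairs)))
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (j in seq_len(nrow(pairs))) {
      bu <- beta_params(pairs$penetrance[j], pairs$precision[j])
      out[, j] <- if (bu$point_mass) rep(bu$value, n_samples)
                  else stats::rbeta(n_samples, bu$alpha, bu$beta)
    }
  })
  out
}

# run expr under a private RNG state, restoring the caller's stream
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

#' Net-utility estimate with propagated penetrance uncertainty
#'
#' Computes the plug-in net utility together with an equal-tailed credible
#' interval, the probability of positive utility and the fifth-percentile
#' "near-worst case" value, all under the Beta uncertainty model.
#'
#' For a single pair the net utility is affine and increasing in the
#' penetrance, so the interval and \eqn{\Pr(\Delta > 0)} are computed
#' exactly by the monotone transform of Beta quantiles and the Beta
#' survival function. For a multi-pair panel the aggregate distribution has
#' no closed form; it is propagated by Monte Carlo over independent
#' penetrance draws ([sample_penetrances()]), and the interval comes from
#' empirical quantiles of the aggregate draws.
#'
#' @param x A [gene_panel()] or single [gene_disease_pair()].
#' @param d Optional [disutility_spec()] (required if `x` carries none).
#' @param n_samples Monte-Carlo draws for the multi-pair case.
#' @param seed Integer seed; required whenever Monte Carlo is used.
#' @param level Credible-interval mass.
#' @param worst_percentile Probability level of the near-worst-case
#'   plug-in (default 0.05: each penetrance at its 5th percentile).
#' @return A list of class `utility_result`: `estimate`, `ci_lower`,
#'   `ci_upper`, `level`, `prob_positive`, `percentile5`, `method`
#'   (`"exact"` or `"monte-carlo"`) and `n_samples` (NA for exact).
#' @export
utility_distribution <- function(x, d = NULL, n_samples = 100000, seed,
                                 level = 0.95, worst_percentile = 0.05) {
  check_level(level)
  check_level(worst_percentile)
  panel <- if (inherits(x, "gene_panel")) x else
    gene_panel(as.data.frame(x, stringsAsFactors = FALSE))
  pairs <- panel$pairs
  if (nrow(pairs) == 0) stop("empty panel", call. = FALSE)
  dd <- resolve_disutilities(panel, d)

  plugin <- net_utility_core(pairs$carrier_prevalence, pairs$penetrance,
                             dd$delta_gpos_dneg, dd$delta_gneg_dpos,
                             pairs$test_disutility)
  # near-worst case: every penetrance at its lower tail quantile
  p_low <- vapply(seq_len(nrow(pairs)), function(j) {
    bu <- beta_params(pairs$penetrance[j], pairs$precision[j])
    if (bu$point_mass) bu$value
    else stats::qbeta(worst_percentile, bu$alpha, bu$beta)
  }, numeric(1))
  pct5 <- sum(net_utility_core(pairs$carrier_prevalence, p_low,
                               dd$delta_gpos_dneg, dd$delta_gneg_dpos,
                               pairs$test_disutility))

  if (nrow(pairs) == 1) {
    # exact monotone transform: Delta is increasing in p
    bu <- beta_params(pairs$penetrance, pairs$precision)
    if (bu$point_mass) {
      lo <- hi <- plugin
    } else {
      q <- stats::qbeta(c((1 - level) / 2, 1 - (1 - level) / 2),
                        bu$alpha, bu$beta)
      bounds <- net_utility_core(pairs$carrier_prevalence, q,
                                 dd$delta_gpos_dneg, dd$delta_gneg_dpos,
                                 pairs$test_disutility)
      lo <- min(bounds); hi <- max(bounds)
    }
    pp <- prob_positive_pair(pairs,
                             disutility_spec(dd$delta_gpos_dneg,
                                             dd$delta_gneg_dpos))
    return(utility_result(sum(plugin), lo, hi, level, pp, pct5,
                          method = "exact", n_samples = NA_integer_))
  }

  if (missing(seed)) {
    stop("seed is required for aggregate (Monte-Carlo) uncertainty",
         call. = FALSE)
  }
  if (n_samples < 1000) {
    warning("n_samples < 1000: empirical quantiles may be unstable",
            call. = FALSE)
  }
  p_draws <- sample_penetrances(panel, n_samples = n_samples, seed = seed)
  draws <- aggregate_draws(panel, p_draws, dd)
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  utility_result(sum(plugin), qs[1], qs[2], level, mean(draws > 0), pct5,
                 method = "monte-carlo", n_samples = n_samples)
}

# aggregate net-utility draws from a penetrance-draw matrix
aggregate_draws <- function(panel, p_draws, dd = NULL) {
  pairs <- panel$pairs
  if (is.null(dd)) dd <- resolve_disutilities(panel)
  draws <- numeric(nrow(p_draws))
  for (j in seq_len(nrow(pairs))) {
    draws <- draws + net_utility_core(pairs$carrier_prevalence[j],
                                      p_draws[, j],
                                      dd$delta_gpos_dneg[j],
                                      dd$delta_gneg_dpos[j],
                                      pairs$test_disutility[j])
  }
  draws
}

utility_result <- function(estimate, lo, hi, level, prob_positive, pct5,
                           method, n_samples) {
  structure(list(estimate = estimate, ci_lower = lo, ci_upper = hi,
                 level = level, prob_positive = prob_positive,
                 percentile5 = pct5, method = method,
                 n_samples = n_samples),
            class = "utility_result")
}

#' @export
print.utility_result <- function(x, ...) {
  cat(sprintf("<utility_result> estimate %.4g, %d%% CI (%.4g, %.4g)\n",
              x$estimate, round(100 * x$level), x$ci_lower, x$ci_upper))
  cat(sprintf("  Pr(positive) %.4g, 5th-percentile value %.4g [%s]\n",
              x$prob_positive, x$percentile5, x$method))
  invisible(x)
}

#' Near-worst-case break-even threshold
#'
#' The break-even threshold recomputed with the penetrance at a lower
#' quantile of its Beta uncertainty distribution (default the 5th
#' percentile), i.e. the ratio needed for positive utility if the true
#' penetrance sits at the low end of its credible range.
#'
#' @inheritParams utility_threshold_pair
#' @param percentile Lower-tail probability of the plug-in quantile.
#' @return The worst-case threshold (scalar, possibly `Inf`).
#' @export
worst_case_threshold <- function(pair, delta_gpos_dneg = 1,
                                 percentile = 0.05) {
  pair <- as_pair_fields(pair)
  check_strictly_positive(delta_gpos_dneg, "delta_gpos_dneg")
  check_level(percentile)
  bu <- pair_beta(pair)
  p <- if (bu$point_mass) bu$value
       else stats::qbeta(percentile, bu$alpha, bu$beta)
  as.numeric(threshold_core(pair$carrier_prevalence, p,
                            pair$test_disutility, delta_gpos_dneg))
}
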