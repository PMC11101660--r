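#' Net utility of testing for one (disease, gene) pair
#'
#' The expected change in utility from adding the gene to the panel,
#' relative to not testing:
#' \deqn{\Delta = \Pr(G=1)\,[-\delta_{G+D-} + (\delta_{G+D-} +
#'   \delta_{G-D+})\,p] + K}
#' where \eqn{p} is the penetrance. \eqn{\Delta > 0} means testing is
#' beneficial. \eqn{K} is added as-is; supply a testing harm as negative
#' `test_disutility`.
#'
#' @param pair A [gene_disease_pair()] (or one-row data.frame / list with
#'   the same fields).
#' @param d A [disutility_spec()].
#' @return The net utility, a finite scalar in the caller's utility units.
#' @seealso [aggregate_utility()], [utility_threshold_pair()]
#' @examples
#' atm <- gene_disease_pair("bc", "ATM", 0.0019, 0.35, 100)
#' net_utility_pair(atm, disutility_spec(1, 2))
#' @export
net_utility_pair <- function(pair, d) {
  pair <- as_pair_fields(pair)
  stopifnot(inherits(d, "disutility_spec"))
  net_utility_core(pair$carrier_prevalence, pair$penetrance,
                   d$delta_gpos_dneg, d$delta_gneg_dpos,
                   pair$test_disutility)
}

# vectorised kernel shared by the pair op, sweeps and MC propagation
net_utility_core <- function(prevalence, penetrance, delta_gpos_dneg,
                             delta_gneg_dpos, k = 0) {
  prevalence * (-delta_gpos_dneg +
                  (delta_gpos_dneg + delta_gneg_dpos) * penetrance) + k
}

#' Expected utility in the testing scenario (four-outcome form)
#'
#' The long-hand expectation over the four (disease, test) outcomes plus
#' the test disutility. Retained as a self-check oracle for the reduced
#' net-utility expression: the difference between this and
#' [utility_without_testing()] equals [net_utility_pair()] for any valid
#' four-outcome utilities, regardless of the background risk.
#'
#' @inheritParams net_utility_pair
#' @param u An [outcome_utilities()] object.
#' @param background_risk \eqn{\Pr(D=1 \mid G=0)}: disease risk among
#'   non-carriers. Carriers of rare variants account for a minority of
#'   cases, so the population marginal risk exceeds prevalence x penetrance;
#'   this argument supplies the remainder. Default 0.
#' @param joint_probs Optional explicit joint outcome probabilities, a named
#'   numeric vector with elements `dpos_gpos`, `dneg_gpos`, `dpos_gneg`,
#'   `dneg_gneg` summing to 1 and consistent with the pair's prevalence and
#'   penetrance. Overrides `background_risk` when given.
#' @return Expected utility of the testing scenario.
#' @export
utility_with_testing <- function(pair, u, background_risk = 0,
                                 joint_probs = NULL) {
  pair <- as_pair_fields(pair)
  stopifnot(inherits(u, "outcome_utilities"))
  jp <- resolve_joint_probs(pair, background_risk, joint_probs)
  u$c_gpos_dpos * jp[["dpos_gpos"]] + u$c_gpos_dneg * jp[["dneg_gpos"]] +
    u$c_gneg_dpos * jp[["dpos_gneg"]] + u$c_gneg_dneg * jp[["dneg_gneg"]] +
    pair$test_disutility
}

#' Expected utility in the no-testing scenario
#'
#' Everyone is treated as test-negative: the expectation weighs the
#' negative-test utilities by the marginal disease risk
#' \eqn{\Pr(D=1) = \Pr(G=1)\,p + (1-\Pr(G=1))\,\Pr(D=1 \mid G=0)}.
#'
#' @inheritParams utility_with_testing
#' @return Expected utility of the no-testing scenario.
#' @export
utility_without_testing <- function(pair, u, background_risk = 0) {
  pair <- as_pair_fields(pair)
  stopifnot(inherits(u, "outcome_utilities"))
  check_probability(background_risk, "background_risk")
  pr_d1 <- pair$carrier_prevalence * pair$penetrance +
    (1 - pair$carrier_prevalence) * background_risk
  u$c_gneg_dpos * pr_d1 + u$c_gneg_dneg * (1 - pr_d1)
}

resolve_joint_probs <- function(pair, background_risk, joint_probs) {
  if (is.null(joint_probs)) {
    check_probability(background_risk, "background_risk")
    g1 <- pair$carrier_prevalence
    p <- pair$penetrance
    jp <- c(dpos_gpos = g1 * p, dneg_gpos = g1 * (1 - p),
            dpos_gneg = (1 - g1) * background_risk,
            dneg_gneg = (1 - g1) * (1 - background_risk))
    return(jp)
  }
  needed <- c("dpos_gpos", "dneg_gpos", "dpos_gneg", "dneg_gneg")
  if (!all(needed %in% names(joint_probs))) {
    stop("joint_probs must carry elements ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  jp <- joint_probs[needed]
  if (abs(sum(jp) - 1) > 1e-8) {
    stop("joint_probs must sum to 1", call. = FALSE)
  }
  g1 <- jp[["dpos_gpos"]] + jp[["dneg_gpos"]]
  if (abs(g1 - pair$carrier_prevalence) > 1e-8) {
    stop("joint_probs inconsistent with carrier_prevalence", call. = FALSE)
  }
  if (g1 > 0 &&
      abs(jp[["dpos_gpos"]] / g1 - pair$penetrance) > 1e-8) {
    stop("joint_probs inconsistent with penetrance", call. = FALSE)
  }
  jp
}

#' Aggregate net utility of a panel
#'
#' The panel-level net utility is the sum of the per-pair net utilities, in
#' declared panel order. Additivity is exact, so the decision to keep any
#' one test depends only on that test's own net utility; the aggregate is a
#' convenient single summary.
#'
#' @param panel A [gene_panel()].
#' @param d Optional [disutility_spec()] overriding the panel's settings.
#' @return The summed net utility; 0 (with a warning) for an empty panel.
#' @export
aggregate_utility <- function(panel, d = NULL) {
  stopifnot(inherits(panel, "gene_panel"))
  if (nrow(panel$pairs) == 0) {
    warning("empty panel: aggregate utility is a vacuous sum (0)",
            call. = FALSE)
    return(0)
  }
  dd <- resolve_disutilities(panel, d)
  vals <- net_utility_core(panel$pairs$carrier_prevalence,
                           panel$pairs$penetrance,
                           dd$delta_gpos_dneg, dd$delta_gneg_dpos,
                           panel$pairs$test_disutility)
  sum(vals)
}

#' Break-even disutility-ratio threshold for one pair
#'
#' The threshold \eqn{b} is the ratio \eqn{\delta_{G-D+}/\delta_{G+D-}} at
#' which the pair's net utility is exactly 0:
#' \deqn{b = \frac{1 - (K/\delta_{G+D-})/\Pr(G=1)}{p} - 1.}
#' Ratios above \eqn{b} make testing beneficial. With \eqn{K = 0} this is
#' \eqn{1/p - 1} and depends only on the penetrance.
#'
#' Zero penetrance yields `Inf` (no finite ratio breaks even). When the
#' test's own utility contribution is large enough that
#' \eqn{(K/\delta_{G+D-})/\Pr(G=1) \ge 1}, the threshold is negative and
#' testing is beneficial at every ratio; the returned value then carries
#' attribute `always_beneficial = TRUE`.
#'
#' @inheritParams net_utility_pair
#' @param delta_gpos_dneg Strictly positive G+D- disutility (only relevant
#'   when the pair's `test_disutility` is nonzero).
#' @return The threshold estimate (scalar, possibly `Inf`).
#' @export
utility_threshold_pair <- function(pair, delta_gpos_dneg = 1) {
  pair <- as_pair_fields(pair)
  check_strictly_positive(delta_gpos_dneg, "delta_gpos_dneg")
  threshold_core(pair$carrier_prevalence, pair$penetrance,
                 pair$test_disutility, delta_gpos_dneg)
}

threshold_core <- function(prevalence, penetrance, k, delta_gpos_dneg) {
  if (k != 0 && prevalence == 0) {
    stop("carrier_prevalence must be > 0 when test_disutility is nonzero",
         call. = FALSE)
  }
  t <- if (k == 0) 0 else (k / delta_gpos_dneg) / prevalence
  if (penetrance == 0) {
    b <- if (1 - t > 0) Inf else -Inf
  } else {
    b <- (1 - t) / penetrance - 1
  }
  if (t >= 1) attr(b, "always_beneficial") <- TRUE
  b
}

#' Break-even disutility-ratio threshold for a whole panel
#'
#' Under shared disutilities across all pairs, the ratio at which the
#' aggregate net utility is 0:
#' \deqn{b = \frac{\sum_j [\Pr(G_j=1) - K_j/\delta_{G+D-}]}
#'                {\sum_j \Pr(G_j=1)\,p_j} - 1,}
#' reducing to \eqn{\sum \Pr(G_j=1) / \sum \Pr(G_j=1) p_j - 1} when all
#' \eqn{K_j = 0}. Pairs with differing disutilities violate the shared-
#' disutility assumption and raise an error.
#'
#' @inheritParams aggregate_utility
#' @inheritParams utility_threshold_pair
#' @return The aggregate threshold estimate.
#' @export
utility_threshold_aggregate <- function(panel, delta_gpos_dneg = 1) {
  stopifnot(inherits(panel, "gene_panel"))
  check_strictly_positive(delta_gpos_dneg, "delta_gpos_dneg")
  pairs <- panel$pairs
  if (nrow(pairs) == 0) stop("empty panel has no threshold", call. = FALSE)
  if (!is.null(pairs$delta_gpos_dneg) || !is.null(pairs$delta_gneg_dpos)) {
    # per-pair columns present: only acceptable if they are all identical
    invisible(shared_disutilities(panel))
  }
  denom <- sum(pairs$carrier_prevalence * pairs$penetrance)
  if (denom <= 0) {
    stop("sum of prevalence x penetrance must be > 0", call. = FALSE)
  }
  numer <- sum(pairs$carrier_prevalence -
                 pairs$test_disutility / delta_gpos_dneg)
  numer / denom - 1
}
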