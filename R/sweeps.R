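#' Default disutility-ratio grid
#'
#' 21 log-spaced ratios \eqn{10^{-1}, 10^{-0.9}, \ldots, 10^{1}} (a step of
#' 0.1 on the log10 scale), covering G-D+/G+D- ratios from 0.1 to 10.
#'
#' @return Numeric vector of length 21.
#' @export
default_ratio_grid <- function() 10^seq(-1, 1, by = 0.1)

#' Sweep net utilities over a grid of disutility ratios
#'
#' Fixes \eqn{\delta_{G+D-} = 1} (a normalisation without loss of
#' generality, since net utility scales linearly in the pair of
#' disutilities) and evaluates, at each ratio
#' \eqn{r = \delta_{G-D+}/\delta_{G+D-}} on the grid, every pair's net
#' utility with credible interval and probability of positive utility, plus
#' the aggregate. Per-pair summaries are exact (monotone transform /
#' analytic tail probability); the aggregate row uses Monte-Carlo
#' propagation with a single penetrance-draw matrix reused across the whole
#' grid, so aggregate curves are smooth in the ratio.
#'
#' @inheritParams aggregate_utility
#' @param ratio_grid Strictly positive ratio values;
#'   default [default_ratio_grid()].
#' @param level Credible-interval mass.
#' @param n_samples Monte-Carlo draws for the aggregate rows.
#' @param seed Integer seed, required when the panel has more than one pair.
#' @param delta_gpos_dneg The fixed G+D- disutility (default 1).
#' @return A long-format `data.frame` of class `ratio_sweep_table` with
#'   columns `ratio`, `unit_id` (each pair label plus `"All"`), `estimate`,
#'   `ci_lower`, `ci_upper`, `prob_positive`.
#' @export
ratio_sweep <- function(panel, ratio_grid = default_ratio_grid(),
                        level = 0.95, n_samples = 100000, seed,
                        delta_gpos_dneg = 1) {
  stopifnot(inherits(panel, "gene_panel"))
  if (any(!is.finite(ratio_grid)) || any(ratio_grid <= 0)) {
    stop("ratio_grid values must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(ratio_grid, strictly = TRUE)) {
    stop("ratio_grid must be strictly increasing", call. = FALSE)
  }
  check_level(level)
  check_strictly_positive(delta_gpos_dneg, "delta_gpos_dneg")
  pairs <- panel$pairs
  if (nrow(pairs) == 0) stop("empty panel", call. = FALSE)
  # the grid defines the disutilities; drop any per-record overrides
  pairs$delta_gpos_dneg <- NULL
  pairs$delta_gneg_dpos <- NULL
  panel <- gene_panel(pairs)
  labels <- pair_labels(pairs)

  multi <- nrow(pairs) > 1
  if (multi) {
    if (missing(seed)) {
      stop("seed is required: aggregate intervals are Monte-Carlo",
           call. = FALSE)
    }
    p_draws <- sample_penetrances(panel, n_samples = n_samples, seed = seed)
  }

  rows <- vector("list", length(ratio_grid))
  alpha2 <- (1 - level) / 2
  for (g in seq_along(ratio_grid)) {
    r <- ratio_grid[g]
    d <- disutility_spec(delta_gpos_dneg, r * delta_gpos_dneg)
    per <- lapply(seq_len(nrow(pairs)), function(j) {
      res <- utility_distribution(pairs[j, , drop = FALSE], d = d,
                                  level = level)
      data.frame(ratio = r, unit_id = labels[j], estimate = res$estimate,
                 ci_lower = res$ci_lower, ci_upper = res$ci_upper,
                 prob_positive = res$prob_positive,
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    if (multi) {
      dd <- data.frame(delta_gpos_dneg = rep(delta_gpos_dneg, nrow(pairs)),
                       delta_gneg_dpos = rep(r * delta_gpos_dneg,
                                             nrow(pairs)))
      draws <- aggregate_draws(panel, p_draws, dd)
      qs <- stats::quantile(draws, c(alpha2, 1 - alpha2), names = FALSE)
      agg <- data.frame(ratio = r, unit_id = "All",
                        estimate = sum(per$estimate),
                        ci_lower = qs[1], ci_upper = qs[2],
                        prob_positive = mean(draws > 0),
                        stringsAsFactors = FALSE)
    } else {
      agg <- per[0, ]
    }
    rows[[g]] <- rbind(per, agg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ratio_sweep_table", "data.frame")
  out
}

#' Two-way disutility heatmap grid
#'
#' Evaluates a summary statistic of the net utility over a grid of
#' \eqn{(\delta_{G+D-}, \delta_{G-D+})} values, for one pair or for the
#' panel aggregate. With zero test disutility the sign of the net utility
#' depends only on the ratio of the two disutilities, so the zero contour
#' of the estimate matrix is the straight line
#' \eqn{\delta_{G-D+} = b\,\delta_{G+D-}} through the origin, with \eqn{b}
#' the break-even threshold.
#'
#' @inheritParams aggregate_utility
#' @param delta0_grid,delta1_grid Strictly positive axis values for
#'   \eqn{\delta_{G+D-}} (columns vary over `delta0_grid`) and
#'   \eqn{\delta_{G-D+}}; default `seq(1, 96, by = 5)` on both axes
#'   (start-anchored 1, 6, ..., 96).
#' @param statistic One of `"estimate"` (plug-in net utility),
#'   `"prob_positive"` or `"percentile5"` (near-worst-case plug-in).
#' @param unit `"All"` for the panel aggregate (default) or one pair label.
#' @param n_samples,seed Monte-Carlo settings, used only for
#'   `statistic = "prob_positive"` on a multi-pair aggregate.
#' @param worst_percentile Quantile for `statistic = "percentile5"`.
#' @return A list of class `heatmap_grid` with elements `delta_gpos_dneg`,
#'   `delta_gneg_dpos`, `values` (matrix, rows indexed by
#'   `delta_gneg_dpos`, columns by `delta_gpos_dneg`), `statistic`, `unit`.
#' @export
disutility_heatmap <- function(panel, delta0_grid = seq(1, 96, by = 5),
                               delta1_grid = seq(1, 96, by = 5),
                               statistic = c("estimate", "prob_positive",
                                             "percentile5"),
                               unit = "All", n_samples = 100000, seed,
                               worst_percentile = 0.05) {
  stopifnot(inherits(panel, "gene_panel"))
  statistic <- match.arg(statistic)
  if (any(delta0_grid <= 0) || any(delta1_grid <= 0)) {
    stop("disutility grids must be strictly positive", call. = FALSE)
  }
  pairs <- panel$pairs
  pairs$delta_gpos_dneg <- NULL
  pairs$delta_gneg_dpos <- NULL
  labels <- pair_labels(pairs)
  if (!identical(unit, "All")) {
    j <- match(unit, labels)
    if (is.na(j)) stop("unknown unit: ", unit, call. = FALSE)
    pairs <- pairs[j, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("empty panel", call. = FALSE)

  need_mc <- statistic == "prob_positive" && nrow(pairs) > 1
  if (need_mc) {
    if (missing(seed)) {
      stop("seed is required: aggregate prob_positive is Monte-Carlo",
           call. = FALSE)
    }
    sub <- gene_panel(pairs)
    p_draws <- sample_penetrances(sub, n_samples = n_samples, seed = seed)
  }

  vals <- matrix(NA_real_, nrow = length(delta1_grid),
                 ncol = length(delta0_grid),
                 dimnames = list(format(delta1_grid, trim = TRUE),
                                 format(delta0_grid, trim = TRUE)))
  for (ci in seq_along(delta0_grid)) {
    for (ri in seq_along(delta1_grid)) {
      d0 <- delta0_grid[ci]; d1 <- delta1_grid[ri]
      vals[ri, ci] <- switch(
        statistic,
        estimate = sum(net_utility_core(pairs$carrier_prevalence,
                                        pairs$penetrance, d0, d1,
                                        pairs$test_disutility)),
        percentile5 = {
          p_low <- vapply(seq_len(nrow(pairs)), function(j) {
            bu <- beta_params(pairs$penetrance[j], pairs$precision[j])
            if (bu$point_mass) bu$value
            else stats::qbeta(worst_percentile, bu$alpha, bu$beta)
          }, numeric(1))
          sum(net_utility_core(pairs$carrier_prevalence, p_low, d0, d1,
                               pairs$test_disutility))
        },
        prob_positive = {
          if (need_mc) {
            dd <- data.frame(delta_gpos_dneg = rep(d0, nrow(pairs)),
                             delta_gneg_dpos = rep(d1, nrow(pairs)))
            mean(aggregate_draws(gene_panel(pairs), p_draws, dd) > 0)
          } else {
            prob_positive_pair(pairs, disutility_spec(d0, d1))
          }
        }
      )
    }
  }
  structure(list(delta_gpos_dneg = delta0_grid,
                 delta_gneg_dpos = delta1_grid,
                 values = vals, statistic = statistic, unit = unit),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid> %s for unit '%s' (%d x %d)\n", x$statistic,
              x$unit, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Break-even threshold table for a panel
#'
#' One row per pair plus an aggregate `"All"` row: threshold estimates and
#' equal-tailed credible intervals. Per-pair rows are exact (monotone
#' transform of Beta quantiles); the aggregate estimate is the closed-form
#' shared-disutility threshold, with a Monte-Carlo interval from the
#' empirical quantiles of the threshold recomputed over penetrance draws.
#'
#' @inheritParams aggregate_utility
#' @inheritParams utility_threshold_pair
#' @param level Credible-interval mass.
#' @param n_samples Monte-Carlo draws for the aggregate row.
#' @param seed Integer seed, required when the panel has more than one pair.
#' @return A `data.frame` of class `threshold_table` with columns
#'   `unit_id`, `estimate`, `ci_lower`, `ci_upper`.
#' @export
threshold_table <- function(panel, level = 0.95, delta_gpos_dneg = 1,
                            n_samples = 100000, seed) {
  stopifnot(inherits(panel, "gene_panel"))
  check_level(level)
  pairs <- panel$pairs
  if (nrow(pairs) == 0) stop("empty panel", call. = FALSE)
  labels <- pair_labels(pairs)
  per <- lapply(seq_len(nrow(pairs)), function(j) {
    res <- threshold_interval_pair(pairs[j, , drop = FALSE],
                                   delta_gpos_dneg = delta_gpos_dneg,
                                   level = level)
    data.frame(unit_id = labels[j], estimate = res$estimate,
               ci_lower = res$ci_lower, ci_upper = res$ci_upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)

  if (nrow(pairs) > 1) {
    if (missing(seed)) {
      stop("seed is required: the aggregate interval is Monte-Carlo",
           call. = FALSE)
    }
    est <- utility_threshold_aggregate(panel,
                                       delta_gpos_dneg = delta_gpos_dneg)
    p_draws <- sample_penetrances(panel, n_samples = n_samples, seed = seed)
    numer <- sum(pairs$carrier_prevalence -
                   pairs$test_disutility / delta_gpos_dneg)
    denom_draws <- as.vector(p_draws %*% pairs$carrier_prevalence)
    b_draws <- numer / denom_draws - 1
    qs <- stats::quantile(b_draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    out <- rbind(data.frame(unit_id = "All", estimate = est,
                            ci_lower = qs[1], ci_upper = qs[2],
                            stringsAsFactors = FALSE),
                 out)
  }
  rownames(out) <- NULL
  class(out) <- c("threshold_table", "data.frame")
  out
}
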