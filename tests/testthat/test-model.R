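test_that("net utility matches hand evaluations and symmetry points", {
  # ratio exactly at the break-even point b = 1 when p = 0.5
  at_b <- net_utility_pair(gene_disease_pair("d", "g", 0.001, 0.5, 10),
                           disutility_spec(1, 1))
  expect_equal(at_b, 0)
  # equal disutilities and p = 0.5 cancel for any prevalence
  for (prev in c(1e-4, 0.01, 0.5, 1)) {
    expect_equal(
      net_utility_pair(gene_disease_pair("d", "g", prev, 0.5, 10),
                       disutility_spec(2.7, 2.7)),
      0
    )
  }
  # hand evaluation: 0.002 * (-1 + 6 * 0.35) = 0.0022
  expect_equal(
    net_utility_pair(gene_disease_pair("d", "g", 0.002, 0.35, 100),
                     disutility_spec(1, 5)),
    0.0022
  )
})

test_that("pair and disutility validation names the offending field", {
  expect_error(gene_disease_pair("d", "g", 1.5, 0.5, 10),
               "carrier_prevalence")
  expect_error(gene_disease_pair("d", "g", 0.5, -0.1, 10), "penetrance")
  expect_error(gene_disease_pair("d", "g", 0.5, 0.5, 0), "precision")
  expect_error(gene_disease_pair("", "g", 0.5, 0.5, 10), "disease_id")
  expect_error(disutility_spec(0, 1), "delta_gpos_dneg")
  expect_error(disutility_spec(1, -2), "delta_gneg_dpos")
})

test_that("no-testing expected utility is the marginal-risk weighted sum", {
  u <- outcome_utilities(c_gpos_dpos = 3, c_gneg_dneg = 4,
                         c_gpos_dneg = 3.5, c_gneg_dpos = 2)
  # Pr(D=1) = 0.1 entirely from background risk: 2*0.1 + 4*0.9 = 3.8
  pair <- gene_disease_pair("d", "g", 0, 0.5, 10)
  expect_equal(utility_without_testing(pair, u, background_risk = 0.1), 3.8)
  # degenerate marginals
  expect_equal(utility_without_testing(pair, u, background_risk = 0), 4)
  expect_equal(utility_without_testing(pair, u, background_risk = 1), 2)
})

test_that("testing-vs-not difference equals the reduced net utility", {
  # the four-outcome expressions are the oracle for the closed form,
  # for any background risk among non-carriers
  set.seed(101)
  for (i in 1:1000) {
    pair <- random_pair()
    u <- random_outcome_utilities()
    bg <- runif(1, 0, 0.3)
    d <- attr(u, "deltas")
    with_test <- utility_with_testing(pair, u, background_risk = bg)
    without_test <- utility_without_testing(pair, u, background_risk = bg)
    rhs <- net_utility_pair(pair, d)
    # 1e-12 relative to the expected-utility scale: the difference itself
    # is orders of magnitude below the terms being cancelled
    scale <- max(1, abs(with_test), abs(without_test))
    expect_lt(abs((with_test - without_test) - rhs), 1e-12 * scale)
  }
})

test_that("explicit joint probabilities are validated against the pair", {
  u <- outcome_utilities(3, 4, 3.5, 2)
  pair <- gene_disease_pair("d", "g", 0.01, 0.4, 100)
  good <- c(dpos_gpos = 0.004, dneg_gpos = 0.006,
            dpos_gneg = 0.099, dneg_gneg = 0.891)
  expect_equal(
    utility_with_testing(pair, u, joint_probs = good),
    utility_with_testing(pair, u, background_risk = 0.1)
  )
  expect_error(utility_with_testing(pair, u, joint_probs = good * 0.9),
               "sum to 1")
  bad <- c(dpos_gpos = 0.008, dneg_gpos = 0.002,
           dpos_gneg = 0.099, dneg_gneg = 0.891)
  expect_error(utility_with_testing(pair, u, joint_probs = bad),
               "penetrance")
})

test_that("aggregate utility is an exact sum over pairs", {
  pair <- gene_disease_pair("d", "g", 0.003, 0.6, 100)
  d <- disutility_spec(1, 3)
  single <- gene_panel(pair, disutilities = d)
  expect_equal(aggregate_utility(single), net_utility_pair(pair, d))

  two <- gene_panel(rbind(pair, gene_disease_pair("d", "g2", 0.003, 0.6, 100)),
                    disutilities = d)
  expect_identical(aggregate_utility(two), 2 * net_utility_pair(pair, d))

  # five-gene fixture at equal unit disutilities: sum of prev * (2p - 1)
  fix <- breast_cancer_panel()
  expect_equal(aggregate_utility(fix, d = disutility_spec(1, 1)),
               sum(fix$pairs$carrier_prevalence *
                     (2 * fix$pairs$penetrance - 1)))

  empty <- synthetic_panel(0, seed = 1,
                           disutilities = disutility_spec(1, 1))
  expect_warning(res <- aggregate_utility(empty), "empty panel")
  expect_identical(res, 0)
})

test_that("pair threshold follows 1/p - 1 and the K-adjusted closed form", {
  expect_equal(utility_threshold_pair(
    gene_disease_pair("d", "g", 0.001, 0.2, 100)), 4, ignore_attr = TRUE)
  expect_equal(utility_threshold_pair(
    gene_disease_pair("d", "g", 0.1, 0.5, 10)), 1, ignore_attr = TRUE)
  expect_equal(utility_threshold_pair(
    gene_disease_pair("d", "g", 0.0019, 0.35, 100)), 1 / 0.35 - 1,
    ignore_attr = TRUE)
  # K = 0 thresholds do not depend on prevalence or on delta_gpos_dneg
  for (prev in c(1e-4, 0.01, 1)) {
    expect_equal(utility_threshold_pair(
      gene_disease_pair("d", "g", prev, 0.2, 10), delta_gpos_dneg = 7),
      4, ignore_attr = TRUE)
  }
  # zero penetrance: no finite ratio breaks even
  expect_identical(utility_threshold_pair(
    gene_disease_pair("d", "g", 0.01, 0, 10)), Inf)
  # K-adjusted: b = [1 - (K/d0)/prev]/p - 1
  pair_k <- gene_disease_pair("d", "g", 0.01, 0.4, 100,
                              test_disutility = -0.005)
  expect_equal(utility_threshold_pair(pair_k, delta_gpos_dneg = 2),
               (1 - (-0.005 / 2) / 0.01) / 0.4 - 1, ignore_attr = TRUE)
  # a large positive K makes testing beneficial at every ratio
  pair_ben <- gene_disease_pair("d", "g", 0.001, 0.4, 100,
                                test_disutility = 0.002)
  b <- utility_threshold_pair(pair_ben, delta_gpos_dneg = 1)
  expect_lt(as.numeric(b), 0)
  expect_true(attr(b, "always_beneficial"))
})

test_that("aggregate threshold collapses and combines as the ratio of sums", {
  d <- disutility_spec(1, 1)
  pair <- gene_disease_pair("d", "g", 0.002, 0.3, 100)
  same <- gene_panel(rbind(pair,
                           gene_disease_pair("d", "g2", 0.002, 0.3, 100)),
                     disutilities = d)
  expect_equal(utility_threshold_aggregate(same),
               as.numeric(utility_threshold_pair(pair)))

  two <- gene_panel(rbind(gene_disease_pair("d", "g1", 0.001, 0.2, 10),
                          gene_disease_pair("d", "g2", 0.001, 0.8, 10)),
                    disutilities = d)
  expect_equal(utility_threshold_aggregate(two), 0.002 / 0.001 - 1)

  # mixed per-pair disutilities violate the shared-disutility assumption
  mixed <- breast_cancer_panel()
  mixed$pairs$delta_gpos_dneg <- c(1, 2, 1, 1, 1)
  mixed$pairs$delta_gneg_dpos <- 1
  mixed <- gene_panel(mixed$pairs)
  expect_error(utility_threshold_aggregate(mixed), "sweep-based")
})

test_that("net utility vanishes at the threshold ratio (root property)", {
  set.seed(7)
  for (i in 1:200) {
    pair <- random_pair()
    if (pair$penetrance == 0) next
    d0 <- runif(1, 0.1, 10)
    b <- as.numeric(utility_threshold_pair(pair, delta_gpos_dneg = d0))
    if (!is.finite(b) || b <= 0) next
    expect_equal(net_utility_pair(pair, disutility_spec(d0, b * d0)), 0,
                 tolerance = 1e-12)
  }
})

test_that("net utility is monotone in each disutility", {
  set.seed(11)
  for (i in 1:50) {
    pair <- random_pair()
    d0 <- runif(1, 0.5, 5)
    grid <- sort(runif(6, 0.1, 10))
    up <- vapply(grid, function(d1)
      net_utility_pair(pair, disutility_spec(d0, d1)), numeric(1))
    expect_true(all(diff(up) >= 0))
    d1 <- runif(1, 0.5, 5)
    down <- vapply(grid, function(d0)
      net_utility_pair(pair, disutility_spec(d0, d1)), numeric(1))
    if (pair$penetrance < 1) expect_true(all(diff(down) < 0))
  }
})
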