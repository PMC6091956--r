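test_that("confidence grades map to interval half-widths with clipping", {
  expect_equal(confidenceHalfWidth(c("very_confident", "confident",
                                     "not_confident")), c(0.05, 0.1, 0.2))
  expect_error(confidenceHalfWidth("sure"), "unknown")
  expect_equal(unname(intervalFor(0.5, "confident")[1, ]), c(0.4, 0.6))
  expect_equal(unname(intervalFor(0.93, "very_confident")[1, ]), c(0.88, 0.98))
  expect_equal(unname(intervalFor(0.95, "not_confident")[1, ]), c(0.75, 1))
  expect_equal(unname(intervalFor(100, type = "cost")[1, ]), c(70, 130))
  expect_equal(unname(intervalFor(100, type = "cost", stale = TRUE)[1, ]),
               c(70, 200))
})

test_that("triangular sampling has the right support, mean and degenerate case", {
  expect_identical(rtriangular(3, 0, 0, 0), c(0, 0, 0))
  set.seed(1)
  x <- rtriangular(1e5, 0.4, 0.5, 0.6)
  expect_true(all(x >= 0.4 & x <= 0.6))
  y <- rtriangular(1e5, 0, 0.5, 1)
  se <- sqrt(1 / 24) / sqrt(1e5)   # triangular(0,.5,1) variance = 1/24
  expect_lt(abs(mean(y) - 0.5), 3 * se)
  # asymmetric mean (lo+mode+hi)/3
  z <- rtriangular(1e5, 0, 0.1, 1)
  sez <- sd(z) / sqrt(1e5)
  expect_lt(abs(mean(z) - (0 + 0.1 + 1) / 3), 3 * sez)
  expect_error(rtriangular(1, 1, 0.5, 0), "lo <= mode <= hi")
})

test_that("zero-width intervals collapse rank intervals to deterministic ranks", {
  pf <- generatePortfolio(generatorSpec(nProjects = 25, seed = 6))
  rec <- prioritize(pf)
  cfg <- simulationConfig(nSims = 40, seed = 2, lFloor = 0)
  sim <- monteCarloRanks(pf, cfg, records = rec, widthScale = 0)
  iv <- rankIntervals(sim)
  expect_equal(iv$rank_lo, iv$rank)
  expect_equal(iv$rank_hi, iv$rank)
  expect_true(all(iv$interval_length == 0))
})

test_that("rank simulations are seed-reproducible, permutation-valid, and shrink with width", {
  pf <- generatePortfolio(generatorSpec(nProjects = 30, seed = 12))
  rec <- prioritize(pf)
  cfg <- simulationConfig(nSims = 300, seed = 99)
  s1 <- monteCarloRanks(pf, cfg, records = rec)
  s2 <- monteCarloRanks(pf, cfg, records = rec)
  expect_identical(rankIntervals(s1), rankIntervals(s2))
  expect_identical(simulatedRanks(s1), simulatedRanks(s2))
  # each replicate's ranks are a permutation of 1..N
  rk <- simulatedRanks(s1)
  expect_true(all(apply(rk[, 1:25], 2, sort) == seq_len(nrow(rk))))
  # intervals are ordered and within 1..N
  iv <- rankIntervals(s1)
  expect_true(all(iv$rank_lo <= iv$rank_hi))
  expect_true(all(iv$rank_lo >= 1 & iv$rank_hi <= nrow(iv)))
  # shrinking every interval shrinks the mean rank interval
  mw <- vapply(c(1, 0.3, 0.05), function(w)
    mean(rankIntervals(monteCarloRanks(pf, cfg, records = rec,
                                       widthScale = w))$interval_length), 0)
  expect_true(all(diff(mw) < 0))
  expect_lt(mw[3], 3)
})

test_that("well-separated projects have certain ranks", {
  species <- data.frame(
    project_id = c("hi", "lo"), species_name = c("a", "b"),
    taxon_group = "plant", p_n = c(0.05, 0.6), p_w = 0.95,
    benefit_confidence = "very_confident", iucn_category = NA,
    recent_site_confirmation = TRUE, cost_total_npv = NA_real_,
    stringsAsFactors = FALSE)
  actions <- data.frame(
    action_id = c("a1", "a2"), project_id = c("hi", "lo"), site_id = "s",
    location_key = c("l1", "l2"), action_type = "weed_control",
    years = "1", annual_cost = c(100, 100000),
    input_success = 0.95, threat_outcome_success = 0.95,
    species_outcome_success = 0.95, confidence = "very_confident",
    stringsAsFactors = FALSE)
  pf <- ProjectPortfolio(species, actions)
  sim <- monteCarloRanks(pf, simulationConfig(nSims = 200, seed = 3))
  iv <- rankIntervals(sim)
  expect_equal(iv$rank_lo, iv$rank_hi)
  expect_equal(sort(iv$rank_lo), c(1L, 2L))
})

test_that("band assignment follows the rank-cutoff rules and partitions projects", {
  mk <- function(lo, hi) data.frame(rank_lo = lo, rank_hi = hi)
  # N = 10: k30 = 3, k70 = 7
  expect_identical(assignBands(mk(1, 2), n = 10), 1L)
  expect_identical(assignBands(mk(4, 6), n = 10), 3L)
  expect_identical(assignBands(mk(8, 10), n = 10), 5L)
  expect_identical(assignBands(mk(2, 5), n = 10), 2L)
  expect_identical(assignBands(mk(5, 9), n = 10), 4L)
  # an interval spanning both cutoffs goes to the lowest-priority band
  expect_identical(assignBands(mk(2, 9), n = 10), 5L)
  # exhaustive: every interval gets exactly one band in 1..5
  all_iv <- expand.grid(lo = 1:10, hi = 1:10)
  all_iv <- all_iv[all_iv$lo <= all_iv$hi, ]
  b <- assignBands(data.frame(rank_lo = all_iv$lo, rank_hi = all_iv$hi),
                   n = 10)
  expect_true(all(b %in% 1:5))
  # the printed variant allocates by the interval's lower limit
  expect_identical(assignBands(mk(2, 9), n = 10, rule = "printed"), 1L)
  expect_identical(assignBands(mk(8, 10), n = 10, rule = "printed"), 5L)
})

test_that("sensitivities match analytic derivatives when only B and L vary", {
  pf <- generatePortfolio(generatorSpec(nProjects = 20, seed = 14,
                                        staleSiteRate = 0))
  rec <- prioritize(pf)
  cfg <- simulationConfig(nSims = 4000, seed = 5, costHalfWidth = 0,
                          lFloor = 0)
  sens <- sensitivityAnalysis(pf, cfg, records = rec,
                              scoreScale = "per_dollar")
  # P is linear in B and L, so with cost held fixed the Monte Carlo mean
  # equals the analytic derivative at the point estimate
  expect_equal(sens$sens_benefit, sens$analytic_benefit, tolerance = 0.02)
  expect_equal(sens$sens_likelihood, sens$analytic_likelihood,
               tolerance = 0.02)
  expect_true(all(sens$sens_cost < 0))
  # spot value: dP for +0.1 B at L = 0.5, C = 1e6 is 5e-8 per dollar
  expect_equal(0.1 * 0.5 / 1e6, 5e-8)
  expect_equal(sens$analytic_benefit,
               0.1 * rec$likelihood[match(sens$project_id, rec$project_id)] /
                 rec$cost[match(sens$project_id, rec$project_id)])
})

test_that("summary statistics report moments, correlations and band splits", {
  pf <- generatePortfolio(generatorSpec(nProjects = 120, seed = 18))
  rec <- prioritize(pf)
  sim <- monteCarloRanks(pf, simulationConfig(nSims = 300, seed = 4),
                         records = rec)
  s <- summaryStatistics(rec, sim)
  expect_equal(unname(s$benefit["mean"]), mean(rec$benefit))
  expect_equal(s$total_annual_cost, sum(rec$cost) / 50)
  # log P = log B + log L - log C makes the cost correlation strongly negative
  expect_lt(s$r_logC_logP, -0.4)
  expect_identical(sum(s$band_counts), 120L)
  expect_gt(s$interval_length_bands_2_4["mean"],
            s$interval_length_bands_1_5["mean"])
  # degenerate portfolio: correlation undefined, warned not crashed
  rec2 <- rec[c(1, 1), ]
  expect_warning(s2 <- summaryStatistics(rec2), "undefined")
  expect_true(is.na(s2$r_logC_logP))
})
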