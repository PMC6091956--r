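test_that("ranking is descending in score with cost and id tie-breaks", {
  rec <- data.frame(project_id = c("a", "b", "c"), score = c(3, 1, 2),
                    cost = 1)
  expect_equal(rankProjects(rec)$rank[match(c("a", "b", "c"),
                                            rankProjects(rec)$project_id)],
               c(1L, 3L, 2L))
  tie <- data.frame(project_id = c("x", "y"), score = c(1, 1),
                    cost = c(10, 5))
  expect_identical(rankProjects(tie)$project_id[1], "y")   # cheaper wins
  set.seed(31)
  for (i in 1:10) {
    n <- sample(2:30, 1)
    rec <- data.frame(project_id = sprintf("p%02d", 1:n),
                      score = sample(runif(5), n, replace = TRUE),
                      cost = runif(n))
    expect_setequal(rankProjects(rec)$rank, seq_len(n))
  }
})

test_that("worked fixture scores and ranks match hand arithmetic", {
  af50 <- (1 - 1.01^-50) / 0.01
  af10 <- (1 - 1.01^-10) / 0.01
  af5 <- (1 - 1.01^-5) / 0.01
  rec <- prioritize(workedFixture())
  expected <- data.frame(
    project_id = c("F1", "F2", "F3", "F4", "F5"),
    benefit = c(0.90, 0.65, 0.05, 0.50, 0.90),
    likelihood = c(0.9^3, 0.9^3 * (0.8 * 0.9 * 0.95), 1,
                   0.7 * 0.8 * 0.9, 0.125),
    cost = c(500 * af50, 500 * af50 + 2000 * af10, 500 * af50,
             10000 * af50, 200 * af5), stringsAsFactors = FALSE)
  expected$score <- expected$benefit * expected$likelihood / expected$cost
  m <- match(expected$project_id, rec$project_id)
  expect_equal(rec$benefit[m], expected$benefit)
  expect_equal(rec$likelihood[m], expected$likelihood)
  expect_equal(rec$cost[m], expected$cost)
  expect_equal(rec$score[m], expected$score)
  expect_equal(rec$rank[m], rank(-expected$score))
})

test_that("budget selection matches a brute-force simulator on random fixtures", {
  for (seed in 1:8) {
    fx <- randomFixture(sample(3:8, 1), seed = 100 + seed)
    pf <- ProjectPortfolio(fx$species, fx$actions)
    full <- sum(prioritize(pf)$cost)
    budget <- runif(1, 0.2, 1.1) * full
    got <- selectUnderBudget(pf, budget)
    want <- oracleSelect(fx$species, fx$actions, budget)
    expect_identical(got$removed, want$removed)
    expect_setequal(got$kept$project_id, want$kept)
    # kept and removed partition the input
    expect_setequal(c(got$kept$project_id, got$removed),
                    fx$species$project_id)
  }
})

test_that("excess budget keeps everything; starvation empties the portfolio", {
  pf <- workedFixture()
  rec <- prioritize(pf)
  all_in <- selectUnderBudget(pf, sum(rec$cost) * 2)
  expect_identical(nrow(all_in$kept), 5L)
  expect_length(all_in$removed, 0)
  expect_warning(none <- selectUnderBudget(pf, 10), "cheapest")
  expect_identical(nrow(none$kept), 0L)
  expect_length(none$removed, 5)
})

test_that("with no sharing, selection is truncation of the ranked list", {
  fx <- randomFixture(7, seed = 55)
  fx$actions$location_key <- paste0("iso_", seq_len(nrow(fx$actions)))
  pf <- ProjectPortfolio(fx$species, fx$actions)
  rec <- prioritize(pf)
  budget <- sum(rec$cost[rec$rank <= 4]) * 1.0001
  got <- selectUnderBudget(pf, budget)
  expect_setequal(got$kept$project_id, rec$project_id[rec$rank <= 4])
  expect_identical(got$removed, rec$project_id[order(-rec$rank)][1:3])
})

test_that("dissolving a cost-share raises the partner's cost and can reorder removals", {
  # p1 and p2 share an action for which p2 proposes the larger amount
  # (1000/yr vs 500/yr); p2 is weak and is removed first, after which p1
  # loses the sharing discount and bears its own full 500/yr proposal
  species <- data.frame(
    project_id = c("p1", "p2", "p3"), species_name = c("s1", "s2", "s3"),
    taxon_group = "plant", p_n = c(0.3, 0.3, 0.3),
    p_w = 0.95, benefit_confidence = "confident",
    iucn_category = "endangered", recent_site_confirmation = TRUE,
    cost_total_npv = NA_real_, stringsAsFactors = FALSE)
  yrs <- paste(1:50, collapse = ";")
  actions <- data.frame(
    action_id = c("a1", "a2", "a3"), project_id = c("p1", "p2", "p3"),
    site_id = "s", location_key = c("SH", "SH", "own"),
    action_type = "weed_control", years = yrs,
    annual_cost = c(500, 1000, 900),
    input_success = c(0.9, 0.2, 0.9), threat_outcome_success = c(0.9, 0.2, 0.9),
    species_outcome_success = c(0.9, 0.2, 0.9),
    confidence = "confident", stringsAsFactors = FALSE)
  pf <- ProjectPortfolio(species, actions)
  before <- prioritize(pf)
  af50 <- (1 - 1.01^-50) / 0.01
  # p1's share of the 1000/yr maximum: 1000 * 500/1500
  expect_equal(before$cost[before$project_id == "p1"], 1000 * 500 / 1500 * af50)
  sel <- selectUnderBudget(pf, budget = 1500 * af50)
  expect_identical(sel$removed, "p2")
  after <- sel$kept
  expect_equal(after$cost[after$project_id == "p1"], 500 * af50)
  # matches the brute-force simulator too
  want <- oracleSelect(species, actions, 1500 * af50)
  expect_identical(sel$removed, want$removed)
})

test_that("the ROI curve is the cumulative mean annual cost in rank order", {
  one <- data.frame(project_id = "p", rank = 1L, cost = 500000)
  expect_equal(roiCurve(one),
               data.frame(n_species = 1L, cumulative_annual_cost = 10000))
  rec <- prioritize(generatePortfolio(generatorSpec(nProjects = 50, seed = 8)))
  curve <- roiCurve(rec)
  expect_identical(nrow(curve), 50L)
  expect_true(all(diff(curve$cumulative_annual_cost) > 0))
  expect_equal(curve$cumulative_annual_cost[50], sum(rec$cost) / 50)
})
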