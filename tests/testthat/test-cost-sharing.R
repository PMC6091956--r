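makeActions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(action_id = r[[1]], project_id = r[[2]], site_id = "s",
               location_key = r[[3]], action_type = r[[4]], years = r[[5]],
               annual_cost = as.numeric(r[[6]]), input_success = 0.9,
               threat_outcome_success = 0.9, species_outcome_success = 0.9,
               confidence = "confident", stringsAsFactors = FALSE)))
}

test_that("shared groups require matching location, type and year across projects", {
  a <- makeActions(list("a1", "p1", "L1", "weed_control", "3", 100),
                   list("a2", "p2", "L1", "weed_control", "3", 100))
  g <- findSharedGroups(a)
  expect_length(g, 1L)
  expect_identical(nrow(g[[1]]@members), 2L)

  # same location, different years: no sharing
  a$years <- c("3", "4")
  expect_length(findSharedGroups(a), 0L)

  # different action type: no sharing
  a$years <- c("3", "3"); a$action_type <- c("weed_control", "fencing")
  expect_length(findSharedGroups(a), 0L)

  # within-project co-location does not count
  a <- makeActions(list("a1", "p1", "L1", "weed_control", "3", 100),
                   list("a2", "p1", "L1", "weed_control", "3", 100))
  expect_length(findSharedGroups(a), 0L)

  # three co-located projects form one group of three, confirmed by a
  # brute-force pairing check
  a <- makeActions(list("a1", "p1", "L1", "weed_control", "7", 100),
                   list("a2", "p2", "L1", "weed_control", "7", 250),
                   list("a3", "p3", "L1", "weed_control", "7", 400),
                   list("a4", "p4", "L2", "weed_control", "7", 50))
  g <- findSharedGroups(a)
  expect_length(g, 1L)
  shared <- vapply(seq_len(nrow(a)), function(i)
    any(a$location_key == a$location_key[i] &
          a$action_type == a$action_type[i] & a$years == a$years[i] &
          a$project_id != a$project_id[i]), NA)
  expect_setequal(g[[1]]@members$action_id, a$action_id[shared])
})

test_that("apportionment splits the group maximum in proportion to proposals", {
  mk <- function(costs) new("SharedActionGroup", locationKey = "L",
                            actionType = "t", year = 1L,
                            members = data.frame(
                              project_id = sprintf("p%d", seq_along(costs)),
                              action_id = sprintf("a%d", seq_along(costs)),
                              proposed_cost = costs))
  expect_equal(unname(apportion(mk(c(100, 100)))), c(50, 50))
  expect_equal(unname(apportion(mk(c(100, 300)))), c(75, 225))
  eq3 <- apportion(mk(c(100, 100, 100)))
  expect_equal(unname(eq3), rep(100 / 3, 3))
  expect_equal(sum(eq3), 100)
  expect_error(apportion(mk(c(0, 100))), "zero")
  # conservation over random groups
  set.seed(9)
  for (i in 1:20) {
    costs <- runif(sample(2:6, 1), 10, 1000)
    expect_equal(sum(apportion(mk(costs))), max(costs))
  }
})

test_that("dissolution re-apportions and never lowers a remaining share", {
  mk <- function(costs) new("SharedActionGroup", locationKey = "L",
                            actionType = "t", year = 1L,
                            members = data.frame(
                              project_id = sprintf("p%d", seq_along(costs)),
                              action_id = sprintf("a%d", seq_along(costs)),
                              proposed_cost = costs))
  # losing the larger partner leaves the survivor on its own full proposal
  solo <- dissolveMember(mk(c(100, 300)), "p2")
  expect_equal(solo, c(p1 = 100))
  # equal three-way split becomes an equal two-way split
  g2 <- dissolveMember(mk(c(100, 100, 100)), "p3")
  expect_equal(unname(apportion(g2)), c(50, 50))
  expect_error(dissolveMember(mk(c(100, 100)), "p9"), "not a member")
  set.seed(13)
  for (i in 1:20) {
    costs <- runif(sample(3:6, 1), 10, 1000)
    g <- mk(costs)
    before <- apportion(g)
    out <- dissolveMember(g, sample(g@members$project_id, 1))
    after <- if (is.numeric(out)) out else apportion(out)
    expect_true(all(after >= before[names(after)] - 1e-9))
    expect_equal(sum(after),
                 max(costs[match(names(after), g@members$project_id)]))
  }
})

test_that("sharing is a pure discount: unshared portfolios cost the same either way", {
  fx <- randomFixture(6, seed = 21)
  fx$actions$location_key <- paste0("iso_", seq_len(nrow(fx$actions)))
  pf <- ProjectPortfolio(fx$species, fx$actions)
  expect_equal(projectCosts(pf, apportion = TRUE),
               projectCosts(pf, apportion = FALSE))
  # and with sharing, nobody ever pays more than standalone
  fx2 <- randomFixture(6, seed = 22)
  pf2 <- ProjectPortfolio(fx2$species, fx2$actions)
  expect_true(all(projectCosts(pf2, apportion = TRUE) <=
                    projectCosts(pf2, apportion = FALSE) + 1e-9))
})
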