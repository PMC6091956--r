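.ACTION_TYPES <- c("weed_control", "predator_baiting", "grazing_exclusion",
                   "habitat_restoration", "fire_management", "translocation",
                   "fencing_maintenance", "survey_monitoring")

## contiguous schedule string over the 50-year horizon
.scheduleString <- function(start, len) {
  paste(seq.int(start, start + len - 1L), collapse = ";")
}

#' Generate a synthetic project portfolio
#'
#' Draws a portfolio with the statistical structure of a state-wide
#' threatened-species program: `p_n` clustered around the IUCN anchoring
#' values (0.9/0.3/0.05) with truncated-normal elicitation jitter, `p_w`
#' fixed at the 0.95 objective except for a small deterministic fraction
#' drawn from 0.5-0.9, 1-20 actions per project with Beta-distributed
#' I/T/S success probabilities, right-skewed lognormal 50-year project
#' costs allocated across actions (so the discounted project total
#' reproduces the drawn cost exactly at the default 1% rate), a low rate of
#' cross-project cost-sharing pairs, qualitative confidence grades and a
#' fraction of projects without recent site confirmation. Output is
#' deterministic given the seed and always satisfies the portfolio
#' invariants.
#'
#' @param spec a [GeneratorSpec-class].
#' @return a [ProjectPortfolio-class].
#' @examples
#' pf <- generatePortfolio(generatorSpec(nProjects = 25, seed = 3))
#' pf
#' @export
generatePortfolio <- function(spec = generatorSpec()) {
  stopifnot(is(spec, "GeneratorSpec"))
  set.seed(spec@seed)
  n <- spec@nProjects
  ids <- sprintf("P%04d", seq_len(n))
  taxon <- sample(names(spec@taxonMix), n, replace = TRUE,
                  prob = spec@taxonMix)
  iucn <- sample(names(spec@iucnMix), n, replace = TRUE, prob = spec@iucnMix)

  ## p_w: the 0.95 objective, except a fixed-count subset in 0.5-0.9
  pw <- rep(0.95, n)
  nLow <- round(spec@fracPwBelowDefault * n)
  if (nLow > 0) {
    low <- sample.int(n, nLow)
    pw[low] <- stats::runif(nLow, 0.5, 0.9)
  }
  ## p_n: anchor + jitter, kept so that benefit stays within 0.05-0.95
  pn <- anchorPn(iucn) + stats::rnorm(n, 0, spec@pnJitterSd)
  pn <- pmin(pmax(pn, pmax(pw - 0.95, 0)), pw - 0.05)

  species <- data.frame(
    project_id = ids,
    species_name = sprintf("%s_sp_%04d", taxon, seq_len(n)),
    taxon_group = taxon, p_n = pn, p_w = pw,
    benefit_confidence = sample(names(spec@confidenceMix), n, replace = TRUE,
                                prob = spec@confidenceMix),
    iucn_category = iucn,
    recent_site_confirmation = stats::runif(n) > spec@staleSiteRate,
    cost_total_npv = NA_real_, stringsAsFactors = FALSE)

  ## actions: counts, schedules, success probabilities
  k <- sample(seq.int(spec@actionRange[1], spec@actionRange[2]), n,
              replace = TRUE)
  nAct <- sum(k)
  projOf <- rep(ids, k)
  actionId <- sprintf("%s_A%02d", projOf, unlist(lapply(k, seq_len)))
  fullRun <- stats::runif(nAct) < 0.7
  start <- ifelse(fullRun, 1L, sample.int(41L, nAct, replace = TRUE))
  len <- ifelse(fullRun, 50L, sample.int(10L, nAct, replace = TRUE))
  schedule <- mapply(.scheduleString, start, len)
  its <- matrix(stats::rbeta(3L * nAct, spec@itsBeta[1], spec@itsBeta[2]),
                ncol = 3L)

  ## project cost drawn lognormal (clipped), split across actions so the
  ## discounted project total equals the draw at the default 1% rate
  dsp <- discountSpec()
  projCost <- exp(stats::rnorm(n, spec@costLogMean, spec@costLogSd))
  projCost <- pmin(pmax(projCost, spec@costClip[1]), spec@costClip[2])
  w <- stats::rexp(nAct)
  w <- w / rep(vapply(split(w, projOf)[ids], sum, 0), k)
  af <- vapply(.parseYears(schedule), .annuityFactor, 0, spec = dsp)
  annual <- rep(projCost, k) * w / af

  actions <- data.frame(
    action_id = actionId, project_id = projOf,
    site_id = sprintf("S_%s", actionId),
    location_key = sprintf("LOC_%s", actionId),
    action_type = sample(.ACTION_TYPES, nAct, replace = TRUE),
    years = schedule, annual_cost = annual,
    input_success = its[, 1], threat_outcome_success = its[, 2],
    species_outcome_success = its[, 3],
    confidence = sample(names(spec@confidenceMix), nAct, replace = TRUE,
                        prob = spec@confidenceMix),
    stringsAsFactors = FALSE)

  ## cost-sharing: pair up projects and force one action of each pair onto
  ## a common location, type and schedule
  nPairs <- floor(spec@sharingRate * n / 2)
  if (nPairs > 0 && n >= 2L) {
    pairProj <- matrix(sample(ids, 2L * nPairs), ncol = 2L)
    for (i in seq_len(nPairs)) {
      a <- which(actions$project_id == pairProj[i, 1L])[1L]
      b <- which(actions$project_id == pairProj[i, 2L])[1L]
      actions$location_key[b] <- actions$location_key[a] <-
        sprintf("SHARED_%03d", i)
      actions$action_type[b] <- actions$action_type[a]
      actions$years[b] <- actions$years[a]
    }
  }
  ProjectPortfolio(species, actions)
}

#' A tiny hand-built portfolio with known scores
#'
#' Five projects covering the structural cases the pipeline must handle:
#' an equal-cost cost-sharing pair (split 50/50), a project below the 0.95
#' viability objective, a stale-site project (no recent confirmation, so
#' the wider +100%/-30% cost interval applies), a near-certain monitoring
#' project, and a cheap low-likelihood project. All benefits, likelihoods,
#' costs and ranks can be verified by hand (see the test suite).
#'
#' @return a [ProjectPortfolio-class] of 5 projects and 6 actions.
#' @examples
#' prioritize(workedFixture())
#' @export
workedFixture <- function() {
  species <- data.frame(
    project_id = c("F1", "F2", "F3", "F4", "F5"),
    species_name = c("plant_alpha", "animal_beta", "plant_gamma",
                     "fungus_delta", "plant_epsilon"),
    taxon_group = c("plant", "animal", "plant", "fungus", "plant"),
    p_n = c(0.05, 0.30, 0.90, 0.30, 0.05),
    p_w = c(0.95, 0.95, 0.95, 0.80, 0.95),
    benefit_confidence = c("confident", "very_confident", "confident",
                           "not_confident", "confident"),
    iucn_category = c("critically_endangered", "endangered", "vulnerable",
                      "endangered", "critically_endangered"),
    recent_site_confirmation = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    cost_total_npv = NA_real_, stringsAsFactors = FALSE)
  allYears <- paste(1:50, collapse = ";")
  actions <- data.frame(
    action_id = c("F1_A1", "F2_A1", "F2_A2", "F3_A1", "F4_A1", "F5_A1"),
    project_id = c("F1", "F2", "F2", "F3", "F4", "F5"),
    site_id = c("S1", "S1", "S2", "S3", "S4", "S5"),
    location_key = c("L1", "L1", "L2", "L3", "L4", "L5"),
    action_type = c("weed_control", "weed_control", "fencing_maintenance",
                    "survey_monitoring", "predator_baiting",
                    "translocation"),
    years = c(allYears, allYears, paste(1:10, collapse = ";"), allYears,
              allYears, paste(1:5, collapse = ";")),
    annual_cost = c(1000, 1000, 2000, 500, 10000, 200),
    input_success = c(0.9, 0.9, 0.8, 1, 0.7, 0.5),
    threat_outcome_success = c(0.9, 0.9, 0.9, 1, 0.8, 0.5),
    species_outcome_success = c(0.9, 0.9, 0.95, 1, 0.9, 0.5),
    confidence = c("confident", "confident", "very_confident",
                   "very_confident", "not_confident", "not_confident"),
    stringsAsFactors = FALSE)
  ProjectPortfolio(species, actions)
}
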