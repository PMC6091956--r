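#' @import methods
NULL

## Qualitative confidence grades used in expert elicitation, and the symmetric
## half-widths of the quantitative intervals they map to.
.CONFIDENCE_LEVELS <- c("very_confident", "confident", "not_confident")
.CONFIDENCE_HALFWIDTH <- c(very_confident = 0.05,
                           confident      = 0.10,
                           not_confident  = 0.20)

.TAXON_GROUPS <- c("plant", "animal", "fungus")
.IUCN_CATEGORIES <- c("vulnerable", "endangered", "critically_endangered")

.SPECIES_COLUMNS <- c("project_id", "species_name", "taxon_group", "p_n",
                      "p_w", "benefit_confidence", "iucn_category",
                      "recent_site_confirmation")
.ACTION_COLUMNS <- c("action_id", "project_id", "site_id", "location_key",
                     "action_type", "years", "annual_cost", "input_success",
                     "threat_outcome_success", "species_outcome_success",
                     "confidence")

#' Map a qualitative confidence grade to its interval half-width
#'
#' Expert estimates of probabilities carry a qualitative confidence grade
#' (`"very_confident"`, `"confident"` or `"not_confident"`) which is
#' translated to a symmetric quantitative interval of half-width 0.05, 0.10
#' or 0.20 respectively.
#'
#' @param grade character vector of confidence grades.
#' @return numeric vector of half-widths.
#' @examples
#' confidenceHalfWidth(c("confident", "not_confident"))
#' @export
confidenceHalfWidth <- function(grade) {
  grade <- tolower(as.character(grade))
  bad <- !(grade %in% .CONFIDENCE_LEVELS)
  if (any(bad))
    stop("unknown confidence grade(s): ",
         paste(unique(grade[bad]), collapse = ", "))
  unname(.CONFIDENCE_HALFWIDTH[grade])
}

## ---- validity helpers -------------------------------------------------------

.checkProb <- function(x, what) {
  bad <- which(!is.finite(x) | x < 0 | x > 1)
  if (length(bad))
    return(sprintf("%s outside [0,1] at row(s) %s", what,
                   paste(utils::head(bad, 5L), collapse = ", ")))
  NULL
}

.parseYears <- function(years) {
  ## "1;2;3" -> integer vector; vectorised over a character column
  lapply(strsplit(as.character(years), ";", fixed = TRUE),
         function(y) as.integer(y))
}

.formatYears <- function(years) {
  vapply(years, function(y) paste(y, collapse = ";"), character(1))
}

#' Portfolio of species projects and their management actions
#'
#' An S4 container holding the two-table dataset on which the prioritization
#' operates: one record per species project (viability probabilities with and
#' without management, confidence grade, taxon, optional IUCN category and an
#' optional pre-aggregated 50-year cost) and one record per management action
#' (schedule of years, annual cost, the three success probabilities and a
#' confidence grade). Validity enforces the domain invariants: probabilities
#' in \[0,1\], `p_w >= p_n`, non-negative costs, schedules within the 50-year
#' horizon, and referential integrity of actions to projects (every project
#' has at least one action).
#'
#' @slot species data.frame of species projects.
#' @slot actions data.frame of management actions.
#' @export
setClass("ProjectPortfolio",
         representation(species = "data.frame", actions = "data.frame"))

.validPortfolio <- function(object) {
  sp <- object@species
  ac <- object@actions
  msgs <- character(0)
  miss <- setdiff(.SPECIES_COLUMNS, names(sp))
  if (length(miss))
    return(sprintf("species table is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  miss <- setdiff(.ACTION_COLUMNS, names(ac))
  if (length(miss))
    return(sprintf("actions table is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  if (anyDuplicated(sp$project_id))
    msgs <- c(msgs, "duplicated project_id in species table")
  if (anyDuplicated(ac$action_id))
    msgs <- c(msgs, "duplicated action_id in actions table")
  msgs <- c(msgs,
            .checkProb(sp$p_n, "p_n"), .checkProb(sp$p_w, "p_w"),
            .checkProb(ac$input_success, "input_success"),
            .checkProb(ac$threat_outcome_success, "threat_outcome_success"),
            .checkProb(ac$species_outcome_success, "species_outcome_success"))
  bad <- which(sp$p_w < sp$p_n)
  if (length(bad))
    msgs <- c(msgs, sprintf("p_w < p_n (negative benefit) at row(s) %s",
                            paste(utils::head(bad, 5L), collapse = ", ")))
  if (any(!is.finite(ac$annual_cost) | ac$annual_cost < 0))
    msgs <- c(msgs, "negative or non-finite annual_cost")
  if (!all(tolower(sp$benefit_confidence) %in% .CONFIDENCE_LEVELS))
    msgs <- c(msgs, "unknown benefit_confidence grade")
  if (!all(tolower(ac$confidence) %in% .CONFIDENCE_LEVELS))
    msgs <- c(msgs, "unknown action confidence grade")
  yrs <- unlist(.parseYears(ac$years))
  if (length(yrs) && (anyNA(yrs) || any(yrs < 1L) || any(yrs > 50L)))
    msgs <- c(msgs, "action schedule years must lie in 1..50")
  orphan <- setdiff(ac$project_id, sp$project_id)
  if (length(orphan))
    msgs <- c(msgs, sprintf("action(s) reference unknown project_id: %s",
                            paste(utils::head(orphan, 5L), collapse = ", ")))
  childless <- setdiff(sp$project_id, ac$project_id)
  if (length(childless))
    msgs <- c(msgs, sprintf(
      "project(s) without any action (likelihood undefined): %s",
      paste(utils::head(childless, 5L), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
}

setValidity("ProjectPortfolio", .validPortfolio)

#' Construct a ProjectPortfolio
#'
#' @param species data.frame with columns `project_id`, `species_name`,
#'   `taxon_group`, `p_n`, `p_w`, `benefit_confidence`, `iucn_category`,
#'   `recent_site_confirmation` and optionally `cost_total_npv` (a
#'   pre-aggregated 50-year net-present-value cost; `NA` where absent).
#' @param actions data.frame with columns `action_id`, `project_id`,
#'   `site_id`, `location_key`, `action_type`, `years` (semicolon-separated
#'   integers in 1..50), `annual_cost`, `input_success`,
#'   `threat_outcome_success`, `species_outcome_success`, `confidence`.
#' @return a validated [ProjectPortfolio-class] object.
#' @examples
#' pf <- workedFixture()
#' pf
#' @export
ProjectPortfolio <- function(species, actions) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  actions <- as.data.frame(actions, stringsAsFactors = FALSE)
  species$cost_total_npv <- if (is.null(species$cost_total_npv))
    NA_real_ else as.numeric(species$cost_total_npv)
  species$benefit_confidence <- tolower(species$benefit_confidence)
  actions$confidence <- tolower(actions$confidence)
  rownames(species) <- rownames(actions) <- NULL
  new("ProjectPortfolio", species = species, actions = actions)
}

#' Discounting specification for multi-year costs
#'
#' Net present value of a stream of annual costs: a cost in year `t` is
#' divided by `(1 + rate)^t`, with year 1 the first discounted year and a
#' default horizon of 50 years.
#'
#' @slot rate annual discount rate (default 0.01).
#' @slot horizon last admissible year (default 50).
#' @export
setClass("DiscountSpec",
         representation(rate = "numeric", horizon = "integer"),
         prototype(rate = 0.01, horizon = 50L),
         validity = function(object) {
           if (length(object@rate) != 1L || !is.finite(object@rate) ||
               object@rate < 0)
             return("rate must be a single non-negative number")
           if (length(object@horizon) != 1L || object@horizon < 1L)
             return("horizon must be a single integer >= 1")
           TRUE
         })

#' @param rate annual discount rate.
#' @param horizon planning horizon in years.
#' @rdname DiscountSpec-class
#' @examples
#' discountSpec()               # 1% over 50 years
#' discountSpec(rate = 0)       # undiscounted
#' @export
discountSpec <- function(rate = 0.01, horizon = 50L) {
  new("DiscountSpec", rate = as.numeric(rate), horizon = as.integer(horizon))
}

#' Monte Carlo simulation settings for uncertainty propagation
#'
#' Settings for propagating elicitation uncertainty into rank likelihood
#' intervals: replicate count, seed, the relative cost interval (a constant
#' +/-30%, replaced by +100%/-30% for projects whose sites lack recent
#' on-ground confirmation), the lower truncation applied to sampled
#' likelihoods, the rank-percentile thresholds defining the five priority
#' bands, and the banding rule variant.
#'
#' @slot nSims number of Monte Carlo replicates (default 10500).
#' @slot seed RNG seed.
#' @slot costHalfWidth relative half-width of the cost interval (default 0.30).
#' @slot costStale lower/upper relative bounds for stale-site projects
#'   (default -0.30, +1.00).
#' @slot lFloor lower truncation applied to sampled likelihood values
#'   (default 0.1).
#' @slot bandThresholds rank-fraction cutoffs for banding (default 0.30, 0.70).
#' @slot bandRule `"disjoint"` (default) or `"printed"`; see [assignBands()].
#' @export
setClass("SimulationConfig",
         representation(nSims = "integer", seed = "integer",
                        costHalfWidth = "numeric", costStale = "numeric",
                        lFloor = "numeric", bandThresholds = "numeric",
                        bandRule = "character"),
         prototype(nSims = 10500L, seed = 1L, costHalfWidth = 0.30,
                   costStale = c(lower = -0.30, upper = 1.00), lFloor = 0.1,
                   bandThresholds = c(0.30, 0.70), bandRule = "disjoint"),
         validity = function(object) {
           if (object@nSims < 1L) return("nSims must be >= 1")
           th <- object@bandThresholds
           if (length(th) != 2L || any(th <= 0) || any(th >= 1) ||
               th[1] >= th[2])
             return("bandThresholds must be two ordered fractions in (0,1)")
           if (length(object@costStale) != 2L ||
               object@costStale[1] <= -1)
             return("costStale must give relative bounds > -100%")
           if (!object@bandRule %in% c("disjoint", "printed"))
             return("bandRule must be 'disjoint' or 'printed'")
           if (object@lFloor < 0 || object@lFloor > 1)
             return("lFloor must be in [0,1]")
           TRUE
         })

#' @param nSims,seed,costHalfWidth,costStale,lFloor,bandThresholds,bandRule
#'   see the class slots.
#' @rdname SimulationConfig-class
#' @examples
#' simulationConfig(nSims = 1000, seed = 7)
#' @export
simulationConfig <- function(nSims = 10500L, seed = 1L, costHalfWidth = 0.30,
                             costStale = c(lower = -0.30, upper = 1.00),
                             lFloor = 0.1, bandThresholds = c(0.30, 0.70),
                             bandRule = c("disjoint", "printed")) {
  new("SimulationConfig", nSims = as.integer(nSims), seed = as.integer(seed),
      costHalfWidth = costHalfWidth, costStale = costStale, lFloor = lFloor,
      bandThresholds = bandThresholds, bandRule = match.arg(bandRule))
}

#' Result of Monte Carlo rank-uncertainty propagation
#'
#' Holds, for each project, the deterministic rank, the 2.5/97.5 percentile
#' rank likelihood interval over simulated replicates, the assigned priority
#' band (1 = highest priority), and optionally the full matrix of simulated
#' ranks (projects x replicates).
#'
#' @slot intervals data.frame with columns `project_id`, `rank`, `rank_lo`,
#'   `rank_hi`, `interval_length`, `band`.
#' @slot simulatedRanks integer matrix of ranks, one row per project, one
#'   column per replicate.
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("RankSimulation",
         representation(intervals = "data.frame", simulatedRanks = "matrix",
                        config = "SimulationConfig"))

#' Parameter specification for the synthetic portfolio generator
#'
#' Encapsulates the distributional assumptions under which synthetic
#' portfolios are generated; the defaults emulate the published statistical
#' structure of a 368-project state-wide program (see the package vignette).
#'
#' @slot nProjects number of species projects.
#' @slot seed RNG seed.
#' @slot taxonMix mixing proportions over plant/animal/fungus.
#' @slot iucnMix mixing proportions over the three IUCN threat categories.
#' @slot pnJitterSd standard deviation of the deviation of elicited `p_n`
#'   from its IUCN anchoring value.
#' @slot fracPwBelowDefault fraction of projects with `p_w` below the 0.95
#'   default (drawn uniformly from 0.5-0.9).
#' @slot actionRange minimum and maximum actions per project.
#' @slot itsBeta shape1/shape2 of the Beta distribution for the I, T, S
#'   success probabilities.
#' @slot costLogMean,costLogSd meanlog/sdlog of the lognormal 50-year
#'   project cost.
#' @slot costClip lower/upper clipping bounds on project cost (dollars).
#' @slot sharingRate fraction of projects participating in cost-sharing
#'   pairs.
#' @slot confidenceMix mixing proportions over the three confidence grades.
#' @slot staleSiteRate fraction of projects without recent site confirmation.
#' @export
setClass("GeneratorSpec",
         representation(nProjects = "integer", seed = "integer",
                        taxonMix = "numeric", iucnMix = "numeric",
                        pnJitterSd = "numeric", fracPwBelowDefault = "numeric",
                        actionRange = "integer", itsBeta = "numeric",
                        costLogMean = "numeric", costLogSd = "numeric",
                        costClip = "numeric", sharingRate = "numeric",
                        confidenceMix = "numeric", staleSiteRate = "numeric"),
         prototype(nProjects = 368L, seed = 1L,
                   taxonMix = c(plant = 312, animal = 47, fungus = 9) / 368,
                   iucnMix = c(vulnerable = 0.32, endangered = 0.33,
                               critically_endangered = 0.35),
                   pnJitterSd = 0.19, fracPwBelowDefault = 22 / 368,
                   actionRange = c(1L, 20L), itsBeta = c(18, 1),
                   costLogMean = 13.345, costLogSd = 1.27,
                   costClip = c(16876, 23462859), sharingRate = 0.08,
                   confidenceMix = c(very_confident = 0.25, confident = 0.50,
                                     not_confident = 0.25),
                   staleSiteRate = 0.20),
         validity = function(object) {
           mixes <- list(taxonMix = object@taxonMix, iucnMix = object@iucnMix,
                         confidenceMix = object@confidenceMix)
           for (nm in names(mixes)) {
             m <- mixes[[nm]]
             if (any(m < 0) || abs(sum(m) - 1) > 1e-8)
               return(sprintf("%s must be non-negative and sum to 1", nm))
           }
           if (object@nProjects < 1L) return("nProjects must be >= 1")
           if (object@actionRange[1] < 1L ||
               object@actionRange[2] < object@actionRange[1])
             return("actionRange must be an ordered pair with min >= 1")
           if (object@costClip[1] <= 0 ||
               object@costClip[2] <= object@costClip[1])
             return("costClip must be ordered positive bounds")
           med <- exp(object@costLogMean)
           if (med < object@costClip[1] || med > object@costClip[2])
             return("cost clip bounds exclude the lognormal median; spec infeasible")
           for (fr in c(object@fracPwBelowDefault, object@sharingRate,
                        object@staleSiteRate))
             if (fr < 0 || fr > 1) return("rates must be fractions in [0,1]")
           TRUE
         })

#' @param nProjects,seed,taxonMix,iucnMix,pnJitterSd,fracPwBelowDefault
#'   see the class slots.
#' @param actionRange,itsBeta,costLogMean,costLogSd,costClip,sharingRate
#'   see the class slots.
#' @param confidenceMix,staleSiteRate see the class slots.
#' @rdname GeneratorSpec-class
#' @examples
#' generatorSpec(nProjects = 20, seed = 42)
#' @export
generatorSpec <- function(nProjects = 368L, seed = 1L,
                          taxonMix = c(plant = 312, animal = 47,
                                       fungus = 9) / 368,
                          iucnMix = c(vulnerable = 0.32, endangered = 0.33,
                                      critically_endangered = 0.35),
                          pnJitterSd = 0.19,
                          fracPwBelowDefault = 22 / 368,
                          actionRange = c(1L, 20L), itsBeta = c(18, 1),
                          costLogMean = 13.345, costLogSd = 1.27,
                          costClip = c(16876, 23462859), sharingRate = 0.08,
                          confidenceMix = c(very_confident = 0.25,
                                            confident = 0.50,
                                            not_confident = 0.25),
                          staleSiteRate = 0.20) {
  new("GeneratorSpec", nProjects = as.integer(nProjects),
      seed = as.integer(seed), taxonMix = taxonMix, iucnMix = iucnMix,
      pnJitterSd = pnJitterSd, fracPwBelowDefault = fracPwBelowDefault,
      actionRange = as.integer(actionRange), itsBeta = itsBeta,
      costLogMean = costLogMean, costLogSd = costLogSd, costClip = costClip,
      sharingRate = sharingRate, confidenceMix = confidenceMix,
      staleSiteRate = staleSiteRate)
}
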