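#' IUCN anchoring value for the no-management viability probability
#'
#' The probability of a viable population in 100 years without targeted
#' management (`p_n`) is anchored on the species' IUCN Red List category via
#' published 100-year cumulative extinction-risk curves: Vulnerable 0.9,
#' Endangered 0.3, Critically endangered 0.05.
#'
#' @param category character vector of categories (`"vulnerable"`,
#'   `"endangered"`, `"critically_endangered"`).
#' @return numeric vector of anchoring probabilities.
#' @examples
#' anchorPn("endangered")
#' @export
anchorPn <- function(category) {
  anchors <- c(vulnerable = 0.9, endangered = 0.3,
               critically_endangered = 0.05)
  category <- tolower(as.character(category))
  bad <- !(category %in% names(anchors))
  if (any(bad))
    stop("unknown IUCN category: ",
         paste(unique(category[bad]), collapse = ", "))
  unname(anchors[category])
}

#' Project benefit: marginal gain in 100-year viability
#'
#' `B = p_w - p_n`, the increase in the species' probability of having a
#' viable population in 100 years attributable to full and successful
#' implementation of the project.
#'
#' @param pWith viability probability with management (`p_w`).
#' @param pWithout viability probability without management (`p_n`).
#' @return benefit in \[0,1\]; vectorised.
#' @examples
#' computeBenefit(0.95, 0.05)
#' @export
computeBenefit <- function(pWith, pWithout) {
  stopifnot(all(is.finite(pWith)), all(is.finite(pWithout)))
  if (any(pWith < 0 | pWith > 1 | pWithout < 0 | pWithout > 1))
    stop("viability probabilities must lie in [0,1]")
  if (any(pWith < pWithout))
    stop("p_w < p_n: negative benefit is not modelled")
  pWith - pWithout
}

#' Project likelihood of success
#'
#' The product over all of a project's actions of the three per-action
#' success probabilities: input success (can the action be implemented),
#' threat-outcome success (does it control the threat) and species-outcome
#' success (does the population respond). The three are elicited as
#' independent, so their product is the probability the action achieves its
#' objective, and the project succeeds only if every action does.
#'
#' @param actions data.frame with columns `input_success`,
#'   `threat_outcome_success`, `species_outcome_success` (one row per
#'   action), or a numeric vector of per-action success products.
#' @return a single probability in \[0,1\].
#' @examples
#' computeLikelihood(data.frame(input_success = 0.9,
#'                              threat_outcome_success = 0.8,
#'                              species_outcome_success = 0.7))
#' @export
computeLikelihood <- function(actions) {
  if (is.data.frame(actions)) {
    if (nrow(actions) == 0L)
      stop("likelihood of success is undefined for a project with no actions")
    p <- actions$input_success * actions$threat_outcome_success *
      actions$species_outcome_success
  } else {
    p <- as.numeric(actions)
    if (length(p) == 0L)
      stop("likelihood of success is undefined for a project with no actions")
  }
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("success probabilities must lie in [0,1]")
  prod(p)
}

## per-project likelihoods for a whole portfolio, in species-table order
.projectLikelihoods <- function(portfolio) {
  ac <- actionsTable(portfolio)
  p <- ac$input_success * ac$threat_outcome_success *
    ac$species_outcome_success
  byProject <- vapply(split(p, ac$project_id), prod, 0)
  unname(byProject[projectIds(portfolio)])
}

#' Net present value of a stream of annual costs
#'
#' `sum_t cost_t / (1 + rate)^t` with year 1 the first discounted year. With
#' `rate = 0` this is the plain sum.
#'
#' @param costs numeric vector of annual costs (>= 0).
#' @param years integer vector of the year each cost falls in (1..horizon);
#'   recycled against `costs` if scalar costs are given.
#' @param spec a [DiscountSpec-class].
#' @return the discounted total.
#' @examples
#' discountCost(rep(1, 50), 1:50, discountSpec(rate = 0))   # 50
#' discountCost(100, 10)                                    # 100 / 1.01^10
#' @export
discountCost <- function(costs, years, spec = discountSpec()) {
  stopifnot(is(spec, "DiscountSpec"))
  years <- as.integer(years)
  if (length(costs) == 1L) costs <- rep(costs, length(years))
  if (length(costs) != length(years))
    stop("costs and years must have equal length")
  if (any(!is.finite(costs) | costs < 0))
    stop("annual costs must be non-negative")
  if (any(years < 1L | years > spec@horizon))
    stop("years must lie within 1..", spec@horizon)
  sum(costs / (1 + spec@rate)^years)
}

## discount factor sum over a schedule (annuity factor for that schedule)
.annuityFactor <- function(years, spec = discountSpec()) {
  sum(1 / (1 + spec@rate)^as.integer(years))
}

#' Total discounted cost of each project
#'
#' Sums the discounted cost of every action of every project over the
#' 50-year horizon. By default shared actions are charged at their
#' apportioned amounts (see [sharedCostTable()]); pass
#' `apportion = FALSE` for standalone costs. Projects carrying a
#' pre-aggregated `cost_total_npv` use that stored value unless
#' `useStored = FALSE`.
#'
#' @param portfolio a [ProjectPortfolio-class].
#' @param spec a [DiscountSpec-class].
#' @param apportion apply cost-sharing apportionment (default `TRUE`).
#' @param useStored honour a pre-aggregated `cost_total_npv` column
#'   (default `TRUE`).
#' @return named numeric vector of per-project costs, in species-table
#'   order; an error if any project's cost is zero (its priority score would
#'   be undefined).
#' @export
projectCosts <- function(portfolio, spec = discountSpec(), apportion = TRUE,
                         useStored = TRUE) {
  stopifnot(is(portfolio, "ProjectPortfolio"))
  tab <- sharedCostTable(actionsTable(portfolio), spec,
                         apportion = apportion)
  byProject <- vapply(split(tab$cost_npv, tab$project_id), sum, 0)
  ids <- projectIds(portfolio)
  C <- stats::setNames(unname(byProject[ids]), ids)
  C[is.na(C)] <- 0
  if (useStored) {
    stored <- speciesTable(portfolio)$cost_total_npv
    use <- !is.na(stored)
    C[use] <- stored[use]
  }
  if (any(C <= 0))
    stop("zero-cost project(s): priority score undefined for ",
         paste(names(C)[C <= 0], collapse = ", "))
  C
}

#' Cost-efficiency priority score
#'
#' `P = B * L / C`: expected marginal viability gain per unit of cost. The
#' score is linear in benefit and likelihood and inversely proportional to
#' cost, so it is covariant under cost rescaling (reporting in dollars or
#' millions changes only the scale, never the ranking).
#'
#' @param benefit benefit `B` in \[0,1\].
#' @param likelihood likelihood of success `L` in \[0,1\].
#' @param cost total discounted cost `C` (> 0).
#' @return numeric score(s); vectorised.
#' @examples
#' priorityScore(0.9, 0.5, 1e6)   # 4.5e-7 per dollar
#' @export
priorityScore <- function(benefit, likelihood, cost) {
  if (any(!is.finite(benefit) | benefit < 0 | benefit > 1))
    stop("benefit must lie in [0,1]")
  if (any(!is.finite(likelihood) | likelihood < 0 | likelihood > 1))
    stop("likelihood must lie in [0,1]")
  if (any(!is.finite(cost) | cost <= 0))
    stop("cost must be positive")
  benefit * likelihood / cost
}
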