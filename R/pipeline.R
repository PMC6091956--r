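#' Score and rank a portfolio
#'
#' Computes, for every project, the benefit `B = p_w - p_n`, the likelihood
#' of success `L` (product of per-action I x T x S), the 50-year discounted
#' cost `C` with cost-sharing apportioned, and the cost-efficiency priority
#' score `P = B L / C`, then ranks descending by score (rank 1 = best;
#' ties broken by lower cost, then project id).
#'
#' @param portfolio a [ProjectPortfolio-class].
#' @param spec a [DiscountSpec-class].
#' @param apportion apply cost-sharing (default `TRUE`).
#' @param useStored honour pre-aggregated `cost_total_npv` values
#'   (default `TRUE`).
#' @return data.frame with columns `project_id`, `benefit`, `likelihood`,
#'   `cost`, `score`, `rank`, sorted by rank.
#' @examples
#' prioritize(workedFixture())
#' @export
prioritize <- function(portfolio, spec = discountSpec(), apportion = TRUE,
                       useStored = TRUE) {
  stopifnot(is(portfolio, "ProjectPortfolio"))
  sp <- speciesTable(portfolio)
  rec <- data.frame(
    project_id = sp$project_id,
    benefit = computeBenefit(sp$p_w, sp$p_n),
    likelihood = .projectLikelihoods(portfolio),
    cost = unname(projectCosts(portfolio, spec, apportion = apportion,
                               useStored = useStored)),
    stringsAsFactors = FALSE)
  rec$score <- priorityScore(rec$benefit, rec$likelihood, rec$cost)
  rankProjects(rec)
}
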