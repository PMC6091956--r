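#' Rank projects by priority score
#'
#' Descending score, rank 1 = best. Ties are broken by lower cost, then by
#' project_id lexicographically, so rankings are deterministic and form a
#' permutation of 1..N.
#'
#' @param records data.frame with columns `project_id`, `score`, `cost`.
#' @return the same data.frame with a `rank` column, sorted by rank.
#' @export
rankProjects <- function(records) {
  stopifnot(all(c("project_id", "score", "cost") %in% names(records)))
  ord <- order(-records$score, records$cost, records$project_id)
  records$rank <- NA_integer_
  records$rank[ord] <- seq_len(nrow(records))
  records[ord, , drop = FALSE]
}

#' Subset a portfolio to a set of projects
#'
#' @param portfolio a [ProjectPortfolio-class].
#' @param ids project identifiers to keep.
#' @return a smaller [ProjectPortfolio-class].
#' @export
subsetProjects <- function(portfolio, ids) {
  sp <- speciesTable(portfolio)
  ac <- actionsTable(portfolio)
  ProjectPortfolio(sp[sp$project_id %in% ids, , drop = FALSE],
                   ac[ac$project_id %in% ids, , drop = FALSE])
}

#' Iterative budget-constrained portfolio selection
#'
#' Repeatedly scores and ranks the remaining projects and removes the
#' last-ranked one until the total cost of the remainder falls below the
#' budget. After each removal, any cost-sharing arrangements involving the
#' removed project dissolve, so the partners' costs are recomputed (and can
#' rise, possibly reordering subsequent removals); benefits and likelihoods
#' are unaffected by removals and are computed once.
#'
#' @param portfolio a [ProjectPortfolio-class].
#' @param budget total available budget, on the same scale as project costs
#'   (50-year net present value by default; divide by 50 for an annual
#'   figure before calling if budgeting annually).
#' @param spec a [DiscountSpec-class].
#' @param freezeRanks if `TRUE`, removals follow the initial ranking instead
#'   of re-ranking after each dissolution (default `FALSE`, the literal
#'   iterative rule).
#' @return a list with `kept` (final scored and ranked data.frame),
#'   `removed` (project ids in removal order) and `log` (one row per
#'   iteration: the project removed, the total cost before removal and the
#'   number of projects then remaining).
#' @export
selectUnderBudget <- function(portfolio, budget, spec = discountSpec(),
                              freezeRanks = FALSE) {
  stopifnot(is(portfolio, "ProjectPortfolio"), budget > 0)
  sp <- speciesTable(portfolio)
  B <- stats::setNames(computeBenefit(sp$p_w, sp$p_n), sp$project_id)
  L <- stats::setNames(.projectLikelihoods(portfolio), sp$project_id)
  remaining <- portfolio
  removed <- character(0)
  log <- list()
  frozen <- NULL
  repeat {
    ids <- projectIds(remaining)
    if (length(ids) == 0L) {
      warning("budget is smaller than the cheapest remaining project; ",
              "nothing can be funded")
      kept <- data.frame(project_id = character(0), benefit = numeric(0),
                         likelihood = numeric(0), cost = numeric(0),
                         score = numeric(0), rank = integer(0))
      break
    }
    C <- projectCosts(remaining, spec)
    rec <- data.frame(project_id = ids, benefit = unname(B[ids]),
                      likelihood = unname(L[ids]), cost = unname(C[ids]),
                      stringsAsFactors = FALSE)
    rec$score <- priorityScore(rec$benefit, rec$likelihood, rec$cost)
    rec <- rankProjects(rec)
    if (freezeRanks) {
      if (is.null(frozen))
        frozen <- stats::setNames(rec$rank, rec$project_id)
      rec <- rec[order(frozen[rec$project_id]), , drop = FALSE]
      rec$rank <- seq_len(nrow(rec))
    }
    total <- sum(rec$cost)
    if (total < budget) {
      kept <- rec
      break
    }
    worst <- rec$project_id[which.max(rec$rank)]
    log[[length(log) + 1L]] <-
      data.frame(iteration = length(log) + 1L, removed_project = worst,
                 total_cost_before = total,
                 n_remaining = length(ids) - 1L, stringsAsFactors = FALSE)
    removed <- c(removed, worst)
    remaining <- subsetProjects(remaining, setdiff(ids, worst))
  }
  list(kept = kept, removed = removed,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(iteration = integer(0), removed_project = character(0),
                    total_cost_before = numeric(0),
                    n_remaining = integer(0)))
}

#' Cumulative cost curve in priority order
#'
#' Return-on-investment view of the ranked list: point k gives the
#' cumulative mean annual cost (50-year NPV divided by the horizon) of
#' securing the k best-ranked species.
#'
#' @param records ranked data.frame (see [rankProjects()]).
#' @param horizon years over which costs were totalled (default 50).
#' @return data.frame with columns `n_species` and
#'   `cumulative_annual_cost`, monotone non-decreasing.
#' @export
roiCurve <- function(records, horizon = 50) {
  stopifnot(all(c("rank", "cost") %in% names(records)))
  rec <- records[order(records$rank), , drop = FALSE]
  data.frame(n_species = seq_len(nrow(rec)),
             cumulative_annual_cost = cumsum(rec$cost) / horizon)
}
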