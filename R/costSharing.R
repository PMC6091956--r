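#' A group of co-located actions sharing costs
#'
#' Two or more projects proposing the same type of action at the same
#' location in the same year share the cost of that action-year. The group
#' carries its matching key and one member row per project with the cost
#' that project proposed for the year.
#'
#' @slot locationKey the shared location identifier.
#' @slot actionType the shared action type.
#' @slot year the shared year.
#' @slot members data.frame with columns `project_id`, `action_id`,
#'   `proposed_cost`.
#' @export
setClass("SharedActionGroup",
         representation(locationKey = "character", actionType = "character",
                        year = "integer", members = "data.frame"),
         validity = function(object) {
           m <- object@members
           if (!all(c("project_id", "action_id", "proposed_cost") %in%
                    names(m)))
             return("members needs project_id, action_id, proposed_cost")
           if (nrow(m) < 2L || anyDuplicated(m$project_id))
             return("a shared group needs >= 2 members from distinct projects")
           TRUE
         })

setMethod("show", "SharedActionGroup", function(object) {
  cat(sprintf("SharedActionGroup '%s'/%s, year %d: %d projects, max cost %s\n",
              object@locationKey, object@actionType, object@year,
              nrow(object@members),
              format(max(object@members$proposed_cost), big.mark = ",")))
  invisible(NULL)
})

## long (action x year) expansion of an actions table
.actionYears <- function(actions) {
  yrs <- .parseYears(actions$years)
  n <- lengths(yrs)
  data.frame(action_id = rep(actions$action_id, n),
             project_id = rep(actions$project_id, n),
             location_key = rep(actions$location_key, n),
             action_type = rep(actions$action_type, n),
             year = unlist(yrs),
             annual_cost = rep(actions$annual_cost, n),
             stringsAsFactors = FALSE)
}

#' Find groups of co-located, co-scheduled actions across projects
#'
#' Actions share a cost in a given year iff they match exactly on
#' `location_key` and `action_type`, are scheduled in that year, and belong
#' to at least two distinct projects. Multi-year actions are grouped
#' year-by-year, so schedules that only partially overlap share only the
#' overlapping years.
#'
#' @param actions an actions data.frame (see [ProjectPortfolio()]).
#' @return list of [SharedActionGroup-class] objects (empty when nothing is
#'   shared).
#' @export
findSharedGroups <- function(actions) {
  long <- .actionYears(actions)
  key <- paste(long$location_key, long$action_type, long$year, sep = "\r")
  keep <- ave(as.integer(factor(long$project_id)), key,
              FUN = function(i) length(unique(i))) >= 2L
  long <- long[keep, , drop = FALSE]
  if (nrow(long) == 0L) return(list())
  groups <- split(long, paste(long$location_key, long$action_type, long$year,
                              sep = "\r"))
  unname(lapply(groups, function(g) {
    new("SharedActionGroup", locationKey = g$location_key[1],
        actionType = g$action_type[1], year = g$year[1],
        members = data.frame(project_id = g$project_id,
                             action_id = g$action_id,
                             proposed_cost = g$annual_cost,
                             stringsAsFactors = FALSE))
  }))
}

## core apportionment rule on a vector of proposed costs: the highest
## proposal (assumed sufficient for all) is split in proportion to the
## proposals; equal proposals reduce to an equal split of that amount.
.shares <- function(costs) {
  if (any(!is.finite(costs) | costs < 0))
    stop("proposed costs must be non-negative")
  if (any(costs == 0)) {
    if (all(costs == costs[1])) return(rep(0, length(costs)))
    stop("relative apportionment is undefined with a zero proposed cost")
  }
  max(costs) * costs / sum(costs)
}

#' Apportion a shared action-year cost among its member projects
#'
#' The highest proposed cost is taken as the amount sufficient to meet every
#' member project's objective and is apportioned in proportion to each
#' project's own proposal; identical proposals are therefore split equally.
#' Shares always sum to the group maximum, so sharing only ever discounts a
#' project's cost, never surcharges it.
#'
#' @param group a [SharedActionGroup-class].
#' @return named numeric vector of per-project shares.
#' @examples
#' g <- findSharedGroups(actionsTable(workedFixture()))[[1]]
#' apportion(g)
#' @export
apportion <- function(group) {
  stopifnot(is(group, "SharedActionGroup"))
  m <- group@members
  stats::setNames(.shares(m$proposed_cost), m$project_id)
}

#' Remove a project from a shared group and re-apportion
#'
#' When a project drops out of the portfolio it no longer shares costs: the
#' remaining members re-apportion by the same rule, and a lone remaining
#' member bears its own full proposed cost. No remaining member's share can
#' decrease.
#'
#' @param group a [SharedActionGroup-class].
#' @param removedProject project_id of the member to remove.
#' @return a smaller [SharedActionGroup-class], or (when a single member
#'   remains) a named numeric vector giving that member's full proposed
#'   cost.
#' @export
dissolveMember <- function(group, removedProject) {
  stopifnot(is(group, "SharedActionGroup"))
  m <- group@members
  if (!removedProject %in% m$project_id)
    stop("project ", removedProject, " is not a member of this group")
  m <- m[m$project_id != removedProject, , drop = FALSE]
  if (nrow(m) == 1L)
    return(stats::setNames(m$proposed_cost, m$project_id))
  initialize(group, members = m)
}

#' Per-action discounted costs with cost-sharing applied
#'
#' Expands every action over its scheduled years, apportions each shared
#' action-year by [apportion()]'s rule, discounts, and aggregates back to
#' one row per action.
#'
#' @param actions an actions data.frame.
#' @param spec a [DiscountSpec-class].
#' @param apportion apply sharing (default `TRUE`); when `FALSE` each action
#'   is charged its full proposed cost.
#' @return data.frame with columns `action_id`, `project_id`, `cost_npv`,
#'   `shared`.
#' @export
sharedCostTable <- function(actions, spec = discountSpec(),
                            apportion = TRUE) {
  long <- .actionYears(actions)
  if (nrow(long) == 0L)
    return(data.frame(action_id = character(0), project_id = character(0),
                      cost_npv = numeric(0), shared = logical(0)))
  long$charged <- long$annual_cost
  long$shared <- FALSE
  if (apportion) {
    key <- paste(long$location_key, long$action_type, long$year, sep = "\r")
    nproj <- ave(as.integer(factor(long$project_id)), key,
                 FUN = function(i) length(unique(i)))
    long$shared <- nproj >= 2L
    if (any(long$shared)) {
      idx <- which(long$shared)
      for (g in split(idx, key[idx]))
        long$charged[g] <- .shares(long$annual_cost[g])
    }
  }
  long$disc <- long$charged / (1 + spec@rate)^long$year
  npv <- rowsum(long$disc, long$action_id)
  anyShared <- tapply(long$shared, long$action_id, any)
  data.frame(action_id = actions$action_id,
             project_id = actions$project_id,
             cost_npv = npv[actions$action_id, 1L],
             shared = unname(anyShared[actions$action_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}
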