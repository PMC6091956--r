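#' @describeIn ProjectPortfolio the species (project) table.
#' @param x a `ProjectPortfolio`.
#' @export
speciesTable <- function(x) {
  stopifnot(is(x, "ProjectPortfolio"))
  x@species
}

#' @describeIn ProjectPortfolio the management-action table.
#' @export
actionsTable <- function(x) {
  stopifnot(is(x, "ProjectPortfolio"))
  x@actions
}

#' @describeIn ProjectPortfolio number of projects.
#' @export
nProjects <- function(x) nrow(speciesTable(x))

#' @describeIn ProjectPortfolio project identifiers, in table order.
#' @export
projectIds <- function(x) speciesTable(x)$project_id

setMethod("show", "ProjectPortfolio", function(object) {
  sp <- object@species
  ac <- object@actions
  cat("ProjectPortfolio with", nrow(sp), "species projects and",
      nrow(ac), "management actions\n")
  tg <- table(sp$taxon_group)
  cat("  taxa:", paste(sprintf("%s %d", names(tg), tg), collapse = ", "), "\n")
  cat(sprintf("  p_w < 0.95 in %d project(s); %d action(s) per project (median %g)\n",
              sum(sp$p_w < 0.95),
              max(table(ac$project_id)),
              stats::median(as.integer(table(ac$project_id)))))
  invisible(NULL)
})

#' @describeIn RankSimulation the per-project rank interval table.
#' @param x a `RankSimulation`.
#' @export
rankIntervals <- function(x) {
  stopifnot(is(x, "RankSimulation"))
  x@intervals
}

#' @describeIn RankSimulation named integer vector of band assignments (1-5).
#' @export
bandAssignments <- function(x) {
  iv <- rankIntervals(x)
  stats::setNames(iv$band, iv$project_id)
}

#' @describeIn RankSimulation matrix of simulated ranks
#'   (projects x replicates).
#' @export
simulatedRanks <- function(x) {
  stopifnot(is(x, "RankSimulation"))
  x@simulatedRanks
}

setMethod("show", "RankSimulation", function(object) {
  iv <- object@intervals
  cat("RankSimulation:", nrow(iv), "projects,",
      object@config@nSims, "replicates (seed", object@config@seed, ")\n")
  cat(sprintf("  mean 95%% rank-interval length: %.1f (range %d-%d)\n",
              mean(iv$interval_length), min(iv$interval_length),
              max(iv$interval_length)))
  bc <- table(factor(iv$band, levels = 1:5))
  cat("  band counts:", paste(sprintf("B%d=%d", 1:5, bc), collapse = " "), "\n")
  invisible(NULL)
})

setMethod("show", "GeneratorSpec", function(object) {
  cat("GeneratorSpec:", object@nProjects, "projects (seed",
      object@seed, ")\n")
  cat(sprintf("  cost ~ lognormal(meanlog=%.3f, sdlog=%.2f) clipped to [%s, %s]\n",
              object@costLogMean, object@costLogSd,
              format(object@costClip[1], big.mark = ","),
              format(object@costClip[2], big.mark = ",")))
  invisible(NULL)
})
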