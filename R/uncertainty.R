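#' Uncertainty interval for an elicited estimate
#'
#' Benefit and likelihood estimates get symmetric intervals of half-width
#' 0.05/0.10/0.20 according to their confidence grade, clipped to \[0,1\].
#' Cost estimates get a constant relative interval of +/-30%, replaced by
#' +100%/-30% for projects whose sites lack recent (< 5 years) on-ground
#' confirmation, reflecting the greater likelihood of unforeseen costs.
#'
#' @param estimate numeric vector of point estimates.
#' @param grade confidence grades (required for `type = "probability"`).
#' @param type `"probability"` or `"cost"`.
#' @param stale logical vector: no recent site confirmation (cost only).
#' @param config a [SimulationConfig-class] (supplies the relative cost
#'   bounds).
#' @return two-column matrix of lower and upper bounds.
#' @examples
#' intervalFor(0.5, "confident")               # 0.4 .. 0.6
#' intervalFor(100, type = "cost", stale = TRUE)  # 70 .. 200
#' @export
intervalFor <- function(estimate, grade = NULL,
                        type = c("probability", "cost"), stale = FALSE,
                        config = simulationConfig()) {
  type <- match.arg(type)
  if (type == "probability") {
    if (is.null(grade))
      stop("probability intervals need a confidence grade")
    hw <- confidenceHalfWidth(grade)
    lo <- pmax(estimate - hw, 0)
    hi <- pmin(estimate + hw, 1)
  } else {
    if (any(estimate < 0)) stop("cost estimates must be non-negative")
    stale <- rep_len(stale, length(estimate))
    lo <- estimate * ifelse(stale, 1 + config@costStale[1],
                            1 - config@costHalfWidth)
    hi <- estimate * ifelse(stale, 1 + config@costStale[2],
                            1 + config@costHalfWidth)
  }
  cbind(lower = lo, upper = hi)
}

#' Draw from a triangular distribution
#'
#' Inverse-CDF sampling from the triangular distribution on
#' \[`lo`, `hi`\] with peak density at `mode`; the natural choice for
#' propagating expert intervals, which carry a best estimate and hard
#' bounds but no distributional theory. A degenerate interval
#' (`lo == hi`) returns `mode` exactly.
#'
#' @param n number of draws.
#' @param lo,mode,hi distribution parameters, recycled to length `n`
#'   (`lo <= mode <= hi`).
#' @return numeric vector of `n` draws.
#' @examples
#' set.seed(1); mean(rtriangular(1e4, 0, 0.5, 1))   # ~ (0 + 0.5 + 1)/3
#' @export
rtriangular <- function(n, lo, mode, hi) {
  lo <- rep_len(lo, n); mode <- rep_len(mode, n); hi <- rep_len(hi, n)
  if (any(lo > mode | mode > hi))
    stop("triangular bounds must satisfy lo <= mode <= hi")
  u <- stats::runif(n)
  rng <- hi - lo
  out <- mode
  pos <- rng > 0
  fc <- ifelse(pos, (mode - lo) / rng, 0.5)
  left <- pos & u < fc
  right <- pos & !left
  out[left] <- lo[left] + sqrt(u[left] * rng[left] * (mode - lo)[left])
  out[right] <- hi[right] - sqrt((1 - u[right]) * rng[right] *
                                   (hi - mode)[right])
  out
}

## per-project point estimates and interval bounds for B, L, C; widthScale
## shrinks every interval toward its point estimate (0 = degenerate)
.uncertaintyInputs <- function(portfolio, config, spec,
                               records = NULL, widthScale = 1) {
  if (is.null(records))
    records <- prioritize(portfolio, spec)
  sp <- speciesTable(portfolio)
  ac <- actionsTable(portfolio)
  records <- records[match(sp$project_id, records$project_id), , drop = FALSE]
  bhw <- widthScale * confidenceHalfWidth(sp$benefit_confidence)
  bInt <- cbind(lower = pmax(records$benefit - bhw, 0),
                upper = pmin(records$benefit + bhw, 1))
  lhw <- tapply(confidenceHalfWidth(ac$confidence), ac$project_id, max)
  lhw <- widthScale * unname(lhw[sp$project_id])
  lInt <- cbind(lower = pmax(records$likelihood - lhw, 0),
                upper = pmin(records$likelihood + lhw, 1))
  stale <- !sp$recent_site_confirmation
  cLo <- ifelse(stale, config@costStale[1], -config@costHalfWidth)
  cHi <- ifelse(stale, config@costStale[2], config@costHalfWidth)
  cInt <- cbind(lower = records$cost * (1 + widthScale * cLo),
                upper = records$cost * (1 + widthScale * cHi))
  list(records = records, bInt = bInt, lInt = lInt, cInt = cInt)
}

## draw one (nProjects x nSims) matrix per parameter
.drawParameters <- function(inp, nSims, lFloor) {
  n <- nrow(inp$records)
  draw <- function(int, mode) {
    matrix(rtriangular(n * nSims, rep(int[, 1], nSims), rep(mode, nSims),
                       rep(int[, 2], nSims)), nrow = n)
  }
  B <- draw(inp$bInt, inp$records$benefit)
  L <- draw(inp$lInt, inp$records$likelihood)
  L[L < lFloor] <- lFloor
  C <- draw(inp$cInt, inp$records$cost)
  list(B = B, L = L, C = C)
}

#' Monte Carlo propagation of elicitation uncertainty into rank intervals
#'
#' For each replicate, benefit, likelihood and cost are drawn for every
#' project from triangular distributions centred on the point estimates and
#' bounded by their confidence-derived intervals (sampled likelihoods are
#' truncated below at `config@lFloor`); scores are recomputed and all
#' projects re-ranked. The 2.5 and 97.5 percentiles (nearest-rank method,
#' appropriate for integer ranks) of each project's simulated-rank
#' distribution give its 95% rank likelihood interval, and intervals are
#' resolved into five priority bands with [assignBands()]. Fixed seed gives
#' bit-identical results.
#'
#' @param portfolio a [ProjectPortfolio-class].
#' @param config a [SimulationConfig-class].
#' @param spec a [DiscountSpec-class].
#' @param records optional pre-computed output of [prioritize()] (saves
#'   recomputing costs).
#' @param widthScale multiplier on every interval width (default 1); 0
#'   collapses all intervals to the point estimates, reproducing the
#'   deterministic ranking.
#' @return a [RankSimulation-class].
#' @export
monteCarloRanks <- function(portfolio, config = simulationConfig(),
                            spec = discountSpec(), records = NULL,
                            widthScale = 1) {
  stopifnot(is(portfolio, "ProjectPortfolio"), is(config, "SimulationConfig"))
  inp <- .uncertaintyInputs(portfolio, config, spec, records, widthScale)
  set.seed(config@seed)
  par <- .drawParameters(inp, config@nSims, config@lFloor)
  P <- par$B * par$L / par$C
  ranks <- apply(P, 2L, function(p) rank(-p, ties.method = "first"))
  qs <- apply(ranks, 1L, stats::quantile, probs = c(0.025, 0.975),
              type = 1L, names = FALSE)
  iv <- data.frame(project_id = inp$records$project_id,
                   rank = inp$records$rank,
                   rank_lo = as.integer(qs[1L, ]),
                   rank_hi = as.integer(qs[2L, ]),
                   stringsAsFactors = FALSE)
  iv$interval_length <- iv$rank_hi - iv$rank_lo
  iv$band <- assignBands(iv, n = nrow(iv),
                         thresholds = config@bandThresholds,
                         rule = config@bandRule)
  rownames(ranks) <- iv$project_id
  new("RankSimulation", intervals = iv, simulatedRanks = ranks,
      config = config)
}

#' Resolve rank likelihood intervals into five priority bands
#'
#' Rank cutoffs `k30 = round(0.30 N)` and `k70 = round(0.70 N)` (rank 1 =
#' best) split the list into a top 30%, middle 40% and bottom 30%. Under
#' the default `"disjoint"` rule: Band 1 holds projects whose whole
#' interval lies in the top 30% (worst-case rank <= k30); Band 3, those
#' entirely within the middle 40%; Band 5, those entirely in the bottom
#' 30% (best-case rank > k70); Bands 2 and 4 hold intervals straddling the
#' k30 or k70 cutoff respectively; an interval wide enough to span both
#' cutoffs goes to the lowest-priority band it reaches (Band 5). The
#' `"printed"` rule applies the source rules literally by the interval's
#' lower limit (Band 1: best-case rank in the top 30%; Band 5: best-case
#' rank in the bottom 30%), which leaves Band 2 empty and is provided only
#' for comparison.
#'
#' @param intervals data.frame with columns `rank_lo`, `rank_hi`.
#' @param n total number of projects.
#' @param thresholds the two rank-fraction cutoffs (default 0.30, 0.70).
#' @param rule `"disjoint"` (default) or `"printed"`.
#' @return integer vector of bands (1 = highest priority); every project
#'   receives exactly one band.
#' @export
assignBands <- function(intervals, n = nrow(intervals),
                        thresholds = c(0.30, 0.70),
                        rule = c("disjoint", "printed")) {
  rule <- match.arg(rule)
  lo <- intervals$rank_lo
  hi <- intervals$rank_hi
  stopifnot(all(lo <= hi), all(lo >= 1L), all(hi <= n))
  k30 <- round(thresholds[1] * n)
  k70 <- round(thresholds[2] * n)
  if (rule == "printed") {
    band <- ifelse(lo <= k30, 1L,
                   ifelse(lo > k70, 5L,
                          ifelse(hi <= k70, 3L, 4L)))
    return(as.integer(band))
  }
  region <- function(r) ifelse(r <= k30, 1L, ifelse(r <= k70, 3L, 5L))
  rlo <- region(lo)
  rhi <- region(hi)
  band <- integer(length(lo))
  band[rlo == rhi] <- rlo[rlo == rhi]
  band[rlo == 1L & rhi == 3L] <- 2L
  band[rlo == 3L & rhi == 5L] <- 4L
  band[rlo == 1L & rhi == 5L] <- 5L   # spans both cutoffs: lowest priority
  band
}

#' Sensitivity of the priority score to each input parameter
#'
#' Monte Carlo estimate of the expected change in `P` attributable to a
#' +0.1 change in benefit, a +0.1 change in likelihood, and a +$1,000,000
#' change in cost, per project, with the other parameters at their sampled
#' values. Because `P` is linear in `B` and `L`, their sensitivities equal
#' `0.1 L / C` and `0.1 B / C` up to the (small) Jensen effect of cost
#' sampling; analytic values at the point estimates are returned alongside.
#'
#' The `scoreScale` argument sets the units of the reported changes:
#' `"published"` (default) quotes benefit and likelihood sensitivities with
#' the score per million dollars but cost sensitivity with the score per
#' dollar, matching the convention evident in the published magnitudes;
#' `"per_million"` and `"per_dollar"` put all three on one scale (see the
#' vignette for why the published orders-of-magnitude gap is partly a scale
#' artifact).
#'
#' @param portfolio a [ProjectPortfolio-class].
#' @param config a [SimulationConfig-class] (replicates, seed, intervals).
#' @param spec a [DiscountSpec-class].
#' @param deltaB,deltaL,deltaC perturbation sizes (defaults 0.1, 0.1, 1e6).
#' @param scoreScale reporting scale, see Details.
#' @param records optional pre-computed [prioritize()] output.
#' @param widthScale multiplier on every interval width (default 1).
#' @return data.frame with per-project Monte Carlo sensitivities
#'   (`sens_benefit`, `sens_likelihood`, `sens_cost`) and their analytic
#'   point-estimate counterparts; the scale is recorded in
#'   `attr(, "scoreScale")`.
#' @export
sensitivityAnalysis <- function(portfolio, config = simulationConfig(),
                                spec = discountSpec(), deltaB = 0.1,
                                deltaL = 0.1, deltaC = 1e6,
                                scoreScale = c("published", "per_million",
                                               "per_dollar"),
                                records = NULL, widthScale = 1) {
  scoreScale <- match.arg(scoreScale)
  inp <- .uncertaintyInputs(portfolio, config, spec, records, widthScale)
  set.seed(config@seed)
  par <- .drawParameters(inp, config@nSims, config@lFloor)
  ## per-draw exact differences, score per dollar
  dB <- deltaB * par$L / par$C
  dL <- deltaL * par$B / par$C
  dC <- par$B * par$L * (1 / (par$C + deltaC) - 1 / par$C)
  sBL <- switch(scoreScale, published = 1e6, per_million = 1e6,
                per_dollar = 1)
  sC <- switch(scoreScale, published = 1, per_million = 1e6, per_dollar = 1)
  rec <- inp$records
  out <- data.frame(project_id = rec$project_id,
                    sens_benefit = rowMeans(dB) * sBL,
                    sens_likelihood = rowMeans(dL) * sBL,
                    sens_cost = rowMeans(dC) * sC,
                    analytic_benefit = deltaB * rec$likelihood / rec$cost * sBL,
                    analytic_likelihood = deltaL * rec$benefit / rec$cost * sBL,
                    analytic_cost = rec$benefit * rec$likelihood *
                      (1 / (rec$cost + deltaC) - 1 / rec$cost) * sC,
                    stringsAsFactors = FALSE)
  attr(out, "scoreScale") <- scoreScale
  out
}

#' Portfolio-level summary statistics
#'
#' Mean/SD/range of benefit, likelihood and cost; Pearson correlations of
#' the (log-transformed) score with log cost, benefit and likelihood, plus
#' the slope of `log P` on `log C`; and, when a [RankSimulation-class] is
#' supplied, band counts and rank-interval statistics overall and split
#' into the extreme (1, 5) versus middle (2-4) bands.
#'
#' @param records output of [prioritize()].
#' @param sim optional [RankSimulation-class].
#' @return a named list.
#' @export
summaryStatistics <- function(records, sim = NULL) {
  stopifnot(all(c("benefit", "likelihood", "cost", "score") %in%
                  names(records)))
  rng <- function(x) c(mean = mean(x), sd = stats::sd(x), min = min(x),
                       max = max(x))
  logP <- log(records$score)
  logC <- log(records$cost)
  degenerate <- stats::sd(logC) == 0 || stats::sd(logP) == 0
  if (degenerate)
    warning("correlations undefined: no variation in cost or score")
  corSafe <- function(x, y)
    if (degenerate || stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  out <- list(
    benefit = rng(records$benefit),
    likelihood = rng(records$likelihood),
    cost = rng(records$cost),
    total_annual_cost = sum(records$cost) / 50,
    r_logC_logP = corSafe(logC, logP),
    slope_logP_logC = if (degenerate) NA_real_ else
      unname(stats::coef(stats::lm(logP ~ logC))[2L]),
    r_B_logP = corSafe(records$benefit, logP),
    r_L_logP = corSafe(records$likelihood, logP))
  if (!is.null(sim)) {
    iv <- rankIntervals(sim)
    extreme <- iv$band %in% c(1L, 5L)
    out$band_counts <- as.integer(table(factor(iv$band, levels = 1:5)))
    out$interval_length <- rng(iv$interval_length)
    out$interval_length_bands_1_5 <- rng(iv$interval_length[extreme])
    out$interval_length_bands_2_4 <- rng(iv$interval_length[!extreme])
  }
  out
}
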