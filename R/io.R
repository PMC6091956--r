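## Header aliases for the legacy spreadsheet dialects: canonical name ->
## normalised variants accepted on input. Matching is done on lowercased
## names with all non-alphanumerics stripped.
.SPECIES_ALIASES <- list(
  project_id = c("projectid", "project", "id"),
  species_name = c("speciesname", "species", "scientificname"),
  taxon_group = c("taxongroup", "taxon", "taxagroup", "group"),
  p_n = c("pn", "pwithout", "probwithout", "pnomanagement"),
  p_w = c("pw", "pwith", "probwith", "pmanagement"),
  benefit_confidence = c("benefitconfidence", "confidenceb", "bconfidence",
                         "confidence"),
  iucn_category = c("iucncategory", "iucn", "threatcategory", "redlist"),
  recent_site_confirmation = c("recentsiteconfirmation", "recentconfirmation",
                               "siteconfirmed"),
  cost_total_npv = c("costtotalnpv", "totalcost", "cost", "c", "npvcost"))

.ACTION_ALIASES <- list(
  action_id = c("actionid", "action"),
  project_id = c("projectid", "project"),
  site_id = c("siteid", "site"),
  location_key = c("locationkey", "location", "loc"),
  action_type = c("actiontype", "type"),
  years = c("years", "schedule", "yearlist"),
  annual_cost = c("annualcost", "costperyear", "yearlycost"),
  input_success = c("inputsuccess", "i", "feasibility"),
  threat_outcome_success = c("threatoutcomesuccess", "threatsuccess", "t"),
  species_outcome_success = c("speciesoutcomesuccess", "speciessuccess", "s"),
  confidence = c("confidence", "lconfidence", "confidencel"))

.normHeader <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.mapHeaders <- function(found, aliases, override = NULL) {
  out <- found
  norm <- .normHeader(found)
  for (canon in names(aliases)) {
    if (!is.null(override) && canon %in% names(override)) {
      hit <- which(found == override[[canon]])
    } else {
      hit <- which(norm %in% c(.normHeader(canon), aliases[[canon]]))
    }
    if (length(hit) >= 1L)
      out[hit[1L]] <- canon
  }
  out
}

#' Read a two-table project dataset
#'
#' Reads the paired-CSV interchange dialect (one species/project table, one
#' management-action table), maps legacy header variants onto the canonical
#' column names, validates all domain invariants, and reconciles any stored
#' benefit column against the normative `p_w - p_n` (the recomputed value
#' wins; a discrepancy beyond 1e-6 raises a warning).
#'
#' @param speciesPath path to the species CSV.
#' @param actionsPath path to the actions CSV.
#' @param headerOverride optional named list mapping canonical column names
#'   to the exact header used in the file, taking precedence over the
#'   built-in alias table.
#' @return a [ProjectPortfolio-class].
#' @examples
#' pf <- workedFixture()
#' d <- tempfile(); dir.create(d)
#' writeDataset(pf, file.path(d, "species.csv"), file.path(d, "actions.csv"))
#' pf2 <- readDataset(file.path(d, "species.csv"), file.path(d, "actions.csv"))
#' @export
readDataset <- function(speciesPath, actionsPath, headerOverride = NULL) {
  for (p in c(speciesPath, actionsPath))
    if (!file.exists(p)) stop("file not found: ", p)
  sp <- utils::read.csv(speciesPath, stringsAsFactors = FALSE,
                        check.names = FALSE)
  ac <- utils::read.csv(actionsPath, stringsAsFactors = FALSE,
                        check.names = FALSE)
  names(sp) <- .mapHeaders(names(sp), .SPECIES_ALIASES, headerOverride)
  names(ac) <- .mapHeaders(names(ac), .ACTION_ALIASES, headerOverride)
  miss <- setdiff(setdiff(.SPECIES_COLUMNS, "iucn_category"), names(sp))
  if (length(miss))
    stop("species table is missing required column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(.ACTION_COLUMNS, names(ac))
  if (length(miss))
    stop("actions table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(sp$iucn_category)) sp$iucn_category <- NA_character_
  if (nrow(ac) == 0L && nrow(sp) > 0L)
    stop("empty actions table: every project needs at least one action")
  sp$recent_site_confirmation <- as.logical(sp$recent_site_confirmation)
  ## stored benefit, if present, is reconciled against p_w - p_n
  bcol <- which(.normHeader(names(sp)) %in% c("b", "benefit"))
  if (length(bcol)) {
    stored <- as.numeric(sp[[bcol[1L]]])
    recomputed <- sp$p_w - sp$p_n
    off <- which(is.finite(stored) & abs(stored - recomputed) > 1e-6)
    if (length(off))
      warning(sprintf(
        "stored benefit differs from p_w - p_n for %d record(s); using the recomputed value",
        length(off)))
    sp[[bcol[1L]]] <- NULL
  }
  ProjectPortfolio(sp, ac)
}

#' Write a portfolio to the paired-CSV dialect
#'
#' @param portfolio a [ProjectPortfolio-class].
#' @param speciesPath,actionsPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(portfolio, speciesPath, actionsPath) {
  stopifnot(is(portfolio, "ProjectPortfolio"))
  utils::write.csv(speciesTable(portfolio), speciesPath, row.names = FALSE)
  utils::write.csv(actionsTable(portfolio), actionsPath, row.names = FALSE)
  invisible(c(speciesPath, actionsPath))
}

#' Write a priority table to CSV
#'
#' Writes one row per project with benefit, likelihood, cost, score, rank
#' and (when uncertainty has been run) the rank likelihood interval and
#' band, in a fixed column order so output files are diffable.
#'
#' @param records data.frame as produced by [prioritize()], optionally
#'   augmented with `rank_lo`, `rank_hi`, `band`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeResults <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a nonempty data.frame")
  cols <- c("project_id", "benefit", "likelihood", "cost", "score", "rank",
            "rank_lo", "rank_hi", "band")
  for (cc in setdiff(cols, names(records)))
    records[[cc]] <- NA
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a priority table written by [writeResults()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readResults <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
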