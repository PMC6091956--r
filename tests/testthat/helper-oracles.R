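# Deliberately naive, loop-based re-implementations of the scoring and
# selection rules, used as independent oracles against the package's
# vectorised code paths.

oracleDiscount <- function(costs, years, r = 0.01) {
  tot <- 0
  for (i in seq_along(years)) tot <- tot + costs[i] / (1 + r)^years[i]
  tot
}

# per-project cost with year-by-year sharing among the actions given,
# computed by brute-force matching
oracleCosts <- function(actions, r = 0.01) {
  ids <- unique(actions$project_id)
  cost <- setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(actions))) {
    yrs <- as.integer(strsplit(actions$years[i], ";")[[1]])
    for (y in yrs) {
      mates <- integer(0)
      for (j in seq_len(nrow(actions))) {
        jy <- as.integer(strsplit(actions$years[j], ";")[[1]])
        if (actions$location_key[j] == actions$location_key[i] &&
            actions$action_type[j] == actions$action_type[i] && y %in% jy)
          mates <- c(mates, j)
      }
      if (length(unique(actions$project_id[mates])) >= 2) {
        cs <- actions$annual_cost[mates]
        charge <- max(cs) * actions$annual_cost[i] / sum(cs)
      } else {
        charge <- actions$annual_cost[i]
      }
      cost[actions$project_id[i]] <- cost[actions$project_id[i]] +
        charge / (1 + r)^y
    }
  }
  cost
}

oracleScores <- function(species, actions, r = 0.01) {
  C <- oracleCosts(actions, r)
  out <- data.frame(project_id = species$project_id, stringsAsFactors = FALSE)
  out$benefit <- species$p_w - species$p_n
  out$likelihood <- vapply(species$project_id, function(id) {
    a <- actions[actions$project_id == id, , drop = FALSE]
    prod(a$input_success * a$threat_outcome_success *
           a$species_outcome_success)
  }, 0)
  out$cost <- unname(C[out$project_id])
  out$score <- out$benefit * out$likelihood / out$cost
  out$rank <- NA_integer_
  out$rank[order(-out$score, out$cost, out$project_id)] <-
    seq_len(nrow(out))
  out
}

# iterative budget-constrained selection, recomputing sharing as projects
# drop out
oracleSelect <- function(species, actions, budget, r = 0.01) {
  removed <- character(0)
  repeat {
    if (nrow(species) == 0L) return(list(kept = species$project_id,
                                         removed = removed))
    sc <- oracleScores(species, actions, r)
    if (sum(sc$cost) < budget)
      return(list(kept = sc$project_id[order(sc$rank)], removed = removed))
    worst <- sc$project_id[which.max(sc$rank)]
    removed <- c(removed, worst)
    species <- species[species$project_id != worst, , drop = FALSE]
    actions <- actions[actions$project_id != worst, , drop = FALSE]
  }
}

# small random fixture with occasional shared locations, for property tests
randomFixture <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R%02d", seq_len(n))
  species <- data.frame(
    project_id = ids, species_name = ids, taxon_group = "plant",
    p_n = runif(n, 0.05, 0.6), p_w = 0.95,
    benefit_confidence = "confident", iucn_category = "endangered",
    recent_site_confirmation = TRUE, cost_total_npv = NA_real_,
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    k <- sample(1:3, 1)
    for (j in seq_len(k)) {
      start <- sample(1:46, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        action_id = sprintf("%s_A%d", ids[i], j), project_id = ids[i],
        site_id = "s", location_key = sample(c("shared_site",
                                               sprintf("own_%s_%d", ids[i], j)),
                                             1, prob = c(0.4, 0.6)),
        action_type = "weed_control",
        years = paste(start:(start + sample(0:4, 1)), collapse = ";"),
        annual_cost = round(runif(1, 100, 5000)),
        input_success = runif(1, 0.5, 1),
        threat_outcome_success = runif(1, 0.5, 1),
        species_outcome_success = runif(1, 0.5, 1),
        confidence = "confident", stringsAsFactors = FALSE)
    }
  }
  list(species = species, actions = do.call(rbind, rows))
}
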