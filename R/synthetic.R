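#' Generator configuration for synthetic encounter data
#'
#' Describes an emergency-department-like event stream: providers grouped
#' into pools (recurring teams, so some pairs share many encounters), team
#' sizes drawn per encounter, a triage-acuity covariate, a logistic outcome
#' model, and optional enriched provider pairs whose shared encounters have
#' an elevated positive-outcome probability.
#'
#' Defaults describe the desk-scale study system: 150 providers, 3000
#' encounters and 8 pools (large enough for well over a hundred edges at a
#' shared-encounter threshold of 6, small enough that a 1000-permutation
#' run takes seconds); team sizes `1 + NegBin` matched to a mean of 9.2
#' providers per encounter with SD about 4.3; acuity levels 1-5 with
#' probabilities (0.01, 0.20, 0.45, 0.27, 0.07) so level 3 ("urgent") is
#' modal and level 1 ("resuscitation") is about 1% of encounters; and an
#' outcome model whose marginal positive rate is about 0.60.
#'
#' @param n_providers Number of providers.
#' @param n_encounters Number of encounters.
#' @param n_pools Number of provider pools.
#' @param team_size List `mean`, `dispersion`, `min`: team size is
#'   `min + NegBin(mu = mean - min, size = dispersion)`; `dispersion <= 0`
#'   gives the constant size `round(mean)`.
#' @param mixing_rate Probability that a team slot is filled from outside
#'   the encounter's home pool.
#' @param acuity_probs Named probabilities of acuity levels 1-5 (must sum
#'   to 1).
#' @param outcome_intercept Intercept of the outcome model on the log-odds
#'   scale.
#' @param acuity_log_odds Named per-acuity log-odds offsets.
#' @param n_enriched_pairs Number of within-pool provider pairs whose
#'   shared encounters get an elevated positive-outcome probability.
#' @param enrichment_delta Probability added (on the probability scale,
#'   clipped to `[0, 1]`) to encounters involving both members of an
#'   enriched pair.
#' @param enriched_pairs Optional explicit data.frame (`provider_a`,
#'   `provider_b`, `delta`) overriding automatic pair selection.
#' @param actions_per_involvement Mean number of extra action instances per
#'   provider-encounter involvement (`action_count = 1 + Poisson(.)`).
#' @param seed Seed controlling every draw; identical configs are
#'   bit-reproducible.
#' @return A list of class `spor_generator_config`.
#' @export
generator_config <- function(n_providers = 150L,
                             n_encounters = 3000L,
                             n_pools = 8L,
                             team_size = list(mean = 9.2, dispersion = 6.5,
                                              min = 1L),
                             mixing_rate = 0.08,
                             acuity_probs = c(`1` = 0.01, `2` = 0.20,
                                              `3` = 0.45, `4` = 0.27,
                                              `5` = 0.07),
                             outcome_intercept = qlogis(0.6),
                             acuity_log_odds = c(`1` = -0.5, `2` = -0.2,
                                                 `3` = 0, `4` = 0.2,
                                                 `5` = 0.4),
                             n_enriched_pairs = 0L,
                             enrichment_delta = 0.25,
                             enriched_pairs = NULL,
                             actions_per_involvement = 1.5,
                             seed = 1L) {
  if (n_providers < 1L || n_encounters < 1L) {
    stop("n_providers and n_encounters must be at least 1")
  }
  if (any(acuity_probs < 0) || abs(sum(acuity_probs) - 1) > 1e-8) {
    stop("acuity_probs must be non-negative and sum to 1")
  }
  if (mixing_rate < 0 || mixing_rate > 1) stop("mixing_rate must be in [0, 1]")
  if (n_pools < 1L || n_pools > n_providers) {
    stop("n_pools must be between 1 and n_providers")
  }
  structure(
    list(n_providers = as.integer(n_providers),
         n_encounters = as.integer(n_encounters),
         n_pools = as.integer(n_pools),
         team_size = team_size,
         mixing_rate = mixing_rate,
         acuity_probs = acuity_probs,
         outcome_intercept = outcome_intercept,
         acuity_log_odds = acuity_log_odds,
         n_enriched_pairs = as.integer(n_enriched_pairs),
         enrichment_delta = enrichment_delta,
         enriched_pairs = enriched_pairs,
         actions_per_involvement = actions_per_involvement,
         seed = as.integer(seed)),
    class = "spor_generator_config"
  )
}

#' Null configuration: outcomes independent of provider pairing
#'
#' The calibration configuration: no enriched pairs, so the outcome of an
#' encounter depends only on its covariates, never on which providers were
#' on the team. Under this configuration every edge's SPOR fluctuates
#' around 1 and permutation p-values are uniform.
#'
#' @param ... Overrides passed to [generator_config()] (except
#'   `n_enriched_pairs`/`enriched_pairs`, which are forced empty).
#' @return A `spor_generator_config` with zero enriched pairs.
#' @export
null_config <- function(...) {
  cfg <- generator_config(...)
  cfg$n_enriched_pairs <- 0L
  cfg$enriched_pairs <- NULL
  cfg
}

.activity_categories <- c("orders", "notes", "intake-output")
.action_types <- c("order", "complete", "performed", "verified", "modified")
.provider_categories <- c("physician", "resident", "student", "nurse",
                          "pharmacist", "other")

#' Generate a synthetic encounter data set
#'
#' Draws, per encounter: a home pool, a team (pool members with occasional
#' outside mixing), an acuity level, and a binary outcome from the logistic
#' model; enriched pairs' shared encounters get `delta` added to the
#' positive-outcome probability (clipped to `[0, 1]`). Emits the same
#' tables [read_encounters()] and [read_events()] produce, plus a truth
#' record carrying all parameters, pool memberships, true probabilities and
#' enriched-pair identities for recovery testing.
#'
#' @param config A `spor_generator_config`.
#' @return A list: `encounters` (encounter_id, outcome, acuity), `events`
#'   (provider_id, encounter_id, activity_category, action_type),
#'   `providers` (provider_id, category, position, pool), `truth`.
#' @export
generate_collaboration_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "spor_generator_config"))
  set.seed(config$seed)
  nP <- config$n_providers
  nE <- config$n_encounters

  provider_id <- sprintf("P%04d", seq_len(nP))
  pool <- sample(rep_len(seq_len(config$n_pools), nP))
  pool_members <- split(seq_len(nP), pool)
  providers <- data.frame(
    provider_id = provider_id,
    category = sample(.provider_categories, nP, replace = TRUE,
                      prob = c(0.15, 0.15, 0.05, 0.45, 0.05, 0.15)),
    position = sprintf("position-%02d", sample.int(20L, nP, replace = TRUE)),
    pool = pool,
    stringsAsFactors = FALSE
  )

  enriched <- config$enriched_pairs
  if (is.null(enriched) && config$n_enriched_pairs > 0L) {
    pools_ok <- which(vapply(pool_members, length, integer(1)) >= 2L)
    max_pairs <- sum(vapply(pool_members[pools_ok], function(m) {
      choose(length(m), 2L)
    }, numeric(1)))
    if (config$n_enriched_pairs > max_pairs) {
      stop("n_enriched_pairs exceeds the number of within-pool pairs")
    }
    seen <- character(0)
    pa <- pb <- character(config$n_enriched_pairs)
    k <- 0L
    while (k < config$n_enriched_pairs) {
      pl <- pool_members[[pools_ok[sample.int(length(pools_ok), 1L)]]]
      pr <- sort(pl[sample.int(length(pl), 2L)])
      key <- paste(pr, collapse = "|")
      if (!key %in% seen) {
        k <- k + 1L
        seen <- c(seen, key)
        pa[k] <- provider_id[pr[1L]]
        pb[k] <- provider_id[pr[2L]]
      }
    }
    enriched <- data.frame(provider_a = pa, provider_b = pb,
                           delta = config$enrichment_delta,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(enriched) && nrow(enriched) == 0L) enriched <- NULL

  ts <- config$team_size
  if (is.null(ts$min)) ts$min <- 1L
  if (ts$dispersion <= 0) {
    sizes <- rep.int(as.integer(round(ts$mean)), nE)
  } else {
    sizes <- ts$min + rnbinom(nE, size = ts$dispersion,
                              mu = ts$mean - ts$min)
  }
  sizes <- pmin(pmax(sizes, ts$min), nP)

  home <- sample.int(config$n_pools, nE, replace = TRUE)
  acuity <- sample(names(config$acuity_probs), nE, replace = TRUE,
                   prob = config$acuity_probs)
  base_p <- plogis(config$outcome_intercept +
                     unname(config$acuity_log_odds[acuity]))

  # fast lookup of enriched pairs by canonical key
  enr_delta <- if (!is.null(enriched)) {
    setNames(enriched$delta,
             paste(pmin(enriched$provider_a, enriched$provider_b),
                   pmax(enriched$provider_a, enriched$provider_b),
                   sep = "|"))
  } else NULL

  teams <- vector("list", nE)
  p_true <- base_p
  for (e in seq_len(nE)) {
    members <- pool_members[[home[e]]]
    k <- sizes[e]
    n_out <- rbinom(1L, k, config$mixing_rate)
    n_in <- min(k - n_out, length(members))
    team <- members[sample.int(length(members), n_in)]
    n_out <- k - n_in
    if (n_out > 0L) {
      outsiders <- setdiff(seq_len(nP), team)
      take <- min(n_out, length(outsiders))
      team <- c(team, outsiders[sample.int(length(outsiders), take)])
    }
    teams[[e]] <- team
    if (!is.null(enr_delta) && length(team) >= 2L) {
      ids <- sort(provider_id[team])
      keys <- outer(ids, ids, function(a, b) paste(a, b, sep = "|"))
      keys <- keys[upper.tri(keys)]
      hit <- keys[keys %in% names(enr_delta)]
      if (length(hit) > 0L) {
        p_true[e] <- min(1, max(0, p_true[e] + sum(enr_delta[hit])))
      }
    }
  }

  outcome <- rbinom(nE, 1L, p_true)
  encounter_id <- sprintf("E%05d", seq_len(nE))
  encounters <- data.frame(
    encounter_id = encounter_id,
    outcome = as.integer(outcome),
    acuity = as.integer(acuity),
    stringsAsFactors = FALSE
  )

  inv_prov <- unlist(lapply(teams, function(t) provider_id[t]))
  inv_enc <- rep(encounter_id, times = lengths(teams))
  n_actions <- 1L + rpois(length(inv_prov),
                          config$actions_per_involvement - 1)
  events <- data.frame(
    provider_id = rep(inv_prov, times = n_actions),
    encounter_id = rep(inv_enc, times = n_actions),
    stringsAsFactors = FALSE
  )
  events$activity_category <- sample(.activity_categories, nrow(events),
                                     replace = TRUE, prob = c(0.5, 0.35, 0.15))
  events$action_type <- sample(.action_types, nrow(events), replace = TRUE,
                               prob = c(0.35, 0.3, 0.2, 0.1, 0.05))

  list(
    encounters = encounters,
    events = events,
    providers = providers,
    truth = list(
      config = config,
      enriched_pairs = enriched,
      pool = setNames(pool, provider_id),
      p_true = setNames(p_true, encounter_id),
      positive_rate = mean(outcome),
      mean_team_size = mean(lengths(teams))
    )
  )
}

#' Write a generated data set to CSV files
#'
#' Emits the same schemas the readers consume, so a generated set can be
#' run through the file-based pipeline unchanged.
#'
#' @param data Output of [generate_collaboration_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`encounters.csv`, `events.csv`,
#'   `providers.csv`, `truth.json`).
#' @export
write_synthetic_data <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("encounters.csv", "events.csv", "providers.csv",
                            "truth.json"))
  utils::write.csv(data$encounters, paths[1], row.names = FALSE)
  utils::write.csv(data$events, paths[2], row.names = FALSE)
  utils::write.csv(data$providers[, c("provider_id", "category", "position")],
                   paths[3], row.names = FALSE)
  truth <- data$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
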