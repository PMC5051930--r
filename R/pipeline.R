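#' Pipeline run configuration
#'
#' Bundles every setting of the end-to-end analysis. Defaults match the
#' reference analysis: threshold sweep over 2, 4, 6, 8, 10 shared
#' encounters; operating threshold 6; 1000 permutations; inclusive
#' high/low p-value cuts at 0.05 / 0.95; scoring-group membership at a 5%
#' flagged fraction with at least 2 flagged edges.
#'
#' Input is either a generator configuration (`generator`) or a pair of
#' CSV paths (`encounters_path`, `events_path`).
#'
#' @param out_dir Output directory; the resolved configuration is echoed
#'   there alongside every result file.
#' @param generator Optional `spor_generator_config`.
#' @param encounters_path,events_path Optional CSV inputs (used when
#'   `generator` is `NULL`).
#' @param schema,event_schema_map Column mappings for the CSV inputs.
#' @param covariates Covariate specification for [fit_risk_model()].
#' @param thresholds Thresholds for the sweep report.
#' @param analysis_threshold Operating shared-encounter threshold.
#' @param n_permutations Permutation count B.
#' @param high_cut,low_cut Classification cuts.
#' @param min_fraction,min_flagged Scoring-group membership rules.
#' @param seed Master seed for the permutation null (and, when generating,
#'   the generator seed already inside `generator`).
#' @return A list of class `spor_run_config`.
#' @export
run_config <- function(out_dir,
                       generator = NULL,
                       encounters_path = NULL,
                       events_path = NULL,
                       schema = encounter_schema(),
                       event_schema_map = event_schema(),
                       covariates = c(acuity = "categorical"),
                       thresholds = c(2L, 4L, 6L, 8L, 10L),
                       analysis_threshold = 6L,
                       n_permutations = 1000L,
                       high_cut = 0.05,
                       low_cut = 0.95,
                       min_fraction = 0.05,
                       min_flagged = 2L,
                       seed = 1L) {
  if (is.null(generator) &&
      (is.null(encounters_path) || is.null(events_path))) {
    stop("provide either a generator config or both input paths")
  }
  structure(
    list(out_dir = out_dir, generator = generator,
         encounters_path = encounters_path, events_path = events_path,
         schema = schema, event_schema_map = event_schema_map,
         covariates = covariates, thresholds = as.integer(thresholds),
         analysis_threshold = as.integer(analysis_threshold),
         n_permutations = as.integer(n_permutations),
         high_cut = high_cut, low_cut = low_cut,
         min_fraction = min_fraction, min_flagged = as.integer(min_flagged),
         seed = as.integer(seed)),
    class = "spor_run_config"
  )
}

.write_num_csv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(x) {
      if (is.double(x)) .fmt_num(x) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Run the full collaboration analysis pipeline
#'
#' Stages: load or generate the tables, fit the risk model, risk-adjust the
#' outcomes, build the bipartite network, write the threshold-sweep report,
#' project the collaboration network at the operating threshold, run the
#' permutation test, classify edges, and collect the high- and low-scoring
#' provider groups. Every output (CSV/GraphML/JSON) plus a stage log and
#' the resolved configuration lands in `config$out_dir`. Runs are
#' byte-reproducible under a fixed seed.
#'
#' If no provider pair reaches the operating threshold the run stops
#' cleanly after writing an empty edge file and the log notes the empty
#' network.
#'
#' @param config A `spor_run_config`.
#' @return Invisibly, a list with the in-memory objects of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "spor_run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_lines <- character(0)
  log_it <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("ABORTED at stage ", name, ": ",
                                     conditionMessage(e))),
                 file.path(config$out_dir, "log.txt"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  cfg_json <- unclass(config)
  cfg_json$schema <- unclass(cfg_json$schema)
  cfg_json$event_schema_map <- unclass(cfg_json$event_schema_map)
  if (!is.null(cfg_json$generator)) {
    cfg_json$generator <- unclass(cfg_json$generator)
  }
  jsonlite::write_json(cfg_json,
                       file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # -- load or generate ------------------------------------------------
  data <- stage("load", {
    if (!is.null(config$generator)) {
      d <- generate_collaboration_data(config$generator)
      log_it("generated ", nrow(d$encounters), " encounters, ",
             nrow(d$events), " events, ", nrow(d$providers), " providers")
      d
    } else {
      enc <- read_encounters(config$encounters_path, config$schema)
      ev <- read_events(config$events_path, enc$encounters$encounter_id,
                        config$event_schema_map)
      log_it("read ", enc$report$n_kept, " encounters (",
             enc$report$n_dropped_missing_id + enc$report$n_dropped_bad_outcome,
             " dropped, ", enc$report$n_missing_outcome,
             " without outcome); ", ev$report$n_kept, " events (",
             ev$report$n_dropped_unknown_encounter +
               ev$report$n_dropped_missing_provider, " dropped)")
      list(encounters = enc$encounters, events = ev$events, providers = NULL)
    }
  })

  model <- stage("fit-risk", {
    m <- fit_risk_model(data$encounters, config$covariates)
    write_risk_model(m, file.path(config$out_dir, "risk_model.json"))
    log_it("risk model fitted on ", m$n_fit, " encounters (",
           m$n_excluded, " excluded); log-likelihood ",
           format(m$log_likelihood, digits = 8))
    m
  })

  ra <- stage("risk-adjust", {
    out <- risk_adjusted_outcomes(model, data$encounters)
    .write_num_csv(out, file.path(config$out_dir, "risk_adjusted.csv"))
    out
  })
  r <- outcome_map(ra)

  bipartite <- stage("bipartite", {
    b <- build_bipartite(data$events, data$encounters)
    log_it("bipartite network: ", length(b$providers), " providers, ",
           length(b$encounters), " encounters, ", nrow(b$involvement),
           " involvement edges")
    b
  })

  sweep <- stage("threshold-sweep", {
    s <- threshold_sweep(bipartite, r, config$thresholds)
    .write_num_csv(s, file.path(config$out_dir, "threshold_sweep.csv"))
    s
  })

  network <- stage("project", {
    n <- suppressWarnings(
      project_collaboration(bipartite, r, config$analysis_threshold)
    )
    log_it("collaboration network at threshold ", config$analysis_threshold,
           ": ", length(n$providers), " providers, ", nrow(n$edges), " edges")
    n
  })

  if (nrow(network$edges) == 0L) {
    log_it("empty collaboration network; stopping after projection")
    .write_num_csv(network$edges,
                   file.path(config$out_dir, "edge_results.csv"))
    writeLines(log_lines, file.path(config$out_dir, "log.txt"))
    return(invisible(list(data = data, model = model, ra = ra,
                          bipartite = bipartite, sweep = sweep,
                          network = network, high = NULL, low = NULL,
                          summary = NULL)))
  }

  network <- stage("permute", {
    n <- permutation_test(network, B = config$n_permutations,
                          seed = config$seed)
    classify_edges(n, config$high_cut, config$low_cut)
  })
  log_it("permutation test: B = ", config$n_permutations, "; ",
         sum(network$edges$label == "high"), " high-scoring and ",
         sum(network$edges$label == "low"), " low-scoring edges")

  stage("report", {
    ecols <- c("provider_a", "provider_b", "shared_count", "sei", "spoi",
               "spor", "exceed_count", "p_value", "label")
    out <- network$edges[, ecols]
    out$n_permutations <- network$n_permutations
    .write_num_csv(out, file.path(config$out_dir, "edge_results.csv"))
    write_network(network, file.path(config$out_dir, "network.graphml"),
                  format = "graphml", providers = data$providers)
    summ <- summarize_network(network)
    jsonlite::write_json(unclass(summ),
                         file.path(config$out_dir, "network_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    summ
  }) -> summ

  high <- stage("scoring-groups", {
    h <- scoring_groups(network, bipartite, data$encounters, "high",
                        config$min_fraction, config$min_flagged)
    l <- scoring_groups(network, bipartite, data$encounters, "low",
                        config$min_fraction, config$min_flagged)
    .write_num_csv(h$members, file.path(config$out_dir, "scoring_high.csv"))
    .write_num_csv(l$members, file.path(config$out_dir, "scoring_low.csv"))
    log_it("scoring groups: ", h$n_members, " high, ", l$n_members, " low")
    list(high = h, low = l)
  })

  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(list(data = data, model = model, ra = ra, bipartite = bipartite,
                 sweep = sweep, network = network, high = high$high,
                 low = high$low, summary = summ))
}
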