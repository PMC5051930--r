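#' Column mapping for an encounter table
#'
#' Maps the canonical fields of an encounter record onto the column names of
#' a particular CSV export. EHR extracts rarely agree on column names, so the
#' readers take an explicit schema instead of assuming fixed headers.
#'
#' @param encounter_id Column holding the unique encounter identifier.
#' @param outcome Column holding the binary outcome (0/1; blank or "NA" means
#'   the encounter was not surveyed).
#' @param covariates Character vector of baseline covariate columns (e.g.,
#'   triage acuity) used for risk adjustment.
#' @return A list with elements `encounter_id`, `outcome`, `covariates`.
#' @seealso [read_encounters()]
#' @export
encounter_schema <- function(encounter_id = "encounter_id",
                             outcome = "outcome",
                             covariates = "acuity") {
  list(encounter_id = encounter_id, outcome = outcome,
       covariates = covariates)
}

#' Column mapping for a provider-event table
#'
#' @param provider_id,encounter_id,activity_category,action_type Column names
#'   in the event CSV. Each row is one action instance ("provider P performed
#'   activity A during encounter E"), so repeated rows are meaningful.
#' @return A list of the four column names.
#' @seealso [read_events()]
#' @export
event_schema <- function(provider_id = "provider_id",
                         encounter_id = "encounter_id",
                         activity_category = "activity_category",
                         action_type = "action_type") {
  list(provider_id = provider_id, encounter_id = encounter_id,
       activity_category = activity_category, action_type = action_type)
}

.missing_token <- function(x) is.na(x) | x == "" | x == "NA"

#' Read and validate encounter records
#'
#' Reads an encounter CSV, validates identifiers and outcomes, and returns
#' the clean records together with a validation report. Rows with a missing
#' encounter identifier or an unparseable outcome (anything other than 0, 1
#' or a missing-value token) are dropped and counted; encounters with a
#' missing outcome are retained (they keep the bipartite structure
#' inspectable) but are excluded from all downstream SPOR computation.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column mapping from [encounter_schema()].
#' @return A list with
#'   \describe{
#'     \item{encounters}{data.frame with columns `encounter_id` (character),
#'       `outcome` (integer 0/1 or `NA`) and one column per covariate.}
#'     \item{report}{list of counts: rows read/kept, rows dropped for a
#'       missing id or bad outcome, retained rows with missing outcome, and
#'       retained rows with incomplete covariates.}
#'   }
#' @export
read_encounters <- function(path, schema = encounter_schema()) {
  if (!file.exists(path)) stop("encounter file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  needed <- c(schema$encounter_id, schema$outcome, schema$covariates)
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0L) {
    stop("encounter table is missing mapped column(s): ",
         paste(absent, collapse = ", "))
  }
  n_rows <- nrow(raw)
  id <- trimws(raw[[schema$encounter_id]])
  oc <- trimws(raw[[schema$outcome]])

  drop_id <- .missing_token(id)
  oc_missing <- .missing_token(oc)
  oc_valid <- oc %in% c("0", "1")
  drop_outcome <- !drop_id & !oc_missing & !oc_valid
  keep <- !drop_id & !drop_outcome

  id <- id[keep]
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L) {
    stop("duplicate encounter_id: ", paste(dup, collapse = ", "))
  }

  outcome <- rep(NA_integer_, sum(keep))
  outcome[oc_valid[keep]] <- as.integer(oc[keep][oc_valid[keep]])

  enc <- data.frame(encounter_id = id, outcome = outcome,
                    stringsAsFactors = FALSE)
  for (cv in schema$covariates) {
    v <- trimws(raw[[cv]][keep])
    v[.missing_token(v)] <- NA
    enc[[cv]] <- utils::type.convert(v, as.is = TRUE)
  }
  incomplete <- if (length(schema$covariates) > 0L) {
    sum(!stats::complete.cases(enc[, schema$covariates, drop = FALSE]))
  } else 0L

  list(
    encounters = enc,
    report = list(
      n_rows = n_rows,
      n_kept = nrow(enc),
      n_dropped_missing_id = sum(drop_id),
      n_dropped_bad_outcome = sum(drop_outcome),
      n_missing_outcome = sum(is.na(enc$outcome)),
      n_incomplete_covariates = incomplete
    )
  )
}

#' Read and validate provider events
#'
#' Reads the hyperedge records (one row per provider action within an
#' encounter). Rows referencing an encounter that is not in `encounter_ids`,
#' or lacking a provider identifier, are dropped and counted. Repeated
#' (provider, encounter, activity, action) rows are kept: each is one action
#' instance.
#'
#' @param path Path to a CSV file with a header row.
#' @param encounter_ids Character vector of known encounter identifiers
#'   (from [read_encounters()]).
#' @param schema Column mapping from [event_schema()].
#' @return A list with `events` (data.frame: provider_id, encounter_id,
#'   activity_category, action_type) and `report` (drop counts plus tables
#'   of activity categories and action types).
#' @export
read_events <- function(path, encounter_ids, schema = event_schema()) {
  if (!file.exists(path)) stop("event file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  needed <- unlist(schema, use.names = FALSE)
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0L) {
    stop("event table is missing mapped column(s): ",
         paste(absent, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("event table is empty: ", path)

  ev <- data.frame(
    provider_id = trimws(raw[[schema$provider_id]]),
    encounter_id = trimws(raw[[schema$encounter_id]]),
    activity_category = trimws(raw[[schema$activity_category]]),
    action_type = trimws(raw[[schema$action_type]]),
    stringsAsFactors = FALSE
  )
  drop_prov <- .missing_token(ev$provider_id)
  drop_enc <- !drop_prov & !(ev$encounter_id %in% encounter_ids)
  keep <- !drop_prov & !drop_enc
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL

  list(
    events = ev,
    report = list(
      n_rows = length(keep),
      n_kept = nrow(ev),
      n_dropped_missing_provider = sum(drop_prov),
      n_dropped_unknown_encounter = sum(drop_enc),
      activity_counts = table(ev$activity_category),
      action_counts = table(ev$action_type)
    )
  )
}

#' Read provider attribute records
#'
#' Optional node metadata (category such as physician/resident/nurse, and a
#' free-text position) carried onto GraphML exports.
#'
#' @param path CSV with columns `provider_id`, `category`, `position`.
#' @return data.frame of provider records; `provider_id` must be unique.
#' @export
read_providers <- function(path) {
  if (!file.exists(path)) stop("provider file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!"provider_id" %in% names(raw)) stop("missing column: provider_id")
  dup <- unique(raw$provider_id[duplicated(raw$provider_id)])
  if (length(dup) > 0L) {
    stop("duplicate provider_id: ", paste(dup, collapse = ", "))
  }
  raw
}

.edge_columns <- c("provider_a", "provider_b", "shared_count",
                   "sei", "spoi", "spor", "p_value")

# full-precision numeric formatting so a CSV round trip is bit-exact
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a collaboration network to disk
#'
#' The CSV dialect writes one row per edge with full-precision numerics so
#' that a read-back reproduces every value bit-exactly. The GraphML dialect
#' (via igraph) carries the same edge attributes plus optional provider node
#' attributes, at printed precision.
#'
#' @param network A `spor_network` from [project_collaboration()].
#' @param path Output file path.
#' @param format `"csv"` or `"graphml"`.
#' @param providers Optional data.frame of provider attributes
#'   (`provider_id` plus e.g. `category`, `position`) attached to GraphML
#'   nodes.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("csv", "graphml"),
                          providers = NULL) {
  format <- match.arg(format)
  edges <- network$edges
  if (format == "csv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste(.edge_columns, collapse = ","), con)
    if (nrow(edges) > 0L) {
      lines <- paste(
        edges$provider_a, edges$provider_b, edges$shared_count,
        .fmt_num(edges$sei), .fmt_num(edges$spoi), .fmt_num(edges$spor),
        .fmt_num(edges$p_value), sep = ","
      )
      writeLines(lines, con)
    }
  } else {
    g <- as_igraph(network, providers = providers)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge CSV written by [write_network()]
#'
#' @param path Path to the edge CSV.
#' @return data.frame with the seven edge columns, properly typed.
#' @export
read_network_csv <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  absent <- setdiff(.edge_columns, names(df))
  if (length(absent) > 0L) {
    stop("edge CSV is missing column(s): ", paste(absent, collapse = ", "))
  }
  df$shared_count <- as.integer(df$shared_count)
  for (cl in c("sei", "spoi", "spor", "p_value")) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Convert a collaboration network to an igraph object
#'
#' @param network A `spor_network`.
#' @param providers Optional provider attribute data.frame (see
#'   [write_network()]).
#' @return An undirected igraph graph whose edges carry `shared_count`,
#'   `sei`, `spoi`, `spor` and `p_value` (plus `label` when edges have been
#'   classified).
#' @export
as_igraph <- function(network, providers = NULL) {
  stopifnot(inherits(network, "spor_network"))
  verts <- data.frame(name = network$providers, stringsAsFactors = FALSE)
  if (!is.null(providers)) {
    idx <- match(verts$name, providers$provider_id)
    for (cl in setdiff(names(providers), "provider_id")) {
      verts[[cl]] <- providers[[cl]][idx]
    }
  }
  edge_cols <- intersect(c(.edge_columns, "label"), names(network$edges))
  igraph::graph_from_data_frame(network$edges[, edge_cols, drop = FALSE],
                                directed = FALSE, vertices = verts)
}
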