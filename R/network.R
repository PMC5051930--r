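#' Build the bipartite provider-encounter network
#'
#' Aggregates the event rows into one involvement edge per (provider,
#' encounter) pair, with `action_count` recording how many action instances
#' the provider performed during that encounter. All providers are treated
#' as equal contributors to an encounter regardless of activity type.
#'
#' @param events data.frame of provider events (see [read_events()]).
#' @param encounters data.frame of encounter records; only referenced
#'   encounters are checked for existence.
#' @return An object of class `spor_bipartite`: `involvement` data.frame
#'   (`provider_id`, `encounter_id`, `action_count`), plus the provider and
#'   encounter id sets.
#' @export
build_bipartite <- function(events, encounters) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) {
    inv <- data.frame(provider_id = character(0), encounter_id = character(0),
                      action_count = integer(0), stringsAsFactors = FALSE)
  } else {
    unknown <- setdiff(events$encounter_id, encounters$encounter_id)
    if (length(unknown) > 0L) {
      stop("events reference unknown encounter(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    key <- paste(events$provider_id, events$encounter_id, sep = "\r")
    cnt <- table(key)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    inv <- data.frame(
      provider_id = vapply(parts, `[`, character(1), 1L),
      encounter_id = vapply(parts, `[`, character(1), 2L),
      action_count = as.integer(cnt),
      stringsAsFactors = FALSE
    )
    inv <- inv[order(inv$provider_id, inv$encounter_id), , drop = FALSE]
    rownames(inv) <- NULL
  }
  structure(
    list(
      involvement = inv,
      providers = sort(unique(inv$provider_id)),
      encounters = sort(unique(inv$encounter_id))
    ),
    class = "spor_bipartite"
  )
}

#' @export
print.spor_bipartite <- function(x, ...) {
  cat("Bipartite provider-encounter network:",
      length(x$providers), "providers,",
      length(x$encounters), "encounters,",
      nrow(x$involvement), "involvement edges\n")
  invisible(x)
}

#' Per-provider encounter sets
#'
#' Returns each provider's set of analysis encounters: those with a
#' computable risk-adjusted outcome. SEI and SPOI must be computed over the
#' same encounter universe, so encounters without an `r` value are excluded
#' here, before any index is formed.
#'
#' @param bipartite A `spor_bipartite`.
#' @param r Named numeric vector of risk-adjusted outcomes keyed by
#'   encounter id (see [outcome_map()]).
#' @return Named list: provider id -> character vector of encounter ids
#'   (possibly empty).
#' @export
encounter_sets <- function(bipartite, r) {
  valid <- names(r)[!is.na(r)]
  inv <- bipartite$involvement
  keep <- inv$encounter_id %in% valid
  sets <- split(inv$encounter_id[keep], inv$provider_id[keep])
  out <- setNames(vector("list", length(bipartite$providers)),
                  bipartite$providers)
  for (p in names(sets)) out[[p]] <- sets[[p]]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Shared Encounter Index
#'
#' Jaccard index of two providers' encounter sets:
#' `|A intersect B| / |A union B|`. Only pairs with a non-empty intersection
#' are ever scored; calling with disjoint sets is a contract violation.
#'
#' @param A,B Character vectors of encounter ids (duplicates ignored).
#' @return The SEI, a value in `(0, 1]`.
#' @export
sei <- function(A, B) {
  n_int <- length(intersect(A, B))
  if (n_int == 0L) stop("SEI undefined: encounter sets are disjoint")
  n_int / length(union(A, B))
}

#' Shared Positive Outcome Index
#'
#' Ratio of risk-adjusted outcome mass in the shared encounters to the mass
#' over the union of both providers' encounters:
#' `sum(r[A intersect B]) / sum(r[A union B])`.
#'
#' @param A,B Character vectors of encounter ids.
#' @param r Named numeric vector of risk-adjusted outcomes covering
#'   `union(A, B)`.
#' @return The SPOI, a value in `(0, 1]`.
#' @export
spoi <- function(A, B, r) {
  shared <- intersect(A, B)
  if (length(shared) == 0L) stop("SPOI undefined: encounter sets are disjoint")
  un <- union(A, B)
  missing_r <- un[!un %in% names(r) | is.na(r[un])]
  if (length(missing_r) > 0L) {
    stop("missing risk-adjusted outcome for encounter(s): ",
         paste(utils::head(missing_r, 5L), collapse = ", "))
  }
  denom <- sum(r[un])
  if (denom <= 0) stop("SPOI undefined: zero outcome mass over the union")
  sum(r[shared]) / denom
}

#' Shared Positive Outcome Ratio
#'
#' `SPOR = SPOI / SEI`: the concentration of risk-adjusted positive
#' outcomes in the encounters a pair shares, relative to what the pair's
#' overlap alone would predict. A value of 1 is neutral; an exclusive pair
#' (identical encounter sets) scores exactly 1 for any outcome values.
#'
#' @param sei_val SEI of the pair (must be positive).
#' @param spoi_val SPOI of the pair.
#' @return The SPOR, a positive real number bounded by `1 / sei_val`.
#' @export
spor <- function(sei_val, spoi_val) {
  if (any(sei_val <= 0)) stop("SPOR undefined: SEI must be positive")
  spoi_val / sei_val
}

#' Project the bipartite network onto provider pairs
#'
#' Builds the collaboration network: one undirected edge for every provider
#' pair sharing at least `min_shared` analysis encounters, weighted with the
#' pair's shared count, SEI, SPOI and SPOR. Providers with no surviving edge
#' are excluded from the node set. Pairs are enumerated through a sparse
#' provider-by-encounter incidence matrix, so only co-incident pairs are
#' ever touched.
#'
#' Encounters without a computable risk-adjusted outcome are excluded from
#' every encounter set (numerators and denominators alike). Edges whose
#' union outcome mass is zero are dropped with a warning; with the fitted
#' probabilities clipped away from 0/1 this cannot occur in practice.
#'
#' @param bipartite A `spor_bipartite`.
#' @param r Named numeric vector of risk-adjusted outcomes keyed by
#'   encounter id.
#' @param min_shared Minimum number of shared encounters for an edge
#'   (at least 2; the stability analysis in [threshold_sweep()] motivates
#'   the operating default of 6).
#' @return An object of class `spor_network`: `edges` data.frame
#'   (`provider_a` < `provider_b` lexicographically, `shared_count`, `sei`,
#'   `spoi`, `spor`, `p_value`), the retained provider ids, the threshold,
#'   and the internal incidence structure reused by the permutation null.
#' @export
project_collaboration <- function(bipartite, r, min_shared = 6L) {
  stopifnot(inherits(bipartite, "spor_bipartite"))
  if (min_shared < 2L) stop("min_shared must be at least 2")
  valid <- names(r)[!is.na(r)]
  inv <- bipartite$involvement
  inv <- inv[inv$encounter_id %in% valid, , drop = FALSE]

  empty_edges <- data.frame(
    provider_a = character(0), provider_b = character(0),
    shared_count = integer(0), sei = numeric(0), spoi = numeric(0),
    spor = numeric(0), p_value = numeric(0), stringsAsFactors = FALSE
  )
  if (nrow(inv) == 0L) {
    warning("no provider pair shares at least ", min_shared, " encounters")
    return(.new_network(empty_edges, bipartite, min_shared, NULL, NULL, NULL))
  }

  prov <- sort(unique(inv$provider_id))
  encs <- sort(unique(inv$encounter_id))
  M <- Matrix::sparseMatrix(
    i = match(inv$provider_id, prov),
    j = match(inv$encounter_id, encs),
    x = 1, dims = c(length(prov), length(encs))
  )
  rvec <- unname(r[encs])

  C <- Matrix::tcrossprod(M)
  TT <- methods::as(Matrix::triu(C, k = 1L), "TsparseMatrix")
  sel <- TT@x >= min_shared
  if (!any(sel)) {
    warning("no provider pair shares at least ", min_shared, " encounters")
    return(.new_network(empty_edges, bipartite, min_shared, M, encs, prov))
  }
  ia <- TT@i[sel] + 1L
  jb <- TT@j[sel] + 1L
  shared <- as.integer(TT@x[sel])

  sizes <- Matrix::rowSums(M)
  sei_v <- shared / (sizes[ia] + sizes[jb] - shared)

  W <- Matrix::tcrossprod(M %*% Matrix::Diagonal(x = rvec), M)
  int_r <- W[cbind(ia, jb)]
  row_r <- as.numeric(M %*% rvec)
  union_r <- row_r[ia] + row_r[jb] - int_r

  ok <- union_r > 0
  if (any(!ok)) {
    warning(sum(!ok), " edge(s) dropped: zero outcome mass over the union")
  }
  ia <- ia[ok]; jb <- jb[ok]; shared <- shared[ok]
  sei_v <- sei_v[ok]
  spoi_v <- int_r[ok] / union_r[ok]
  spor_v <- spoi_v / sei_v

  pa <- prov[ia]; pb <- prov[jb]
  swap <- pa > pb
  tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp

  edges <- data.frame(
    provider_a = pa, provider_b = pb, shared_count = shared,
    sei = sei_v, spoi = spoi_v, spor = spor_v, p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  ord <- order(edges$provider_a, edges$provider_b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL

  net <- .new_network(edges, bipartite, min_shared, M, encs, prov)
  net$edge_index <- cbind(ia, jb)[ord, , drop = FALSE]
  net$r <- rvec
  net
}

.new_network <- function(edges, bipartite, min_shared, M, encs, prov) {
  structure(
    list(
      edges = edges,
      providers = sort(unique(c(edges$provider_a, edges$provider_b))),
      min_shared = as.integer(min_shared),
      incidence = M,
      encounter_ids = encs,
      incidence_providers = prov,
      edge_index = NULL,
      r = NULL
    ),
    class = "spor_network"
  )
}

#' @export
print.spor_network <- function(x, ...) {
  cat("Collaboration network (min shared encounters ", x$min_shared, "): ",
      length(x$providers), " providers, ", nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges) > 0L) {
    cat("mean SPOR:", format(mean(x$edges$spor), digits = 4))
    if (any(!is.na(x$edges$p_value))) {
      cat("; permutation p-values attached")
    }
    cat("\n")
  }
  invisible(x)
}

#' Summary statistics for a collaboration network
#'
#' Density, mean degree, diameter, mean local clustering coefficient and
#' mean shortest-path length. Diameter and path length are computed on the
#' largest connected component, since thresholded collaboration networks
#' are not guaranteed connected; clustering averages local coefficients
#' over the whole network with degree-deficient nodes contributing 0.
#'
#' @param network A non-empty `spor_network`.
#' @return A list of class `spor_summary` with elements `n_providers`,
#'   `n_edges`, `density`, `mean_degree`, `diameter`, `mean_clustering`,
#'   `mean_path_length`.
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "spor_network"))
  if (nrow(network$edges) == 0L) stop("cannot summarise an empty network")
  g <- as_igraph(network)
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize))
  )
  structure(
    list(
      n_providers = igraph::vcount(g),
      n_edges = igraph::ecount(g),
      density = igraph::edge_density(g),
      mean_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
      diameter = igraph::diameter(big, unconnected = FALSE),
      mean_clustering = igraph::transitivity(g, type = "localaverage",
                                             isolates = "zero"),
      mean_path_length = igraph::mean_distance(big)
    ),
    class = "spor_summary"
  )
}

#' @export
print.spor_summary <- function(x, ...) {
  cat("providers:", x$n_providers, " edges:", x$n_edges, "\n")
  cat("density:", format(x$density, digits = 4),
      " mean degree:", format(x$mean_degree, digits = 4), "\n")
  cat("diameter:", x$diameter,
      " mean clustering:", format(x$mean_clustering, digits = 4),
      " mean path length:", format(x$mean_path_length, digits = 4), "\n")
  invisible(x)
}

#' Shared-encounter threshold sweep
#'
#' Rebuilds the collaboration network at each threshold and reports the
#' SPOR distribution: provider and edge counts, mean, SD and the 5th, 10th,
#' 90th and 95th percentiles (linear interpolation between order
#' statistics). SPOR values are volatile for pairs sharing few encounters,
#' so the distribution narrows as the threshold rises; the sweep is how the
#' operating threshold is chosen for a given data set.
#'
#' @param bipartite A `spor_bipartite`.
#' @param r Named risk-adjusted outcome vector.
#' @param thresholds Integer vector of thresholds, each at least 2.
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_providers`, `n_edges`, `mean_spor`, `sd_spor`, `p5`, `p10`, `p90`,
#'   `p95`. Thresholds yielding an empty network give zero counts and `NA`
#'   statistics.
#' @export
threshold_sweep <- function(bipartite, r, thresholds = c(2L, 4L, 6L, 8L, 10L)) {
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  if (any(thresholds < 2L)) stop("every threshold must be at least 2")
  rows <- lapply(thresholds, function(t) {
    net <- suppressWarnings(project_collaboration(bipartite, r, t))
    v <- net$edges$spor
    if (length(v) == 0L) {
      data.frame(threshold = t, n_providers = 0L, n_edges = 0L,
                 mean_spor = NA_real_, sd_spor = NA_real_,
                 p5 = NA_real_, p10 = NA_real_, p90 = NA_real_,
                 p95 = NA_real_)
    } else {
      q <- quantile(v, c(0.05, 0.10, 0.90, 0.95), names = FALSE, type = 7)
      data.frame(threshold = t, n_providers = length(net$providers),
                 n_edges = length(v), mean_spor = mean(v),
                 sd_spor = if (length(v) > 1L) sd(v) else 0,
                 p5 = q[1], p10 = q[2], p90 = q[3], p95 = q[4])
    }
  })
  do.call(rbind, rows)
}
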