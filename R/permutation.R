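#' Permute risk-adjusted outcomes across encounters
#'
#' Draws a uniform random bijection of the outcome values onto the same
#' encounter ids: the multiset of values is preserved exactly and the
#' network topology is untouched. Uses the current R random number stream;
#' seed with `set.seed()` for reproducibility.
#'
#' @param r Named numeric vector of risk-adjusted outcomes.
#' @return Named numeric vector over the same encounter ids with the values
#'   permuted.
#' @export
permute_outcomes <- function(r) {
  if (length(r) == 0L) stop("cannot permute an empty outcome map")
  setNames(unname(r)[sample.int(length(r))], names(r))
}

# per-permutation substream seeds derived from the master seed, so results
# do not depend on the order in which permutations are evaluated
.substream_seeds <- function(seed, B) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, B)
}

#' Null SPOR distribution for every observed edge
#'
#' Generates `B` outcome permutations and recomputes each observed edge's
#' SPOR on the permuted outcomes. The edge set and every SEI are unchanged
#' by construction: shared-encounter structure does not depend on outcomes,
#' so the observed topology is computed once and reused rather than
#' rebuilding the network `B` times. One master seed spawns a substream
#' seed per permutation.
#'
#' @param network A `spor_network` from [project_collaboration()] (it
#'   carries the incidence structure and outcome vector).
#' @param B Number of permutations (at least 1; the reference analysis uses
#'   1000).
#' @param seed Master seed.
#' @return Numeric matrix of null SPOR values, one row per observed edge
#'   (in `network$edges` order, rownames `"a|b"`), one column per
#'   permutation.
#' @export
null_distribution <- function(network, B = 1000L, seed = 1L) {
  stopifnot(inherits(network, "spor_network"))
  if (B < 1L) stop("B must be at least 1")
  edges <- network$edges
  if (nrow(edges) == 0L) stop("observed network has no edges")
  M <- network$incidence
  r <- network$r
  idx <- network$edge_index
  n_enc <- length(r)

  seeds <- .substream_seeds(seed, B)
  R_perm <- matrix(0, nrow = n_enc, ncol = B)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    R_perm[, b] <- r[sample.int(n_enc)]
  }

  # per-edge intersection incidence: row k flags encounters in A_a ∩ A_b
  Mt <- methods::as(M, "TsparseMatrix")
  enc_by_prov <- split(Mt@j + 1L, Mt@i + 1L)
  ii <- vector("list", nrow(edges))
  jj <- vector("list", nrow(edges))
  for (k in seq_len(nrow(edges))) {
    inter <- intersect(enc_by_prov[[as.character(idx[k, 1L])]],
                       enc_by_prov[[as.character(idx[k, 2L])]])
    ii[[k]] <- rep.int(k, length(inter))
    jj[[k]] <- inter
  }
  E_int <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                                dims = c(nrow(edges), n_enc))

  prov_sums <- as.matrix(M %*% R_perm)
  int_sums <- as.matrix(E_int %*% R_perm)
  union_sums <- prov_sums[idx[, 1L], , drop = FALSE] +
    prov_sums[idx[, 2L], , drop = FALSE] - int_sums
  spoi_null <- int_sums / union_sums
  out <- spoi_null / edges$sei
  rownames(out) <- paste(edges$provider_a, edges$provider_b, sep = "|")
  out
}

#' Permutation p-value for one edge
#'
#' `p = #{null SPOR strictly greater than observed} / B`; ties count as not
#' exceeding. Small p flags an edge whose shared encounters concentrate
#' more positive outcomes than chance; large p (near 1) flags the opposite
#' tail. The optional smoothed estimator `(k + 1) / (B + 1)` guarantees
#' `p > 0` for users who need it.
#'
#' @param observed Observed SPOR.
#' @param null_samples Numeric vector of null SPOR values.
#' @param smoothed Use the `(k + 1) / (B + 1)` estimator.
#' @return A list (class `spor_permutation_result`): `observed_spor`,
#'   `exceed_count`, `n_permutations`, `p_value`.
#' @export
edge_pvalue <- function(observed, null_samples, smoothed = FALSE) {
  if (length(null_samples) == 0L) stop("null_samples must be non-empty")
  k <- sum(null_samples > observed)
  B <- length(null_samples)
  structure(
    list(
      observed_spor = observed,
      exceed_count = k,
      n_permutations = B,
      p_value = if (smoothed) (k + 1) / (B + 1) else k / B
    ),
    class = "spor_permutation_result"
  )
}

#' Attach permutation p-values to every edge
#'
#' Runs [null_distribution()] and stores, per edge, the exceedance count
#' and p-value.
#'
#' @param network A `spor_network`.
#' @param B Number of permutations.
#' @param seed Master seed.
#' @param smoothed Use the `(k + 1) / (B + 1)` p-value estimator.
#' @return The network with `exceed_count` and `p_value` filled in and
#'   `n_permutations` recorded.
#' @export
permutation_test <- function(network, B = 1000L, seed = 1L,
                             smoothed = FALSE) {
  nulls <- null_distribution(network, B = B, seed = seed)
  k <- rowSums(nulls > network$edges$spor)
  network$edges$exceed_count <- as.integer(k)
  network$edges$p_value <- if (smoothed) (k + 1) / (B + 1) else k / B
  network$n_permutations <- as.integer(B)
  network
}

#' Classify edges as high- or low-scoring
#'
#' High-scoring: permutation `p <= high_cut` (the shared encounters
#' concentrate significantly more positive outcomes than chance).
#' Low-scoring: `p >= low_cut`. Both cuts are inclusive. Everything else is
#' labelled `"neither"`.
#'
#' @param network A `spor_network` with p-values attached
#'   (see [permutation_test()]).
#' @param high_cut,low_cut Inclusive p-value cuts (defaults 0.05 and 0.95).
#' @return The network with an edge `label` column
#'   (`"high"`/`"low"`/`"neither"`).
#' @export
classify_edges <- function(network, high_cut = 0.05, low_cut = 0.95) {
  p <- network$edges$p_value
  if (nrow(network$edges) > 0L && all(is.na(p))) {
    stop("edges carry no p-values; run permutation_test() first")
  }
  network$edges$label <- ifelse(
    is.na(p), NA_character_,
    ifelse(p <= high_cut, "high", ifelse(p >= low_cut, "low", "neither"))
  )
  network
}

#' Provider scoring groups
#'
#' Collects the providers for whom at least `min_fraction` of their
#' collaborations (edges in the thresholded network) are flagged in the
#' given direction, with an additional multiplicity floor of `min_flagged`
#' flagged edges (set `min_flagged = 1` to disable it). A provider can
#' belong to both the high and the low group. The group summary is the
#' degree-weighted average flagged fraction over members.
#'
#' @param network A classified `spor_network` (see [classify_edges()]).
#' @param bipartite The `spor_bipartite` the network was projected from
#'   (for per-provider encounter totals).
#' @param encounters Encounter data.frame (for positive-outcome counts);
#'   only encounters with a non-missing outcome are counted.
#' @param direction `"high"` or `"low"`.
#' @param min_fraction Minimum flagged fraction for membership.
#' @param min_flagged Minimum number of flagged edges for membership.
#' @return A list of class `spor_scoring_group`: `direction`, `members`
#'   data.frame (`provider_id`, `flagged_count`, `degree`, `fraction`,
#'   `positive_encounters`, `total_encounters`) sorted by descending
#'   flagged count, `weighted_average` and `n_members`.
#' @export
scoring_groups <- function(network, bipartite, encounters,
                           direction = c("high", "low"),
                           min_fraction = 0.05, min_flagged = 2L) {
  direction <- match.arg(direction)
  edges <- network$edges
  if (!"label" %in% names(edges)) {
    stop("edges are not classified; run classify_edges() first")
  }
  all_prov <- c(edges$provider_a, edges$provider_b)
  degree <- table(all_prov)
  flagged <- table(factor(
    c(edges$provider_a[edges$label == direction],
      edges$provider_b[edges$label == direction]),
    levels = names(degree)
  ))
  fraction <- as.numeric(flagged) / as.numeric(degree)
  member <- fraction >= min_fraction & as.numeric(flagged) >= min_flagged

  ids <- names(degree)[member]
  surveyed <- encounters[!is.na(encounters$outcome), , drop = FALSE]
  inv <- bipartite$involvement
  inv <- inv[inv$encounter_id %in% surveyed$encounter_id, , drop = FALSE]
  pos_ids <- surveyed$encounter_id[surveyed$outcome == 1L]

  totals <- vapply(ids, function(p) {
    sum(inv$provider_id == p)
  }, numeric(1))
  positives <- vapply(ids, function(p) {
    sum(inv$provider_id == p & inv$encounter_id %in% pos_ids)
  }, numeric(1))

  members <- data.frame(
    provider_id = ids,
    flagged_count = as.integer(flagged[member]),
    degree = as.integer(degree[member]),
    fraction = fraction[member],
    positive_encounters = as.integer(positives),
    total_encounters = as.integer(totals),
    stringsAsFactors = FALSE
  )
  members <- members[order(-members$flagged_count, members$provider_id), ,
                     drop = FALSE]
  rownames(members) <- NULL

  structure(
    list(
      direction = direction,
      members = members,
      weighted_average = if (nrow(members) > 0L) {
        sum(members$flagged_count) / sum(members$degree)
      } else NA_real_,
      n_members = nrow(members)
    ),
    class = "spor_scoring_group"
  )
}

#' @export
print.spor_scoring_group <- function(x, ...) {
  cat(x$direction, "-scoring group: ", x$n_members, " provider(s)",
      sep = "")
  if (x$n_members > 0L) {
    cat("; degree-weighted average flagged fraction ",
        format(x$weighted_average, digits = 3), sep = "")
  }
  cat("\n")
  invisible(x)
}
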