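# Shared fixtures and independent oracles.

# The two-encounter toy: five actions performed by four providers during two
# encounters; provider 4 performed two activities during encounter 2.
make_toy_data <- function(outcomes = c(1L, 0L)) {
  encounters <- data.frame(
    encounter_id = c("E1", "E2"),
    outcome = outcomes,
    acuity = c(3L, 3L),
    stringsAsFactors = FALSE
  )
  events <- data.frame(
    provider_id = c("P1", "P2", "P3", "P4", "P4"),
    encounter_id = c("E1", "E1", "E1", "E2", "E2"),
    activity_category = c("orders", "notes", "notes", "notes",
                          "intake-output"),
    action_type = c("order", "complete", "performed", "performed",
                    "performed"),
    stringsAsFactors = FALSE
  )
  list(encounters = encounters, events = events)
}

write_fixture_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# brute-force oracles: explicit element-wise loops, no set algebra reuse
brute_sei <- function(A, B) {
  A <- unique(A); B <- unique(B)
  n_int <- 0L
  for (a in A) if (a %in% B) n_int <- n_int + 1L
  n_union <- length(B)
  for (a in A) if (!a %in% B) n_union <- n_union + 1L
  n_int / n_union
}

brute_spoi <- function(A, B, r) {
  A <- unique(A); B <- unique(B)
  num <- 0
  den <- 0
  for (e in unique(c(A, B))) {
    in_a <- e %in% A
    in_b <- e %in% B
    if (in_a && in_b) num <- num + r[[e]]
    if (in_a || in_b) den <- den + r[[e]]
  }
  num / den
}

# random overlapping encounter-set pair over a small universe
random_set_pair <- function(universe_size = 40L, max_size = 30L) {
  universe <- sprintf("e%02d", seq_len(universe_size))
  repeat {
    A <- sample(universe, sample.int(max_size, 1L))
    B <- sample(universe, sample.int(max_size, 1L))
    if (length(intersect(A, B)) > 0L) return(list(A = A, B = B))
  }
}

# small generated analysis: data -> risk model -> r map -> bipartite
small_analysis <- function(config) {
  d <- generate_collaboration_data(config)
  m <- fit_risk_model(d$encounters)
  ra <- risk_adjusted_outcomes(m, d$encounters)
  list(data = d, model = m, r = outcome_map(ra),
       bipartite = build_bipartite(d$events, d$encounters))
}

# hand-built classified network for scoring-group rules
manual_network <- function(edges) {
  structure(
    list(edges = edges,
         providers = sort(unique(c(edges$provider_a, edges$provider_b))),
         min_shared = 2L),
    class = "spor_network"
  )
}
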