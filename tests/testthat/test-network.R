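test_that("bipartite build aggregates action counts per involvement", {
  toy <- make_toy_data()
  b <- build_bipartite(toy$events, toy$encounters)
  expect_equal(nrow(b$involvement), 4L)
  p4 <- b$involvement[b$involvement$provider_id == "P4", ]
  expect_equal(p4$action_count, 2L)
  expect_setequal(b$providers, c("P1", "P2", "P3", "P4"))

  empty <- build_bipartite(toy$events[0, ], toy$encounters)
  expect_equal(nrow(empty$involvement), 0L)
})

test_that("encounter sets are restricted to encounters with outcomes", {
  inv <- data.frame(
    provider_id = c("P1", "P1", "P1", "P2"),
    encounter_id = c("E1", "E2", "E3", "E3"),
    activity_category = "orders", action_type = "order"
  )
  enc <- data.frame(encounter_id = c("E1", "E2", "E3"),
                    outcome = c(1L, NA, 0L))
  b <- build_bipartite(inv, enc)
  r <- setNames(c(0.6, NA, 0.4), c("E1", "E2", "E3"))
  sets <- encounter_sets(b, r)
  expect_length(sets$P1, 2L)
  expect_setequal(sets$P1, c("E1", "E3"))

  # provider whose every encounter lacks an outcome gets an empty set
  r2 <- setNames(c(0.6, NA, NA), c("E1", "E2", "E3"))
  sets2 <- encounter_sets(b, r2)
  expect_length(sets2$P2, 0L)
})

test_that("SEI and SPOI match direct counting on worked examples", {
  expect_equal(sei(c("e1", "e2", "e3"), c("e3", "e4")), 0.25)
  expect_equal(sei(sprintf("e%d", 1:5), sprintf("e%d", 1:5)), 1.0)
  expect_error(sei(c("e1"), c("e2")), "disjoint")

  r <- c(e1 = 1.0, e2 = 0.5, e3 = 0.5)
  expect_equal(spoi(c("e1", "e2"), c("e1", "e3"), r), 0.5)
  # all outcomes identical: the constants cancel and SPOI equals SEI
  rc <- setNames(rep(0.37, 6), sprintf("e%d", 1:6))
  A <- c("e1", "e2", "e3", "e4")
  B <- c("e3", "e4", "e5", "e6")
  expect_equal(spoi(A, B, rc), sei(A, B))
  expect_error(spoi(A, B, rc[1:4]), "missing risk-adjusted outcome")
})

test_that("SEI and SPOI agree with brute-force oracles and are symmetric", {
  set.seed(202)
  for (i in 1:400) {
    pr <- random_set_pair()
    universe <- unique(c(pr$A, pr$B))
    r <- setNames(runif(length(universe), 0.05, 1), universe)
    s1 <- sei(pr$A, pr$B)
    expect_equal(s1, brute_sei(pr$A, pr$B), tolerance = 1e-12)
    expect_identical(s1, sei(pr$B, pr$A))
    v1 <- spoi(pr$A, pr$B, r)
    expect_equal(v1, brute_spoi(pr$A, pr$B, r), tolerance = 1e-12)
    expect_identical(v1, spoi(pr$B, pr$A, r))
    # bounds: both indices in (0, 1], SPOR bounded by 1/SEI
    expect_true(s1 > 0 && s1 <= 1)
    expect_true(v1 > 0 && v1 <= 1)
    expect_lte(spor(s1, v1), 1 / s1 + 1e-12)
  }
})

test_that("exclusive collaborators score exactly 1 for any outcomes", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    A <- sprintf("e%02d", seq_len(n))
    r <- setNames(runif(n, 0.01, 1), A)
    expect_identical(spor(sei(A, A), spoi(A, A, r)), 1)
  }
  expect_equal(spor(0.25, 0.5), 2.0)
  expect_error(spor(0, 0.5), "positive")
})

test_that("projection thresholds on shared encounters exactly", {
  n_shared <- 4L
  enc_ids <- sprintf("E%02d", 1:10)
  enc <- data.frame(encounter_id = enc_ids, outcome = rep(c(1L, 0L), 5))
  # P1 and P2 share E01..E04; P3 dangles off unshared encounters
  inv <- rbind(
    data.frame(provider_id = "P1", encounter_id = enc_ids[1:6]),
    data.frame(provider_id = "P2", encounter_id = enc_ids[c(1:4, 7, 8)]),
    data.frame(provider_id = "P3", encounter_id = enc_ids[9:10])
  )
  inv$activity_category <- "orders"; inv$action_type <- "order"
  b <- build_bipartite(inv, enc)
  r <- setNames(seq(0.1, 1, length.out = 10), enc_ids)

  net <- project_collaboration(b, r, min_shared = n_shared)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$shared_count, 4L)
  expect_equal(net$edges$sei, 4 / 8)
  expect_equal(net$edges$spoi, sum(r[1:4]) / sum(r[1:8]))
  expect_equal(net$edges$spor, net$edges$spoi / net$edges$sei)
  # isolated providers are excluded from the node set
  expect_setequal(net$providers, c("P1", "P2"))

  # one fewer shared encounter than the threshold: no edge
  expect_warning(net2 <- project_collaboration(b, r, min_shared = 5L),
                 "no provider pair")
  expect_equal(nrow(net2$edges), 0L)
  expect_error(project_collaboration(b, r, min_shared = 1L), "at least 2")
})

test_that("edge fields agree with set-based recomputation on generated data", {
  an <- small_analysis(null_config(n_providers = 40L, n_encounters = 400L,
                                   n_pools = 4L, seed = 31L))
  net <- project_collaboration(an$bipartite, an$r, 4L)
  expect_gt(nrow(net$edges), 10L)
  sets <- encounter_sets(an$bipartite, an$r)
  for (k in sample.int(nrow(net$edges), 10L)) {
    e <- net$edges[k, ]
    A <- sets[[e$provider_a]]
    B <- sets[[e$provider_b]]
    expect_equal(e$shared_count, length(intersect(A, B)))
    expect_equal(e$sei, sei(A, B), tolerance = 1e-12)
    expect_equal(e$spoi, spoi(A, B, an$r), tolerance = 1e-12)
    expect_equal(e$spor, e$spoi / e$sei, tolerance = 1e-12)
  }
})

test_that("sparsification is monotone in the threshold", {
  an <- small_analysis(null_config(n_providers = 60L, n_encounters = 600L,
                                   n_pools = 6L, seed = 13L))
  sweep <- threshold_sweep(an$bipartite, an$r, thresholds = 2:10)
  expect_true(all(diff(sweep$n_edges) <= 0))
  expect_true(all(diff(sweep$n_providers) <= 0))
})

test_that("network summaries match hand-computed values on named graphs", {
  mk <- function(a, b) {
    edges <- data.frame(provider_a = a, provider_b = b, shared_count = 2L,
                        sei = 0.5, spoi = 0.5, spor = 1, p_value = NA_real_)
    manual_network(edges)
  }
  triangle <- summarize_network(mk(c("A", "A", "B"), c("B", "C", "C")))
  expect_equal(triangle$density, 1)
  expect_equal(triangle$mean_degree, 2)
  expect_equal(triangle$diameter, 1)
  expect_equal(triangle$mean_clustering, 1)

  path3 <- summarize_network(mk(c("A", "B"), c("B", "C")))
  expect_equal(path3$diameter, 2)
  expect_equal(path3$mean_clustering, 0)

  star <- summarize_network(mk(rep("H", 5), c("L1", "L2", "L3", "L4", "L5")))
  expect_equal(star$mean_degree, 10 / 6)
  expect_equal(star$diameter, 2)

  empty <- manual_network(mk("A", "B")$edges[0, ])
  expect_error(summarize_network(empty), "empty")
})

test_that("sweep statistics honor the percentile ordering invariant", {
  set.seed(44)
  for (i in 1:5) {
    an <- small_analysis(null_config(n_providers = 30L, n_encounters = 250L,
                                     n_pools = 3L, seed = 100L + i))
    sw <- threshold_sweep(an$bipartite, an$r, thresholds = c(2L, 4L, 6L))
    ok <- !is.na(sw$mean_spor)
    expect_true(all(sw$p5[ok] <= sw$p10[ok]))
    expect_true(all(sw$p10[ok] <= sw$p90[ok]))
    expect_true(all(sw$p90[ok] <= sw$p95[ok]))
    # percentile oracle: sorted-vector quantile on the raw SPOR values
    net <- suppressWarnings(project_collaboration(an$bipartite, an$r, 2L))
    expect_equal(sw$p5[sw$threshold == 2],
                 unname(quantile(sort(net$edges$spor), 0.05, type = 7)))
  }
})

test_that("a single-edge sweep row reports its SPOR with zero spread", {
  enc <- data.frame(encounter_id = sprintf("E%d", 1:4),
                    outcome = c(1L, 0L, 1L, 1L))
  inv <- data.frame(provider_id = rep(c("P1", "P2"), each = 3),
                    encounter_id = c("E1", "E2", "E3", "E1", "E2", "E4"),
                    activity_category = "orders", action_type = "order")
  b <- build_bipartite(inv, enc)
  r <- setNames(c(0.9, 0.2, 0.7, 0.6), sprintf("E%d", 1:4))
  sw <- threshold_sweep(b, r, thresholds = c(2L, 4L))
  expect_equal(sw$n_edges, c(1L, 0L))
  expect_equal(sw$sd_spor, c(0, NA_real_))
  expect_equal(sw$mean_spor[1], spoi(c("E1", "E2", "E3"),
                                     c("E1", "E2", "E4"), r) / 0.5)
  expect_true(is.na(sw$mean_spor[2]))
})
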