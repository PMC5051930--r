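test_that("outcome permutation preserves the value multiset on the same ids", {
  set.seed(21)
  r <- setNames(runif(50), sprintf("E%02d", 1:50))
  p1 <- permute_outcomes(r)
  expect_identical(names(p1), names(r))
  expect_identical(sort(unname(p1)), sort(unname(r)))

  set.seed(5); a <- permute_outcomes(r)
  set.seed(5); b <- permute_outcomes(r)
  expect_identical(a, b)
  set.seed(6); c3 <- permute_outcomes(r)
  expect_false(identical(a, c3))

  single <- c(E1 = 0.4)
  expect_identical(permute_outcomes(single), single)
  expect_error(permute_outcomes(numeric(0)), "empty")
})

test_that("the permuted networks keep the observed topology", {
  an <- small_analysis(null_config(n_providers = 30L, n_encounters = 300L,
                                   n_pools = 3L, seed = 17L))
  net <- project_collaboration(an$bipartite, an$r, 4L)
  expect_gt(nrow(net$edges), 5L)

  # re-projecting on permuted outcomes yields the identical edge set,
  # shared counts and SEI values: topology is outcome-free
  set.seed(99)
  rp <- permute_outcomes(an$r)
  net_p <- project_collaboration(an$bipartite, rp, 4L)
  expect_identical(net_p$edges$provider_a, net$edges$provider_a)
  expect_identical(net_p$edges$provider_b, net$edges$provider_b)
  expect_identical(net_p$edges$shared_count, net$edges$shared_count)
  expect_identical(net_p$edges$sei, net$edges$sei)

  # and the vectorised null reproduces per-edge SPORs computed the slow way
  nulls <- null_distribution(net, B = 3L, seed = 123L)
  seeds <- spornet:::.substream_seeds(123L, 3L)
  for (b in 1:3) {
    set.seed(seeds[b])
    perm <- sample.int(length(net$r))
    r_b <- setNames(net$r[perm], net$encounter_ids)
    net_b <- project_collaboration(an$bipartite, r_b, 4L)
    expect_equal(unname(nulls[, b]), net_b$edges$spor, tolerance = 1e-12)
  }
})

test_that("constant outcomes collapse every null SPOR to 1", {
  an <- small_analysis(null_config(n_providers = 20L, n_encounters = 200L,
                                   n_pools = 2L, seed = 23L))
  r_const <- setNames(rep(0.5, length(an$r)), names(an$r))
  net <- project_collaboration(an$bipartite, r_const, 4L)
  nulls <- null_distribution(net, B = 10L, seed = 1L)
  expect_equal(unname(nulls), matrix(1, nrow(net$edges), 10L),
               tolerance = 1e-12)
  expect_equal(net$edges$spor, rep(1, nrow(net$edges)), tolerance = 1e-12)
})

test_that("per-edge null SPOR means sit near 1", {
  an <- small_analysis(null_config(n_providers = 40L, n_encounters = 500L,
                                   n_pools = 4L, seed = 29L))
  net <- project_collaboration(an$bipartite, an$r, 5L)
  B <- 500L
  nulls <- null_distribution(net, B = B, seed = 7L)
  m <- rowMeans(nulls)
  se <- apply(nulls, 1, sd) / sqrt(B)
  # permutation makes each edge's null SPOR mean exactly 1 in expectation
  expect_gt(mean(abs(m - 1) <= 3 * se), 0.95)
})

test_that("p-values count strict exceedances", {
  res <- edge_pvalue(1.2, c(1.3, 1.1, 1.0, 0.9))
  expect_equal(res$p_value, 0.25)
  expect_equal(res$exceed_count, 1L)
  expect_equal(edge_pvalue(2.0, c(1.3, 1.1, 1.0, 0.9))$p_value, 0)
  # ties are not exceedances
  expect_equal(edge_pvalue(1.0, rep(1.0, 10))$p_value, 0)
  expect_equal(edge_pvalue(1.0, rep(1.0, 9), smoothed = TRUE)$p_value, 0.1)
  expect_error(edge_pvalue(1.0, numeric(0)), "non-empty")
})

test_that("classification cuts are inclusive on both tails", {
  edges <- data.frame(provider_a = c("A", "A", "B"),
                      provider_b = c("B", "C", "C"),
                      shared_count = 3L, sei = 0.3, spoi = 0.3, spor = 1,
                      p_value = c(0.05, 0.95, 0.50))
  net <- classify_edges(manual_network(edges))
  expect_identical(net$edges$label, c("high", "low", "neither"))
})

test_that("permutation results are reproducible from the master seed", {
  an <- small_analysis(null_config(n_providers = 25L, n_encounters = 250L,
                                   n_pools = 3L, seed = 37L))
  net <- project_collaboration(an$bipartite, an$r, 4L)
  a <- permutation_test(net, B = 50L, seed = 31L)
  b <- permutation_test(net, B = 50L, seed = 31L)
  expect_identical(a$edges$p_value, b$edges$p_value)
  c3 <- permutation_test(net, B = 50L, seed = 32L)
  expect_false(identical(a$edges$p_value, c3$edges$p_value))
})

test_that("scoring groups apply the fraction and multiplicity rules", {
  # provider H sits on 20 edges with exactly 1 flagged (5%): excluded by
  # the multiplicity floor, included when the floor is disabled
  spokes <- sprintf("S%02d", 1:20)
  edges <- data.frame(
    provider_a = "H", provider_b = spokes, shared_count = 6L,
    sei = 0.3, spoi = 0.3, spor = 1,
    p_value = c(0.01, rep(0.5, 19))
  )
  net <- classify_edges(manual_network(edges))
  enc <- data.frame(encounter_id = sprintf("E%02d", 1:10),
                    outcome = rep(c(1L, 0L), 5))
  inv <- data.frame(provider_id = "H",
                    encounter_id = sprintf("E%02d", 1:10),
                    activity_category = "orders", action_type = "order")
  b <- build_bipartite(inv, enc)

  strict <- scoring_groups(net, b, enc, "high")
  expect_equal(strict$n_members, 0L)
  lax <- scoring_groups(net, b, enc, "high", min_flagged = 1L)
  expect_true("H" %in% lax$members$provider_id)
  h <- lax$members[lax$members$provider_id == "H", ]
  expect_equal(h$fraction, 0.05)
  expect_equal(h$degree, 20L)
  expect_equal(h$total_encounters, 10L)
  expect_equal(h$positive_encounters, 5L)

  # degree 40 with 2 flagged edges: exactly 5%, passes both rules
  edges2 <- data.frame(
    provider_a = "H", provider_b = sprintf("S%02d", 1:40), shared_count = 6L,
    sei = 0.3, spoi = 0.3, spor = 1,
    p_value = c(0.0, 0.05, rep(0.5, 38))
  )
  net2 <- classify_edges(manual_network(edges2))
  g2 <- scoring_groups(net2, b, enc, "high")
  expect_equal(g2$members$provider_id, "H")
  expect_equal(g2$weighted_average, 2 / 40)
})

test_that("a provider can belong to both scoring groups", {
  spokes <- sprintf("S%02d", 1:10)
  edges <- data.frame(
    provider_a = "H", provider_b = spokes, shared_count = 6L,
    sei = 0.3, spoi = 0.3, spor = 1,
    p_value = c(0.01, 0.02, 0.99, 0.96, rep(0.5, 6))
  )
  net <- classify_edges(manual_network(edges))
  enc <- data.frame(encounter_id = "E01", outcome = 1L)
  inv <- data.frame(provider_id = "H", encounter_id = "E01",
                    activity_category = "orders", action_type = "order")
  b <- build_bipartite(inv, enc)
  hi <- scoring_groups(net, b, enc, "high")
  lo <- scoring_groups(net, b, enc, "low")
  expect_true("H" %in% hi$members$provider_id)
  expect_true("H" %in% lo$members$provider_id)
})
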