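# Randomisation null models and hypothesis-testing machinery.

helix <- function(n, seed = 1, ...)
  read_structure(generate_toy_structure(
    c(list(n_res = n, geometry = "ideal_helix"), list(...)),
    seed = seed)$pdb)

test_that("random-region null resamples contiguous window exposure", {
  st <- helix(30)
  sasa <- compute_rasa(st)
  sasa$exposed <- rep(TRUE, 30)
  nd <- random_region_null(st, 8, sasa, n = 200, seed = 1)
  expect_true(all(nd$samples == 1))

  # degenerate full-chain window
  nd2 <- random_region_null(st, 30, sasa, n = 50, seed = 1)
  expect_true(all(nd2$samples == mean(sasa$exposed)))
  expect_error(random_region_null(st, 31, sasa), "longer")

  # half-exposed chain: sample mean within 3 sigma of the exact average
  # over all enumerable windows
  sasa$exposed <- rep(c(TRUE, FALSE), 15)
  len <- 7
  windows <- vapply(seq_len(30 - len + 1), function(s)
    mean(sasa$exposed[s:(s + len - 1)]), numeric(1))
  nd3 <- random_region_null(st, len, sasa, n = 4000, seed = 3)
  se <- stats::sd(windows) / sqrt(4000)
  expect_lt(abs(mean(nd3$samples) - mean(windows)), 3 * se + 1e-8)
})

test_that("grown random clusters cover the site extremes and reproduce", {
  st <- helix(30)
  dm <- residue_distance_matrix(st)
  all_sites <- seq_len(30)
  nd <- random_cluster_null(st, 4, all_sites, n = 300, seed = 1, dmat = dm)
  expect_true(all(nd$samples == 1))           # a site is always a member
  nd0 <- random_cluster_null(st, 4, integer(0), n = 300, seed = 1,
                             dmat = dm)
  expect_true(all(nd0$samples == 0))

  # independent-seed rerun agreement (3 sigma)
  sites <- 12:14
  a <- random_cluster_null(st, 5, sites, n = 3000, seed = 5, dmat = dm)
  b <- random_cluster_null(st, 5, sites, n = 3000, seed = 99, dmat = dm)
  pa <- mean(a$samples); pb <- mean(b$samples)
  se <- sqrt(pa * (1 - pa) / 3000 + pb * (1 - pb) / 3000)
  expect_lt(abs(pa - pb), 3 * se + 1e-8)
  # reproducibility from the seed
  a2 <- random_cluster_null(st, 5, sites, n = 3000, seed = 5, dmat = dm)
  expect_identical(a$samples, a2$samples)
  expect_error(random_cluster_null(st, 2, sites), "at least 3")
})

test_that("pattern-placement null equals exhaustive offset enumeration", {
  st <- helix(30)
  dm <- residue_distance_matrix(st)
  pattern <- c(5, 6, 9, 11)                  # X-X---X-X spacing
  sites <- c(20, 21)
  nd <- residue_pattern_null(st, pattern, sites, n = 5000, seed = 2,
                             dmat = dm)
  span <- max(pattern) - min(pattern)
  offsets <- seq_len(30 - span)
  exact <- mean(vapply(offsets, function(s)
    min(dm[s + pattern - min(pattern), sites]) <= 4, logical(1)))
  p_hat <- mean(nd$samples)
  se <- sqrt(exact * (1 - exact) / 5000)
  expect_lt(abs(p_hat - exact), 3 * se + 1e-8)

  # full-span pattern: every placement identical
  nd2 <- residue_pattern_null(st, c(1, 30), sites, n = 100, seed = 1,
                              dmat = dm)
  expect_equal(length(unique(nd2$samples)), 1)
  # no sites: never close
  nd3 <- residue_pattern_null(st, pattern, integer(0), n = 100, seed = 1,
                              dmat = dm)
  expect_true(all(!nd3$samples))
  expect_error(residue_pattern_null(st, c(1, 40), sites), "longer")
})

test_that("functional-vicinity sampling is uniform over the vicinity", {
  st <- helix(30)
  dm <- residue_distance_matrix(st)
  # radius 0: only residues overlapping site atoms (the site itself)
  s0 <- functional_vicinity_residue_sample(st, 15, radius = 0, n = 50,
                                           seed = 1, dmat = dm)
  expect_true(all(s0 == 15))

  sites <- c(10, 20)
  vic <- which(apply(dm[, sites], 1, min) <= 4)
  s1 <- functional_vicinity_residue_sample(st, sites, radius = 4,
                                           n = 6000, seed = 2, dmat = dm)
  expect_true(all(s1 %in% vic))
  # multinomial 3-sigma check of uniformity
  freq <- table(factor(s1, levels = vic))
  p0 <- 1 / length(vic)
  se <- sqrt(p0 * (1 - p0) / 6000)
  expect_true(all(abs(freq / 6000 - p0) < 4 * se))
  expect_error(functional_vicinity_residue_sample(st, 15, radius = -1,
                                                  n = 10, dmat = dm))
})

test_that("signed-rank test matches exact enumeration", {
  r <- wilcoxon_signed_rank(c(0.3, 0.5, 0.2, 0.4, 0.1))
  expect_equal(r$p_value, 2 / 32)            # all-positive, n = 5

  r2 <- wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3) + 0)
  expect_equal(r2$p_value, 1)                # antisymmetric differences

  set.seed(61)
  for (k in 1:8) {
    d <- round(stats::rnorm(8), 3)
    d <- d[d != 0]
    if (length(d) < 5 || any(duplicated(abs(d)))) next
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, oracle_signed_rank_p(d), tolerance = 1e-9)
  }
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4)), "at least 5")
})

test_that("rank-sum test matches exact permutation enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)               # 2 / C(6,3)

  set.seed(62)
  for (k in 1:8) {
    a <- round(stats::rnorm(5), 3); b <- round(stats::rnorm(6) + 0.5, 3)
    if (any(duplicated(c(a, b)))) next
    got <- mann_whitney_u(a, b)
    expect_equal(got$p_value, oracle_ranksum_p(a, b), tolerance = 1e-9)
  }
  expect_error(mann_whitney_u(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("z-score test is one-sided against the null spread", {
  nd <- new_null_distribution("x", c(rep(0.2, 20), rep(0.4, 20)), 1)
  m <- mean(nd$samples); s <- stats::sd(nd$samples)
  expect_equal(zscore_test(m, nd)$statistic, 0)
  expect_equal(zscore_test(m, nd)$p_value, 0.5)
  expect_equal(zscore_test(m + 2 * s, nd)$statistic, 2)
  # matches recomputation from raw samples
  set.seed(77)
  nd2 <- new_null_distribution("y", stats::rnorm(500, 5, 2), 1)
  zt <- zscore_test(7, nd2)
  expect_equal(zt$statistic,
               (7 - mean(nd2$samples)) / stats::sd(nd2$samples))
  expect_equal(zt$p_value, stats::pnorm(zt$statistic, lower.tail = FALSE))
  expect_error(zscore_test(1, new_null_distribution("z", rep(1, 50), 1)),
               "zero variance")
  expect_error(zscore_test(1, new_null_distribution("z", stats::rnorm(10),
                                                    1)), "n < 30")
})

test_that("Fisher/BH enrichment matches hypergeometric enumeration", {
  r <- fisher_bh_enrichment(list(even = matrix(5, 2, 2)))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  expect_false(r$significant)

  set.seed(9)
  tabs <- lapply(1:10, function(i)
    matrix(stats::rpois(4, lambda = c(8, 4, 3, 12)) , 2, 2))
  names(tabs) <- paste0("u", 1:10)
  got <- fisher_bh_enrichment(tabs)
  for (i in 1:10)
    expect_equal(got$p[i], oracle_fisher_p(tabs[[i]]), tolerance = 1e-7)
  # BH step-up closed form and invariants
  expect_equal(got$q, stats::p.adjust(got$p, "BH"))
  expect_true(all(got$q >= got$p - 1e-12))
  ord <- order(got$p)
  expect_true(all(diff(got$q[ord]) >= -1e-12))
  m <- 5
  ps <- 0.05 * (1:m) / m
  q_hand <- rev(cummin(rev(ps * m / (1:m))))
  got2 <- fisher_bh_enrichment(data.frame(a = c(9, 8, 7, 6, 5), b = 1:5,
                                          c = 1:5, d = c(9, 8, 7, 6, 5)))
  expect_equal(stats::p.adjust(ps, "BH"), q_hand)
  expect_error(fisher_bh_enrichment(list(matrix(c(-1, 2, 3, 4), 2))),
               "negative")
  # Haldane correction only fires on zero cells, flagged
  rz <- fisher_bh_enrichment(list(matrix(c(5, 0, 2, 7), 2, byrow = TRUE)))
  expect_true(rz$haldane)
  expect_equal(rz$odds_ratio, (5.5 * 7.5) / (0.5 * 2.5))
})

test_that("empirical p-values use the add-one estimator", {
  nd <- new_null_distribution("d", c(1, 2, 3, 4, 5, 6, 7, 8, 9), 1)
  expect_equal(as.numeric(empirical_pvalue(2.5, nd, "less")), 3 / 10)
  expect_equal(as.numeric(empirical_pvalue(0, nd, "less")), 1 / 10)
  expect_equal(attr(empirical_pvalue(0, nd, "less"), "label"),
               sprintf("<%g", 1 / 9))
  expect_equal(as.numeric(empirical_pvalue(5, nd, "less")), 6 / 10)
  big <- new_null_distribution("d", stats::runif(10000, 1, 2), 1)
  expect_equal(attr(empirical_pvalue(0.5, big, "less"), "label"),
               "<0.0001")
})

test_that("null generators are reproducible and seed-indistinguishable", {
  st <- helix(40, seed = 3)
  dm <- residue_distance_matrix(st)
  sasa <- compute_rasa(st)
  a <- random_region_null(st, 10, sasa, n = 5000, seed = 11)
  b <- random_region_null(st, 10, sasa, n = 5000, seed = 11)
  expect_identical(a$samples, b$samples)
  c1 <- random_region_null(st, 10, sasa, n = 5000, seed = 12)
  ks <- suppressWarnings(stats::ks.test(a$samples, c1$samples))
  expect_gt(ks$p.value, 0.01)
})
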