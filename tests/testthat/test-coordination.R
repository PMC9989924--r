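test_that("pearson_r matches the direct-formula oracle and its contracts", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  expect_equal(pearson_r(x, y), 0.8285714, tolerance = 1e-7)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)

  # symmetry + invariance under positive affine maps, randomized cases
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(8)
    b <- rnorm(8)
    expect_equal(pearson_r(a, b), pearson_r(b, a))
    expect_equal(pearson_r(2.5 * a + 7, b), pearson_r(a, b), tolerance = 1e-12)
    expect_equal(pearson_r(a, 0.1 * b - 3), pearson_r(a, b), tolerance = 1e-12)
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }

  expect_error(pearson_r(1:4, 1:5), "length mismatch")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "constant")
})

test_that("pearson_pvalue matches numeric t-integration over a grid", {
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_equal(pearson_pvalue(1, 5), 0)
  expect_equal(pearson_pvalue(-1, 5), 0)
  expect_equal(pearson_pvalue(0.8285714, 6), 0.04156, tolerance = 1e-4)

  for (n in c(4, 6, 12, 30)) {
    for (r in c(-0.95, -0.5, -0.1, 0.05, 0.3, 0.7, 0.99)) {
      expect_equal(pearson_pvalue(r, n), oracle_pvalue(r, n),
                   tolerance = 1e-8)
    }
  }
  expect_error(pearson_pvalue(0.5, 2), "n must be")
})

test_that("pearson_pvalue agrees with exhaustive permutation at n = 5", {
  # all 120 permutations of y give the exact permutation null; the t-based
  # p should land within coarse Monte-Carlo-style agreement of it
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  set.seed(3)
  for (rep in 1:3) {
    x <- rnorm(5)
    y <- rnorm(5)
    r_obs <- abs(pearson_r(x, y))
    null_r <- vapply(perms(y), function(p) abs(oracle_pearson(x, p)),
                     numeric(1))
    p_perm <- mean(null_r >= r_obs - 1e-12)
    expect_lt(abs(pearson_pvalue(pearson_r(x, y), 5) - p_perm), 0.12)
  }
})

test_that("critical_r inverts pearson_pvalue and is monotone in n", {
  expect_equal(critical_r(6, 0.05), 0.8114014, tolerance = 1e-6)
  expect_equal(critical_r(6, 0.05), oracle_critical_r(6, 0.05),
               tolerance = 1e-8)
  for (n in c(4, 6, 10, 50)) {
    for (alpha in c(0.001, 0.01, 0.05, 0.5)) {
      expect_equal(pearson_pvalue(critical_r(n, alpha), n), alpha,
                   tolerance = 1e-9)
    }
  }
  expect_lt(critical_r(10, 0.05), critical_r(6, 0.05))
  expect_lt(critical_r(6, 0.999), 0.01)
  expect_error(critical_r(6, 1.5), "alpha")
})

test_that("correlation_profile has unit self-entry and oracle-equal entries", {
  f1 <- get_F1()$matrix
  prof <- correlation_profile(f1, "RASSF1")
  expect_length(prof$r_values, length(f1$gene_ids))
  expect_identical(unname(prof$r_values["RASSF1"]), 1)
  expect_true(all(abs(prof$r_values) <= 1))

  # entries match a brute-force per-pair recomputation
  i <- match("RASSF1", f1$gene_ids)
  for (g in c("HSPA5", "DDIT3", "DDIT3alt", "BG_0001", "BG_1999")) {
    expect_equal(unname(prof$r_values[g]),
                 oracle_pearson(f1$values[i, ], f1$values[g, ]),
                 tolerance = 1e-12)
  }

  # planted target correlates with all 6 module genes above critical r
  rcrit <- critical_r(f1$n_samples, 0.05)
  expect_true(all(prof$r_values[upr_panel] > rcrit))

  expect_error(correlation_profile(f1, "NOPE"), "NOPE")
})

test_that("coordination excludes self-entries, is symmetric, matches oracle", {
  fake_profile <- function(gene, ids, r) {
    structure(list(gene = gene, r_values = setNames(r, ids), n_samples = 12),
              class = "correlation_profile")
  }
  ids <- c("A", "B", "P", "Q", "R")
  a <- fake_profile("A", ids, c(1, 0.2, 0.9, 0.1, -0.5))
  b <- fake_profile("B", ids, c(0.2, 1, -0.9, -0.1, 0.5))
  res <- coordination(a, b)
  expect_equal(res$coordination_r, -1)
  expect_equal(res$n_points, 3)
  expect_equal(coordination(a, a)$coordination_r, 1)

  f1 <- get_F1()$matrix
  pa <- correlation_profile(f1, "HSPA5")
  pb <- correlation_profile(f1, "RASSF1")
  res <- coordination(pa, pb)
  expect_equal(res$coordination_r, coordination(pb, pa)$coordination_r)
  expect_equal(res$n_points, length(f1$gene_ids) - 2)

  R <- oracle_profile_matrix(f1$values)
  ia <- match("HSPA5", f1$gene_ids)
  ib <- match("RASSF1", f1$gene_ids)
  expect_equal(res$coordination_r, oracle_coordination(R, ia, ib),
               tolerance = 1e-10)
  expect_equal(res$p_analytic,
               pearson_pvalue(res$coordination_r, res$n_points))

  bad <- fake_profile("B", rev(ids), c(0.5, -0.1, -0.9, 1, 0.2))
  expect_error(coordination(a, bad), "mismatch")
})

test_that("permutation_pvalue is bounded, seeded and sensitive", {
  f1 <- get_F1()$matrix
  res <- permutation_pvalue(f1, "RASSF1", "HSPA5", n_permutations = 99,
                            seed = 17)
  expect_gte(res$p_permutation, 1 / 100)
  expect_lte(res$p_permutation, 1)
  # a strongly coordinated planted pair should be at the estimator floor
  expect_equal(res$p_permutation, 1 / 100)

  res2 <- permutation_pvalue(f1, "RASSF1", "HSPA5", n_permutations = 99,
                             seed = 17)
  expect_identical(res$p_permutation, res2$p_permutation)
  expect_error(permutation_pvalue(f1, "RASSF1", "HSPA5",
                                  n_permutations = 50, seed = 1), ">= 99")
  expect_error(permutation_pvalue(f1, "RASSF1", "HSPA5",
                                  n_permutations = 99), "seed")
})

test_that("coordination_scan ranks, excludes the panel and matches spot checks", {
  f1 <- get_F1()$matrix
  scan <- get_F1_scan()
  df <- scan$candidates
  expect_false(any(upr_panel %in% df$candidate))
  expect_equal(nrow(df), length(f1$gene_ids) - length(upr_panel))
  coord_cols <- paste0("coord_", upr_panel)
  expect_true(all(abs(as.matrix(df[coord_cols])) <= 1))
  expect_equal(df$mean_coordination, rowMeans(df[coord_cols]))
  expect_equal(df$min_coordination, apply(df[coord_cols], 1, min))

  # rank 1 holds the maximal aggregate and ranks are dense
  expect_equal(df$rank[1], 1)
  expect_equal(max(df$mean_coordination), df$mean_coordination[1])
  expect_true(all(diff(df$rank) %in% c(0, 1)))
  expect_equal(df$candidate[1], "RASSF1")

  # per-pair values match the brute-force oracle for a handful of candidates
  R <- oracle_profile_matrix(f1$values)
  for (cand in c("RASSF1", "DDIT3alt", "BG_0100")) {
    row <- df[df$candidate == cand, ]
    ic <- match(cand, f1$gene_ids)
    for (p in upr_panel) {
      ip <- match(p, f1$gene_ids)
      expect_equal(row[[paste0("coord_", p)]],
                   oracle_coordination(R, ic, ip), tolerance = 1e-10)
    }
  }
  expect_error(coordination_scan(f1, c("HSPA5", "GHOST")), "GHOST")
})

test_that("correlated_gene_set applies the threshold, direction and ordering", {
  f1 <- get_F1()$matrix
  gs <- correlated_gene_set(f1, "RASSF1", alpha = 0.05)
  expect_false("RASSF1" %in% gs$gene)
  expect_true(all(gs$r > 0))
  expect_true(all(gs$p < 0.05))
  expect_true(!is.unsorted(rev(gs$r)))

  # member count equals a brute-force per-gene test
  i <- match("RASSF1", f1$gene_ids)
  r_all <- vapply(seq_along(f1$gene_ids), function(j) {
    oracle_pearson(f1$values[i, ], f1$values[j, ])
  }, numeric(1))
  p_all <- vapply(r_all, oracle_pvalue, numeric(1), n = f1$n_samples)
  brute <- sum(p_all < 0.05 & r_all > 0 & f1$gene_ids != "RASSF1")
  expect_equal(nrow(gs), brute)

  # alpha = 1 with direction positive degenerates to { R > 0 }
  gs_all <- correlated_gene_set(f1, "RASSF1", alpha = 1)
  expect_equal(nrow(gs_all), sum(r_all > 0 & f1$gene_ids != "RASSF1"))
  # direction = both admits negative correlations too
  gs_both <- correlated_gene_set(f1, "RASSF1", alpha = 0.05,
                                 direction = "both")
  expect_gte(nrow(gs_both), nrow(gs))
  expect_error(correlated_gene_set(f1, "GHOST"), "GHOST")
})
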