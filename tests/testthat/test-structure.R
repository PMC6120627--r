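test_that("Euclidean distances satisfy the basic identities", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- as.matrix(distance_matrix(m))
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  # permuting site columns leaves distances unchanged
  expect_equal(distance_matrix(m[, 2:1]), distance_matrix(m))
  expect_error(distance_matrix(rbind(c(1, NA))), "missing")
})

test_that("tree cutting partitions into exactly k groups", {
  set.seed(2)
  m <- matrix(rnorm(40), 8)
  tree <- hcluster(distance_matrix(m))
  expect_equal(length(unique(cut_tree(tree, 1))), 1)
  expect_equal(length(unique(cut_tree(tree, 8))), 8)
  expect_error(cut_tree(tree, 9), "exceeds")
})

test_that("separable populations are recovered exactly at k = 2", {
  cfg <- sim_config(n_accessions = 12, subgenome_length = 4000,
                    conversion_rate = 1, epiallele_rate = 0.4, seed = 77)
  g <- simulate_genome(cfg)
  p <- simulate_panel(cfg, g, pop_scatter = 0)  # zero within-pop variance
  m <- identify_smps(p$reports)
  labels <- cut_tree(hcluster(distance_matrix(t(m$codes))), 2)
  expect_equal(adjusted_rand_index(labels, p$truth$population_labels), 1)
})

test_that("adjusted Rand index matches its defining extremes", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(6)
  vals <- replicate(50, adjusted_rand_index(sample(1:3, 30, TRUE),
                                            sample(1:3, 30, TRUE)))
  expect_lt(abs(mean(vals)), 0.1)  # ~0 for independent labelings
})

test_that("Mantel statistic is 1 for identical or rescaled matrices", {
  set.seed(14)
  m <- matrix(rnorm(60), 10)
  d1 <- distance_matrix(m)
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)$r, 1)
  d2 <- distance_matrix(matrix(rnorm(33), 11))
  expect_error(mantel_test(d1, d2), "different sizes")
})

test_that("Mantel p is roughly uniform under the null", {
  set.seed(26)
  ps <- replicate(60, {
    d1 <- distance_matrix(matrix(rnorm(8 * 5), 8))
    d2 <- distance_matrix(matrix(rnorm(8 * 5), 8))
    mantel_test(d1, d2, n_perm = 99)$p
  })
  # super-uniformity at the 0.1 level within Monte Carlo error
  expect_lte(mean(ps <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / 60))
  expect_gt(mean(ps), 0.3)
})

test_that("runs test reproduces the closed-form Z values", {
  alt <- rep(c("A", "B"), 5)          # ABAB...: R = 10
  out <- runs_test(alt)
  expect_equal(out$runs, 10)
  expect_equal(out$mu, 6)
  expect_equal(out$sigma, 1.4907, tolerance = 1e-4)
  expect_equal(out$Z, 2.683, tolerance = 1e-3)
  blocks <- rep(c("A", "B"), each = 5)  # AAAAABBBBB: R = 2
  expect_equal(runs_test(blocks)$Z, -2.683, tolerance = 1e-3)
  # reversal preserves the run count, hence Z
  expect_equal(runs_test(rev(alt))$Z, out$Z)
  expect_error(runs_test(rep("A", 5)), "two labels")
})

test_that("runs-test moments match exact enumeration for n <= 12", {
  for (cfg in list(c(3, 3), c(5, 5), c(4, 8), c(2, 9))) {
    mom <- runs_enum_moments(cfg[1], cfg[2])
    out <- runs_test(rep(c("A", "B"), cfg))  # any sequence: moments only
    expect_equal(out$mu, mom$mean, tolerance = 1e-12,
                 info = paste(cfg, collapse = ","))
    expect_equal(out$sigma^2, mom$var, tolerance = 1e-9,
                 info = paste(cfg, collapse = ","))
  }
})

test_that("geography concordance counts majority regions", {
  out <- geography_concordance(rep(1, 6), rep("r1", 6))
  expect_equal(out$majority_fraction, 1)
  # region split 1/1 across two clusters: modal share 0.5 counts under >=
  out <- geography_concordance(c(1, 2), c("r1", "r1"))
  expect_equal(out$per_region$modal_share, 0.5)
  expect_equal(out$majority_fraction, 1)
})

test_that("geography-linked epialleles beat permuted labels", {
  cl <- clean_panel()
  p <- cl$panel
  m <- identify_smps(p$reports)
  labels <- cut_tree(hcluster(distance_matrix(t(m$codes))), 2)
  out <- geography_concordance_test(labels, p$accessions$region,
                                    n_perm = 199, seed = 3)
  expect_lt(out$p, 0.05)
})

test_that("AU support is deterministic and saturates for clear clades", {
  set.seed(19)
  m <- rbind(matrix(rnorm(4 * 30, 0), 4, 30),
             matrix(rnorm(4 * 30, 8), 4, 30))
  rownames(m) <- paste0("s", 1:8)
  s1 <- au_support(m, n_boot = 500, seed = 10)
  s2 <- au_support(m, n_boot = 500, seed = 10)
  expect_equal(s1$support, s2$support)
  # the two true 4-leaf clades appear in every bootstrap
  big <- s1$support[nchar(s1$support$leaves) >= 10, ]
  clade_keys <- c(paste(sort(paste0("s", 1:4)), collapse = "|"),
                  paste(sort(paste0("s", 5:8)), collapse = "|"))
  found <- s1$support[s1$support$leaves %in% clade_keys, ]
  expect_equal(nrow(found), 2)
  expect_true(all(found$bp == 1))
  expect_true(all(found$au >= 0.95))
})

test_that("random data yields unsupported fine-scale clades", {
  set.seed(33)
  m <- matrix(rnorm(10 * 40), 10, 40)
  s <- au_support(m, n_boot = 500, seed = 4)
  nontrivial <- s$support[s$support$node < nrow(m) - 1, ]
  expect_lt(mean(nontrivial$au), 0.95)
})
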