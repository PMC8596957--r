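toy_table <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    t1 = c(10L, 0L, 4L), t2 = c(10L, 10L, 4L), t3 = c(0L, 10L, 4L),
    t4 = c(5L, 5L, 4L)
  )
}

test_that("Shannon diversity matches the defining formula in any base", {
  expect_equal(shannon_index(c(5, 5, 5, 5), base = 2), 2)
  expect_equal(shannon_index(c(7, 0, 0)), 0)
  expect_equal(shannon_index(c(1, 2, 3), base = exp(1)),
               oracle_shannon(c(1, 2, 3), base = exp(1)))
  expect_equal(shannon_index(c(3, 9, 1), base = 2),
               oracle_shannon(c(3, 9, 1), base = 2))
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Chao1 handles singleton/doubleton structure in both forms", {
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4)) # S_obs 10, F1 4, F2 2
  expect_equal(chao1_index(x), 10 + 4 * 3 / (2 * 3))
  expect_equal(chao1_index(x, bias_corrected = FALSE), 10 + 16 / 4)
  no_singletons <- c(rep(3, 6))
  expect_equal(chao1_index(no_singletons), 6)
  # bias-corrected form stays defined without doubletons
  f2_zero <- c(1, 1, 1, 5)
  expect_equal(chao1_index(f2_zero), 4 + 3 * 2 / 2)
  # agrees with the independent vegan estimator
  set.seed(3)
  for (rep in 1:10) {
    y <- rpois(30, 2)
    if (sum(y) == 0) next
    expect_equal(chao1_index(y),
                 unname(vegan::estimateR(y)["S.chao1"]))
  }
})

test_that("Chao1 never falls below observed richness", {
  set.seed(21)
  for (rep in 1:50) {
    y <- rpois(40, runif(1, 0.5, 4))
    expect_gte(chao1_index(y), sum(y > 0))
  }
})

test_that("Faith's PD equals the union of root paths on random trees", {
  set.seed(13)
  for (rep in 1:10) {
    tree <- ape::rcoal(8)
    present <- sample(tree$tip.label, sample(2:8, 1))
    expect_equal(faith_pd(tree, present), oracle_faith_pd(tree, present))
  }
  tree <- ape::rcoal(8)
  # all leaves present: the whole tree's branch length
  expect_equal(faith_pd(tree, tree$tip.label), sum(tree$edge.length))
  # star tree with unit branches: k leaves give PD k
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  expect_equal(faith_pd(star, star$tip.label[1:4]), 4)
  expect_error(faith_pd(tree, "nonexistent"), "not in tree")
  expect_error(faith_pd(tree, character(0)), "no taxa")
})

test_that("Faith's PD is monotone under taxon addition", {
  set.seed(17)
  tree <- ape::rcoal(10)
  tips <- sample(tree$tip.label)
  pd_seq <- vapply(seq_along(tips),
                   function(k) faith_pd(tree, tips[1:k]), numeric(1))
  expect_true(all(diff(pd_seq) >= -1e-12))
})

test_that("Bray-Curtis follows its definition with metric bounds", {
  tab <- tibble::tibble(sample_id = c("a", "b"),
                        t1 = c(1, 0), t2 = c(1, 1), t3 = c(0, 1))
  d <- bray_curtis(tab)
  expect_equal(as.numeric(d), 0.5)
  same <- tibble::tibble(sample_id = c("a", "b"), t1 = c(3, 3), t2 = c(1, 1))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disjoint <- tibble::tibble(sample_id = c("a", "b"), t1 = c(3, 0), t2 = c(0, 7))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  set.seed(19)
  m <- matrix(rpois(50, 4), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:10)))
  d5 <- as.matrix(bray_curtis(m))
  expect_true(all(diag(d5) == 0))
  expect_equal(d5, t(d5))
  expect_true(all(d5 >= 0 & d5 <= 1))
  # pairwise values agree with the hand formula
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d5[i, j], oracle_bray(m[i, ], m[j, ]))
  }
  expect_error(bray_curtis(m[1, , drop = FALSE]), "at least 2")
  m0 <- m; m0[1, ] <- 0
  expect_error(bray_curtis(m0), "zero total")
})

test_that("rarefaction hits the exact depth, preserves proportions in expectation", {
  tab <- toy_table()
  r <- rarefy_counts(tab, depth = 12, seed = 4)
  expect_equal(unname(rowSums(otu_matrix(r))), rep(12, 3))
  # depth equal to the sample total leaves the sample unchanged
  full <- rarefy_counts(tab[3, ], depth = 16, seed = 1)
  expect_equal(otu_matrix(full)["s3", ], otu_matrix(tab[3, ])["s3", ])
  # samples below depth are dropped with a warning
  expect_warning(r2 <- rarefy_counts(tab, depth = 17, seed = 1), "dropping")
  expect_equal(nrow(r2), 2)
  expect_error(rarefy_counts(tab, depth = 0), "> 0")
  # mean subsampled proportions approach the input proportions
  x <- c(a = 400L, b = 100L, c = 0L)
  tab1 <- tibble::tibble(sample_id = "s", a = 400L, b = 100L, c = 0L)
  sums <- colMeans(do.call(rbind, lapply(1:300, function(s) {
    otu_matrix(rarefy_counts(tab1, depth = 50, seed = s))[1, ]
  })))
  expect_equal(unname(sums / 50), c(0.8, 0.2, 0), tolerance = 0.02)
})

test_that("rarefaction is reproducible under a seed", {
  tab <- toy_table()
  expect_identical(rarefy_counts(tab, 12, seed = 99),
                   rarefy_counts(tab, 12, seed = 99))
})

test_that("the alpha panel is internally consistent across indices", {
  com <- make_community(list(n_samples = 3, n_taxa = 20), seed = 8)
  a <- alpha_diversity(com$table, com$tree)
  expect_equal(nrow(a), 6)
  expect_true(all(a$chao1 >= a$observed_species))
  expect_true(all(a$shannon >= 0))
  expect_true(all(a$faith_pd > 0))
  no_tree <- alpha_diversity(com$table)
  expect_true(all(is.na(no_tree$faith_pd)))
})

test_that("NMDS recovers exactly embeddable configurations with near-zero stress", {
  set.seed(23)
  pts <- matrix(rnorm(16), ncol = 2)
  d <- dist(pts)
  ord <- nmds_ordination(d, k = 2, seed = 7)
  expect_lt(ord$stress, 0.01)
  expect_equal(colMeans(as.matrix(ord$points[, c("NMDS1", "NMDS2")])),
               c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
  # three points always embed exactly in the plane
  d3 <- dist(matrix(rnorm(6), ncol = 2))
  expect_lt(nmds_ordination(d3, k = 2, seed = 7, n_restarts = 5)$stress, 1e-3)
  expect_error(nmds_ordination(d3, k = 3), "smaller than")
})

test_that("NMDS is reproducible under a fixed seed", {
  d <- dist(matrix(rnorm(20, sd = 2), ncol = 2))
  o1 <- nmds_ordination(d, seed = 31)
  o2 <- nmds_ordination(d, seed = 31)
  expect_identical(o1$points, o2$points)
  expect_identical(o1$stress, o2$stress)
})

test_that("PERMANOVA statistics match the brute-force partition of squares", {
  set.seed(29)
  m <- matrix(rpois(5 * 6, 5), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:6)))
  d <- bray_curtis(m)
  groups <- c("a", "a", "b", "b", "b")
  fit <- permanova(d, groups, n_permutations = 199, seed = 3)
  oracle <- oracle_permanova_stats(d, groups)
  expect_equal(fit$r_squared, oracle$r_squared)
  expect_equal(fit$pseudo_f, oracle$pseudo_f)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_gte(fit$p_value, 1 / 200)
  expect_error(permanova(d, rep("a", 5), 99), "2 groups")
})

test_that("well-separated clusters reach the minimal attainable p-value", {
  # enough samples per group that a random permutation essentially never
  # reproduces the observed partition
  com <- make_community(list(n_samples = 10, dominance_abundance = 0.99,
                             concentration = 500), seed = 12)
  d <- bray_curtis(com$table)
  grp <- com$metadata$group
  fit <- permanova(d, grp, n_permutations = 999, seed = 2)
  expect_equal(fit$p_value, 1 / 1000)
})
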