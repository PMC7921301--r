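test_that("standardization matches hand z-scores and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_matrix(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  z2 <- standardize_matrix(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  m2 <- cbind(a = c(1, 2, 3), flat = c(4, 4, 4))
  expect_error(standardize_matrix(m2), "flat")
})

test_that("well-separated archetypes select k = 2 with exact assignments", {
  m <- archetype_matrix(sep = 6)
  truth <- rep(1:2, each = 10)
  sel <- select_clustering(m, k_range = 2:5)
  expect_equal(sel$best$k, 2)
  expect_true(sel$best$silhouette >= -1 && sel$best$silhouette <= 1)
  expect_gt(sel$best$silhouette, 0.7)
  # exact recovery (up to label permutation)
  expect_equal(mclust::adjustedRandIndex(sel$best$assignments, truth), 1)

  # all three metrics prefer k = 2 within the hierarchical family
  h <- sel$solutions[sel$solutions$method == "hierarchical", ]
  expect_equal(h$k[which.max(h$silhouette)], 2)
  expect_equal(h$k[which.min(h$connectivity)], 2)
  expect_equal(h$k[which.max(h$dunn)], 2)
})

test_that("three archetypes maximize the Dunn index at k = 3", {
  set.seed(42)
  m <- rbind(matrix(rnorm(30), 5), matrix(rnorm(30, 8), 5),
             matrix(rnorm(30, 16), 5))
  colnames(m) <- paste0("t", 1:6)
  rownames(m) <- paste0("g", 1:15)
  sel <- select_clustering(m, methods = "hierarchical", k_range = 2:5)
  s <- sel$solutions
  expect_equal(s$k[which.max(s$dunn)], 3)
})

test_that("a single homogeneous cloud gives weak silhouettes", {
  set.seed(5)
  m <- matrix(rnorm(120), 20)
  colnames(m) <- paste0("t", 1:6)
  rownames(m) <- paste0("g", 1:20)
  sel <- select_clustering(m, methods = "hierarchical", k_range = 2:3)
  expect_lt(max(sel$solutions$silhouette), 0.3)
})

test_that("Ward merge heights are monotone and order does not matter", {
  m <- archetype_matrix(sep = 4, seed = 7)
  sel <- select_clustering(m, methods = "hierarchical")
  expect_true(all(diff(sel$linkage$height) >= -1e-12))

  perm <- sample(nrow(m))
  sel2 <- select_clustering(m[perm, ], methods = "hierarchical")
  a1 <- sel$best$assignments
  a2 <- sel2$best$assignments[match(rownames(m), rownames(m)[perm])]
  expect_equal(mclust::adjustedRandIndex(a1, a2), 1)
})

test_that("cluster trait comparisons route through the documented test choices", {
  set.seed(23)
  g1 <- rnorm(12, 10, 1)
  means <- data.frame(
    same = c(g1, g1),                       # identical distributions
    shifted = c(rnorm(12, 0, 1), rnorm(12, 5, 1)),   # 5 SD apart
    heavy = c(rcauchy(12), rcauchy(12)))    # fails normality
  assignments <- rep(1:2, each = 12)
  res <- compare_cluster_traits(means, assignments)
  expect_equal(res$p_value[res$trait == "same"], 1, tolerance = 1e-9)
  expect_identical(res$stars[res$trait == "same"], "")
  expect_lt(res$p_value[res$trait == "shifted"], 0.001)
  expect_identical(res$stars[res$trait == "shifted"], "***")
  expect_identical(res$test[res$trait == "heavy"], "mann_whitney")
  expect_true(res$test[res$trait == "shifted"] %in%
                c("student_t", "welch_t"))

  expect_error(compare_cluster_traits(means, rep(1:3, each = 8)),
               "exactly 2")
  expect_error(compare_cluster_traits(means[1:4, ], c(1, 1, 2, 2)),
               "at least 3")
})

test_that("clustering trait set excludes subsample and collinear traits", {
  expect_identical(sort(cluster_traits()),
                   sort(c("dw", "a_op", "wue_op", "c_mass", "cn_ratio",
                          "lma", "tiller_count", "la_tiller")))
  expect_false(any(c("vcmax", "jmax", "rd", "g_sop", "n_mass") %in%
                     cluster_traits()))
  plants <- generate_plants(small_config(), seed = 2)
  m <- genotype_trait_matrix(plants, "ambient")
  expect_identical(colnames(m), cluster_traits())
  expect_identical(nrow(m), 12L)
})
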