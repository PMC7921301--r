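#' Traits used for genotype clustering
#'
#' The clustering trait set: whole-plant and leaf traits available for
#' every plant. A-Ci-derived parameters (Vcmax, Jmax, Rd, and the
#' light-saturated rate) are excluded because they exist only for a
#' measured subsample, and stomatal conductance and N_mass are excluded
#' for collinearity with WUE_op and the C:N ratio.
#'
#' @return Character vector of trait column names.
#' @export
cluster_traits <- function() {
  c("dw", "a_op", "wue_op", "c_mass", "cn_ratio", "lma",
    "tiller_count", "la_tiller")
}

#' Genotype x trait matrix of means
#'
#' Per-genotype trait means for one treatment, restricted to genotypes
#' with complete means over the requested traits.
#'
#' @param plants Per-plant table.
#' @param treatment Treatment to subset on (NULL = all rows).
#' @param traits Trait columns (default [cluster_traits()]).
#' @return Numeric matrix, genotypes in rows.
#' @export
genotype_trait_matrix <- function(plants, treatment = NULL,
                                  traits = cluster_traits()) {
  d <- if (is.null(treatment)) plants else
    plants[plants$treatment == treatment, ]
  g <- dplyr::summarise(dplyr::group_by(d, .data$genotype_id),
                        dplyr::across(dplyr::all_of(traits),
                                      ~ mean(.x, na.rm = TRUE)),
                        .groups = "drop")
  m <- as.matrix(g[, traits])
  rownames(m) <- g$genotype_id
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Z-score standardization of a trait matrix
#'
#' Centers each column to mean 0 and scales to sample SD 1. A constant
#' column is an error naming the trait.
#'
#' @param m Numeric matrix (genotypes x traits), >= 2 rows.
#' @return The standardized matrix.
#' @export
standardize_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 genotypes", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("constant trait column: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scale(m)[, , drop = FALSE]
}

#' Connectivity score of a clustering
#'
#' For each observation, its `L` nearest neighbours are examined; a
#' neighbour in a different cluster adds `1/j` (j = neighbour rank).
#' Lower is better (0 = every neighbourhood is cluster-pure).
#'
#' @param dist_mat A `dist` object or distance matrix.
#' @param assignments Integer cluster labels.
#' @param L Neighbourhood size (default 10).
#' @return Non-negative connectivity score.
#' @export
connectivity_score <- function(dist_mat, assignments, L = 10) {
  dm <- as.matrix(dist_mat)
  n <- nrow(dm)
  L <- min(L, n - 1)
  total <- 0
  for (i in seq_len(n)) {
    nn <- order(dm[i, -i]) # neighbour ranks among the others
    others <- seq_len(n)[-i][nn]
    mismatch <- assignments[others[seq_len(L)]] != assignments[i]
    total <- total + sum(1 / seq_len(L)[mismatch])
  }
  total
}

#' Dunn index of a clustering
#'
#' Minimum between-cluster distance divided by maximum within-cluster
#' diameter; larger is better.
#'
#' @param dist_mat A `dist` object or distance matrix.
#' @param assignments Integer cluster labels.
#' @return The Dunn index.
#' @export
dunn_index <- function(dist_mat, assignments) {
  dm <- as.matrix(dist_mat)
  ks <- unique(assignments)
  min_between <- Inf
  max_within <- 0
  for (a in ks) {
    ia <- which(assignments == a)
    if (length(ia) > 1) {
      max_within <- max(max_within, max(dm[ia, ia]))
    }
    for (b in ks[ks > a]) {
      ib <- which(assignments == b)
      min_between <- min(min_between, min(dm[ia, ib, drop = FALSE]))
    }
  }
  if (max_within == 0) return(Inf)
  min_between / max_within
}

#' Select a clustering method and number of clusters
#'
#' Standardizes the genotype x trait matrix, then evaluates Ward
#' hierarchical clustering (Euclidean distances, Ward.D2 — the
#' Lance-Williams minimum-variance update on squared distances) and
#' k-means (25 restarts, seeded) for each k in `k_range` under three
#' internal validation metrics: connectivity (neighbourhood `L`), mean
#' silhouette width, and the Dunn index. Solutions are ranked by
#' silhouette (descending), ties broken by lower connectivity.
#'
#' @param m Genotype x trait matrix of means (raw; standardized
#'   internally).
#' @param methods Subset of `c("hierarchical", "kmeans")`.
#' @param k_range Candidate cluster counts (within \[2, n-1\]).
#' @param L Connectivity neighbourhood size.
#' @param seed Seed for the k-means restarts.
#' @return An object of class `cluster_selection`: tibble `solutions`
#'   (method, k, connectivity, silhouette, dunn, assignments list-col,
#'   rank), `best` (the top row's assignments etc.), `linkage` (the
#'   hclust tree), and the standardized matrix `z`.
#' @export
#' @examples
#' m <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 6), 10))
#' colnames(m) <- paste0("t", 1:4); rownames(m) <- paste0("g", 1:20)
#' sel <- select_clustering(m, k_range = 2:4)
#' sel$best$k
select_clustering <- function(m, methods = c("hierarchical", "kmeans"),
                              k_range = 2:6, L = 10, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  z <- standardize_matrix(m)
  n <- nrow(z)
  if (any(k_range >= n) || any(k_range < 2)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  dm <- stats::dist(z)
  hc <- stats::hclust(dm, method = "ward.D2")

  rows <- list()
  for (method in methods) {
    for (k in k_range) {
      assign <- if (method == "hierarchical") {
        stats::cutree(hc, k = k)
      } else {
        set.seed(seed)
        stats::kmeans(z, centers = k, nstart = 25)$cluster
      }
      sil <- mean(cluster::silhouette(assign, dm)[, "sil_width"])
      rows[[length(rows) + 1]] <- tibble::tibble(
        method = method, k = k,
        connectivity = connectivity_score(dm, assign, L),
        silhouette = sil,
        dunn = dunn_index(dm, assign),
        assignments = list(assign))
    }
  }
  sol <- dplyr::bind_rows(rows)
  ord <- order(-sol$silhouette, sol$connectivity)
  sol <- sol[ord, ]
  sol$rank <- seq_len(nrow(sol))
  best <- as.list(sol[1, c("method", "k", "connectivity", "silhouette",
                           "dunn")])
  best$assignments <- sol$assignments[[1]]
  structure(list(solutions = sol, best = best, linkage = hc, z = z),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("best clustering: %s, k = %d (silhouette %.3f, connectivity %.2f, Dunn %.3f)\n",
              x$best$method, x$best$k, x$best$silhouette,
              x$best$connectivity, x$best$dunn))
  invisible(x)
}

#' Per-trait comparison between two clusters
#'
#' For each trait, tests the difference between the two clusters'
#' genotype means with the assumption-driven test choice: Shapiro-Wilk
#' normality per cluster (alpha 0.05); both normal and Levene-equal
#' variances -> Student's t; both normal, unequal variances -> Welch's t;
#' any non-normal -> Mann-Whitney U.
#'
#' @param genotype_means Data frame / matrix of per-genotype trait means
#'   (rows aligned with `assignments`).
#' @param assignments Cluster labels with exactly 2 distinct values, each
#'   cluster >= 3 genotypes.
#' @param alpha Diagnostic significance level.
#' @return A tibble: `trait`, `mean_1`, `sd_1`, `mean_2`, `sd_2`,
#'   `test` (student_t / welch_t / mann_whitney), `p_value`, `stars`.
#' @export
compare_cluster_traits <- function(genotype_means, assignments,
                                   alpha = 0.05) {
  m <- as.data.frame(genotype_means)
  ks <- sort(unique(assignments))
  if (length(ks) != 2) stop("exactly 2 clusters required", call. = FALSE)
  if (min(table(assignments)) < 3) {
    stop("each cluster needs at least 3 genotypes", call. = FALSE)
  }
  i1 <- assignments == ks[1]
  i2 <- assignments == ks[2]
  rows <- lapply(names(m), function(tr) {
    x1 <- m[[tr]][i1]; x2 <- m[[tr]][i2]
    norm1 <- tryCatch(shapiro.test(x1)$p.value, error = function(e) 0)
    norm2 <- tryCatch(shapiro.test(x2)$p.value, error = function(e) 0)
    if (norm1 >= alpha && norm2 >= alpha) {
      lev <- car::leveneTest(c(x1, x2) ~ factor(rep(ks, c(length(x1), length(x2)))))
      if (lev[["Pr(>F)"]][1] >= alpha) {
        test <- "student_t"
        p <- stats::t.test(x1, x2, var.equal = TRUE)$p.value
      } else {
        test <- "welch_t"
        p <- stats::t.test(x1, x2, var.equal = FALSE)$p.value
      }
    } else {
      test <- "mann_whitney"
      p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
    }
    tibble::tibble(trait = tr, mean_1 = mean(x1), sd_1 = sd(x1),
                   mean_2 = mean(x2), sd_2 = sd(x2),
                   test = test, p_value = p,
                   stars = significance_stars(p))
  })
  dplyr::bind_rows(rows)
}
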