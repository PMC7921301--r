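test_that("treatment comparison recovers a configured effect and takes sane paths", {
  plants <- generate_plants(generator_config(), seed = 17)
  cmp <- compare_treatments(plants, "a_op")
  expect_gt(cmp$estimate, 0)
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$model_path %in% c("mixed", "robust_mixed"))
  expect_gt(cmp$df, 0)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  # raw mean gap near the configured +3.3 umol m-2 s-1
  gap <- diff(cmp$means$mean)
  se_gap <- sqrt(sum((cmp$means$sd / sqrt(cmp$means$n))^2))
  expect_lt(abs(gap - 3.3), 3 * se_gap)
})

test_that("degenerate inputs fall through to the regression path", {
  plants <- generate_plants(small_config(), seed = 9)
  # constant response: estimate 0 on the degenerate-variance path
  plants$flat <- 1.0
  cmp <- compare_treatments(plants, "flat")
  expect_equal(cmp$estimate, 0)
  expect_identical(cmp$model_path, "ols")
  expect_equal(cmp$p_value, 1)

  # genotype-free iid response: genotype variance ~0 -> plain regression
  set.seed(10)
  plants$iid <- rnorm(nrow(plants))
  cmp2 <- compare_treatments(plants, "iid")
  expect_true(cmp2$model_path %in% c("ols", "ols_hc"))
  expect_lt(cmp2$diagnostics$genotype_variance, 1e-6)

  expect_error(compare_treatments(plants[plants$treatment == "ambient", ],
                                  "dw"), "both treatments")
})

test_that("status-group contrasts detect a shifted group with BH adjustment", {
  plants <- generate_plants(small_config(), seed = 12)
  # an exchangeable trait with one status group pushed 5 SD up
  set.seed(120)
  plants$marker <- rnorm(nrow(plants), 10, 1)
  plants$marker[plants$status == "wild"] <-
    plants$marker[plants$status == "wild"] + 5
  res <- compare_status_groups(plants, "marker")
  amb <- res[res$treatment == "ambient", ]
  wild_contrasts <- grepl("wild", amb$contrast)
  expect_true(all(amb$p_adj[wild_contrasts] < 0.01))
  expect_true(all(amb$p_adj[!wild_contrasts] > 0.05))
  # BH never decreases p-values and respects the step-up ordering
  expect_true(all(amb$p_adj >= amb$p_value - 1e-15))
  expect_equal(amb$p_adj, p.adjust(amb$p_value, "BH"), tolerance = 1e-12)
})

test_that("ANCOVA recovers exact and null relationships with coherent R2", {
  plants <- generate_plants(small_config(), seed = 13)
  # exact line: slope recovered, marginal R2 -> 1
  plants$resp <- 2 * plants$tiller_count
  fr <- suppressMessages(fit_relationship(plants, "resp", "tiller_count"))
  expect_equal(fr$fits$slope, 2, tolerance = 1e-6)
  expect_equal(fr$fits$marginal_R2, 1, tolerance = 1e-6)

  # independent covariate: CIs cover zero at roughly nominal rate and
  # marginal R2 stays near zero (checked over repeated draws)
  set.seed(14)
  null_runs <- vapply(1:10, function(i) {
    plants$noise <- rnorm(nrow(plants))
    f <- fit_relationship(plants, "noise", "tiller_count")$fits
    c(covers = f$slope_lo < 0 && f$slope_hi > 0, r2 = f$marginal_R2)
  }, numeric(2))
  expect_gte(sum(null_runs["covers", ]), 8)
  expect_lt(mean(null_runs["r2", ]), 0.05)

  # invariants: 0 <= marginal <= conditional <= 1, affine-invariant
  fr3 <- fit_relationship(plants, "dw", "tiller_count", by_treatment = TRUE)
  expect_true(all(fr3$fits$marginal_R2 >= 0))
  expect_true(all(fr3$fits$marginal_R2 <= fr3$fits$conditional_R2 + 1e-9))
  expect_true(all(fr3$fits$conditional_R2 <= 1 + 1e-9))
  plants$tiller_resc <- 100 * plants$tiller_count + 7
  fr4 <- fit_relationship(plants, "dw", "tiller_resc", by_treatment = TRUE)
  expect_equal(fr4$fits$marginal_R2, fr3$fits$marginal_R2, tolerance = 1e-5)

  plants$const <- 5
  expect_error(fit_relationship(plants, "dw", "const"), "constant")
})

test_that("genotype responses and rank concordance match hand computations", {
  d <- tibble::tibble(
    genotype_id = rep(c("g1", "g2"), each = 4),
    treatment = rep(c("ambient", "ambient", "high_CO2", "high_CO2"), 2),
    dw = c(10, 12, 20, 24, 8, 8, 8, 8))
  r <- genotype_mean_responses(d, "dw")
  expect_equal(r$mean_ambient, c(11, 8))
  expect_equal(r$mean_high, c(22, 8))
  expect_equal(r$response_pct, c(100, 0))
  expect_equal(r$se_ambient, c(sd(c(10, 12)) / sqrt(2), 0))

  expect_equal(rank_concordance(1:5, 1:5 * 3)$rho, 1)
  expect_equal(rank_concordance(1:5, rev(1:5))$rho, -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4
  rc <- rank_concordance(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(rc$rho, 0.6, tolerance = 1e-12)
  expect_equal(rc$rank_r2, 0.36, tolerance = 1e-12)
  expect_error(rank_concordance(1:2, 1:2), "3 genotypes")
})

test_that("correlograms are symmetric, rank-invariant and honestly starred", {
  set.seed(15)
  n <- 500
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                      d = rnorm(n), e = rnorm(n))
  cg <- correlogram(d, letters[1:5])
  expect_identical(cg$rho, t(cg$rho))
  expect_equal(unname(diag(cg$rho)), rep(1, 5))
  off <- cg$rho[upper.tri(cg$rho)]
  expect_lt(max(abs(off)), 0.2)
  starred <- mean(cg$stars[upper.tri(cg$stars)] != "")
  expect_lt(starred, 0.31)  # ~5% expected among 10 cells

  # monotone transform leaves Spearman rho at 1
  d$amono <- exp(d$a)
  cg2 <- correlogram(d, c("a", "amono"))
  expect_equal(cg2$rho["a", "amono"], 1, tolerance = 1e-12)

  expect_error(correlogram(d[1:3, ], letters[1:3]), "5 complete")
})

test_that("neat delta-R2 matches a from-scratch all-subsets oracle", {
  set.seed(16)
  n <- 200
  # exactly orthogonal centred predictors via QR
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 4), n), scale = FALSE)))
  X <- Q %*% diag(4)
  colnames(X) <- paste0("p", 1:4)
  y <- X %*% c(3, -2, 1, 0) + rnorm(n)
  d <- tibble::as_tibble(as.data.frame(X))
  d$dw <- as.numeric(y)
  res <- neat_analysis(d, "dw", paste0("p", 1:4))

  # oracle: R2 of any subset from projection algebra on standardized data
  z <- scale(cbind(y, X))
  r2_of <- function(cols) {
    Xs <- z[, cols + 1, drop = FALSE]
    yh <- Xs %*% solve(crossprod(Xs), crossprod(Xs, z[, 1]))
    sum(yh^2) / sum(z[, 1]^2)
  }
  full <- r2_of(1:4)
  for (j in 1:4) {
    expect_equal(res$coefficients$delta_r2[j], full - r2_of(setdiff(1:4, j)),
                 tolerance = 1e-10)
    # orthogonal design: delta R2 equals the squared simple correlation
    expect_equal(res$coefficients$delta_r2[j],
                 cor(d[[paste0("p", j)]], d$dw)^2, tolerance = 1e-10)
  }

  # single predictor: delta R2 is the full R2
  res1 <- neat_analysis(d, "dw", "p1")
  expect_equal(res1$coefficients$delta_r2, res1$full_r2, tolerance = 1e-12)

  # near-duplicate -> VIF flag; exact duplicate -> error naming the pair
  d$p1b <- d$p1 + rnorm(n, 0, 1e-4)
  res2 <- neat_analysis(d, "dw", c("p1", "p1b", "p2"))
  expect_true(all(c("p1", "p1b") %in% res2$excluded$predictor) ||
                any(grepl("VIF", res2$excluded$reason)))
  d$p1c <- d$p1
  expect_error(neat_analysis(d, "dw", c("p1", "p1c", "p2")),
               "perfect collinearity.*p1")
})

test_that("germination tests agree with hand chi-square and enumeration", {
  same <- rbind(c(300, 100), c(300, 100))
  colnames(same) <- c("germinated", "failed")
  gt <- germination_test(same)
  expect_equal(gt$fisher_p, 1)
  expect_equal(gt$chi_sq, 0)

  tab <- rbind(c(450, 150), c(438, 162))
  colnames(tab) <- c("germinated", "failed")
  gt2 <- germination_test(tab)
  # hand chi-square: E = (444, 156) per row, X2 = 2*(36/444 + 36/156)
  expect_equal(gt2$chi_sq, 2 * (36 / 444 + 36 / 156), tolerance = 1e-12)
  expect_equal(gt2$chi_sq, 0.6238, tolerance = 1e-3)

  # exhaustive hypergeometric enumeration oracle for the extreme table
  ext <- rbind(c(10, 0), c(0, 10))
  colnames(ext) <- c("germinated", "failed")
  probs <- dhyper(0:10, 10, 10, 10)
  p_exact <- sum(probs[probs <= dhyper(10, 10, 10, 10) + 1e-12])
  expect_equal(germination_test(ext)$fisher_p, p_exact, tolerance = 1e-12)
  expect_equal(p_exact, 2 / choose(20, 10), tolerance = 1e-12)

  expect_error(germination_test(rbind(c(0, 0), c(1, 2))), "zero-margin")
  expect_error(germination_test(rbind(c(1.5, 2), c(1, 2))), "integers")
})
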