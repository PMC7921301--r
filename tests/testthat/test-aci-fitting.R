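test_that("leak correction is the identity at 0, linear in k, and invertible", {
  cv <- noiseless_curve()
  expect_equal(leak_correct(cv, 0)$points$A, cv$points$A, tolerance = 1e-15)

  k <- 0.002
  adj1 <- leak_correct(cv, k)$points$A - cv$points$A
  adj2 <- leak_correct(cv, 2 * k)$points$A - cv$points$A
  expect_equal(adj2, 2 * adj1, tolerance = 1e-12)

  # inject a leak with k*, correct with k*: recovers the clean curve
  leaky <- cv
  leaky$points$A <- leaky$points$A - k * (leaky$points$Ci - 400)
  recovered <- leak_correct(leaky, k)
  expect_equal(recovered$points$A, cv$points$A, tolerance = 1e-10)

  expect_error(leak_correct(cv, -1), "leak_coefficient")
})

test_that("TPU exclusion follows the trailing-drop rule", {
  # monotonically increasing: nothing excluded
  cv <- aci_curve(aci_grid(), seq(1, 21, length.out = 11))
  res <- exclude_tpu_points(cv)
  expect_identical(nrow(res$excluded), 0L)

  # plateau at 20, final two points lower by 1.0: exactly those excluded
  A <- c(2, 6, 10, 14, 16, 18, 19, 20, 20, 19, 19)
  cv2 <- aci_curve(aci_grid(), A)
  res2 <- exclude_tpu_points(cv2, drop_threshold = 0.5, min_Ci = 800)
  expect_identical(sort(res2$excluded$Ci), c(1200, 1500))
  expect_identical(max(res2$curve$points$Ci), 1000)

  # a dip below min_Ci is never removed
  A3 <- c(2, 6, 10, 9, 16, 18, 19, 20, 20.5, 21, 21.5)  # dip at Ci = 300
  res3 <- exclude_tpu_points(aci_curve(aci_grid(), A3))
  expect_identical(nrow(res3$excluded), 0L)

  # refuses to leave fewer than 5 points
  cv4 <- aci_curve(c(800, 900, 1000, 1200, 1500), c(20, 20, 15, 14, 13))
  expect_error(exclude_tpu_points(cv4), "unusable")
})

test_that("noiseless curves are recovered exactly across a parameter hypercube", {
  kin <- kinetic_constants()
  set.seed(21)
  # stratified draws over (Vcmax, Jmax, Rd); Jmax/Vcmax kept in two-phase range
  for (i in 1:10) {
    vcmax <- runif(1, 40, 110)
    truth <- fvcb_params(vcmax, vcmax * runif(1, 1.4, 2.4),
                         runif(1, 0.3, 2), warn = FALSE)
    cv <- noiseless_curve(truth)
    fit <- fit_aci(cv)
    est <- fit$params_at_leafT
    expect_equal(est$Vcmax, truth$Vcmax, tolerance = 1e-6)
    expect_equal(est$Jmax, truth$Jmax, tolerance = 1e-6)
    expect_equal(est$Rd, truth$Rd, tolerance = 1e-4)
    expect_lt(fit$sum_of_squares, 1e-10)
    expect_true(fit$converged)
  }
})

test_that("selected split beats an independent exhaustive least-squares oracle", {
  set.seed(31)
  truth <- table1_params()
  cv <- generate_aci(truth, noise_sd = 0.4, seed = 31)
  fit <- fit_aci(cv)
  Ci <- cv$points$Ci; A <- cv$points$A; n <- length(Ci)
  kin <- kinetic_constants()
  Km <- kin$Kc * (1 + kin$O / kin$Ko)
  x <- (Ci - kin$gamma_star) / (Ci + Km)
  y <- (Ci - kin$gamma_star) / (4 * Ci + 8 * kin$gamma_star)
  # oracle: brute-force every two-sided split with lm()
  # (intercept plays the role of -Rd, unconstrained; equal to the fit's
  # active-set solution whenever the Rd >= 0 bound is inactive)
  oracle_sse <- sapply(2:(n - 2), function(m) {
    xs <- c(x[1:m], rep(0, n - m))
    ys <- c(rep(0, m), y[(m + 1):n])
    sum(resid(lm(A ~ xs + ys))^2)
  })
  expect_lte(fit$sum_of_squares, min(oracle_sse) + 1e-9)

  # reported SSE equals the independent recomputation from returned params
  p <- fit$params_at_leafT
  pred <- ifelse(fit$phase_labels == "RUBISCO",
                 p$Vcmax * x - p$Rd, p$Jmax * y - p$Rd)
  expect_equal(fit$sum_of_squares, sum((A - pred)^2), tolerance = 1e-9)
})

test_that("estimates at 25 C equal leaf-T estimates passed through Arrhenius", {
  truth <- fvcb_params(80, 150, 1.1, at_temperature = 28, warn = FALSE)
  cv <- generate_aci(truth, leaf_temperature = 28)
  fit <- fit_aci(cv)
  arr <- default_arrhenius()
  expect_equal(fit$params_at_leafT$Vcmax, truth$Vcmax, tolerance = 1e-6)
  expect_equal(fit$params_at_25C$Vcmax,
               arrhenius_scale(fit$params_at_leafT$Vcmax, arr$Vcmax, 25, 28),
               tolerance = 1e-12)
  expect_equal(fit$params_at_25C$Jmax,
               arrhenius_scale(fit$params_at_leafT$Jmax, arr$Jmax, 25, 28),
               tolerance = 1e-12)
})

test_that("a purely Rubisco-limited curve selects the one-phase split and is flagged", {
  p <- fvcb_params(71.1, 1e6, 0.89, warn = FALSE)
  cv <- noiseless_curve(p)
  fit <- fit_aci(cv)
  expect_true(all(fit$phase_labels == "RUBISCO"))
  expect_true(is.na(fit$params_at_leafT$Jmax))
  expect_false(fit$converged)  # Jmax unidentifiable
  expect_equal(fit$params_at_leafT$Vcmax, 71.1, tolerance = 1e-6)

  # degenerate curve: all Ci below the compensation point
  low <- aci_curve(c(1, 5, 10, 20, 30), c(-1, -0.9, -0.8, -0.6, -0.5))
  expect_error(fit_aci(low), "compensation")
})

test_that("batch fitting isolates failures per curve", {
  truth <- table1_params()
  good <- generate_aci(truth, noise_sd = 0.2, seed = 7, curve_id = "ok")
  tbl <- rbind(
    data.frame(curve_id = "ok", Ci = good$points$Ci, A = good$points$A),
    data.frame(curve_id = "short", Ci = c(100, 400, 800),
               A = c(5, 15, 25)))
  res <- fit_aci_curves(tbl)
  expect_identical(nrow(res), 2L)
  ok <- res[res$curve_id == "ok", ]
  expect_true(is.na(ok$error))
  expect_equal(ok$Vcmax, 71.1, tolerance = 0.1)
  expect_false(is.na(res$error[res$curve_id == "short"]))
})
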