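test_that("generation is deterministic given a seed and respects invariants", {
  cfg <- small_config()
  a <- generate_plants(cfg, seed = 5)
  b <- generate_plants(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_plants(cfg, seed = 6)
  expect_false(identical(a$dw, c$dw))

  expect_true(all(a$dw > 0))
  expect_true(all(a$tiller_count >= 1 &
                    a$tiller_count == round(a$tiller_count)))
  expect_true(all(a$lma > 0))
  expect_true(all(a$n_mass > 0 & a$n_mass < a$c_mass & a$c_mass < 100))
  expect_true(all(a$lmf_ab > 0 & a$lmf_ab < 1))
  expect_identical(nrow(a), 12L * 2L * 3L)
  # gas-exchange traits only on the subsample
  expect_true(all(is.na(a$vcmax[!a$gas_exchange_subsample])))
  expect_true(all(!is.na(a$vcmax[a$gas_exchange_subsample])))
})

test_that("population means match the configured treatment means at large n", {
  # many genotypes so that genotype-level noise averages out
  cfg <- generator_config(
    n_genotypes = 250,
    status_mix = c(cultivar = 100, semi_natural = 100, wild = 50),
    plants_per_genotype = 20)
  plants <- generate_plants(cfg, seed = 1)
  expect_gte(nrow(plants), 10000)

  tt <- default_trait_table()
  direct <- c("tiller_count", "lma", "a_op", "g_sop", "e_op", "n_mass",
              "c_mass", "vcmax", "jmax", "rd", "dw")
  for (trt in c("ambient", "high_CO2")) {
    d <- plants[plants$treatment == trt, ]
    for (tr in direct) {
      target <- if (trt == "ambient") tt$mean_ambient[tt$trait == tr] else
        tt$mean_high[tt$trait == tr]
      # SE of the sample mean under genotype clustering: genotype means
      # are the effective independent replicates
      gm <- tapply(d[[tr]], d$genotype_id, mean, na.rm = TRUE)
      se <- sd(gm) / sqrt(length(gm))
      expect_lt(abs(mean(d[[tr]], na.rm = TRUE) - target), 2 * se,
                label = sprintf("mean of %s (%s)", tr, trt))
    }
  }
})

test_that("the mechanistic link makes tillering the dominant DW correlate", {
  cfg <- generator_config(
    n_genotypes = 250,
    status_mix = c(cultivar = 100, semi_natural = 100, wild = 50),
    plants_per_genotype = 20)
  plants <- generate_plants(cfg, seed = 2)
  amb <- plants[plants$treatment == "ambient", ]
  r_till <- cor(amb$dw, amb$tiller_count, method = "spearman")
  r_aop <- cor(amb$dw, amb$a_op, method = "spearman")
  expect_gt(r_till, r_aop)
  expect_gt(r_till, 0.5)
})

test_that("a null configuration yields no genotype or treatment signal", {
  cfg <- small_config(genotype_frac = 0, null_effects = TRUE)
  plants <- generate_plants(cfg, seed = 8)
  # between-genotype F close to 1 on log DW
  f <- anova(lm(log(dw) ~ genotype_id, data = plants))$`F value`[1]
  expect_gt(f, 0.3)
  expect_lt(f, 2.5)
  t <- t.test(log(dw) ~ treatment, data = plants)$statistic
  expect_lt(abs(t), 3)
})

test_that("simulated A-Ci curves honour noise and TPU settings", {
  p <- table1_params()
  clean <- generate_aci(p, noise_sd = 0)
  env <- predict_envelope(aci_grid(), p, kinetic_constants())
  expect_equal(clean$points$A, env$A, tolerance = 1e-12)

  a1 <- generate_aci(p, noise_sd = 0.3, seed = 4)
  a2 <- generate_aci(p, noise_sd = 0.3, seed = 4)
  expect_identical(a1$points, a2$points)

  # TPU tail is capped/declining and removed by the exclusion rule
  tpu <- generate_aci(p, with_tpu = TRUE)
  res <- exclude_tpu_points(tpu)
  expect_identical(sort(res$excluded$Ci), c(1000, 1200, 1500))
  expect_equal(res$curve$points$A, env$A[env$Ci < 1000], tolerance = 1e-12)
})

test_that("germination tables are binomial draws with the configured rates", {
  sure <- generate_germination(c(a = 1, b = 1), c(50, 50), seed = 1)
  expect_identical(unname(sure[, "failed"]), c(0L, 0L))
  none <- generate_germination(c(a = 0, b = 0), c(50, 50), seed = 1)
  expect_identical(unname(none[, "germinated"]), c(0L, 0L))

  tab <- generate_germination(c(ambient = 0.75, high_CO2 = 0.73),
                              c(600, 600), seed = 2)
  rates <- germination_rates(tab)
  expect_equal(rates$pooled, 74, tolerance = 5)  # binomial scatter
  expect_error(generate_germination(c(1.5, 0.5)), "rates")
})
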