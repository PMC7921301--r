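#' @importFrom stats as.formula coef cor mad median na.omit p.adjust pnorm
#'   predict pt qt quantile resid residuals sd setNames shapiro.test var
#'   weighted.mean
NULL

# within-treatment chamber position (chamber is nested in treatment, so a
# flat chamber factor would be collinear with treatment; the identifiable
# fixed effect is the chamber's position within its treatment)
chamber_position <- function(treatment, chamber_id) {
  pos <- stats::ave(as.character(chamber_id), as.character(treatment),
                    FUN = function(x) as.integer(factor(x)))
  factor(pos)
}

treatment_factor <- function(x) {
  lev <- c("ambient", "high_CO2")
  if (all(unique(x) %in% lev)) factor(x, levels = lev) else factor(x)
}

huber_weights <- function(res, scale, k) {
  u <- abs(res) / scale
  w <- ifelse(u > k, k / u, 1)
  w[!is.finite(w)] <- 1
  w
}

# Huber-weighted IRLS around lme4::lmer: downweight large scaled residuals
# (psi = Huber, tuning constant k), refit with the weights, iterate until
# the weights stabilize. Successive fits are warm-started from the previous
# variance-component estimates.
robust_lmer <- function(formula, data, k = 1.345, max_iter = 15, tol = 1e-4,
                        init_fit = NULL) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  data$.huber_w <- rep(1, nrow(data))
  fit <- if (!is.null(init_fit)) init_fit else
    suppressMessages(lme4::lmer(formula, data = data, REML = TRUE,
                                control = ctrl))
  for (i in seq_len(max_iter)) {
    res <- residuals(fit)
    scale <- mad(res)
    if (scale <= 0) scale <- sd(res)
    if (!is.finite(scale) || scale <= 0) break
    w_new <- huber_weights(res, scale, k)
    if (max(abs(w_new - data$.huber_w)) < tol) break
    data$.huber_w <- w_new
    fit <- suppressMessages(lme4::lmer(formula, data = data, REML = TRUE,
                                       weights = .huber_w, control = ctrl,
                                       start = lme4::getME(fit, "theta")))
  }
  fit
}

#' Compare treatments for one trait with the model-selection decision tree
#'
#' Fits the study design's default model — trait ~ treatment + chamber
#' (fixed) + genotype (random intercept), REML — and reports the marginal
#' treatment effect via its t-value with Satterthwaite-approximated
#' degrees of freedom. Model choice follows a fixed decision tree:
#'
#' * residuals pass Shapiro-Wilk normality and Levene homoscedasticity
#'   (by treatment) at `diag_alpha` -> report the mixed model (`mixed`);
#' * either diagnostic fails -> refit by Huber-weighted robust IRLS and
#'   report the robust t with the regular model's Satterthwaite df
#'   (`robust_mixed`);
#' * the genotype variance component is ~0 (< 1e-8 x residual variance)
#'   -> plain regression on treatment + chamber (`ols`), switching to a
#'   heteroscedasticity-consistent covariance when a studentized
#'   Breusch-Pagan test rejects homoscedasticity (`ols_hc`).
#'
#' @param data Per-plant table (needs `treatment`, `chamber_id`,
#'   `genotype_id` and the trait column); rows with a missing trait are
#'   dropped.
#' @param trait Name of the trait column.
#' @param diag_alpha Significance level of the diagnostic tests.
#' @param huber_k Huber tuning constant of the robust path.
#' @return An object of class `treatment_comparison`: `estimate` (high
#'   minus ambient), `se`, `t_value`, `df`, `p_value`, `model_path`,
#'   per-treatment `means` (with n, sd, 95% CI), and `diagnostics`.
#' @export
compare_treatments <- function(data, trait, diag_alpha = 0.05,
                               huber_k = 1.345) {
  d <- data[!is.na(data[[trait]]), ]
  if (length(unique(d$treatment)) < 2) {
    stop("both treatments must be present", call. = FALSE)
  }
  d$treatment <- treatment_factor(d$treatment)
  if (length(unique(d$genotype_id)) < 2) {
    stop("need at least 2 genotypes", call. = FALSE)
  }
  d$chamber_pos <- chamber_position(d$treatment, d$chamber_id)
  d$.y <- d[[trait]]

  means <- dplyr::summarise(
    dplyr::group_by(d, .data$treatment),
    n = dplyr::n(), mean = mean(.data$.y), sd = sd(.data$.y),
    ci_lo = mean - qt(0.975, pmax(n - 1, 1)) * sd / sqrt(n),
    ci_hi = mean + qt(0.975, pmax(n - 1, 1)) * sd / sqrt(n),
    .groups = "drop")

  rhs <- if (nlevels(d$chamber_pos) > 1) "treatment + chamber_pos" else "treatment"
  f_mixed <- as.formula(paste(".y ~", rhs, "+ (1 | genotype_id)"))
  f_ols <- as.formula(paste(".y ~", rhs))

  resid_var_zero <- var(d$.y) < 1e-12
  fit <- if (resid_var_zero) NULL else tryCatch(
    suppressMessages(lmerTest::lmer(f_mixed, data = d, REML = TRUE)),
    error = function(e) NULL)

  diagnostics <- list(normality_p = NA_real_, homoscedasticity_p = NA_real_,
                      genotype_variance = NA_real_, bp_p = NA_real_)

  r_var <- NA_real_
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    g_var <- vc$vcov[vc$grp == "genotype_id"][1]
    r_var <- vc$vcov[vc$grp == "Residual"][1]
    diagnostics$genotype_variance <- g_var
  }

  if (is.null(fit) || resid_var_zero ||
      diagnostics$genotype_variance < 1e-8 * max(r_var, 1e-300)) {
    # degenerate-genotype path: plain regression
    ols <- stats::lm(f_ols, data = d)
    if (resid_var_zero || var(residuals(ols)) < 1e-12) {
      cf <- coef(ols)
      est <- unname(cf["treatmenthigh_CO2"])
      if (is.na(est)) est <- 0
      out <- list(estimate = est, se = 0, t_value = 0,
                  df = stats::df.residual(ols), p_value = 1,
                  model_path = "ols", means = means,
                  diagnostics = diagnostics, trait = trait)
      return(structure(out, class = "treatment_comparison"))
    }
    bp <- lmtest::bptest(ols, studentize = TRUE)
    diagnostics$bp_p <- bp$p.value
    if (bp$p.value < diag_alpha) {
      ct <- lmtest::coeftest(ols, vcov. = sandwich::vcovHC(ols, type = "HC3"))
      row <- ct["treatmenthigh_CO2", ]
      out <- list(estimate = row[["Estimate"]], se = row[["Std. Error"]],
                  t_value = row[["t value"]], df = stats::df.residual(ols),
                  p_value = row[["Pr(>|t|)"]], model_path = "ols_hc",
                  means = means, diagnostics = diagnostics, trait = trait)
    } else {
      sm <- summary(ols)$coefficients["treatmenthigh_CO2", ]
      out <- list(estimate = sm[["Estimate"]], se = sm[["Std. Error"]],
                  t_value = sm[["t value"]], df = stats::df.residual(ols),
                  p_value = sm[["Pr(>|t|)"]], model_path = "ols",
                  means = means, diagnostics = diagnostics, trait = trait)
    }
    return(structure(out, class = "treatment_comparison"))
  }

  res <- residuals(fit)
  sw <- tryCatch(shapiro.test(res[seq_len(min(length(res), 4999))]),
                 error = function(e) list(p.value = 1))
  lev <- tryCatch(car::leveneTest(res ~ d$treatment),
                  error = function(e) data.frame(`Pr(>F)` = 1, check.names = FALSE))
  diagnostics$normality_p <- sw$p.value
  diagnostics$homoscedasticity_p <- lev[["Pr(>F)"]][1]

  sm <- summary(fit)$coefficients["treatmenthigh_CO2", ]
  satt_df <- sm[["df"]]

  if (diagnostics$normality_p >= diag_alpha &&
      diagnostics$homoscedasticity_p >= diag_alpha) {
    out <- list(estimate = sm[["Estimate"]], se = sm[["Std. Error"]],
                t_value = sm[["t value"]], df = satt_df,
                p_value = sm[["Pr(>|t|)"]], model_path = "mixed",
                means = means, diagnostics = diagnostics, trait = trait)
  } else {
    rfit <- robust_lmer(f_mixed, d, k = huber_k, init_fit = fit)
    rcf <- summary(rfit)$coefficients["treatmenthigh_CO2", ]
    t_rob <- rcf[["t value"]]
    out <- list(estimate = rcf[["Estimate"]], se = rcf[["Std. Error"]],
                t_value = t_rob, df = satt_df,
                p_value = 2 * pt(-abs(t_rob), satt_df),
                model_path = "robust_mixed",
                means = means, diagnostics = diagnostics, trait = trait)
  }
  structure(out, class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("%s: high CO2 - ambient = %.3g (SE %.3g), t = %.2f, df = %.1f, p = %.3g [%s]\n",
              x$trait, x$estimate, x$se, x$t_value, x$df, x$p_value,
              x$model_path))
  invisible(x)
}

#' Pairwise status-group contrasts with BH adjustment
#'
#' Within each treatment, fits trait ~ status + chamber + (1 | genotype)
#' and reports all pairwise least-squares-mean contrasts between status
#' groups, with Benjamini-Hochberg adjustment over each treatment's
#' contrast family.
#'
#' @param data Per-plant table.
#' @param trait Trait column name.
#' @param min_group Minimum genotypes per status group to include it.
#' @return A tibble: `treatment`, `contrast`, `estimate`, `se`, `df`,
#'   `t_value`, `p_value`, `p_adj`.
#' @export
compare_status_groups <- function(data, trait, min_group = 1) {
  d <- data[!is.na(data[[trait]]), ]
  d$.y <- d[[trait]]
  out <- lapply(unique(d$treatment), function(trt) {
    dt <- d[d$treatment == trt, ]
    keep <- names(which(table(unique(dt[, c("genotype_id", "status")])$status) >= min_group))
    dt <- dt[dt$status %in% keep, ]
    dt$status <- factor(dt$status)
    if (nlevels(dt$status) < 2) {
      stop("need at least 2 status groups per treatment", call. = FALSE)
    }
    dt$chamber_pos <- chamber_position(dt$treatment, dt$chamber_id)
    rhs <- if (nlevels(dt$chamber_pos) > 1) "status + chamber_pos" else "status"
    f <- as.formula(paste(".y ~", rhs, "+ (1 | genotype_id)"))
    fit <- suppressMessages(lmerTest::lmer(f, data = dt, REML = TRUE))
    em <- emmeans::emmeans(fit, "status")
    pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "none"))
    tibble::tibble(treatment = trt, contrast = pr$contrast,
                   estimate = pr$estimate, se = pr$SE, df = pr$df,
                   t_value = pr$t.ratio,
                   p_value = pr$p.value,
                   p_adj = p.adjust(pr$p.value, method = "BH"))
  })
  dplyr::bind_rows(out)
}
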