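# marginal and conditional R2 from a single-random-intercept lmer fit:
# marginal   = var(fixed predictions) / (fixed + random + residual)
# conditional = (fixed + random) / (same denominator)
mixed_r2 <- function(fit) {
  X <- stats::model.matrix(fit)
  beta <- lme4::fixef(fit)
  var_f <- var(as.numeric(X %*% beta))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_g <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"][1]
  denom <- var_f + var_g + var_e
  c(marginal = var_f / denom, conditional = (var_f + var_g) / denom)
}

#' Mixed-model ANCOVA between two traits
#'
#' Fits response ~ covariate + chamber + (1 | genotype) by REML, per
#' treatment when `by_treatment = TRUE`, and reports slope, intercept,
#' slope CI, and marginal and conditional R2 from the variance
#' components. With `by_treatment = TRUE` an additional full-data model
#' with a treatment x covariate interaction supplies the interaction
#' p-value (Satterthwaite df).
#'
#' @param data Per-plant table.
#' @param response,covariate Trait column names.
#' @param by_treatment Fit separate relationships per treatment and test
#'   the treatment x covariate interaction.
#' @return An object of class `relationship_fit`: tibble `fits` (one row
#'   per treatment or one overall), `interaction_p` (NA unless
#'   `by_treatment`), `response`, `covariate`.
#' @export
#' @examples
#' plants <- generate_plants(generator_config(), seed = 1)
#' fit_relationship(plants, "dw", "tiller_count", by_treatment = TRUE)
fit_relationship <- function(data, response, covariate, by_treatment = FALSE) {
  d <- data[!is.na(data[[response]]) & !is.na(data[[covariate]]), ]
  if (nrow(d) < 10) stop("need at least 10 complete pairs", call. = FALSE)
  if (var(d[[covariate]]) == 0) stop("constant covariate", call. = FALSE)
  d$.y <- d[[response]]
  d$.x <- d[[covariate]]
  d$chamber_pos <- chamber_position(d$treatment, d$chamber_id)

  fit_one <- function(dd, label) {
    rhs <- if (nlevels(droplevels(dd$chamber_pos)) > 1) ".x + chamber_pos" else ".x"
    f <- as.formula(paste(".y ~", rhs, "+ (1 | genotype_id)"))
    # the mixed machinery fails on degenerate (zero-residual) responses;
    # fall back to plain OLS of the fixed part in that case
    mixed <- tryCatch({
      fit <- suppressMessages(lmerTest::lmer(f, data = dd, REML = TRUE))
      list(sm = summary(fit)$coefficients, r2 = mixed_r2(fit))
    }, error = function(e) NULL)
    if (is.null(mixed)) {
      fit <- stats::lm(as.formula(paste(".y ~", rhs)), data = dd)
      sm <- summary(fit)$coefficients
      colnames(sm)[4] <- "Pr(>|t|)"
      var_f <- var(stats::fitted(fit))
      var_e <- var(residuals(fit))
      r2 <- c(marginal = var_f / (var_f + var_e),
              conditional = var_f / (var_f + var_e))
    } else {
      sm <- mixed$sm
      if (!"Pr(>|t|)" %in% colnames(sm)) {
        sm <- cbind(sm, "Pr(>|t|)" = 2 * pnorm(-abs(sm[, "t value"])))
      }
      r2 <- mixed$r2
    }
    tibble::tibble(
      treatment = label,
      slope = sm[".x", "Estimate"], slope_se = sm[".x", "Std. Error"],
      slope_lo = sm[".x", "Estimate"] - 1.96 * sm[".x", "Std. Error"],
      slope_hi = sm[".x", "Estimate"] + 1.96 * sm[".x", "Std. Error"],
      intercept = sm["(Intercept)", "Estimate"],
      p_value = sm[".x", "Pr(>|t|)"],
      marginal_R2 = r2[["marginal"]], conditional_R2 = r2[["conditional"]],
      n = nrow(dd))
  }

  interaction_p <- NA_real_
  if (by_treatment) {
    fits <- dplyr::bind_rows(lapply(unique(d$treatment), function(trt) {
      fit_one(d[d$treatment == trt, ], trt)
    }))
    d$treatment <- treatment_factor(d$treatment)
    f_int <- .y ~ .x * treatment + chamber_pos + (1 | genotype_id)
    if (nlevels(droplevels(d$chamber_pos)) < 2) {
      f_int <- .y ~ .x * treatment + (1 | genotype_id)
    }
    int_fit <- suppressMessages(lmerTest::lmer(f_int, data = d, REML = TRUE))
    smi <- summary(int_fit)$coefficients
    int_row <- grep("^\\.x:", rownames(smi))
    if (length(int_row) == 1) interaction_p <- smi[int_row, "Pr(>|t|)"]
  } else {
    fits <- fit_one(d, "all")
  }
  structure(list(fits = fits, interaction_p = interaction_p,
                 response = response, covariate = covariate),
            class = "relationship_fit")
}

#' @export
print.relationship_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s (mixed ANCOVA)\n", x$response, x$covariate))
  print(x$fits)
  if (!is.na(x$interaction_p)) {
    cat(sprintf("treatment x covariate interaction p = %.3g\n",
                x$interaction_p))
  }
  invisible(x)
}

#' Per-genotype treatment means and percent responses
#'
#' Genotype means (+- SE of the mean, as plotted in response figures) per
#' treatment and the percent change of the genotype mean from ambient to
#' high CO2. Genotypes missing either treatment are excluded with a
#' warning.
#'
#' @param data Per-plant table.
#' @param trait Trait column name.
#' @return A tibble: `genotype_id`, `mean_ambient`, `se_ambient`,
#'   `mean_high`, `se_high`, `response_pct`.
#' @export
genotype_mean_responses <- function(data, trait) {
  d <- data[!is.na(data[[trait]]), ]
  d$.y <- d[[trait]]
  g <- dplyr::summarise(
    dplyr::group_by(d, .data$genotype_id, .data$treatment),
    mean = mean(.data$.y), se = sd(.data$.y) / sqrt(dplyr::n()),
    .groups = "drop")
  w <- tidyr::pivot_wider(g, names_from = "treatment",
                          values_from = c("mean", "se"))
  need <- c("mean_ambient", "mean_high_CO2")
  incomplete <- !stats::complete.cases(w[, need])
  if (any(incomplete)) {
    warning("excluding genotypes missing a treatment: ",
            paste(w$genotype_id[incomplete], collapse = ", "), call. = FALSE)
    w <- w[!incomplete, ]
  }
  tibble::tibble(
    genotype_id = w$genotype_id,
    mean_ambient = w$mean_ambient, se_ambient = w$se_ambient,
    mean_high = w$mean_high_CO2, se_high = w$se_high_CO2,
    response_pct = percent_response(w$mean_ambient, w$mean_high_CO2))
}

#' Rank concordance of genotype means between treatments
#'
#' Spearman's rank correlation (average ties) between genotype means in
#' the two treatments, plus the R2 of the rank-on-rank regression.
#'
#' @param means_ambient,means_high Numeric vectors of genotype means,
#'   aligned (>= 3 genotypes).
#' @return A list: `rho`, `rank_r2`, `n`.
#' @export
#' @examples
#' rank_concordance(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
rank_concordance <- function(means_ambient, means_high) {
  ok <- !is.na(means_ambient) & !is.na(means_high)
  x <- means_ambient[ok]; y <- means_high[ok]
  if (length(x) < 3) stop("need at least 3 genotypes", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  fit <- stats::lm(ry ~ rx)
  list(rho = rho, rank_r2 = summary(fit)$r.squared, n = length(x))
}

#' Spearman correlogram of traits
#'
#' Pairwise Spearman rank correlations over complete-case rows, with
#' per-cell p-values and significance stars (p <= 0.05 / 0.01 / 0.001).
#'
#' @param data Per-plant table.
#' @param traits Character vector of trait columns.
#' @return An object of class `correlogram`: matrices `rho`, `p`,
#'   `stars`, and `n` (complete cases used).
#' @export
correlogram <- function(data, traits) {
  d <- data[, traits]
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 5) stop("need at least 5 complete rows", call. = FALSE)
  k <- length(traits)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- suppressWarnings(
        stats::cor.test(d[[traits[i]]], d[[traits[j]]],
                        method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = p, stars = significance_stars(p),
                 n = nrow(d)), class = "correlogram")
}

significance_stars <- function(p) {
  s <- ifelse(p <= 0.001, "***",
       ifelse(p <= 0.01, "**",
       ifelse(p <= 0.05, "*", "")))
  s[is.na(p)] <- ""
  s
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("Spearman correlogram (%d complete cases)\n", x$n))
  print(round(x$rho, 2))
  invisible(x)
}
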