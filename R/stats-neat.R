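#' Multiple regression with incremental-R2 ("neat") predictor attribution
#'
#' Quantifies each trait's unique predictive power for a response
#' (canonically aboveground dry mass) in three steps: (1) a variance
#' inflation factor screen drops predictors with VIF above `vif_cutoff`
#' (perfect collinearity is an error naming the offending pair);
#' (2) all variables are standardized to zero mean and unit SD and the
#' full regression gives standardized coefficients; (3) each predictor's
#' increment `delta_R2 = R2(full) - R2(model without it)` — the gain from
#' adding that predictor to a model already containing all the others.
#' Residual diagnostics (Durbin-Watson, studentized Breusch-Pagan,
#' Shapiro-Wilk, maximum Cook's distance) are reported alongside.
#'
#' Predictors computed from the response itself (e.g. leaf area per
#' tiller, which is derived from DW) must not be offered; the function
#' does not second-guess the caller's list.
#'
#' @param data Per-plant table; complete cases over response and
#'   predictors are used.
#' @param response Response column name (default `"dw"`).
#' @param predictors Character vector of predictor columns.
#' @param vif_cutoff Exclude predictors with VIF above this (default 10).
#' @return An object of class `neat_result`: tibble `coefficients`
#'   (`predictor`, `std_coef`, `p_value`, `delta_r2`, `vif`), `full_r2`,
#'   `excluded` (tibble with reasons), `diagnostics`, `n`.
#' @export
neat_analysis <- function(data, response = "dw", predictors,
                          vif_cutoff = 10) {
  stopifnot(length(predictors) >= 1)
  d <- data[, c(response, predictors)]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  if (n < length(predictors) + 2) {
    stop("too few complete cases for the predictor set", call. = FALSE)
  }
  z <- as.data.frame(scale(d))
  names(z) <- c(".y", predictors)

  full_formula <- function(preds) {
    as.formula(paste(".y ~", paste(sprintf("`%s`", preds), collapse = " + ")))
  }

  fit0 <- stats::lm(full_formula(predictors), data = z)
  aliased <- is.na(coef(fit0))[-1]
  if (any(aliased)) {
    bad <- predictors[aliased][1]
    # name a partner: the remaining predictor it is perfectly collinear with
    others <- setdiff(predictors, bad)
    r <- vapply(others, function(o) abs(cor(z[[bad]], z[[o]])), numeric(1))
    stop(sprintf("perfect collinearity between '%s' and '%s'", bad,
                 others[which.max(r)]), call. = FALSE)
  }

  vifs <- if (length(predictors) > 1) car::vif(fit0) else
    setNames(1, predictors)
  names(vifs) <- predictors
  flagged <- names(vifs)[vifs > vif_cutoff]
  kept <- setdiff(predictors, flagged)
  if (length(kept) == 0) {
    stop("all predictors exceeded the VIF cutoff", call. = FALSE)
  }
  excluded <- tibble::tibble(
    predictor = flagged,
    reason = sprintf("VIF %.1f > %g", unname(vifs[flagged]), vif_cutoff))

  fit <- stats::lm(full_formula(kept), data = z)
  smc <- summary(fit)$coefficients
  full_r2 <- summary(fit)$r.squared
  delta <- vapply(kept, function(pr) {
    rest <- setdiff(kept, pr)
    r2_wo <- if (length(rest) == 0) 0 else
      summary(stats::lm(full_formula(rest), data = z))$r.squared
    full_r2 - r2_wo
  }, numeric(1))

  res <- residuals(fit)
  diagnostics <- list(
    durbin_watson = unname(car::durbinWatsonTest(fit)$dw),
    breusch_pagan_p = lmtest::bptest(fit, studentize = TRUE)$p.value,
    normality_p = shapiro.test(res[seq_len(min(length(res), 4999))])$p.value,
    max_cooks_distance = max(stats::cooks.distance(fit)))

  structure(list(
    coefficients = tibble::tibble(
      predictor = kept,
      std_coef = unname(smc[coef_rows <- match(kept, gsub("`", "", rownames(smc))),
                            "Estimate"]),
      p_value = unname(smc[coef_rows, "Pr(>|t|)"]),
      delta_r2 = unname(delta),
      vif = unname(vifs[kept])),
    full_r2 = full_r2, excluded = excluded,
    diagnostics = diagnostics, n = n,
    response = response), class = "neat_result")
}

#' @export
print.neat_result <- function(x, ...) {
  cat(sprintf("neat analysis of %s (n = %d, full R2 = %.3f)\n",
              x$response, x$n, x$full_r2))
  print(dplyr::arrange(x$coefficients, dplyr::desc(.data$delta_r2)))
  if (nrow(x$excluded) > 0) {
    cat("excluded:", paste(x$excluded$predictor, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Germination-rate contingency test
#'
#' Fisher's exact test for a 2x2 germinated/failed table, with the
#' chi-square statistic (no continuity correction) reported alongside;
#' for 2xk tables (k > 2, e.g. four chambers) the chi-square test is the
#' primary result.
#'
#' @param counts Integer matrix, groups x (germinated, failed).
#' @return A list: `fisher_p` (NA for k > 2), `chi_sq`, `chi_df`,
#'   `chi_p`.
#' @export
#' @examples
#' tab <- generate_germination(seed = 1)
#' germination_test(tab)
germination_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero-margin table", call. = FALSE)
  }
  chi <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  fisher_p <- if (nrow(counts) == 2 && ncol(counts) == 2) {
    stats::fisher.test(counts)$p.value
  } else NA_real_
  list(fisher_p = fisher_p, chi_sq = unname(chi$statistic),
       chi_df = unname(chi$parameter), chi_p = chi$p.value)
}
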