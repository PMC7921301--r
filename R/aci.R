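#' Construct an A-Ci curve
#'
#' One leaf's CO2-response series: net assimilation `A` measured over a grid
#' of intercellular CO2 `Ci`, plus the cuvette conditions. Points are stored
#' sorted by ascending `Ci`; `Ci` values must be distinct.
#'
#' The default measurement grid of this package's simulations follows the
#' common stepped protocol: Ca lowered 400 -> 50 then raised to 1500
#' (50, 100, 200, 300, 400, 600, 700, 800, 1000, 1200, 1500).
#'
#' @param Ci Intercellular CO2 \[umol mol^-1\].
#' @param A Net assimilation \[umol m^-2 s^-1\].
#' @param curve_id,genotype_id,treatment Identifying labels.
#' @param leaf_temperature Leaf temperature during the curve \[C\].
#' @param O2_fraction Chloroplastic/atmospheric O2 \[mmol mol^-1\].
#' @param Ca Optional cuvette CO2 per point \[umol mol^-1\] (used by leak
#'   correction; defaults to `Ci` as gradient proxy when absent).
#' @return An object of class `aci_curve`.
#' @export
aci_curve <- function(Ci, A, curve_id = "curve", genotype_id = NA_character_,
                      treatment = NA_character_, leaf_temperature = 25,
                      O2_fraction = 210, Ca = NULL) {
  if (length(Ci) != length(A)) stop("Ci and A lengths differ", call. = FALSE)
  if (length(Ci) < 5) stop("an A-Ci curve needs at least 5 points", call. = FALSE)
  if (anyDuplicated(Ci)) stop("Ci values must be distinct", call. = FALSE)
  if (any(Ci < 0)) stop("Ci must be >= 0", call. = FALSE)
  ord <- order(Ci)
  pts <- tibble::tibble(Ci = Ci[ord], A = A[ord])
  if (!is.null(Ca)) pts$Ca <- Ca[ord]
  structure(list(curve_id = curve_id, genotype_id = genotype_id,
                 treatment = treatment, points = pts,
                 leaf_temperature = leaf_temperature,
                 O2_fraction = O2_fraction),
            class = "aci_curve")
}

#' @export
print.aci_curve <- function(x, ...) {
  cat(sprintf("A-Ci curve '%s' (%d points, leaf T %.1f C)\n",
              x$curve_id, nrow(x$points), x$leaf_temperature))
  print(x$points, n = 5)
  invisible(x)
}

#' The standard 11-point Ci measurement grid
#'
#' @return Numeric vector of Ci values \[umol mol^-1\], ascending.
#' @export
aci_grid <- function() c(50, 100, 200, 300, 400, 600, 700, 800, 1000, 1200, 1500)

#' Correct an A-Ci curve for cuvette leaks
#'
#' Diffusive leaks through cuvette gaskets scale with the CO2 gradient
#' between cuvette air and the surrounding atmosphere. The correction is
#' linear: `A_corrected = A + k * (C_cuvette - C_room)` with `C_cuvette`
#' taken from the stored `Ca` column when present, otherwise proxied by
#' `Ci`. A coefficient of 0 (the default used throughout, since leak
#' coefficients are instrument specific) is the identity.
#'
#' @param curve An [aci_curve()].
#' @param leak_coefficient Leak coefficient \[umol m^-2 s^-1 per
#'   umol mol^-1 gradient\], >= 0.
#' @param room_CO2 CO2 mole fraction of the surrounding air
#'   \[umol mol^-1\].
#' @return The corrected `aci_curve`.
#' @export
leak_correct <- function(curve, leak_coefficient = 0, room_CO2 = 400) {
  stopifnot(inherits(curve, "aci_curve"))
  if (leak_coefficient < 0) {
    stop("leak_coefficient must be >= 0", call. = FALSE)
  }
  cuvette <- if ("Ca" %in% names(curve$points)) curve$points$Ca else curve$points$Ci
  curve$points$A <- curve$points$A + leak_coefficient * (cuvette - room_CO2)
  curve
}

#' Exclude triose-phosphate-use limited points
#'
#' At very high Ci, assimilation can plateau and then decline when triose
#' phosphate use (TPU) becomes limiting; such trailing points do not belong
#' to either FvCB branch and are removed before fitting. Working from the
#' highest Ci downwards, a trailing point is dropped while its `A` falls
#' more than `drop_threshold` below the maximum `A` of the retained points
#' and its Ci is at least `min_Ci`; points below `min_Ci` are never removed.
#'
#' @param curve An [aci_curve()].
#' @param drop_threshold Drop when A is this far \[umol m^-2 s^-1\] below
#'   the retained maximum (> 0).
#' @param min_Ci Only points at or above this Ci \[umol mol^-1\] are
#'   candidates.
#' @return A list with `curve` (retained points) and `excluded`
#'   (tibble of removed points, possibly empty).
#' @export
exclude_tpu_points <- function(curve, drop_threshold = 0.5, min_Ci = 800) {
  stopifnot(inherits(curve, "aci_curve"))
  if (drop_threshold <= 0) stop("drop_threshold must be > 0", call. = FALSE)
  pts <- curve$points
  excluded <- pts[0, ]
  repeat {
    n <- nrow(pts)
    if (n == 0) break
    last <- pts[n, ]
    if (last$Ci >= min_Ci && last$A < max(pts$A) - drop_threshold) {
      excluded <- dplyr::bind_rows(last, excluded)
      pts <- pts[-n, ]
    } else {
      break
    }
  }
  if (nrow(pts) < 5) {
    stop(sprintf("curve '%s' unusable: fewer than 5 points would remain after TPU exclusion",
                 curve$curve_id), call. = FALSE)
  }
  curve$points <- pts
  list(curve = curve, excluded = excluded)
}

# Exact least squares for one phase split.
# For a fixed assignment (prefix -> Ac, suffix -> Aj) both branches are
# linear in (Vcmax, Jmax, Rd):
#   Ac_i = Vcmax * x_i - Rd,  x_i = (Ci - G*)/(Ci + Kc(1 + O/Ko))
#   Aj_i = Jmax  * y_i - Rd,  y_i = (Ci - G*)/(4 Ci + 8 G*)
# so each candidate split is solved exactly by OLS; Rd < 0 is handled by an
# active-set refit at Rd = 0.
fit_split <- function(Ci, A, m, kin) {
  n <- length(Ci)
  Km <- kin$Kc * (1 + kin$O / kin$Ko)
  x <- (Ci - kin$gamma_star) / (Ci + Km)
  y <- (Ci - kin$gamma_star) / (4 * Ci + 8 * kin$gamma_star)
  idx_c <- seq_len(m)
  idx_j <- if (m < n) (m + 1):n else integer(0)

  solve_ols <- function(X, A) {
    fit <- stats::lm.fit(X, A)
    coef <- unname(fit$coefficients)
    coef[is.na(coef)] <- 0
    coef
  }

  if (m == n) {            # all Rubisco-limited: Jmax unidentifiable
    X <- cbind(x, -1)
    cf <- solve_ols(X, A)
    Vcmax <- cf[1]; Jmax <- NA_real_; Rd <- cf[2]
    if (Rd < 0) { Rd <- 0; Vcmax <- solve_ols(cbind(x), A)[1] }
    pred <- Vcmax * x - Rd
  } else if (m == 0) {     # all RuBP-limited: Vcmax unidentifiable
    X <- cbind(y, -1)
    cf <- solve_ols(X, A)
    Jmax <- cf[1]; Vcmax <- NA_real_; Rd <- cf[2]
    if (Rd < 0) { Rd <- 0; Jmax <- solve_ols(cbind(y), A)[1] }
    pred <- Jmax * y - Rd
  } else {
    X <- cbind(c(x[idx_c], rep(0, n - m)), c(rep(0, m), y[idx_j]), -1)
    cf <- solve_ols(X, A)
    Vcmax <- cf[1]; Jmax <- cf[2]; Rd <- cf[3]
    if (Rd < 0) {
      Rd <- 0
      X0 <- X[, 1:2, drop = FALSE]
      cf <- solve_ols(X0, A)
      Vcmax <- cf[1]; Jmax <- cf[2]
    }
    pred <- c(Vcmax * x[idx_c], Jmax * y[idx_j]) - Rd
  }

  feasible <- (is.na(Vcmax) || Vcmax > 0) && (is.na(Jmax) || Jmax > 0)
  sse <- if (feasible) sum((A - pred)^2) else Inf
  list(Vcmax = Vcmax, Jmax = Jmax, Rd = Rd, sse = sse, m = m,
       pred = pred, feasible = feasible)
}

#' Fit the FvCB model to an A-Ci curve
#'
#' Estimates `Vcmax`, `Jmax` and `Rd` (one shared `Rd`) from a
#' leak-corrected, TPU-excluded curve by exhaustive transition-point
#' search: every contiguous low-Ci prefix is assigned to the
#' Rubisco-limited branch and the remaining suffix to the
#' RuBP-regeneration branch (each side at least 2 points), plus the two
#' one-phase degenerate assignments. For each candidate split the joint
#' sum of squared errors is minimized exactly (the model is linear in the
#' parameters for a fixed split; see `fit_split` source), and the split
#' with the smallest SSE wins, ties going to the smaller transition Ci.
#'
#' The kinetic constants are Arrhenius-scaled to the curve's leaf
#' temperature before fitting, and the fitted parameters are reported both
#' at leaf temperature and normalized to 25 C.
#'
#' Consistency of the selected split is checked: the Rubisco branch must
#' lie at or below the RuBP branch on the prefix and vice versa on the
#' suffix, within `branch_tolerance`; violation (or an unidentifiable
#' branch parameter) clears the `converged` flag rather than erroring.
#'
#' @param curve An [aci_curve()] (already leak-corrected and
#'   TPU-excluded).
#' @param kin [kinetic_constants()] at their reference temperature.
#' @param arrhenius Arrhenius set from [default_arrhenius()].
#' @param branch_tolerance Allowed branch-inequality violation
#'   \[umol m^-2 s^-1\].
#' @return An object of class `aci_fit`: `params_at_leafT`,
#'   `params_at_25C` (both [fvcb_params()]), `transition_Ci`,
#'   `phase_labels`, `sum_of_squares`, `converged`, `candidates`
#'   (per-split SSE table), and the input `curve`.
#' @export
#' @examples
#' p <- fvcb_params(71.1, 134.3, 0.89)
#' env <- predict_envelope(aci_grid(), p, kinetic_constants())
#' fit <- fit_aci(aci_curve(env$Ci, env$A))
#' fit$params_at_leafT
fit_aci <- function(curve, kin = kinetic_constants(),
                    arrhenius = default_arrhenius(),
                    branch_tolerance = 0.5) {
  stopifnot(inherits(curve, "aci_curve"))
  kin_leaf <- kinetics_at(kin, curve$leaf_temperature, arrhenius)
  Ci <- curve$points$Ci
  A <- curve$points$A
  n <- length(Ci)
  if (all(Ci < kin_leaf$gamma_star)) {
    stop("degenerate curve: all Ci below the CO2 compensation point",
         call. = FALSE)
  }

  splits <- c(0L, if (n >= 4) 2:(n - 2) else integer(0), n)
  fits <- lapply(splits, function(m) fit_split(Ci, A, m, kin_leaf))
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  if (all(!is.finite(sses))) {
    stop("no feasible split: every candidate fit was degenerate", call. = FALSE)
  }

  trans_ci <- vapply(fits, function(f) {
    if (f$m == 0) min(Ci) else if (f$m == n) max(Ci)
    else (Ci[f$m] + Ci[f$m + 1]) / 2
  }, numeric(1))
  best_sse <- min(sses)
  tied <- which(sses <= best_sse + 1e-12)
  best <- tied[which.min(trans_ci[tied])]
  sel <- fits[[best]]
  m <- sel$m

  # branch consistency on the selected split
  converged <- sel$feasible
  identifiable <- !is.na(sel$Vcmax) && !is.na(sel$Jmax)
  if (identifiable) {
    pl <- fvcb_params(sel$Vcmax, sel$Jmax, max(sel$Rd, 1e-12),
                      at_temperature = curve$leaf_temperature, warn = FALSE)
    pl$Rd <- sel$Rd
    ac <- ac_assimilation(Ci, pl, kin_leaf)
    aj <- aj_assimilation(Ci, pl, kin_leaf$gamma_star)
    ok_prefix <- m == 0 || all(ac[seq_len(m)] <= aj[seq_len(m)] + branch_tolerance)
    ok_suffix <- m == n || all(aj[(m + 1):n] <= ac[(m + 1):n] + branch_tolerance)
    converged <- converged && ok_prefix && ok_suffix
  } else {
    converged <- FALSE   # one-phase fit: the other branch is unidentifiable
  }

  sse <- sel$sse
  mk_params <- function(Vcmax, Jmax, Rd, temp) {
    structure(list(Vcmax = Vcmax, Jmax = Jmax, Rd = Rd,
                   at_temperature = temp), class = "fvcb_params")
  }
  t_leaf <- curve$leaf_temperature
  p_leaf <- mk_params(sel$Vcmax, sel$Jmax, sel$Rd, t_leaf)
  p_25 <- mk_params(
    if (is.na(sel$Vcmax)) NA_real_ else
      arrhenius_scale(sel$Vcmax, arrhenius$Vcmax, 25, t_leaf),
    if (is.na(sel$Jmax)) NA_real_ else
      arrhenius_scale(sel$Jmax, arrhenius$Jmax, 25, t_leaf),
    if (is.na(sel$Rd) || sel$Rd == 0) sel$Rd else
      arrhenius_scale(sel$Rd, arrhenius$Rd, 25, t_leaf),
    25)

  structure(list(
    params_at_leafT = p_leaf,
    params_at_25C = p_25,
    transition_Ci = trans_ci[best],
    phase_labels = c(rep("RUBISCO", m), rep("RUBP", n - m)),
    sum_of_squares = sse,
    converged = converged,
    candidates = tibble::tibble(prefix_n = splits, sse = sses,
                                transition_Ci = trans_ci),
    curve = curve
  ), class = "aci_fit")
}

#' @export
print.aci_fit <- function(x, ...) {
  p <- x$params_at_25C
  cat(sprintf(
    "A-Ci fit '%s': Vcmax25 = %.2f, Jmax25 = %.2f, Rd25 = %.3f | SSE = %.3g | %s\n",
    x$curve$curve_id, p$Vcmax, p$Jmax, p$Rd, x$sum_of_squares,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit many A-Ci curves from a long-format table
#'
#' Applies leak correction, TPU exclusion and [fit_aci()] to every curve in
#' a long table (columns `curve_id`, `Ci`, `A`, optionally `genotype_id`,
#' `treatment`, `T_leaf`, `O2`). Curves that fail (too few points,
#' degenerate) are reported, not fatal.
#'
#' @param data Long-format data frame of A-Ci measurements.
#' @param kin,arrhenius Kinetics configuration, as in [fit_aci()].
#' @param leak_coefficient Passed to [leak_correct()].
#' @param tpu_drop_threshold,tpu_min_Ci Passed to [exclude_tpu_points()].
#' @return A tibble, one row per curve: parameters at leaf T and at 25 C,
#'   `transition_Ci`, `sum_of_squares`, `converged`, `n_excluded`,
#'   `error` (NA unless the curve failed).
#' @export
fit_aci_curves <- function(data, kin = kinetic_constants(),
                           arrhenius = default_arrhenius(),
                           leak_coefficient = 0,
                           tpu_drop_threshold = 0.5, tpu_min_Ci = 800) {
  stopifnot(all(c("curve_id", "Ci", "A") %in% names(data)))
  ids <- unique(data$curve_id)
  rows <- lapply(ids, function(id) {
    d <- data[data$curve_id == id, ]
    out <- tibble::tibble(
      curve_id = id,
      genotype_id = if ("genotype_id" %in% names(d)) d$genotype_id[1] else NA,
      treatment = if ("treatment" %in% names(d)) d$treatment[1] else NA,
      Vcmax = NA_real_, Jmax = NA_real_, Rd = NA_real_,
      Vcmax_25 = NA_real_, Jmax_25 = NA_real_, Rd_25 = NA_real_,
      transition_Ci = NA_real_, sum_of_squares = NA_real_,
      converged = NA, n_excluded = NA_integer_, error = NA_character_)
    res <- tryCatch({
      cv <- aci_curve(
        d$Ci, d$A, curve_id = id,
        genotype_id = out$genotype_id, treatment = out$treatment,
        leaf_temperature = if ("T_leaf" %in% names(d)) d$T_leaf[1] else 25,
        O2_fraction = if ("O2" %in% names(d)) d$O2[1] else 210)
      cv <- leak_correct(cv, leak_coefficient)
      ex <- exclude_tpu_points(cv, tpu_drop_threshold, tpu_min_Ci)
      fit <- fit_aci(ex$curve, kin, arrhenius)
      list(fit = fit, n_excluded = nrow(ex$excluded))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      f <- res$fit
      out$Vcmax <- f$params_at_leafT$Vcmax
      out$Jmax <- f$params_at_leafT$Jmax
      out$Rd <- f$params_at_leafT$Rd
      out$Vcmax_25 <- f$params_at_25C$Vcmax
      out$Jmax_25 <- f$params_at_25C$Jmax
      out$Rd_25 <- f$params_at_25C$Rd
      out$transition_Ci <- f$transition_Ci
      out$sum_of_squares <- f$sum_of_squares
      out$converged <- f$converged
      out$n_excluded <- res$n_excluded
    }
    out
  })
  dplyr::bind_rows(rows)
}
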