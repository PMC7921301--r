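#' Default per-trait calibration table for the generator
#'
#' Treatment means and SDs per trait. Means and SDs follow the summary
#' statistics of the emulated growth-room study; for respiration in the
#' light (`rd`) and leaf mass per area (`lma`) — the two traits whose CO2
#' response was not statistically detectable — the default high-CO2 mean
#' equals the ambient mean, i.e. the generator's ground truth is a null
#' effect. Strictly positive traits are drawn log-normally (`log_scale`).
#' `e_op` (transpiration) is calibrated so the derived WUE_op means land
#' at 5.0 and 7.9 umol mmol^-1.
#'
#' @return A tibble with columns `trait`, `mean_ambient`, `mean_high`,
#'   `sd_ambient`, `sd_high`, `log_scale`.
#' @export
default_trait_table <- function() {
  tibble::tribble(
    ~trait,         ~mean_ambient, ~mean_high, ~sd_ambient, ~sd_high, ~log_scale,
    "dw",            23.0,          33.4,       10.8,        17.5,     TRUE,
    "tiller_count",  131,           146,        51,          65,       TRUE,
    "la_tiller",     0.0040,        0.0045,     0.0010,      0.0011,   TRUE,
    "lma",           30.9,          30.9,       7.5,         9.9,      TRUE,
    "a_op",          13.5,          16.8,       3.2,         3.1,      TRUE,
    "g_sop",         0.32,          0.26,       0.14,        0.11,     TRUE,
    "e_op",          2.70,          2.13,       0.65,        0.55,     TRUE,
    "n_mass",        4.9,           4.7,        0.6,         0.6,      TRUE,
    "c_mass",        38.7,          39.1,       1.5,         1.6,      TRUE,
    "vcmax",         71.1,          59.4,       12.5,        13.5,     TRUE,
    "jmax",          134.3,         112.8,      24.4,        26.8,     TRUE,
    "rd",            0.89,          0.89,       0.25,        0.28,     TRUE
  )
}

#' Generator configuration
#'
#' Describes the hierarchical design the generator emulates: genotypes
#' (with a status mix of cultivars, semi-natural and wild perennial
#' accessions plus one annual and one hybrid cultivar), two CO2
#' treatments, two chambers nested in each treatment, and a fixed number
#' of plants per genotype and treatment split across the chambers.
#'
#' Variance structure (log scale for positive traits): each trait's total
#' log-variance is split into a genotype share (`genotype_frac`), a small
#' chamber effect (`chamber_sd`), and residual; genotype intercepts are
#' shared across treatments. Genotype-specific CO2-response multipliers
#' (log-SD `response_sd`, mean corrected to 1) act on tiller count — the
#' trait through which the emulated study's biomass responses diverge —
#' and on the operational photosynthetic rate. Tiller count and leaf area
#' per tiller get a negative genotype-level log-correlation
#' (`tiller_la_cor`), the familiar size-number trade-off.
#'
#' With `mechanistic_link = TRUE` (default), aboveground dry mass is
#' computed from the generated tiller count, latent leaf area per tiller,
#' LMA and LMF_ab (times residual noise), with a closed-form
#' normalization constant so the population mean of DW still equals the
#' configured treatment mean (a mean of products is not a product of
#' means). Tiller count is then the dominant DW predictor, and genotype
#' DW means are rank-concordant across treatments.
#'
#' @param n_genotypes Number of genotypes (default 38).
#' @param status_mix Named integer vector of genotype counts by status;
#'   must sum to `n_genotypes`.
#' @param plants_per_genotype Plants per genotype per treatment (split
#'   over the 2 chambers of each treatment).
#' @param traits Trait calibration table, see [default_trait_table()].
#' @param genotype_frac Fraction of each trait's log-variance placed at
#'   genotype level.
#' @param chamber_sd Log-SD of the per-chamber, per-trait effect.
#' @param response_sd Named numeric: genotype CO2-response log-SD per
#'   trait (traits not named get 0).
#' @param tiller_la_cor Genotype-level log-correlation between tiller
#'   count and leaf area per tiller.
#' @param mechanistic_link Compute DW from tillers x LA_tiller x LMA /
#'   LMF_ab (TRUE) or draw it directly (FALSE).
#' @param dw_resid_sd Extra log-SD of DW noise in the mechanistic link.
#' @param gas_exchange_per_genotype Plants per genotype and treatment
#'   carrying A-Ci-derived traits (vcmax, jmax, rd); others get NA, as in
#'   a subsampled campaign.
#' @param null_effects If TRUE, all treatment effects and response SDs
#'   are zeroed (for type-I-error simulation).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genotypes = 38,
                             status_mix = c(cultivar = 11, semi_natural = 16,
                                            wild = 9, annual = 1, hybrid = 1),
                             plants_per_genotype = 5,
                             traits = default_trait_table(),
                             genotype_frac = 0.85,
                             chamber_sd = 0.005,
                             response_sd = c(tiller_count = 0.15, a_op = 0.15),
                             tiller_la_cor = -0.3,
                             mechanistic_link = TRUE,
                             dw_resid_sd = 0.20,
                             gas_exchange_per_genotype = 2,
                             null_effects = FALSE) {
  if (n_genotypes < 1 || plants_per_genotype < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  if (sum(status_mix) != n_genotypes) {
    stop("status_mix must sum to n_genotypes", call. = FALSE)
  }
  if (genotype_frac < 0 || genotype_frac > 1) {
    stop("genotype_frac must lie in [0, 1]", call. = FALSE)
  }
  if (any(traits$sd_ambient < 0) || any(traits$sd_high < 0) ||
      chamber_sd < 0 || any(response_sd < 0) || dw_resid_sd < 0) {
    stop("SDs must be non-negative", call. = FALSE)
  }
  if (abs(tiller_la_cor) > 1) stop("correlation out of range", call. = FALSE)
  if (null_effects) {
    traits$mean_high <- traits$mean_ambient
    traits$sd_high <- traits$sd_ambient
    response_sd[] <- 0
  }
  structure(list(
    n_genotypes = n_genotypes, status_mix = status_mix,
    plants_per_genotype = plants_per_genotype, traits = traits,
    genotype_frac = genotype_frac, chamber_sd = chamber_sd,
    response_sd = response_sd, tiller_la_cor = tiller_la_cor,
    mechanistic_link = mechanistic_link, dw_resid_sd = dw_resid_sd,
    gas_exchange_per_genotype = gas_exchange_per_genotype
  ), class = "generator_config")
}

# log-SD implied by an arithmetic mean/SD pair under log-normality
sdlog_of <- function(mean, sd) sqrt(log1p((sd / mean)^2))

#' Generate a per-plant trait dataset
#'
#' Draws a full synthetic dataset under the design described by
#' [generator_config()]: genotype intercepts shared across treatments,
#' genotype-specific CO2-response multipliers, chamber effects and
#' residual noise, with DW tied mechanistically to tillering when the
#' link is on. Derived traits (C:N, WUE_op, LA_tiller, A_plant) are
#' populated through [derive_traits()], so every record satisfies the
#' trait identities. Reproducible given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (optional).
#' @return A tibble, one row per plant; see [load_plants()] for columns.
#' @export
#' @examples
#' plants <- generate_plants(generator_config(), seed = 1)
#' dplyr::count(plants, treatment)
generate_plants <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)

  tr <- config$traits
  fg <- config$genotype_frac
  nG <- config$n_genotypes
  status <- rep(names(config$status_mix), times = config$status_mix)
  species <- ifelse(status == "annual", "annual",
                    ifelse(status == "hybrid", "hybrid", "perennial"))
  geno <- tibble::tibble(
    genotype_id = sprintf("G%02d", seq_len(nG)),
    status = status, species = species,
    # tetraploids occur mainly among bred material
    ploidy = ifelse(status == "cultivar" & seq_len(nG) %% 3 == 0, "4n", "2n"))

  treatments <- c("ambient", "high_CO2")
  chambers <- list(ambient = c("A1", "A2"), high_CO2 = c("E1", "E2"))
  ppg <- config$plants_per_genotype

  # plant skeleton: genotype x treatment x plant, chambers balanced
  grid <- tidyr::expand_grid(genotype_id = geno$genotype_id,
                             treatment = treatments,
                             plant = seq_len(ppg))
  grid <- dplyr::left_join(grid, geno, by = "genotype_id")
  g_index <- match(grid$genotype_id, geno$genotype_id)
  grid$chamber_id <- mapply(function(trt, pl, gi) {
    chambers[[trt]][1 + (pl + gi) %% 2]
  }, grid$treatment, grid$plant, g_index)
  n <- nrow(grid)
  is_high <- grid$treatment == "high_CO2"

  # per-trait log-SDs from the ambient-arm CV
  s_tot <- stats::setNames(sdlog_of(tr$mean_ambient, tr$sd_ambient), tr$trait)
  s_g <- sqrt(fg) * s_tot
  s_e <- sqrt(1 - fg) * s_tot

  # genotype intercepts; tiller_count ~ la_tiller correlated at genotype level
  b <- sapply(tr$trait, function(t) stats::rnorm(nG, 0, s_g[t]))
  rho <- config$tiller_la_cor
  if (rho != 0 && all(c("tiller_count", "la_tiller") %in% tr$trait) &&
      s_g["tiller_count"] > 0 && s_g["la_tiller"] > 0) {
    z <- stats::rnorm(nG)
    b[, "la_tiller"] <- s_g["la_tiller"] *
      (rho * b[, "tiller_count"] / s_g["tiller_count"] + sqrt(1 - rho^2) * z)
  }

  # genotype CO2-response log effects (mean-corrected multipliers)
  r_sd <- stats::setNames(rep(0, nrow(tr)), tr$trait)
  r_sd[names(config$response_sd)] <- config$response_sd
  r <- sapply(tr$trait, function(t) stats::rnorm(nG, 0, r_sd[t]))

  # chamber effects per trait
  all_ch <- unlist(chambers)
  ch_eff <- sapply(tr$trait, function(t) {
    stats::setNames(stats::rnorm(length(all_ch), 0, config$chamber_sd), all_ch)
  })

  vals <- list()
  for (t in tr$trait) {
    row <- tr[tr$trait == t, ]
    m <- ifelse(is_high, row$mean_high, row$mean_ambient)
    z <- b[g_index, t] + ifelse(is_high, r[g_index, t], 0) +
      unname(ch_eff[grid$chamber_id, t]) + stats::rnorm(n, 0, s_e[t])
    vz <- s_g[t]^2 + ifelse(is_high, r_sd[t]^2, 0) +
      config$chamber_sd^2 + s_e[t]^2
    vals[[t]] <- m * exp(z - vz / 2)
  }

  plants <- dplyr::bind_cols(grid["genotype_id"], grid["status"],
                             grid["species"], grid["ploidy"],
                             grid["treatment"], grid["chamber_id"],
                             tibble::as_tibble(vals))
  plants$plant_id <- sprintf("%s_%s_%d", plants$genotype_id,
                             ifelse(is_high, "E", "A"), grid$plant)

  plants$tiller_count <- pmax(1, round(plants$tiller_count))
  plants$lmf_ab <- lmf_ab(plants$species, plants$treatment)

  if (config$mechanistic_link) {
    # DW = c * tillers * LA_tiller * LMA / LMF_ab * noise, with c chosen so
    # the population mean equals the configured DW mean.
    trt_row <- function(t) tr[tr$trait == t, ]
    eps <- stats::rnorm(n, 0, config$dw_resid_sd)
    cov_tla <- rho * fg * s_tot["tiller_count"] * s_tot["la_tiller"]
    m_dw <- ifelse(is_high, trt_row("dw")$mean_high, trt_row("dw")$mean_ambient)
    m_t <- ifelse(is_high, trt_row("tiller_count")$mean_high,
                  trt_row("tiller_count")$mean_ambient)
    m_la <- ifelse(is_high, trt_row("la_tiller")$mean_high,
                   trt_row("la_tiller")$mean_ambient)
    m_lma <- ifelse(is_high, trt_row("lma")$mean_high,
                    trt_row("lma")$mean_ambient)
    calib <- m_dw * plants$lmf_ab / (m_t * m_la * m_lma * exp(cov_tla))
    plants$dw <- calib * plants$tiller_count * plants$la_tiller *
      plants$lma / plants$lmf_ab *
      exp(eps - config$dw_resid_sd^2 / 2)
  }

  # sampled blade: area ~ lognormal around 1 cm^2, dry mass from LMA
  la_blade <- 1e-4 * exp(stats::rnorm(n, 0, 0.2) - 0.02)
  plants$leaf_area <- la_blade
  plants$leaf_dry_mass <- plants$lma * la_blade

  # A-Ci-derived traits only exist on the measured subsample
  sub <- grid$plant <= config$gas_exchange_per_genotype
  for (t in intersect(c("vcmax", "jmax", "rd"), names(plants))) {
    plants[[t]][!sub] <- NA_real_
  }
  plants$gas_exchange_subsample <- sub

  plants <- derive_traits(plants)
  cols <- c("plant_id", "genotype_id", "status", "species", "ploidy",
            "treatment", "chamber_id", "dw", "tiller_count",
            "leaf_dry_mass", "leaf_area", "lma", "n_mass", "c_mass",
            "cn_ratio", "a_op", "g_sop", "e_op", "wue_op", "lmf_ab",
            "la_tiller", "a_plant", "vcmax", "jmax", "rd",
            "gas_exchange_subsample")
  plants[, cols]
}

#' Generate a synthetic A-Ci curve
#'
#' FvCB envelope prediction on a Ci grid plus iid Gaussian noise;
#' optionally with a triose-phosphate-use plateau: for Ci >= `tpu_from`
#' the assimilation is capped at the pre-plateau maximum and declines by
#' `tpu_decline` per point, to exercise [exclude_tpu_points()].
#'
#' @param params An [fvcb_params()].
#' @param Ci_grid Ci values \[umol mol^-1\]; default [aci_grid()].
#' @param noise_sd Gaussian noise SD \[umol m^-2 s^-1\], >= 0.
#' @param with_tpu Add the TPU plateau/decline tail.
#' @param tpu_from Ci at and above which TPU limitation applies.
#' @param tpu_decline Per-point decline of the TPU tail
#'   \[umol m^-2 s^-1\].
#' @param kin [kinetic_constants()] (scaled internally to `leaf_temperature`).
#' @param leaf_temperature Leaf temperature of the simulated curve \[C\].
#' @param seed Integer seed (optional).
#' @param curve_id,genotype_id,treatment Labels passed to [aci_curve()].
#' @return An [aci_curve()].
#' @export
generate_aci <- function(params, Ci_grid = aci_grid(), noise_sd = 0,
                         with_tpu = FALSE, tpu_from = 1000,
                         tpu_decline = 0.75, kin = kinetic_constants(),
                         leaf_temperature = 25, seed = NULL,
                         curve_id = "sim", genotype_id = NA_character_,
                         treatment = NA_character_) {
  if (length(Ci_grid) == 0) stop("Ci_grid must be non-empty", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  kin_leaf <- kinetics_at(kin, leaf_temperature)
  grid <- sort(Ci_grid)
  A <- predict_envelope(grid, params, kin_leaf)$A
  if (with_tpu) {
    tail_idx <- which(grid >= tpu_from)
    if (length(tail_idx) > 0 && min(tail_idx) > 1) {
      cap <- max(A[seq_len(min(tail_idx) - 1)])
      A[tail_idx] <- cap - tpu_decline * seq_along(tail_idx)
    }
  }
  if (noise_sd > 0) A <- A + stats::rnorm(length(A), 0, noise_sd)
  aci_curve(grid, A, curve_id = curve_id, genotype_id = genotype_id,
            treatment = treatment, leaf_temperature = leaf_temperature)
}

#' Generate a germination contingency table
#'
#' Binomial germination counts per treatment, as a 2x2 table
#' (rows: treatments; columns: germinated / failed).
#'
#' @param rates Germination probabilities per treatment, in \[0, 1\].
#' @param n_seeds Seeds sown per treatment.
#' @param seed Integer seed (optional).
#' @return An integer matrix with treatment rows and
#'   `germinated`/`failed` columns.
#' @export
#' @examples
#' generate_germination(c(ambient = 0.75, high_CO2 = 0.73),
#'                      c(600, 600), seed = 1)
generate_germination <- function(rates = c(ambient = 0.75, high_CO2 = 0.73),
                                 n_seeds = c(600, 600), seed = NULL) {
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  germ <- as.integer(stats::rbinom(length(rates), n_seeds, rates))
  out <- cbind(germinated = germ, failed = as.integer(n_seeds) - germ)
  rownames(out) <- names(rates)
  out
}

#' Germination rates from a contingency table
#'
#' Per-group and pooled germination rates (percent) from a counts table
#' with `germinated` and `failed` columns.
#'
#' @param counts Matrix as returned by [generate_germination()].
#' @return A list with `per_group` (named percent vector) and `pooled`
#'   (percent).
#' @export
germination_rates <- function(counts) {
  stopifnot(all(c("germinated", "failed") %in% colnames(counts)))
  tot <- rowSums(counts)
  list(per_group = 100 * counts[, "germinated"] / tot,
       pooled = 100 * sum(counts[, "germinated"]) / sum(tot))
}
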