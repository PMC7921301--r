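#' Column dictionary for per-plant tables
#'
#' @return A tibble: `column`, `required`, `description`.
#' @export
plant_schema <- function() {
  tibble::tribble(
    ~column, ~required, ~description,
    "plant_id",       TRUE,  "unique plant identifier",
    "genotype_id",    TRUE,  "genotype code",
    "status",         TRUE,  "cultivar / semi_natural / wild / annual / hybrid",
    "ploidy",         FALSE, "2n or 4n",
    "species",        FALSE, "perennial / annual / hybrid (default perennial)",
    "treatment",      TRUE,  "ambient or high_CO2",
    "chamber_id",     TRUE,  "growth chamber label",
    "dw",             TRUE,  "aboveground dry mass [g per plant]",
    "tiller_count",   TRUE,  "number of tillers (integer >= 1)",
    "leaf_dry_mass",  FALSE, "sampled blade dry mass [g]",
    "leaf_area",      FALSE, "sampled blade area [m2]",
    "lma",            TRUE,  "leaf mass per area [g m-2]",
    "n_mass",         TRUE,  "leaf N [% dry mass]",
    "c_mass",         TRUE,  "leaf C [% dry mass]",
    "a_op",           TRUE,  "operational photosynthetic rate [umol m-2 s-1]",
    "g_sop",          TRUE,  "operational stomatal conductance [mol m-2 s-1]",
    "e_op",           TRUE,  "transpiration [mmol m-2 s-1]",
    "vcmax",          FALSE, "max carboxylation rate [umol m-2 s-1]",
    "jmax",           FALSE, "max RuBP regeneration rate [umol m-2 s-1]",
    "rd",             FALSE, "respiration in the light [umol m-2 s-1]"
  )
}

#' Load and validate a per-plant CSV
#'
#' Reads a per-plant trait table (see [plant_schema()] for the column
#' dictionary; empty cells are missing values; lines starting with `#`
#' are header comments). Rows violating the record invariants (positive
#' DW and LMA, integer tiller count >= 1, 0 < N_mass < C_mass < 100) are
#' rejected with line-numbered diagnostics; unknown columns only warn.
#' Derived traits are recomputed with [derive_traits()].
#'
#' @param path CSV path.
#' @return A validated tibble of plant records; rejected rows are
#'   attached as `attr(x, "rejected")`.
#' @export
load_plants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  schema <- plant_schema()
  missing_cols <- setdiff(schema$column[schema$required], names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  derived <- c("cn_ratio", "wue_op", "la_tiller", "a_plant", "lmf_ab",
               "gas_exchange_subsample")
  unknown <- setdiff(names(raw), c(schema$column, derived))
  if (length(unknown) > 0) {
    warning("unknown columns ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }

  problems <- character(0)
  bad <- rep(FALSE, nrow(raw))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      problems <<- c(problems, sprintf("line %d: %s", which(cond), msg))
      bad <<- bad | cond
    }
  }
  flag(raw$dw <= 0, "dw must be > 0")
  flag(raw$tiller_count < 1 | raw$tiller_count != round(raw$tiller_count),
       "tiller_count must be an integer >= 1")
  flag(raw$lma <= 0, "lma must be > 0")
  flag(raw$n_mass <= 0 | raw$n_mass >= raw$c_mass,
       "need 0 < n_mass < c_mass")
  flag(raw$c_mass >= 100, "c_mass must be < 100 %")
  flag(!raw$treatment %in% c("ambient", "high_CO2"),
       "treatment must be ambient or high_CO2")
  if (length(problems) > 0) {
    warning("rejected ", sum(bad), " row(s):\n  ",
            paste(problems, collapse = "\n  "), call. = FALSE)
  }
  rejected <- raw[bad, ]
  out <- derive_traits(raw[!bad, ])
  attr(out, "rejected") <- rejected
  out
}

#' Write a per-plant table with a provenance header
#'
#' Writes CSV preceded by `#`-comment header lines recording the seed
#' and configuration hash, so every output file carries its provenance.
#' Readable back with [load_plants()].
#'
#' @param plants Per-plant tibble.
#' @param path Output path.
#' @param seed Seed to record (optional).
#' @param config_hash Configuration hash to record (optional).
#' @export
write_plants <- function(plants, path, seed = NULL, config_hash = NULL) {
  header <- sprintf("# ryeco2 plant table | seed=%s | config=%s",
                    if (is.null(seed)) "NA" else seed,
                    if (is.null(config_hash)) "NA" else config_hash)
  writeLines(header, path)
  readr::write_csv(plants, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Table-1-style treatment summary over many traits
#'
#' Runs [compare_treatments()] for each trait and assembles the summary:
#' per-treatment n / mean / SD / 95% CI, the treatment t-value with
#' Satterthwaite df, p-value, significance stars, and the model path the
#' decision tree took.
#'
#' @param plants Per-plant table.
#' @param traits Trait columns to summarize.
#' @return A tibble, one row per trait.
#' @export
treatment_summary_table <- function(plants,
                                    traits = c("dw", "a_op", "vcmax", "jmax",
                                               "rd", "g_sop", "wue_op",
                                               "n_mass", "c_mass", "cn_ratio",
                                               "lma", "tiller_count",
                                               "la_tiller")) {
  rows <- lapply(traits, function(tr) {
    cmp <- compare_treatments(plants, tr)
    m <- cmp$means
    amb <- m[m$treatment == "ambient", ]
    hi <- m[m$treatment == "high_CO2", ]
    tibble::tibble(
      trait = tr,
      n_ambient = amb$n, mean_ambient = amb$mean, sd_ambient = amb$sd,
      ci_ambient = sprintf("%.3g-%.3g", amb$ci_lo, amb$ci_hi),
      n_high = hi$n, mean_high = hi$mean, sd_high = hi$sd,
      ci_high = sprintf("%.3g-%.3g", hi$ci_lo, hi$ci_hi),
      estimate = cmp$estimate, t_value = cmp$t_value, df = cmp$df,
      p_value = cmp$p_value, sig = significance_stars(cmp$p_value),
      model_path = cmp$model_path)
  })
  dplyr::bind_rows(rows)
}

#' Run the full synthetic-study pipeline
#'
#' Executes the whole chain on generated data: simulate plants, simulate
#' and fit one A-Ci curve per genotype x treatment from the genotype's
#' gas-exchange parameters, derive traits, and run the inference stages
#' (treatment summary, trait relationships, rank concordance, genotype
#' responses, correlograms, neat analysis, clustering per treatment,
#' germination test). Deterministic given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, CSV outputs, the
#'   dendrograms (Newick) and a provenance JSON are written there.
#' @param aci_noise_sd Noise SD of the simulated A-Ci curves.
#' @return A list of result objects (see names), plus `provenance`.
#' @export
run_full_pipeline <- function(config = generator_config(), seed = 1,
                              out_dir = NULL, aci_noise_sd = 0.3) {
  set.seed(seed)
  config_hash <- rlang::hash(config)
  plants <- generate_plants(config)

  # A-Ci campaign: one curve per genotype x treatment from the genotype's
  # mean gas-exchange parameters on the measured subsample
  sub <- plants[plants$gas_exchange_subsample & !is.na(plants$vcmax), ]
  gmeans <- dplyr::summarise(
    dplyr::group_by(sub, .data$genotype_id, .data$treatment),
    vcmax = mean(.data$vcmax), jmax = mean(.data$jmax), rd = mean(.data$rd),
    .groups = "drop")
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(gmeans)), function(i) {
    g <- gmeans[i, ]
    p <- fvcb_params(g$vcmax, g$jmax, g$rd, warn = FALSE)
    cv <- generate_aci(p, noise_sd = aci_noise_sd,
                       curve_id = paste(g$genotype_id, g$treatment, sep = "_"),
                       genotype_id = g$genotype_id, treatment = g$treatment)
    dplyr::mutate(cv$points, curve_id = cv$curve_id,
                  genotype_id = g$genotype_id, treatment = g$treatment,
                  true_vcmax = g$vcmax, true_jmax = g$jmax, true_rd = g$rd)
  }))
  aci_fits <- fit_aci_curves(curves)
  truth <- dplyr::distinct(curves, .data$curve_id, .data$true_vcmax,
                           .data$true_jmax, .data$true_rd)
  aci_fits <- dplyr::left_join(aci_fits, truth, by = "curve_id")

  summary_tbl <- treatment_summary_table(plants)

  relationships <- list(
    dw_tiller = fit_relationship(plants, "dw", "tiller_count",
                                 by_treatment = TRUE),
    dw_la_tiller = fit_relationship(plants, "dw", "la_tiller",
                                    by_treatment = TRUE),
    dw_cn = fit_relationship(plants, "dw", "cn_ratio", by_treatment = TRUE),
    dw_a_plant = fit_relationship(plants, "dw", "a_plant",
                                  by_treatment = TRUE),
    dw_a_op = fit_relationship(plants, "dw", "a_op", by_treatment = TRUE))

  responses <- genotype_mean_responses(plants, "dw")
  gm_dw <- genotype_mean_responses(plants, "dw")
  concordance <- rank_concordance(gm_dw$mean_ambient, gm_dw$mean_high)

  neat_preds <- c("a_op", "wue_op", "c_mass", "cn_ratio", "lma",
                  "tiller_count")
  neat <- lapply(c(ambient = "ambient", high_CO2 = "high_CO2"),
                 function(trt) {
    neat_analysis(plants[plants$treatment == trt, ], "dw", neat_preds)
  })

  cors <- lapply(c(ambient = "ambient", high_CO2 = "high_CO2"),
                 function(trt) {
    correlogram(plants[plants$treatment == trt, ],
                c("dw", cluster_traits()[-1], "n_mass", "g_sop"))
  })

  clusterings <- lapply(c(ambient = "ambient", high_CO2 = "high_CO2"),
                        function(trt) {
    m <- genotype_trait_matrix(plants, trt)
    sel <- select_clustering(m)
    # the per-trait comparison table is defined for a two-cluster split;
    # use the selected solution when it has k = 2, else the Ward 2-split
    two <- if (sel$best$k == 2) sel$best$assignments else
      stats::cutree(sel$linkage, k = 2)
    tests <- tryCatch(compare_cluster_traits(as.data.frame(m), two),
                      error = function(e) conditionMessage(e))
    list(selection = sel, trait_tests = tests)
  })

  germination <- generate_germination()
  germ_test <- germination_test(germination)

  provenance <- list(seed = seed, config_hash = config_hash,
                     package_version = as.character(utils::packageVersion("ryeco2")),
                     n_plants = nrow(plants))

  out <- list(plants = plants, aci_fits = aci_fits,
              treatment_summary = summary_tbl,
              relationships = relationships, responses = responses,
              rank_concordance = concordance, neat = neat,
              correlograms = cors, clusterings = clusterings,
              germination = germination, germination_test = germ_test,
              provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_plants(plants, file.path(out_dir, "plants.csv"), seed, config_hash)
    readr::write_csv(summary_tbl, file.path(out_dir, "treatment_summary.csv"))
    readr::write_csv(aci_fits, file.path(out_dir, "aci_fits.csv"))
    readr::write_csv(responses, file.path(out_dir, "genotype_responses.csv"))
    for (trt in names(clusterings)) {
      sel <- clusterings[[trt]]$selection
      readr::write_csv(
        tibble::tibble(genotype_id = rownames(sel$z),
                       cluster = sel$best$assignments),
        file.path(out_dir, paste0("clusters_", trt, ".csv")))
      writeLines(hclust_to_newick(sel$linkage),
                 file.path(out_dir, paste0("dendrogram_", trt, ".nwk")))
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Serialize an hclust tree as Newick text
#'
#' @param hc An `hclust` object.
#' @return A Newick string (branch lengths from merge heights).
#' @export
hclust_to_newick <- function(hc) {
  labels <- hc$labels
  if (is.null(labels)) labels <- as.character(seq_along(hc$order))
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6g", labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.6g", node(hc$merge[i, 1], h),
              node(hc$merge[i, 2], h), parent_h - h)
    }
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  sprintf("(%s,%s);", node(hc$merge[top, 1], h), node(hc$merge[top, 2], h))
}
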