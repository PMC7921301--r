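#' Aboveground leaf dry-mass fraction defaults
#'
#' LMF_ab — the fraction of aboveground dry mass that is leaf blade —
#' is conserved within ryegrass species but shifts with growth CO2.
#' Defaults: perennial ryegrass 0.66 (ambient) / 0.59 (high CO2); annual
#' ryegrass 0.57 / 0.53; the hybrid is assigned the perennial values.
#'
#' @param species One of `"perennial"`, `"annual"`, `"hybrid"` (vectorized).
#' @param treatment One of `"ambient"`, `"high_CO2"` (vectorized).
#' @return LMF_ab \[g g^-1\].
#' @export
lmf_ab <- function(species = "perennial", treatment = "ambient") {
  tab <- c(perennial.ambient = 0.66, perennial.high_CO2 = 0.59,
           annual.ambient = 0.57, annual.high_CO2 = 0.53,
           hybrid.ambient = 0.66, hybrid.high_CO2 = 0.59)
  key <- paste(species, treatment, sep = ".")
  bad <- !(key %in% names(tab))
  if (any(bad)) {
    stop("unknown species/treatment combination: ", paste(unique(key[bad]),
         collapse = ", "), call. = FALSE)
  }
  unname(tab[key])
}

#' Leaf mass per area
#'
#' @param leaf_dry_mass Dry mass of the sampled blade \[g\].
#' @param leaf_area Area of the sampled blade \[m^2\].
#' @return LMA \[g m^-2\].
#' @export
#' @examples
#' compute_lma(0.0031, 0.0001)  # 31 g m^-2
compute_lma <- function(leaf_dry_mass, leaf_area) {
  if (any(leaf_area <= 0, na.rm = TRUE)) {
    stop("leaf_area must be > 0", call. = FALSE)
  }
  if (any(leaf_dry_mass < 0, na.rm = TRUE)) {
    stop("leaf_dry_mass must be >= 0", call. = FALSE)
  }
  leaf_dry_mass / leaf_area
}

#' Mean leaf area per tiller
#'
#' The plant's total leaf area is its leaf dry mass (`DW * LMF_ab`)
#' divided by LMA; dividing by the tiller count gives the mean leaf area
#' carried by one tiller: `LA_tiller = DW * LMF_ab / (LMA * tiller_count)`.
#'
#' @param DW Aboveground dry mass \[g per plant\].
#' @param tiller_count Number of tillers (>= 1).
#' @param LMA Leaf mass per area \[g m^-2\].
#' @param LMF_ab Aboveground leaf dry-mass fraction \[g g^-1\].
#' @return LA_tiller \[m^2 per tiller\].
#' @export
compute_la_tiller <- function(DW, tiller_count, LMA, LMF_ab) {
  if (any(tiller_count <= 0, na.rm = TRUE)) {
    stop("tiller_count must be >= 1", call. = FALSE)
  }
  if (any(LMA <= 0, na.rm = TRUE) || any(LMF_ab <= 0, na.rm = TRUE)) {
    stop("LMA and LMF_ab must be > 0", call. = FALSE)
  }
  DW * LMF_ab / (LMA * tiller_count)
}

#' Whole-plant rate of net carbon gain
#'
#' Scales the operational leaf photosynthetic rate to the whole plant by
#' the plant's total leaf area: `A_plant = A_op * DW * LMF_ab / LMA`.
#' This assumes every leaf receives the measured average irradiance and
#' photosynthesizes at `A_op`; it is an approximation of in situ
#' whole-plant net carbon gain, not a canopy model.
#'
#' @param A_op Operational photosynthetic rate \[umol m^-2 s^-1\].
#' @param DW Aboveground dry mass \[g per plant\].
#' @param LMF_ab Aboveground leaf dry-mass fraction \[g g^-1\].
#' @param LMA Leaf mass per area \[g m^-2\].
#' @return A_plant \[umol s^-1 per plant\].
#' @export
#' @examples
#' compute_a_plant(13.5, 23.0, 0.66, 30.9)  # ~6.6 umol s^-1
compute_a_plant <- function(A_op, DW, LMF_ab, LMA) {
  if (any(LMA <= 0, na.rm = TRUE)) stop("LMA must be > 0", call. = FALSE)
  A_op * DW * LMF_ab / LMA
}

#' Operational water-use efficiency
#'
#' `WUE_op = A_op / E_op` in umol CO2 per mmol H2O; defined from
#' transpiration (not stomatal conductance) so the units match the
#' umol mmol^-1 convention.
#'
#' @param A_op Operational photosynthetic rate \[umol m^-2 s^-1\].
#' @param E_op Transpiration \[mmol m^-2 s^-1\], > 0.
#' @return WUE_op \[umol mmol^-1\].
#' @export
compute_wue <- function(A_op, E_op) {
  if (any(E_op <= 0, na.rm = TRUE)) stop("E_op must be > 0", call. = FALSE)
  A_op / E_op
}

#' Relative response to elevated CO2
#'
#' `100 * (mean_high - mean_ambient) / mean_ambient`, in percent.
#'
#' @param mean_ambient Trait mean under ambient CO2 (nonzero).
#' @param mean_high Trait mean under high CO2.
#' @return Relative change \[%\].
#' @export
#' @examples
#' percent_response(5.0, 7.9)  # +58%
percent_response <- function(mean_ambient, mean_high) {
  if (any(mean_ambient == 0, na.rm = TRUE)) {
    stop("zero baseline: percent response undefined", call. = FALSE)
  }
  100 * (mean_high - mean_ambient) / mean_ambient
}

#' Populate derived traits on a per-plant table
#'
#' Given measured columns, fills in the derived ones: `lma` (from the
#' sampled blade when `leaf_dry_mass`/`leaf_area` are present), `cn_ratio`,
#' `wue_op`, `la_tiller`, `a_plant`, and `lmf_ab` (from `species` and
#' `treatment`). A derived value is `NA` whenever any input is missing.
#'
#' @param plants Data frame with per-plant measured traits; see
#'   [load_plants()] for the column dictionary.
#' @return The table with derived columns added/overwritten.
#' @export
derive_traits <- function(plants) {
  p <- tibble::as_tibble(plants)
  if (!"species" %in% names(p)) p$species <- "perennial"
  p$lmf_ab <- lmf_ab(p$species, p$treatment)
  if (all(c("leaf_dry_mass", "leaf_area") %in% names(p)) &&
      !("lma" %in% names(p))) {
    p$lma <- compute_lma(p$leaf_dry_mass, p$leaf_area)
  }
  p$cn_ratio <- p$c_mass / p$n_mass
  p$wue_op <- compute_wue(p$a_op, p$e_op)
  p$la_tiller <- compute_la_tiller(p$dw, p$tiller_count, p$lma, p$lmf_ab)
  p$a_plant <- compute_a_plant(p$a_op, p$dw, p$lmf_ab, p$lma)
  p
}
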