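# shared fixtures: small generator configs and curve factories

table1_params <- function() fvcb_params(71.1, 134.3, 0.89, warn = FALSE)

# noiseless envelope curve on the standard grid
noiseless_curve <- function(params = table1_params(),
                            kin = kinetic_constants(), grid = aci_grid()) {
  env <- predict_envelope(grid, params, kin)
  aci_curve(env$Ci, env$A)
}

small_config <- function(...) {
  generator_config(n_genotypes = 12,
                   status_mix = c(cultivar = 4, semi_natural = 4, wild = 4),
                   plants_per_genotype = 3, ...)
}

null_config <- function() small_config(null_effects = TRUE)

# genotype x trait matrix with two well-separated archetypes
archetype_matrix <- function(n_per = 10, p = 6, sep = 6, seed = 99) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = sep), n_per))
  colnames(m) <- paste0("trait", seq_len(p))
  rownames(m) <- paste0("g", seq_len(2 * n_per))
  m
}
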