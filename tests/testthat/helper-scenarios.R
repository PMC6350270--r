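# Shared fixtures built in code.

# Single-drug scenario with every stochastic element switched off; used for
# closed-form recovery checks.
exact_scenario <- function(p = 0.5, a = 2, g = 0.5, seed = 1, ...) {
  scenario_config(
    seed = seed,
    drug_effects = drug_effect("drugX", p, a, g),
    deterministic = TRUE,
    ...
  )
}

# Paired VitroF/VivoF computation for one simulated replicate; returns the
# Pearson r of the score pairs.
replicate_concordance_r <- function(seed, concordant, n_drugs = 5) {
  eff <- sample_drug_effects(n_drugs, seed = seed, concordant = concordant)
  cfg <- scenario_config(seed = seed, drug_effects = eff)
  vit <- vitro_scores(simulate_explants(cfg), n_boot = 0)
  viv <- vivo_scores(caliper_volumes(simulate_growth(cfg)))
  pairs <- dplyr::inner_join(dplyr::select(vit, drug, vitro_f),
                             dplyr::select(viv, drug, vivo_f), by = "drug")
  concordance(pairs, n_perm = 0)$r
}

# Tiny image with k disjoint 3x3 supra-threshold squares on a blank field.
squares_image <- function(k, side = 40, value = 1) {
  img <- matrix(0, side, side)
  for (i in seq_len(k)) {
    r0 <- 2 + (i - 1) * 8
    img[r0:(r0 + 2), 5:7] <- value
  }
  img
}
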