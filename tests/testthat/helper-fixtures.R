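## shared in-code fixtures

## compact three-peak library for fast FID tests
tiny_library <- function() {
  data.frame(metabolite = c("TSP", "lactate", "glucose"),
             center_ppm = c(0, 1.33, 5.23),
             protons = c(9, 3, 1),
             linewidth_hz = 1.0)
}

## small two-group one-tissue table with a configurable planted effect
tiny_table <- function(seed = 1, n = 5, fold = 1, cv = 0.15,
                       metabolite = "glucose") {
  base <- default_baselines()
  eff <- if (fold != 1)
    data.frame(metabolite = metabolite, tissue = "maternal_heart",
               fold_change = fold)
  else default_effects()[0, ]
  generate_concentration_table(study_design(
    tissues = "maternal_heart", n_per_group = n, cv = cv,
    effects = eff, seed = seed))
}

## tiny enrichment network: 20 reactions over 4 subsystems
enrichment_toy_network <- function() {
  mets <- data.frame(id = c("a_c", "atp_c"), name = c("a", "ATP"),
                     compartment = "cytosol")
  rxns <- lapply(seq_len(19), function(i)
    list(id = sprintf("R%02d", i),
         stoich = c(a_c = (-1)^i),
         reversible = TRUE, lb = -10, ub = 10,
         subsystem = c("s1", "s2", "s3", "s4")[(i - 1) %% 4 + 1],
         tags = character(0), exchange_metabolite = NA_character_))
  rxns <- c(rxns, list(list(id = "DM", stoich = c(atp_c = -1, a_c = 1),
                            reversible = FALSE, lb = 0, ub = 10,
                            subsystem = "s1", tags = "atp_demand",
                            exchange_metabolite = NA_character_)))
  metabolic_network(mets, rxns)
}
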