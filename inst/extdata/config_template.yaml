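# Analysis configuration template (arguments of analysis_config()).
# Either `input` (a CSV phenotype table) or `simulate` must be given.

seed: 1          # mandatory; governs every stochastic step
alpha: 0.05      # significance level for cascading decisions
n_boot: 10000    # bootstrap replicates for fixed-effect CIs

# --- simulated input -------------------------------------------------------
simulate:
  design:                      # arguments to build_pedigree()
    n_blocks: 7
    sires_per_block: [2, 2, 3, 3, 3, 4, 6]
    dams_per_sire: [2, 3]
    total_dams: 59
    offspring_per_dam_per_treatment: 6
    attrition: 0.041
  traits:
    mass_eclosion:
      type: trait              # trait | repeated | latency
      model:                   # arguments to trait_model()/repeated_model()
        mu: 0.73
        beta_density: 0.05
        beta_sex: -0.09
        V_S: 0.0013
        V_block: 0.0021
        V_R: 0.0144

# --- per-trait analysis settings ------------------------------------------
traits:
  mass_eclosion:
    behavioural: false         # true adds test-day intercept + days_std
    repeated: false            # true runs the per-minute model comparison

# output_dir: results/         # omit to skip writing artifacts
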