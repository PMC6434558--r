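# Shared fixtures: compact breeding designs and generating models used
# across the test files.  Everything is built in code under fixed seeds.

# 3 blocks x 3 sires x 2 dams x 4 offspring per dam per treatment = 216
small_design <- function(seed = 1) {
  build_pedigree(n_blocks = 3, sires_per_block = 3, dams_per_sire = 2,
                 offspring_per_dam_per_treatment = 4, seed = seed)
}

# one independent family per "block" so that every random-effect vector has
# n_families independent draws (moment checks)
family_array_design <- function(n_families, offspring_per_treatment = 1,
                                seed = 1) {
  build_pedigree(n_blocks = n_families, sires_per_block = 1,
                 dams_per_sire = 1,
                 offspring_per_dam_per_treatment = offspring_per_treatment,
                 seed = seed)
}

# balanced nested fixture: s sires x d dams x k offspring, single block
balanced_nested_table <- function(s = 10, d = 2, k = 5, V_S = 2, V_M = 1.5,
                                  V_R = 1, seed = 1) {
  set.seed(seed)
  sire <- factor(rep(sprintf("s%02d", seq_len(s)), each = d * k))
  dam <- factor(rep(sprintf("d%03d", seq_len(s * d)), each = k))
  y <- rnorm(s, 0, sqrt(V_S))[as.integer(sire)] +
    rnorm(s * d, 0, sqrt(V_M))[as.integer(dam)] +
    rnorm(s * d * k, 0, sqrt(V_R))
  data.frame(sire = sire, dam = dam, value = y)
}

# standard variance-component model specification used in most fits
std_spec <- function(response = "value",
                     fixed = c("treatment", "sex", "treatment:sex")) {
  model_spec(response, fixed = fixed,
             random = list(ran_intercept("dam_in_sire"),
                           ran_intercept("sire_in_block"),
                           ran_intercept("block")))
}

# Henderson / expected-mean-squares estimators for the balanced nested
# sire/dam design: the independent closed-form oracle for REML.
henderson_nested <- function(tab, k_per_dam, dams_per_sire) {
  a <- anova(lm(value ~ sire + dam, data = tab))
  ms <- a$"Mean Sq"
  list(V_S = (ms[1] - ms[2]) / (k_per_dam * dams_per_sire),
       V_M = (ms[2] - ms[3]) / k_per_dam,
       V_R = ms[3])
}
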