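#!/usr/bin/env Rscript
# Simulate the primary phagocytosis screen: 489 compounds at 10 uM, three
# replicate wells split across plates, 12 fields per well, DMSO and 2 uM
# cytochalasin D controls in fixed columns. About 10% of the library is
# planted as phagocytosis inhibitors (half-maximal effect) and 7% as toxic
# (cell loss below the 10% survival threshold), matching the composition
# the downstream stages are designed to resolve.

library(phagoscreen)

dir.create("results", showWarnings = FALSE)

# graded inhibitor potencies (25-70% of the DMSO phagocytic index) so the
# secondary screen has a real potency gradient to confirm
set.seed(1)
classes <- sample(rep(c("inhibitor", "null", "toxic"), c(47L, 407L, 35L)))
potency <- ifelse(classes == "inhibitor", runif(489, 0.25, 0.70), 1)
cfg <- screen_sim_config(n_compounds = 489L,
                         effect_classes = classes,
                         pi_multipliers = potency,
                         seed = 1L)
sim <- simulate_screen(cfg)

write_screen_table(sim$fields, "results/primary_fields.tsv")
write_screen_table(sim$truth, "results/primary_truth.tsv")

cat("simulated", nrow(sim$fields), "fields over",
    length(unique(sim$fields$plate)), "plates\n")
print(table(sim$truth$class))
cat("wrote results/primary_fields.tsv and results/primary_truth.tsv\n")
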