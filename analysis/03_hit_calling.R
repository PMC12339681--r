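#!/usr/bin/env Rscript
# Hit calling on the simulated primary screen: per-compound Z-scores
# against the DMSO wells, hits at Z <= -2 after toxicity exclusion, then a
# simulated secondary confirmation screen (15 fields per well) on the hit
# compounds with ratio-to-DMSO classification.

library(phagoscreen)

fields <- read_screen_table("results/primary_fields.tsv")
truth <- read_screen_table("results/primary_truth.tsv")
pr <- run_primary_screen(fields)
res <- pr$results

cat(sprintf("toxicity filter removed %d compounds\n",
            sum(res$toxic_primary)))
cat(sprintf("primary hits (Z <= -2): %d; activators (Z >= 2): %d\n",
            sum(res$primary_hit), sum(res$activator)))
m <- merge(res, truth, by = "compound")
cat(sprintf("sensitivity on planted inhibitors: %.3f\n",
            sum(m$primary_hit & m$class == "inhibitor") /
              sum(m$class == "inhibitor")))

# secondary screen on the hits: same true effects, fresh noise, 15 fields
hit_rows <- m[m$primary_hit, ]
hit_rows <- hit_rows[order(hit_rows$compound), ]
cfg2 <- screen_sim_config(n_compounds = nrow(hit_rows),
                          fields_per_well = 15L,
                          effect_classes = hit_rows$class,
                          pi_multipliers = hit_rows$pi_multiplier,
                          seed = 101L)
sim2 <- simulate_screen(cfg2)
w2 <- summarize_wells(sim2$fields)
dmso_fields <- sim2$fields[sim2$fields$role == "dmso" &
                             sim2$fields$cell_count > 0, ]
dmso_pi <- dmso_fields$synaptosome_area / dmso_fields$cell_count
sec <- do.call(rbind, lapply(sort(unique(sim2$truth$compound)),
  function(cp) {
    f <- sim2$fields[!is.na(sim2$fields$compound) &
                       sim2$fields$compound == cp &
                       sim2$fields$cell_count > 0, ]
    r <- secondary_ratio(f$synaptosome_area / f$cell_count, dmso_pi)
    data.frame(compound = cp, ratio = r$ratio, sem = r$sem)
  }))
tox2 <- unique(w2$compound[w2$exclusion_reason == "toxicity"])
sec$classification <- classify_compound(sec$ratio,
                                        sec$compound %in% tox2)
print(table(sec$classification))

cc <- primary_secondary_concordance(
  res$mean_pi[res$primary_hit], sec$ratio)
cat(sprintf("primary/secondary concordance: r = %.2f, p = %.3g (n = %d)\n",
            cc$r, cc$p, cc$n))

write_screen_table(res, "results/primary_results.tsv")
write_screen_table(sec, "results/secondary_results.tsv")
cat("wrote results/primary_results.tsv and results/secondary_results.tsv\n")
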