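#!/usr/bin/env Rscript
# Morphological phenotyping: per-compound solidity / eccentricity / IBA1
# phenotypes from the primary screen wells, feature correlations, and a
# PCA of functional plus morphological features. Also demonstrates the
# image-level route: a rendered field is measured and its cells classified
# into morphotypes.

library(phagoscreen)

wells <- read_screen_table("results/primary_wells.tsv")
ph <- compound_phenotypes(wells)

fc_se <- feature_correlation(ph, "mean_solidity", "mean_eccentricity")
fc_ei <- feature_correlation(ph, "mean_eccentricity", "mean_iba1")
fc_si <- feature_correlation(ph, "mean_solidity", "mean_iba1")
cat(sprintf("solidity vs eccentricity: r = %.3f (p = %.2g)\n",
            fc_se$r, fc_se$p))
cat(sprintf("eccentricity vs IBA1:     r = %.3f (p = %.2g)\n",
            fc_ei$r, fc_ei$p))
cat(sprintf("solidity vs IBA1:         r = %.3f (p = %.2g)\n",
            fc_si$r, fc_si$p))

p <- phenotype_pca(ph)
cat("PCA variance fractions:",
    paste(sprintf("%.2f", p$variance_fraction), collapse = " "), "\n")
write_screen_table(ph, "results/compound_phenotypes.tsv")
write_screen_table(cbind(feature = rownames(p$loadings),
                         as.data.frame(p$loadings)),
                   "results/pca_loadings.tsv")

# image-level morphotyping on one rendered field; rendered cells are
# convex ellipses (solidity ~ 1), so this route separates compact from
# elongated cells while the ramified (low-solidity) class needs branched
# real cells
spec <- field_render_spec(width = 512, height = 512,
  cells = data.frame(x = seq(60, 460, length.out = 6),
                     y = rep(c(120, 380), 3),
                     a = c(60, 30, 45, 55, 35, 40),
                     b = c(15, 28, 30, 14, 33, 18),
                     theta = seq(0, 2, length.out = 6),
                     iba1 = 0.8),
  puncta_inside = 20L, seed = 2L)
rf <- render_field(spec)
mf <- measure_field(list(nuclei = rf$image[, , 1],
                         iba1 = rf$image[, , 2],
                         phrodo = rf$image[, , 3]))
mf$cells$morphotype <- classify_morphotype(mf$cells$solidity,
                                           mf$cells$eccentricity)
print(mf$cells[, c("label", "solidity", "eccentricity", "morphotype")])
cat("wrote results/compound_phenotypes.tsv and results/pca_loadings.tsv\n")
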