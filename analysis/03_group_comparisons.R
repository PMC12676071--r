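#!/usr/bin/env Rscript
# Group statistics on the crossover traits: one-way ANOVA with Tukey's HSD
# over the subpopulation x treatment cells (and over treatment alone, the
# nutrient-deficiency contrast), plus trait correlations.

library(gametecross)

traits <- read.csv("results/02_trait_table.csv")

dir.create("results", showWarnings = FALSE)
rows <- list()
for (trait in c("cc_per_chromatid", "icd_mean", "ics_mean")) {
  ge_cells <- group_effects(traits, trait)
  ge_nd <- group_effects(traits, trait, factors = "treatment")
  cat(sprintf("\n== %s ==\n", trait))
  cat(sprintf("ANOVA over 4 cells: F = %.2f, p = %.3g\n",
              ge_cells$anova$f, ge_cells$anova$p))
  est <- ge_nd$contrasts$estimate[1]
  ctl <- ge_nd$group_means[["control"]]
  cat(sprintf("ND effect: %+.3f (%+.1f%%), Tukey p = %.3g\n",
              est, 100 * est / ctl, ge_nd$contrasts$p_adj[1]))
  ge_cells$contrasts$trait <- trait
  rows[[trait]] <- ge_cells$contrasts
}
write.csv(do.call(rbind, rows), "results/03_tukey_contrasts.csv",
          row.names = FALSE)

cat(sprintf("\nTrait correlations: cor(CC, ICS) = %.2f, cor(CC, ICD) = %.2f\n",
            cor(traits$cc_per_chromatid, traits$ics_mean),
            cor(traits$cc_per_chromatid, traits$icd_mean, use = "complete.obs")))
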