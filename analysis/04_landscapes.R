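#!/usr/bin/env Rscript
# Broad-scale recombination landscapes in 10% windows, converted to cM/Mb,
# compared between control and nutrient-deficient conditions: genome-wide
# rates, Pearson correlation of the window profiles, and per-window
# chi-square tests with Benjamini-Hochberg correction.

library(gametecross)

bundle <- read_cohort("scratch/cohort")
events <- read.csv("scratch/02_crossover_events.csv")
traits <- read.csv("results/02_trait_table.csv")

# count retained gametes per condition from the analysed individuals
retained_ids <- traits$individual_id
per_trt_gametes <- table(bundle$meta$treatment[match(
  bundle$nuclei$individual_id, bundle$meta$individual_id)][
    bundle$nuclei$individual_id %in% retained_ids])

ev_trt <- traits$treatment[match(events$individual_id, traits$individual_id)]
ls <- list()
for (trt in c("control", "nutrient_deficiency")) {
  ls[[trt]] <- build_landscape(events[ev_trt == trt, ],
                               per_trt_gametes[[trt]], bundle$map)
  cat(sprintf("%s: genome-wide rate %.3f cM/Mb over %d gametes\n",
              trt, attr(ls[[trt]], "genome_rate_cm_per_mb"),
              per_trt_gametes[[trt]]))
}
cmp <- compare_landscapes(ls$control, ls$nutrient_deficiency)
cat(sprintf("Landscape correlation control vs ND: r = %.3f (p = %.3g)\n",
            cmp$pearson_r, cmp$cor_p))
cat(sprintf("Per-window chi-square: min BH-adjusted p = %.3f (%d windows)\n",
            min(cmp$windows$p_adj), nrow(cmp$windows)))

dir.create("results", showWarnings = FALSE)
both <- rbind(cbind(as.data.frame(ls$control), condition = "control"),
              cbind(as.data.frame(ls$nutrient_deficiency),
                    condition = "nutrient_deficiency"))
write.csv(both, "results/04_landscapes.csv", row.names = FALSE)
write.csv(cmp$windows, "results/04_window_tests.csv", row.names = FALSE)
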