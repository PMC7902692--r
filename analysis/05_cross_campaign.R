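#!/usr/bin/env Rscript
# Cross-campaign comparison: three synthetic campaigns on their historical
# panels (7, 12 and 19 biomarkers), independent network estimation per
# campaign, then the conserved network across all three on the 6 shared
# biomarkers and across the last two on the 12 shared biomarkers.

library(hbmnet)

panels <- flehs_panels()
seed <- 20260928L
campaign <- function(panel, n, seed) {
  full <- default_synthetic_spec(n_samples = n, seed = seed)
  part <- full$partition[panel]
  spec <- synthetic_spec(n, part, within_block_pcorr = 0.4,
                         bridge_edges = NULL,
                         lod_quantile = 0.15, missing_rate = 0.02,
                         seed = seed)
  sim <- simulate_dataset(spec)
  am <- preprocess_dataset(sim$dataset, adjust = c("age", "bmi", "smoking"),
                           seed = seed)
  stars_select(am, seed = seed)$selected_graph
}
nets <- list(flehs1 = campaign(panels$flehs1, 1196, derive_seed(seed, 1)),
             flehs2 = campaign(panels$flehs2, 255, derive_seed(seed, 2)),
             flehs3 = campaign(panels$flehs3, 281, derive_seed(seed, 3)))

dir.create("results/cross_campaign", recursive = TRUE, showWarnings = FALSE)
for (nm in names(nets)) {
  write_network_tsv(nets[[nm]],
                    file.path("results/cross_campaign",
                              paste0("network_", nm, ".tsv")))
  cat(nm, ": ", length(nets[[nm]]$labels), " biomarkers, ",
      n_edges(nets[[nm]]), " edges\n", sep = "")
}

cons3 <- conserved_network(nets)
write_network_tsv(cons3, "results/cross_campaign/conserved_all3.tsv")
pt3 <- cna_communities(cons3, min_size = 6)
write_partition_tsv(pt3, "results/cross_campaign/conserved_all3_communities.tsv")
cat("conserved across 3 campaigns (", length(cons3$labels),
    " shared biomarkers): ", n_edges(cons3), " edges\n", sep = "")

cons2 <- conserved_network(nets[c("flehs2", "flehs3")])
write_network_tsv(cons2, "results/cross_campaign/conserved_2_3.tsv")
pt2 <- cna_communities(cons2, min_size = 6)
write_partition_tsv(pt2, "results/cross_campaign/conserved_2_3_communities.tsv")
plot_network(cons2, "results/cross_campaign/conserved_2_3.svg",
             cna_mode = TRUE)
cat("conserved across campaigns 2-3 (", length(cons2$labels),
    " shared biomarkers): ", n_edges(cons2), " edges\n", sep = "")
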