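#!/usr/bin/env Rscript
# Richness/diversity and ordination on the simulated two-group experiment:
# rarefy all samples to a common depth, compute observed richness, Chao1 and
# Gini-Simpson diversity, then ordinate Bray-Curtis distances by PCoA (and
# NMDS for the stress value).

library(metacompare)
dir.create("results", showWarnings = FALSE)

spec <- table1_community_spec(reads_per_library = 800L, n_individuals_b = 20L,
                              seed = 7L)
sim <- simulate_metagenome(spec, n_samples_b = 20L)
prof <- profile_taxa(sim, rank = "phylum")

depth <- min(colSums(prof$abundance))
message(sprintf("rarefaction depth: %d reads per sample.", depth))
set.seed(7)
ds <- diversity_summary(prof$abundance, depth = depth)
agg <- aggregate(cbind(richness, chao1, simpson) ~ group, ds, mean)
print(agg, row.names = FALSE)

rc <- rarefaction_curve(prof$abundance)
write.table(rc, "results/rarefaction_curves.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ds, "results/diversity_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

norm <- normalize_abundance(prof$abundance)
d <- bray_curtis(log_transform(norm))
pcoa <- ordinate(d, "PCoA", k = 2)
nmds <- ordinate(d, "NMDS", k = 2)
sep <- group_separation(d, sim$groups)
message(sprintf("Bray-Curtis: mean within-group %.3f, between-group %.3f; NMDS stress-1 %.4f.",
                sep$mean_within, sep$mean_between, nmds$stress))

coords <- data.frame(sample = rownames(pcoa$points),
                     group = sim$groups[rownames(pcoa$points)],
                     axis1 = pcoa$points[, 1], axis2 = pcoa$points[, 2])
write.table(coords, "results/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/{rarefaction_curves,diversity_summary,pcoa_coordinates}.tsv")
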