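#!/usr/bin/env Rscript
# Stage 6 -- does phylogenetic distance predict proximity in signal space?
#
# Joins patristic distances from the phylogeny with log centroid distances
# in signal space for all 435 pairs, fits the pair-type x phylogenetic
# distance interaction OLS, and reports Tukey-adjusted pair-type contrasts.

library(warblerspace)

songs <- read_traits("results/data/songs.csv")
niches <- build_niches(build_signal_space(per_male_means(songs)))

tab <- pair_distance_table(niches, "results/data/tree.nwk")
write.csv(tab, "results/pair_distances.csv", row.names = FALSE)

fit <- fit_interaction_ols(tab)
cat(sprintf("OLS: R^2 = %.3f, F = %.2f on %d/%d df, p = %.3g (n = %d pairs)\n",
            fit$r_squared, fit$F, fit$df[1], fit$df[2], fit$p, fit$n_pairs))
cat("per-type slopes of log centroid distance on patristic distance:\n")
print(fit$slopes, row.names = FALSE)
cat("Tukey-adjusted pair-type contrasts at the mean patristic distance:\n")
print(fit$tukey, row.names = FALSE)
cat("note:", fit$note, "\n")
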