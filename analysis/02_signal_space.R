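#!/usr/bin/env Rscript
# Stage 2 -- build the 2-D signal space and the species' signalling niches.
#
# Per-male trait means -> correlation-matrix PCA (components with
# eigenvalue > 1) -> convex-hull niches with areas and centroids, plus the
# sample-size diagnostics that motivate NOT correcting niche areas.

library(warblerspace)

songs <- read_traits("results/data/songs.csv")
means <- per_male_means(songs)
space <- build_signal_space(means)
niches <- build_niches(space)

cat(sprintf("retained %d components explaining %.1f%% of variance\n",
            ncol(space$scores), 100 * sum(space$explained_fraction)))
cat(sprintf("community signal space: %.2f PCA units^2 (hull), %.2f (union of niches)\n",
            community_area(space), community_area(space, "union")))

ns <- niche_summary(niches)
write.csv(ns, "results/niches.csv", row.names = FALSE)
cat(sprintf("niche areas: %.2f-%.2f (mean %.2f)\n",
            min(ns$area), max(ns$area), mean(ns$area)))

reg <- sample_size_regression(niches)
cat(sprintf("log(area) ~ n_individuals: slope %.3f, R^2 = %.2f, F = %.2f, p = %.2g\n",
            reg$slope, reg$r_squared, reg$F, reg$p))
cat("VIFs for the status-interaction variant:",
    paste(sprintf("%s %.2f", names(reg$vif), reg$vif), collapse = ", "), "\n")
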