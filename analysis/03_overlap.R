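#!/usr/bin/env Rscript
# Stage 3 -- maximum potential niche overlap, assuming all species co-occur.
#
# Every pairwise hull intersection (any nonzero area counts as an overlap),
# group-wise proportions of each niche covered by migrants / breeders / all
# others, and a chi-square goodness-of-fit test of the realized overlap
# counts against equal expectations across the three pair types.

library(warblerspace)

songs <- read_traits("results/data/songs.csv")
space <- build_signal_space(per_male_means(songs))
niches <- build_niches(space)
ot <- overlap_table(niches)

write.csv(ot$pairs, "results/pair_overlaps.csv", row.names = FALSE)
write.csv(ot$groups, "results/group_overlaps.csv", row.names = FALSE)

cp <- classify_pairs(setNames(vapply(niches, `[[`, "", "status"),
                              vapply(niches, `[[`, "", "species")))
realized <- table(factor(ot$pairs$pair_type[ot$pairs$overlaps],
                         names(cp$counts)[1:3]))
cat(sprintf("possible pairs: %d (%s)\n", cp$counts[["total"]],
            paste(names(cp$counts)[1:3], cp$counts[1:3], collapse = ", ")))
cat(sprintf("realized overlaps: %d (%s)\n", sum(realized),
            paste(names(realized), realized, collapse = ", ")))
gof <- chisq_gof(as.numeric(realized))
cat(sprintf("chi-square GOF vs equal thirds: X2 = %.2f, df = %d, p = %.3g\n",
            gof$statistic, gof$df, gof$p_value))
cat(sprintf("mean total proportion overlapped: %.2f\n",
            mean(ot$groups$prop_total)))
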