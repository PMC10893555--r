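#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study inputs.
#
# Emulates the data a field season would produce for a 30-species warbler
# community (19 migrants, 11 breeders; 4-24 recorded males per species,
# ~8 songs per male): a song-trait table, a spring season of birding
# checklists (100/day, April 1 - June 15, with a sprinkling of
# quality-rule violations to exercise filtering), and an ultrametric
# phylogeny over the species.

library(warblerspace)

seed <- 11
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

profiles <- demo_profiles()
songs <- simulate_traits(profiles, seed = seed)
checklists <- simulate_checklists(
  profiles, n_per_day = 100, day_range = c(91, 166), seed = seed + 1,
  violation_rates = c(incomplete = 0.05, observers = 0.02, duration = 0.02,
                      distance = 0.02, protocol = 0.04))
tree <- simulate_tree(vapply(profiles, `[[`, "", "code"), seed = seed + 2)

write.csv(songs, file.path(out, "songs.csv"), row.names = FALSE)
write_checklists(checklists, file.path(out, "checklists.csv"))
writeLines(tree$newick, file.path(out, "tree.nwk"))
write.csv(data.frame(code = vapply(profiles, `[[`, "", "code"),
                     status = vapply(profiles, `[[`, "", "status")),
          file.path(out, "statuses.csv"), row.names = FALSE)

cat(sprintf("simulated %d songs from %d males of %d species; %d checklists; tree with %d tips\n",
            nrow(songs), length(unique(songs$individual_id)),
            length(profiles), nrow(checklists), length(profiles)))
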