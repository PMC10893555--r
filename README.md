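# warblerspace

Acoustic signal-space partitioning in a warbler community with migratory
turnover.

## The problem

Songbirds that sing at the same time and place compete for acoustic
bandwidth. In eastern North American wood-warbler (Parulidae) communities
this competition is seasonal: during spring migration, up to 19 migrant
species pass through the breeding range of 11 resident species, all
singing. `warblerspace` implements the full analysis chain for asking how
much of the residents' acoustic niche space those transients occupy, and
for how long:

1. **Signal space** — six song traits per song (duration, number of notes,
   peak/min/max frequency, bandwidth) are averaged per male and ordinated
   by PCA on the correlation matrix; the components with eigenvalue > 1
   (two, for warbler-like data) define a 2-D signal space.
2. **Signalling niches** — each species' niche is the convex hull of its
   males' (PC1, PC2) scores, with shoelace area and polygon centroid.
3. **Overlap geometry** — exact pairwise hull-intersection areas (any
   nonzero area counts), and the proportion of a focal niche covered by
   the *union* of other niches, computed by exact convex clipping with no
   double counting.
4. **Phenology** — community composition through time is reconstructed
   from birding checklists: quality filtering, daily occurrence
   (% of checklists reporting a species), 3-day window averages across
   Julian days 96–158 (21 windows), presence at occurrence ≥ 1.5%.
5. **Dynamics** — per-window overlap counts by pair type
   (migrant–breeding / breeding–breeding / migrant–migrant) and per-species
   overlap proportions, modelled with Poisson and binomial GLMs in a cubic
   polynomial of standardized day, plus a paired t test at the migration
   peak.
6. **Null model** — the observed mean interspecific centroid distance is
   compared with 10,000 randomized communities (individuals placed
   uniformly within the observed per-axis score ranges, species sizes
   preserved): Z = (obs − mean(null)) / sd(null), with per-pair versions.
7. **Phylogenetic signal** — OLS of log centroid distance on pair type ×
   patristic distance, with Tukey-adjusted type contrasts.

A synthetic-data generator produces song-trait tables, checklist tables,
and phylogenies with the statistical structure the analysis assumes, so
every stage is fully testable without recordings. The package also ships
the published per-species summary of the real 30-species community
(`warbler_community()`): status, number of recorded males, niche area, and
maximum overlap proportions.

## Worked example

The numbered scripts under `analysis/` run the whole study on the seeded
synthetic community (`Rscript analysis/01_simulate.R`, then `02`…`06`).
Abridged output:

```
simulated 2632 songs from 329 males of 30 species; 7600 checklists; tree with 30 tips
retained 2 components explaining 71.2% of variance
community signal space: 31.16 PCA units^2 (hull), 15.65 (union of niches)
niche areas: 0.09-1.82 (mean 0.72)
possible pairs: 435 (migrant-breeding 209, breeding-breeding 55, migrant-migrant 171)
realized overlaps: 45 (migrant-breeding 19, breeding-breeding 10, migrant-migrant 16)
richness across the 21 windows: 0 2 3 6 8 14 17 21 26 27 27 25 25 22 19 16 15 13 12 11 11
Poisson GLM AIC by polynomial degree:  1: 503.6  2: 195.7  3: 193.8
peak window 11: paired t = -3.270 on 10 df, p = 0.008
<null_model_result> obs 2.3684 vs null 1.1671 +/- 0.1156: Z = 10.39 (overdispersed), empirical p = 0.0002 [10000 reps]
pairs: 48% overdispersed, 0% underdispersed, 52% random
```

Reading this: the 30 synthetic species tile a 31-unit signal space with
only 45 of 435 possible pairwise overlaps, richness swells from 2 species
to 27 and back as migrants pass through, overlap counts need a cubic time
term, and the niches are strongly overdispersed (Z ≈ 10) — the
partitioned-signal-space signature. (Window-by-window richness is
stochastic; your exact counts depend on the checklist seed.)

Equivalent single call:

```r
library(warblerspace)
profs <- demo_profiles()
res <- run_pipeline(simulate_traits(profs, seed = 11),
                    simulate_checklists(profs, 100, c(91, 166), seed = 12),
                    simulate_tree(vapply(profs, `[[`, "", "code"), seed = 13)$tree,
                    out_dir = "results/demo", seed = 11)
res$null_model
```

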