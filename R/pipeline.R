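# End-to-end pipeline and CSV / Newick I/O.

#' Write a checklist table to CSV
#'
#' The `species_reported` list-column is flattened to a semicolon-separated
#' string; [read_checklists()] inverts this.
#'
#' @param checklists Checklist data frame.
#' @param path Output CSV path.
#' @export
write_checklists <- function(checklists, path) {
  out <- checklists
  out$species_reported <- vapply(out$species_reported, paste, "", collapse = ";")
  utils::write.csv(out, path, row.names = FALSE)
}

#' Read a checklist table from CSV
#'
#' @param path CSV path written by [write_checklists()] (or any table with
#'   the same columns; `species_reported` is split on `;`).
#' @return Checklist data frame with `species_reported` as a list-column.
#' @export
read_checklists <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  sr <- as.character(cl$species_reported)
  sr[is.na(sr)] <- ""  # empty species sets come back from read.csv as NA
  cl$species_reported <- lapply(strsplit(sr, ";"), function(s) s[nzchar(s)])
  cl
}

#' Read a song-trait table from CSV
#'
#' Validates the trait-record schema and its invariants (positive duration,
#' note count >= 1, min <= peak <= max).
#'
#' @param path CSV with columns species, status, individual_id, duration,
#'   n_notes, peak_freq, min_freq, max_freq, bandwidth.
#' @return Validated data frame.
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "status", "individual_id", TRAIT_NAMES)
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trait CSV missing column(s): ", paste(miss, collapse = ", "))
  if (any(tr$duration <= 0)) stop("non-positive durations in trait CSV")
  if (any(tr$n_notes < 1)) stop("note counts below 1 in trait CSV")
  if (any(tr$min_freq > tr$peak_freq | tr$peak_freq > tr$max_freq))
    stop("frequency ordering violated in trait CSV")
  tr
}

#' Run the full analysis pipeline on one community
#'
#' Executes every stage in order on a song-trait table, checklist table,
#' and phylogeny: per-male means, 2-D signal space, niches, global overlap
#' tables, checklist filtering and community snapshots, windowed overlap
#' dynamics with Poisson/binomial GLM fits and the peak-window paired
#' comparison, the community and per-pair null models, and the
#' phylogenetic-distance regression. Writes all tables as CSV plus a JSON
#' run manifest recording every setting in effect, so a rerun with the same
#' inputs is reproducible.
#'
#' @param songs Song-trait data frame (or CSV path).
#' @param checklists Checklist data frame (or CSV path).
#' @param tree Phylogeny (`phylo`, Newick string, or file); `NULL` skips the
#'   phylogenetic stage.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param start_day,end_day,width Window grid (defaults 96, 158, 3).
#' @param threshold Presence threshold in percent (default 1.5).
#' @param null_reps,pair_null_reps Null-model replicates (defaults 10000
#'   and 1000).
#' @param seed Seed for the null models and tie-breaks.
#' @param glm_degree Polynomial degree for the time-course GLMs (default 3).
#' @param binomial_weight Nominal binomial weight (default 100).
#' @return List with every stage result (`space`, `niches`, `overlap`,
#'   `phenology`, `dynamics`, `poisson_fit`, `binomial_fit`, `peak_test`,
#'   `null_model`, `pair_dispersion`, `phylo`, `manifest`).
#' @export
run_pipeline <- function(songs, checklists, tree = NULL, out_dir = NULL,
                         start_day = 96, end_day = 158, width = 3,
                         threshold = 1.5, null_reps = 10000,
                         pair_null_reps = 1000, seed = 1, glm_degree = 3,
                         binomial_weight = 100) {
  if (is.character(songs)) songs <- read_traits(songs)
  if (is.character(checklists)) checklists <- read_checklists(checklists)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))

  means <- stage("trait_space", per_male_means(songs))
  space <- stage("trait_space", build_signal_space(means))
  niches <- stage("trait_space", build_niches(space))
  statuses <- stats::setNames(vapply(niches, `[[`, "", "status"),
                              vapply(niches, `[[`, "", "species"))
  overlap <- stage("overlap_geometry", overlap_table(niches))
  phen <- stage("phenology",
                community_phenology(checklists, statuses,
                                    start_day = start_day, end_day = end_day,
                                    width = width, threshold = threshold))
  rich <- vapply(phen$snapshots, function(s) length(s$present_species), 0L)
  if (all(rich == 0))
    warning("no species reaches the presence threshold (", threshold,
            "%) in any window; snapshots are empty")
  dyn <- stage("temporal_dynamics", window_overlaps(phen$snapshots, niches))
  pois <- if (all(rich == 0)) NULL else
    stage("temporal_dynamics", fit_overlap_poisson(dyn$counts, glm_degree))
  binom <- if (is.null(dyn$proportions) ||
               length(unique(dyn$proportions$window_index)) < glm_degree + 2) NULL else
    stage("temporal_dynamics",
          fit_overlap_binomial(dyn$proportions, glm_degree, binomial_weight))
  peak <- if (all(rich == 0)) NULL else
    stage("temporal_dynamics", peak_overlap_comparison(dyn, phen$snapshots, seed))
  nm <- stage("null_model", null_model_test(space, niches, null_reps, seed))
  pdisp <- stage("null_model",
                 pairwise_dispersion(niches, observed_ranges(space),
                                     pair_null_reps, seed))
  phylo <- NULL
  if (!is.null(tree)) {
    phylo <- stage("phylo_signal", {
      tab <- pair_distance_table(niches, tree)
      list(pairs = tab, fit = fit_interaction_ols(tab))
    })
  }
  manifest <- list(
    package = "warblerspace",
    version = as.character(utils::packageVersion("warblerspace")),
    r_version = R.version.string,
    seed = seed, start_day = start_day, end_day = end_day, width = width,
    threshold = threshold, null_reps = null_reps,
    pair_null_reps = pair_null_reps, glm_degree = glm_degree,
    binomial_weight = binomial_weight,
    conventions = list(
      eigenvalue_threshold = 1, pca_sign = "largest-|loading| positive",
      community_area = "hull over all individual scores",
      overlap_zero_tol = .area_tol, geometric_tol = .coincident_tol,
      presence_rule = ">= threshold", boundary_filters = "strict > rejected",
      null_sd = "sample", null_centroid = "mean of sampled points",
      binomial_model = "fixed-effects GLM, no species random intercept",
      polynomials = "raw powers of standardized day"))
  res <- list(means = means, space = space, niches = niches, overlap = overlap,
              phenology = phen, dynamics = dyn, poisson_fit = pois,
              binomial_fit = binom, peak_test = peak, null_model = nm,
              pair_dispersion = pdisp, phylo = phylo, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline outputs to a directory
#'
#' @param res Result of [run_pipeline()].
#' @param out_dir Directory (created recursively).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  w(niche_summary(res$niches), "niches.csv")
  w(res$overlap$pairs, "pair_overlaps.csv")
  w(res$overlap$groups, "group_overlaps.csv")
  occ <- data.frame(species = rownames(res$phenology$occurrence),
                    res$phenology$occurrence, check.names = FALSE)
  w(occ, "occurrence_windows.csv")
  snaps <- do.call(rbind, lapply(res$phenology$snapshots, function(s)
    data.frame(window_index = s$window_index, start = s$window_days[1],
               end = s$window_days[2], n_migrants = s$n_migrants,
               n_breeders = s$n_breeders,
               present = paste(s$present_species, collapse = ";"))))
  w(snaps, "snapshots.csv")
  w(res$dynamics$counts, "window_overlap_counts.csv")
  if (!is.null(res$dynamics$proportions))
    w(res$dynamics$proportions, "window_overlap_proportions.csv")
  nm <- res$null_model
  w(data.frame(observed = nm$observed, null_mean = nm$null_mean,
               null_sd = nm$null_sd, z = nm$z, p_empirical = nm$p_empirical,
               n_replicates = nm$n_replicates,
               classification = nm$classification), "null_model.csv")
  w(res$pair_dispersion$pairs, "pair_dispersion.csv")
  if (!is.null(res$phylo)) w(res$phylo$pairs, "pair_distances.csv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
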