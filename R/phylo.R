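# Phylogenetic distance vs proximity in signal space.

#' Patristic distance matrix from a phylogeny
#'
#' Sum of branch lengths along the unique tip-to-tip path, for all tip
#' pairs.
#'
#' @param tree An `ape` `phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @return Symmetric tip-by-tip distance matrix.
#' @export
patristic_distances <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
    if (is.null(tree)) stop("could not parse Newick input")
  }
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Pair table of phylogenetic and signal-space distances
#'
#' Joins, for every unordered species pair, the patristic distance from the
#' tree with the Euclidean distance between niche centroids in signal
#' space. Pairs with zero centroid distance are excluded (with a warning)
#' because the model works on the log centroid distance.
#'
#' @param niches A `niche_set`.
#' @param tree Phylogeny accepted by [patristic_distances()] whose tips
#'   cover all niche species.
#' @return Data frame: species_a, species_b, pair_type, patristic_distance,
#'   centroid_distance, log_centroid_distance.
#' @export
pair_distance_table <- function(niches, tree) {
  codes <- vapply(niches, `[[`, "", "species")
  pd <- patristic_distances(tree)
  missing <- setdiff(codes, rownames(pd))
  if (length(missing)) stop("tips missing from tree: ", paste(missing, collapse = ", "))
  statuses <- stats::setNames(vapply(niches, `[[`, "", "status"), codes)
  cp <- classify_pairs(statuses)$pairs
  cd <- centroid_distance_matrix(niches)$distances
  cp$patristic_distance <- pd[cbind(cp$species_a, cp$species_b)]
  cp$centroid_distance <- cd[cbind(cp$species_a, cp$species_b)]
  zero <- cp$centroid_distance <= 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " pair(s) with zero centroid distance from log-scale table")
    cp <- cp[!zero, ]
  }
  cp$log_centroid_distance <- log(cp$centroid_distance)
  cp
}

#' Interaction OLS of signal-space distance on phylogenetic distance
#'
#' Fits `log_centroid_distance ~ pair_type * patristic_distance` by OLS,
#' reports per-type simple slopes, and Tukey-HSD-adjusted pairwise
#' contrasts of the adjusted pair-type means (evaluated, by default, at the
#' mean patristic distance). Pairwise distances between species pairs are
#' not independent observations; `n_pairs` is reported and inference
#' follows the pairwise design without correcting for that
#' non-independence.
#'
#' @param records Data frame from [pair_distance_table()].
#' @param at Patristic-distance value at which type means are compared
#'   (default: mean of the data).
#' @return List with `fit`, `r_squared`, `F`, `df`, `p`, `slopes` (per-type
#'   simple slopes with SEs, via emmeans), `tukey` (pairwise contrasts,
#'   Tukey-adjusted), `n_pairs`, `note`.
#' @export
fit_interaction_ols <- function(records, at = NULL) {
  types <- unique(records$pair_type)
  if (nrow(records) < 4) stop("too few pairs to fit")
  if (length(types) < 2) {
    warning("single pair type present; fitting without interaction")
    fit <- stats::lm(log_centroid_distance ~ patristic_distance, data = records)
    sm <- summary(fit)
    return(list(fit = fit, r_squared = sm$r.squared,
                F = unname(sm$fstatistic[1]),
                df = unname(sm$fstatistic[2:3]),
                p = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                     sm$fstatistic[3], lower.tail = FALSE)),
                slopes = NULL, tukey = NULL, n_pairs = nrow(records),
                note = "single pair type; no contrasts"))
  }
  records$pair_type <- factor(records$pair_type)
  zero_var <- stats::var(records$log_centroid_distance) == 0
  fit <- suppressWarnings(
    stats::lm(log_centroid_distance ~ pair_type * patristic_distance,
              data = records))
  sm <- suppressWarnings(summary(fit))
  if (is.null(at)) at <- mean(records$patristic_distance)
  slopes <- suppressWarnings(suppressMessages(as.data.frame(
    emmeans::emtrends(fit, ~ pair_type, var = "patristic_distance"))))
  emm <- suppressWarnings(suppressMessages(
    emmeans::emmeans(fit, ~ pair_type, at = list(patristic_distance = at))))
  tukey <- suppressWarnings(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))
  fs <- sm$fstatistic
  # convention: a zero-variance response carries no signal -> F = 0, p = 1
  no_f <- zero_var || is.null(fs) || !is.finite(fs[1])
  p <- if (no_f) 1 else
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  list(fit = fit, r_squared = if (zero_var) 0 else sm$r.squared,
       F = if (no_f) 0 else unname(fs[1]),
       df = if (no_f) c(NA, NA) else unname(fs[2:3]), p = p,
       slopes = slopes, tukey = tukey, n_pairs = nrow(records),
       note = paste("pairwise distances are non-independent;",
                    "inference mirrors the pairwise design"))
}
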