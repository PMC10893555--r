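# Pairwise and group-wise niche overlap.

#' Classify all species pairs by migratory status
#'
#' Enumerates all unordered species pairs and counts them by pair type:
#' with M migrants and B breeders there are M*B migrant-breeding pairs,
#' choose(B, 2) breeding-breeding, and choose(M, 2) migrant-migrant.
#'
#' @param statuses Named character vector mapping species code to
#'   `"migrant"` or `"breeding"` (>= 2 species).
#' @return List with `pairs` (data frame `species_a`, `species_b`,
#'   `pair_type`) and `counts` (named vector `migrant-breeding`,
#'   `breeding-breeding`, `migrant-migrant`, `total`).
#' @export
classify_pairs <- function(statuses) {
  if (length(statuses) < 2) stop("need at least 2 species")
  bad <- !statuses %in% c("migrant", "breeding")
  if (any(bad)) stop("unknown status for: ", paste(names(statuses)[bad], collapse = ", "))
  sp <- names(statuses)
  idx <- utils::combn(length(sp), 2)
  type <- apply(idx, 2, function(ij) {
    st <- sort(statuses[ij])
    if (st[1] == st[2]) paste0(st[1], "-", st[2]) else "migrant-breeding"
  })
  pairs <- data.frame(species_a = sp[idx[1, ]], species_b = sp[idx[2, ]],
                      pair_type = type, stringsAsFactors = FALSE)
  counts <- c(`migrant-breeding` = sum(type == "migrant-breeding"),
              `breeding-breeding` = sum(type == "breeding-breeding"),
              `migrant-migrant` = sum(type == "migrant-migrant"))
  list(pairs = pairs, counts = c(counts, total = ncol(idx)))
}

#' Proportion of a focal niche covered by other niches
#'
#' Exact fraction of the focal hull's area covered by the union of a set of
#' other hulls: each other hull is clipped to the focal hull and the union
#' area of the clipped convex pieces is divided by the focal area. Exact
#' polygon operations; no double counting where the others overlap each
#' other.
#'
#' @param focal A niche (list with `hull`, `area`) or a CCW hull matrix.
#' @param others List of niches or hull matrices (may be empty).
#' @return Proportion in `[0, 1]`.
#' @export
proportion_overlapped <- function(focal, others) {
  fh <- if (is.matrix(focal)) focal else focal$hull
  if (is.null(nrow(fh)) || nrow(fh) < 3 || polygon_area(fh) < .area_tol)
    stop("degenerate focal hull")
  if (length(others) == 0) return(0)
  pieces <- lapply(others, function(o) {
    oh <- if (is.matrix(o)) o else o$hull
    intersect_convex(oh, fh)$polygon
  })
  min(union_area_convex(pieces) / polygon_area(fh), 1)
}

#' Full pairwise and group-wise overlap tables
#'
#' Computes, for every unordered species pair, the exact area of
#' intersection of the two niche hulls and whether it is nonzero (every
#' nonzero overlap counts, however small), and, for every species, the
#' proportion of its niche overlapped by migrants, by breeding species
#' (excluding itself), and by all others in total.
#'
#' @param niches A `niche_set` with >= 2 niches.
#' @return List with `pairs` (data frame `species_a`, `species_b`,
#'   `pair_type`, `overlap_area`, `overlaps`) and `groups` (data frame
#'   `species`, `status`, `prop_migrant`, `prop_breeding`, `prop_total`).
#' @export
overlap_table <- function(niches) {
  if (length(niches) < 2) stop("need at least 2 niches")
  codes <- vapply(niches, `[[`, "", "species")
  statuses <- stats::setNames(vapply(niches, `[[`, "", "status"), codes)
  names(niches) <- codes
  cp <- classify_pairs(statuses)
  pairs <- cp$pairs
  pairs$overlap_area <- mapply(function(a, b)
    intersect_convex(niches[[a]]$hull, niches[[b]]$hull)$area,
    pairs$species_a, pairs$species_b)
  pairs$overlaps <- pairs$overlap_area > 0
  groups <- do.call(rbind, lapply(codes, function(sp) {
    others <- niches[setdiff(codes, sp)]
    st <- vapply(others, `[[`, "", "status")
    data.frame(
      species = sp, status = statuses[[sp]],
      prop_migrant = proportion_overlapped(niches[[sp]], others[st == "migrant"]),
      prop_breeding = proportion_overlapped(niches[[sp]], others[st == "breeding"]),
      prop_total = proportion_overlapped(niches[[sp]], others),
      stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(pairs = pairs, groups = groups)
}

#' Chi-square goodness-of-fit test on overlap counts
#'
#' Pearson chi-square test of observed counts against expected proportions
#' (default: equal across cells).
#'
#' @param observed Non-negative integer counts (sum > 0).
#' @param expected_proportions Probabilities summing to 1, same length as
#'   `observed`; default equal.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_gof <- function(observed,
                      expected_proportions = rep(1 / length(observed),
                                                 length(observed))) {
  if (any(observed < 0) || sum(observed) <= 0) stop("invalid observed counts")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  if (any(expected_proportions <= 0)) stop("zero expected cell")
  ct <- suppressWarnings(stats::chisq.test(observed, p = expected_proportions))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value),
       expected = unname(ct$expected))
}
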