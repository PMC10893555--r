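# Signal-space construction: per-male trait means, correlation-matrix PCA,
# convex-hull signalling niches.

#' Average song traits per male
#'
#' Collapses a song-trait table to one row per individual by taking the
#' arithmetic mean of each trait over that male's songs, the first step
#' before ordination so that well-recorded males do not dominate the space.
#'
#' @param songs Song-trait data frame as returned by [simulate_traits()]
#'   (columns `species`, `status`, `individual_id`, six traits).
#' @return Data frame with one row per individual, same columns.
#' @export
per_male_means <- function(songs) {
  sp_per_ind <- tapply(songs$species, songs$individual_id,
                       function(s) length(unique(s)))
  if (any(sp_per_ind > 1))
    stop("data integrity: individual(s) appear under two species codes: ",
         paste(names(sp_per_ind)[sp_per_ind > 1], collapse = ", "))
  agg <- stats::aggregate(songs[TRAIT_NAMES],
                          by = songs[c("species", "status", "individual_id")],
                          FUN = mean)
  agg <- agg[order(agg$species, agg$individual_id), ]
  rownames(agg) <- NULL
  agg
}

#' Build the 2-D community signal space by correlation-matrix PCA
#'
#' Standardizes each trait column to zero mean and unit SD, eigendecomposes
#' the 6 x 6 correlation matrix, and retains components with eigenvalue
#' greater than `eigenvalue_threshold` (Kaiser rule). Each retained
#' component is sign-flipped so its largest-magnitude loading is positive;
#' scores are the standardized data projected on the retained loadings and
#' are in dimensionless "PCA units".
#'
#' @param means Per-male mean table from [per_male_means()] (>= 3 rows).
#' @param eigenvalue_threshold Retain components with eigenvalue strictly
#'   greater than this (default 1).
#' @param traits Trait columns to ordinate (default: the six song traits).
#' @return An object of class `signal_space`: list with `loadings` (6 x K),
#'   `eigenvalues` (all 6), `explained_fraction` (per retained component),
#'   `standardization` (per-trait mean/SD), `scores` (individual x K matrix),
#'   and the `species`/`status`/`individual_id` labels aligned with score
#'   rows.
#' @export
build_signal_space <- function(means, eigenvalue_threshold = 1.0,
                               traits = TRAIT_NAMES) {
  if (nrow(means) < 3) stop("need at least 3 individuals")
  X <- as.matrix(means[traits])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: constant trait column(s): ",
         paste(traits[sds == 0], collapse = ", "))
  mu <- colMeans(X)
  Z <- scale(X, center = mu, scale = sds)
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  # descending eigenvalues (eigen() already sorts); ties keep trait order
  keep <- which(ev$values > eigenvalue_threshold)
  if (length(keep) < 2)
    warning("fewer than 2 components retained (", length(keep),
            "); 2-D niche geometry will not be available")
  L <- ev$vectors[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(L))) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) L[, k] <- -L[, k]
  }
  rownames(L) <- traits
  if (ncol(L) > 0) colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- Z %*% L
  structure(list(
    loadings = L,
    eigenvalues = ev$values,
    explained_fraction = ev$values[keep] / length(traits),
    standardization = data.frame(trait = traits, mean = mu, sd = sds,
                                 row.names = NULL),
    scores = scores,
    species = means$species, status = means$status,
    individual_id = means$individual_id
  ), class = "signal_space")
}

#' @export
print.signal_space <- function(x, ...) {
  cat(sprintf("<signal_space> %d individuals, %d retained components (%s%% of variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(round(100 * x$explained_fraction, 1), collapse = " + ")))
  invisible(x)
}

#' Convex-hull signalling niches per species
#'
#' Builds each species' signalling niche as the convex hull of its males'
#' (PC1, PC2) scores, with shoelace area and area-weighted centroid.
#'
#' @param space A 2-component [build_signal_space()] result.
#' @param min_points Minimum individuals per species (default 3; fewer, or
#'   exactly collinear scores, is a degeneracy error).
#' @return A list of niches (class `niche_set`); each niche has `species`,
#'   `status`, `hull` (CCW vertex matrix), `area`, `centroid`,
#'   `n_individuals`.
#' @export
build_niches <- function(space, min_points = 3) {
  if (ncol(space$scores) != 2)
    stop("niche geometry requires exactly 2 retained components, got ",
         ncol(space$scores))
  out <- lapply(split(seq_len(nrow(space$scores)), space$species), function(idx) {
    sp <- space$species[idx[1]]
    pts <- space$scores[idx, , drop = FALSE]
    if (nrow(pts) < min_points)
      stop("degenerate niche for species ", sp, ": only ", nrow(pts), " individuals")
    h <- convex_hull(pts)
    if (nrow(h) < 3 || polygon_area(h) < .area_tol)
      stop("degenerate niche for species ", sp, ": collinear scores")
    list(species = sp, status = space$status[idx[1]], hull = h,
         area = polygon_area(h), centroid = polygon_centroid(h),
         n_individuals = length(idx))
  })
  structure(out, class = "niche_set")
}

#' @export
print.niche_set <- function(x, ...) {
  cat(sprintf("<niche_set> %d species, areas %.3g-%.3g PCA units^2\n",
              length(x), min(vapply(x, `[[`, 0, "area")),
              max(vapply(x, `[[`, 0, "area"))))
  invisible(x)
}

#' Niche summary table
#'
#' @param niches A `niche_set`.
#' @return Data frame: species, status, n_individuals, area, centroid_x/y.
#' @export
niche_summary <- function(niches) {
  data.frame(
    species = vapply(niches, `[[`, "", "species"),
    status = vapply(niches, `[[`, "", "status"),
    n_individuals = vapply(niches, `[[`, 0L, "n_individuals"),
    area = vapply(niches, `[[`, 0, "area"),
    centroid_x = vapply(niches, function(n) n$centroid[1], 0),
    centroid_y = vapply(niches, function(n) n$centroid[2], 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Total community signal-space area
#'
#' Area of the signal space occupied by the whole community. By default the
#' convex hull over all individuals' scores; `method = "union"` instead sums
#' the union of the species hulls (excluding unoccupied space between
#' niches).
#'
#' @param space A 2-component signal space.
#' @param method `"hull"` (default) or `"union"`.
#' @return Area in PCA units squared.
#' @export
community_area <- function(space, method = c("hull", "union")) {
  method <- match.arg(method)
  if (ncol(space$scores) != 2) stop("community area requires a 2-D space")
  if (method == "hull") {
    h <- convex_hull(space$scores)
    if (nrow(h) < 3) stop("degenerate community: collinear scores")
    polygon_area(h)
  } else {
    niches <- build_niches(space)
    union_area_convex(lapply(niches, `[[`, "hull"))
  }
}

#' Sample-size diagnostics for niche areas
#'
#' OLS of log niche area on the number of individuals sampled per species,
#' plus variance-inflation factors for the two-predictor variant (sample
#' size, migratory status, and their interaction) that motivates dropping
#' collinear predictors (VIF above ~10 is flagged).
#'
#' @param niches A `niche_set` (>= 3 species; zero-area niches are excluded
#'   with a warning).
#' @return List with `fit` (the lm), `slope`, `intercept`, `r_squared`, `F`,
#'   `p`, and `vif` (named vector for the status-interaction model, `NA`
#'   when statuses are aliased).
#' @export
sample_size_regression <- function(niches) {
  d <- niche_summary(niches)
  if (any(d$area <= 0)) {
    warning("excluding ", sum(d$area <= 0), " species with non-positive area")
    d <- d[d$area > 0, ]
  }
  if (nrow(d) < 3) stop("need at least 3 species with positive area")
  fit <- stats::lm(log(area) ~ n_individuals, data = d)
  sm <- suppressWarnings(summary(fit))  # noiseless fits trip lm's perfect-fit warning
  vif <- c(n_individuals = NA_real_, status = NA_real_, interaction = NA_real_)
  if (length(unique(d$status)) > 1) {
    X <- stats::model.matrix(~ n_individuals * status, data = d)[, -1, drop = FALSE]
    vif <- vapply(seq_len(ncol(X)), function(j) {
      r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
    names(vif) <- colnames(X)
  }
  fstat <- sm$fstatistic
  list(fit = fit, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, F = unname(fstat[1]),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       vif = vif)
}
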