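# Randomization null model for niche dispersion in signal space.

#' Pairwise centroid distances and their mean
#'
#' Euclidean distances between species niche centroids in the 2-D signal
#' space, and the mean over all unordered pairs.
#'
#' @param niches A `niche_set` (>= 2 niches), or a species x 2 matrix of
#'   centroids.
#' @return List with `distances` (symmetric matrix) and `mean_distance`.
#' @export
centroid_distance_matrix <- function(niches) {
  cent <- if (is.matrix(niches)) niches else
    t(vapply(niches, `[[`, numeric(2), "centroid"))
  if (nrow(cent) < 2) stop("need at least 2 niches")
  if (!is.matrix(niches))
    rownames(cent) <- vapply(niches, `[[`, "", "species")
  d <- as.matrix(stats::dist(cent))
  list(distances = d, mean_distance = mean(d[upper.tri(d)]))
}

#' Observed per-axis score ranges
#'
#' @param space A 2-D signal space.
#' @return 2 x 2 matrix, rows = axes, columns = c(min, max).
#' @export
observed_ranges <- function(space) {
  r <- apply(space$scores, 2, range)
  t(r)  # rows axes, cols min/max
}

# group-mean "centroids" of uniformly resampled individuals, vectorized over
# replicates; returns list of two n_reps x S matrices (one per axis)
.null_centroids <- function(axis_ranges, sizes, n_reps, centroid = "mean") {
  N <- sum(sizes)
  S <- length(sizes)
  g <- rep(seq_len(S), sizes)
  if (centroid == "mean") {
    G <- matrix(0, N, S); G[cbind(seq_len(N), g)] <- 1 / rep(sizes, sizes)
    lapply(1:2, function(ax) {
      U <- matrix(stats::runif(n_reps * N, axis_ranges[ax, 1], axis_ranges[ax, 2]),
                  nrow = n_reps)
      U %*% G
    })
  } else {  # hull centroid of each species' sampled points
    C1 <- matrix(0, n_reps, S); C2 <- matrix(0, n_reps, S)
    for (r in seq_len(n_reps)) {
      x <- stats::runif(N, axis_ranges[1, 1], axis_ranges[1, 2])
      y <- stats::runif(N, axis_ranges[2, 1], axis_ranges[2, 2])
      for (s in seq_len(S)) {
        pts <- cbind(x[g == s], y[g == s])
        cc <- polygon_centroid(convex_hull(pts))
        C1[r, s] <- cc[1]; C2[r, s] <- cc[2]
      }
    }
    list(C1, C2)
  }
}

#' Null distribution of mean interspecific centroid distance
#'
#' Builds randomized communities by drawing every individual's (PC1, PC2)
#' position independently and uniformly within the observed per-axis score
#' ranges, preserving the number of species and the number of individuals
#' per species, then computes each null community's mean interspecific
#' centroid distance.
#'
#' @param axis_ranges 2 x 2 matrix of per-axis (min, max), e.g. from
#'   [observed_ranges()].
#' @param sizes Integer vector of individuals per species (>= 1 for the
#'   point-mean centroid; >= 3 when `centroid = "hull"`).
#' @param n_reps Number of null communities (default 10000).
#' @param seed Integer seed.
#' @param centroid `"mean"` (default): species centroid is the mean of its
#'   sampled points; `"hull"`: centroid of the convex hull of its points.
#' @return Numeric vector of `n_reps` null mean distances.
#' @export
null_communities <- function(axis_ranges, sizes, n_reps = 10000, seed = 1,
                             centroid = c("mean", "hull")) {
  centroid <- match.arg(centroid)
  axis_ranges <- as.matrix(axis_ranges)
  if (any(!is.finite(axis_ranges)) || any(axis_ranges[, 1] >= axis_ranges[, 2]))
    stop("axis ranges must be finite with min < max")
  if (any(sizes < 1)) stop("all species sizes must be >= 1")
  if (centroid == "hull" && any(sizes < 3))
    stop("hull centroids require all species sizes >= 3")
  if (length(sizes) < 2) stop("need at least 2 species")
  with_seed(seed, {
    C <- .null_centroids(axis_ranges, sizes, n_reps, centroid)
    S <- length(sizes)
    idx <- utils::combn(S, 2)
    dx <- C[[1]][, idx[1, ], drop = FALSE] - C[[1]][, idx[2, ], drop = FALSE]
    dy <- C[[2]][, idx[1, ], drop = FALSE] - C[[2]][, idx[2, ], drop = FALSE]
    rowMeans(sqrt(dx^2 + dy^2))
  })
}

#' Z-score dispersion test against a null distribution
#'
#' Z = (observed - mean(null)) / sd(null). Communities with z above +1.96
#' are classified overdispersed (niches farther apart than chance, a
#' partitioned signal space), below -1.96 underdispersed, otherwise random.
#' An empirical two-sided tail probability with the +1/(n+1) correction is
#' reported alongside, so inference need not lean on normality of the null.
#'
#' @param observed Observed mean interspecific centroid distance.
#' @param null_distribution Numeric vector of null values; fewer than 100
#'   replicates triggers a warning (the Z score is then unstable).
#' @param sd_method `"sample"` (default, n-1 denominator) or `"population"`.
#' @return List of class `null_model_result`: `observed`, `null_mean`,
#'   `null_sd`, `z`, `p_empirical`, `n_replicates`, `classification`.
#' @export
dispersion_test <- function(observed, null_distribution,
                            sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  n <- length(null_distribution)
  if (n < 2) stop("null distribution must have >= 2 values")
  if (n < 100) warning("fewer than 100 null replicates; Z score is unstable")
  m <- mean(null_distribution)
  s <- stats::sd(null_distribution)
  if (sd_method == "population") s <- s * sqrt((n - 1) / n)
  if (s == 0) stop("null distribution has zero spread")
  z <- (observed - m) / s
  p_emp <- 2 * min((1 + sum(null_distribution >= observed)) / (n + 1),
                   (1 + sum(null_distribution <= observed)) / (n + 1))
  structure(list(
    observed = observed, null_mean = m, null_sd = s, z = z,
    p_empirical = min(p_emp, 1), n_replicates = n,
    classification = if (z > 1.96) "overdispersed"
                     else if (z < -1.96) "underdispersed" else "random"
  ), class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("<null_model_result> obs %.4f vs null %.4f +/- %.4f: Z = %.2f (%s), empirical p = %.4g [%d reps]\n",
              x$observed, x$null_mean, x$null_sd, x$z, x$classification,
              x$p_empirical, x$n_replicates))
  invisible(x)
}

#' Community-level null-model test
#'
#' Convenience wrapper: observed statistic is the mean pairwise distance
#' between the observed niche hull centroids; the null resamples the whole
#' community within the observed score ranges.
#'
#' @param space The 2-D signal space (supplies the axis ranges and
#'   per-species sample sizes).
#' @param niches The matching `niche_set` (supplies observed centroids).
#' @inheritParams null_communities
#' @inheritParams dispersion_test
#' @return A `null_model_result` with the null distribution attached as
#'   attribute `"null"`.
#' @export
null_model_test <- function(space, niches, n_reps = 10000, seed = 1,
                            centroid = "mean", sd_method = "sample") {
  obs <- centroid_distance_matrix(niches)$mean_distance
  sizes <- vapply(niches, `[[`, 0L, "n_individuals")
  nulls <- null_communities(observed_ranges(space), sizes, n_reps, seed, centroid)
  res <- dispersion_test(obs, nulls, sd_method)
  attr(res, "null") <- nulls
  res
}

#' Per-pair dispersion tests
#'
#' Repeats the null-model comparison for every unordered species pair: the
#' observed centroid distance of the pair is compared to nulls built from
#' just those two species (their observed sample sizes) resampled within
#' the full observed ranges. Summarizes the proportion of pairs
#' overdispersed, underdispersed, and random.
#'
#' @param niches A `niche_set`.
#' @param axis_ranges 2 x 2 per-axis (min, max) matrix.
#' @param n_reps Null replicates per pair (default 1000).
#' @param seed Integer seed (each pair uses a sub-stream derived from it).
#' @param sd_method Passed to [dispersion_test()].
#' @return List with `pairs` (data frame species_a, species_b, pair_type,
#'   observed, z, classification) and `summary` (named proportions over the
#'   three classes, summing to 1).
#' @export
pairwise_dispersion <- function(niches, axis_ranges, n_reps = 1000, seed = 1,
                                sd_method = "sample") {
  codes <- vapply(niches, `[[`, "", "species")
  statuses <- stats::setNames(vapply(niches, `[[`, "", "status"), codes)
  names(niches) <- codes
  cp <- classify_pairs(statuses)$pairs
  sizes <- stats::setNames(vapply(niches, `[[`, 0L, "n_individuals"), codes)
  res <- do.call(rbind, lapply(seq_len(nrow(cp)), function(k) {
    a <- cp$species_a[k]; b <- cp$species_b[k]
    obs <- sqrt(sum((niches[[a]]$centroid - niches[[b]]$centroid)^2))
    nulls <- null_communities(axis_ranges, sizes[c(a, b)], n_reps,
                              seed = (seed + k) %% .Machine$integer.max)
    dt <- dispersion_test(obs, nulls, sd_method)
    data.frame(species_a = a, species_b = b, pair_type = cp$pair_type[k],
               observed = obs, z = dt$z, classification = dt$classification,
               stringsAsFactors = FALSE)
  }))
  tab <- table(factor(res$classification,
                      c("overdispersed", "underdispersed", "random")))
  list(pairs = res,
       summary = stats::setNames(as.vector(tab) / nrow(res), names(tab)))
}
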