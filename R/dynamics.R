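# Time-resolved overlap dynamics: counts and proportions per window, GLM
# time-course models, peak-window paired comparison.

#' Overlap counts and proportions per community snapshot
#'
#' For each 3-day window, restricts the global pairwise overlap table to
#' species pairs that are both present, counts realized (nonzero-area)
#' overlaps by pair type, and recomputes for each present breeding species
#' the proportion of its niche overlapped by co-present migrants, co-present
#' other breeders, and all co-present others. Window middays are
#' standardized to mean 0, SD 1 across windows.
#'
#' @param snapshots A `snapshot_list` from [reconstruct_communities()].
#' @param niches A `niche_set` covering every species that appears in any
#'   snapshot.
#' @return List with `counts` (long data frame: window_index, midday,
#'   standardized_day, pair_type, n_overlaps, n_possible) and `proportions`
#'   (data frame: window_index, standardized_day, species, overlap_type
#'   in migrant/breeding/total, proportion).
#' @export
window_overlaps <- function(snapshots, niches) {
  codes <- vapply(niches, `[[`, "", "species")
  names(niches) <- codes
  all_present <- unique(unlist(lapply(snapshots, `[[`, "present_species")))
  missing <- setdiff(all_present, codes)
  if (length(missing))
    stop("present species without a niche: ", paste(missing, collapse = ", "))
  glob <- overlap_table(niches)
  middays <- vapply(snapshots, `[[`, 0, "midday")
  sday <- as.numeric(scale(middays))
  types <- c("migrant-breeding", "breeding-breeding", "migrant-migrant")
  counts <- do.call(rbind, lapply(seq_along(snapshots), function(i) {
    pres <- snapshots[[i]]$present_species
    sub <- glob$pairs[glob$pairs$species_a %in% pres &
                        glob$pairs$species_b %in% pres, ]
    data.frame(window_index = snapshots[[i]]$window_index,
               midday = middays[i], standardized_day = sday[i],
               pair_type = types,
               n_overlaps = vapply(types, function(tp)
                 sum(sub$overlaps[sub$pair_type == tp]), 0),
               n_possible = vapply(types, function(tp)
                 sum(sub$pair_type == tp), 0),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  props <- do.call(rbind, lapply(seq_along(snapshots), function(i) {
    pres <- snapshots[[i]]$present_species
    st <- vapply(niches[pres], `[[`, "", "status")
    breeders <- pres[st == "breeding"]
    if (length(breeders) == 0) return(NULL)
    do.call(rbind, lapply(breeders, function(sp) {
      others <- niches[setdiff(pres, sp)]
      ost <- vapply(others, `[[`, "", "status")
      data.frame(window_index = snapshots[[i]]$window_index,
                 standardized_day = sday[i], species = sp,
                 overlap_type = c("migrant", "breeding", "total"),
                 proportion = c(
                   proportion_overlapped(niches[[sp]], others[ost == "migrant"]),
                   proportion_overlapped(niches[[sp]], others[ost == "breeding"]),
                   proportion_overlapped(niches[[sp]], others)),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))
  list(counts = counts, proportions = props)
}

# shared helper: raw or orthogonal polynomial formula in standardized day
.poly_term <- function(degree, orthogonal) {
  if (orthogonal) sprintf("poly(standardized_day, %d)", degree)
  else sprintf("poly(standardized_day, %d, raw = TRUE)", degree)
}

#' Poisson GLM of overlap counts through time
#'
#' Fits `n_overlaps ~ pair_type * poly(standardized_day, degree)` with a
#' log link, reports AIC across degrees 1-3, and an overdispersion
#' statistic from Pearson residuals.
#'
#' @param counts The `counts` table from [window_overlaps()].
#' @param degree Polynomial degree of the reported model (default 3).
#' @param orthogonal Use orthogonal instead of raw polynomials (default
#'   `FALSE`; centering already tames collinearity of odd/even powers).
#' @return List with `fit` (glm), `coefficients`, `aic_table` (degree vs
#'   AIC), `dispersion` (Pearson chi-square / df), `interaction_lrt`
#'   (likelihood-ratio test of the pair_type x time interaction).
#' @export
fit_overlap_poisson <- function(counts, degree = 3, orthogonal = FALSE) {
  stopifnot(degree %in% 1:3, all(counts$n_overlaps >= 0))
  fits <- lapply(1:3, function(d)
    stats::glm(stats::as.formula(paste("n_overlaps ~ pair_type *",
                                       .poly_term(d, orthogonal))),
               family = stats::poisson(), data = counts))
  fit <- fits[[degree]]
  null_fit <- stats::glm(stats::as.formula(paste("n_overlaps ~ pair_type +",
                                                 .poly_term(degree, orthogonal))),
                         family = stats::poisson(), data = counts)
  lrt <- stats::anova(null_fit, fit, test = "Chisq")
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  list(fit = fit, coefficients = summary(fit)$coefficients,
       aic_table = data.frame(degree = 1:3, aic = vapply(fits, stats::AIC, 0)),
       dispersion = disp,
       interaction_lrt = list(statistic = lrt$Deviance[2], df = lrt$Df[2],
                              p_value = lrt$`Pr(>Chi)`[2]))
}

#' Binomial GLM of overlap proportions through time
#'
#' Fits a fixed-effects binomial GLM (logit link) of the proportion of each
#' breeding species' niche overlapped, on overlap type crossed with a
#' polynomial in standardized day. Proportions are area fractions rather
#' than counts, so each observation carries a nominal binomial weight
#' (default 100); the Pearson dispersion statistic is reported to flag the
#' arbitrariness. Species can be added as a fixed covariate. (A species
#' random intercept is deliberately not fitted; the metadata records this.)
#'
#' @param proportions The `proportions` table from [window_overlaps()]
#'   restricted to the types to contrast (rows with `overlap_type` in
#'   migrant/breeding are used; "total" rows are ignored).
#' @param degree Polynomial degree (default 3).
#' @param weight Binomial weight per observation (default 100).
#' @param species_effect Include species as a fixed covariate (default
#'   `FALSE`).
#' @param orthogonal Orthogonal polynomial flag, as in
#'   [fit_overlap_poisson()].
#' @return List with `fit`, `coefficients`, `aic_table`, `dispersion`,
#'   `separation` (logical: fitted probabilities collapsed to 0/1),
#'   `metadata` (model-family notes).
#' @export
fit_overlap_binomial <- function(proportions, degree = 3, weight = 100,
                                 species_effect = FALSE, orthogonal = FALSE) {
  stopifnot(degree %in% 1:3, weight > 0)
  d <- proportions[proportions$overlap_type %in% c("migrant", "breeding"), ]
  if (any(d$proportion < 0 | d$proportion > 1)) stop("proportions outside [0, 1]")
  d$w <- weight
  rhs <- function(deg) paste("overlap_type *", .poly_term(deg, orthogonal),
                             if (species_effect) "+ species" else "")
  fits <- lapply(1:3, function(deg)
    suppressWarnings(stats::glm(stats::as.formula(paste("proportion ~", rhs(deg))),
                                family = stats::binomial(), weights = w, data = d)))
  fit <- fits[[degree]]
  mu <- stats::fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) && !fit$converged
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  list(fit = fit, coefficients = summary(fit)$coefficients,
       aic_table = data.frame(degree = 1:3, aic = vapply(fits, stats::AIC, 0)),
       dispersion = disp, separation = separation,
       metadata = paste("fixed-effects binomial GLM on area proportions;",
                        "nominal weight", weight, "per observation;",
                        "no species random intercept"))
}

#' Peak-migration window(s)
#'
#' The window(s) with maximum species richness; when several tie, one is
#' picked uniformly at random under the given seed.
#'
#' @param snapshots A `snapshot_list`.
#' @param seed Seed for tie-breaking (default 1).
#' @return List with `window_index` (the chosen window), `ties` (all
#'   maximal windows), `richness`.
#' @export
peak_window <- function(snapshots, seed = 1) {
  rich <- vapply(snapshots, function(s) length(s$present_species), 0L)
  ties <- which(rich == max(rich))
  pick <- if (length(ties) == 1) ties else
    with_seed(seed, ties[sample.int(length(ties), 1)])
  list(window_index = pick, ties = ties, richness = rich)
}

#' Paired t test of migrant vs breeding overlap of breeding species
#'
#' Classic paired t statistic t = mean(d) / (sd(d)/sqrt(n)) on aligned
#' per-species proportions. Zero-variance differences are handled by
#' convention: all-zero differences give t = 0, p = 1; constant nonzero
#' differences give infinite t, p = 0.
#'
#' @param x,y Aligned numeric vectors (same species order, length >= 2).
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be aligned vectors of equal length >= 2")
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p_value = 1,
                                  mean_difference = 0))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p_value = 0,
                mean_difference = mean(d)))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1,
       p_value = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
       mean_difference = mean(d))
}

#' Migrant vs breeding overlap comparison at the migration peak
#'
#' Extracts, for the peak-richness window, each present breeding species'
#' proportion overlapped by migrants and by other breeders, and runs the
#' paired t test. Species with zero overlap from both groups can optionally
#' be excluded.
#'
#' @param dynamics Result of [window_overlaps()].
#' @param snapshots The matching `snapshot_list`.
#' @param seed Tie-break seed for [peak_window()].
#' @param exclude_zero Drop species with zero overlap by both groups
#'   (default `FALSE`).
#' @return List with `window_index`, `species`, `by_migrant`, `by_breeding`,
#'   and `test` (the [paired_t_test()] result).
#' @export
peak_overlap_comparison <- function(dynamics, snapshots, seed = 1,
                                    exclude_zero = FALSE) {
  pk <- peak_window(snapshots, seed)
  d <- dynamics$proportions[dynamics$proportions$window_index == pk$window_index, ]
  wide <- stats::reshape(d[d$overlap_type != "total",
                           c("species", "overlap_type", "proportion")],
                         idvar = "species", timevar = "overlap_type",
                         direction = "wide")
  names(wide) <- sub("proportion\\.", "", names(wide))
  if (exclude_zero) wide <- wide[wide$migrant > 0 | wide$breeding > 0, ]
  list(window_index = pk$window_index, species = wide$species,
       by_migrant = wide$migrant, by_breeding = wide$breeding,
       test = paired_t_test(wide$migrant, wide$breeding))
}
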