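# Species profiles: the parameters the synthetic-data generator draws from.

TRAIT_NAMES <- c("duration", "n_notes", "peak_freq", "min_freq", "max_freq",
                 "bandwidth")

#' Construct a species profile for the synthetic-data generator
#'
#' A profile holds everything the generator needs for one species: mean song
#' traits, between-individual and within-individual (between-song) trait
#' standard deviations, sampling effort, and migration phenology.
#'
#' Trait vectors are ordered as duration (s), number of notes, peak
#' frequency (Hz), minimum frequency (Hz), maximum frequency (Hz),
#' bandwidth (Hz). The mean vector must satisfy min <= peak <= max and
#' bandwidth = max - min.
#'
#' @param code Short species identifier.
#' @param status `"migrant"` or `"breeding"`.
#' @param trait_mean Numeric length-6 mean trait vector.
#' @param trait_sd_between Numeric length-6 between-individual SDs (>= 0).
#' @param trait_sd_within Numeric length-6 within-individual SDs (>= 0).
#' @param n_individuals Number of males sampled (>= 1; the analysis assumes
#'   >= 4 for non-degenerate niches).
#' @param songs_per_individual Songs recorded per male (>= 1).
#' @param arrival_day,departure_day Day-of-year bounds of the species'
#'   singing period (arrival <= departure).
#' @param peak_detectability Probability a checklist at the phenology peak
#'   reports the species, in `[0, 1]`.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(code, status, trait_mean,
                            trait_sd_between = rep(0, 6),
                            trait_sd_within = rep(0, 6),
                            n_individuals = 8, songs_per_individual = 8,
                            arrival_day = 96, departure_day = 158,
                            peak_detectability = 0.3) {
  status <- match.arg(status, c("migrant", "breeding"))
  trait_mean <- as.numeric(trait_mean)
  if (length(trait_mean) != 6)
    stop("trait_mean must have 6 entries (", paste(TRAIT_NAMES, collapse = ", "), ")")
  names(trait_mean) <- TRAIT_NAMES
  if (!(trait_mean["min_freq"] <= trait_mean["peak_freq"] &&
        trait_mean["peak_freq"] <= trait_mean["max_freq"]))
    stop("trait_mean must satisfy min_freq <= peak_freq <= max_freq")
  if (abs(trait_mean["bandwidth"] - (trait_mean["max_freq"] - trait_mean["min_freq"])) > 1e-6)
    stop("trait_mean bandwidth must equal max_freq - min_freq")
  for (sd in list(trait_sd_between, trait_sd_within))
    if (length(sd) != 6 || any(sd < 0)) stop("trait SDs must be 6 non-negative values")
  if (n_individuals < 1 || songs_per_individual < 1)
    stop("invalid profile: n_individuals and songs_per_individual must be >= 1")
  if (arrival_day > departure_day) stop("arrival_day must be <= departure_day")
  if (peak_detectability < 0 || peak_detectability > 1)
    stop("peak_detectability must be in [0, 1]")
  structure(list(
    code = as.character(code), status = status, trait_mean = trait_mean,
    trait_sd_between = stats::setNames(as.numeric(trait_sd_between), TRAIT_NAMES),
    trait_sd_within = stats::setNames(as.numeric(trait_sd_within), TRAIT_NAMES),
    n_individuals = as.integer(n_individuals),
    songs_per_individual = as.integer(songs_per_individual),
    arrival_day = as.integer(arrival_day),
    departure_day = as.integer(departure_day),
    peak_detectability = peak_detectability
  ), class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s (%s): %d males x %d songs, days %d-%d, p_det %.2f\n",
              x$code, x$status, x$n_individuals, x$songs_per_individual,
              x$arrival_day, x$departure_day, x$peak_detectability))
  invisible(x)
}

#' Statuses of a profile list as a named character vector
#'
#' @param profiles List of [species_profile()] objects.
#' @return Named character vector mapping species code to status.
#' @export
profile_statuses <- function(profiles) {
  stats::setNames(vapply(profiles, `[[`, "", "status"),
                  vapply(profiles, `[[`, "", "code"))
}

#' Load the published warbler community summary
#'
#' Per-species summary of the 30-species (11 breeding, 19 migrant) warbler
#' community of Kalamazoo County, south-west Michigan: migratory status,
#' number of males recorded, signalling-niche area (PCA units squared), and
#' the maximum proportion of each species' niche overlapped by migrants, by
#' breeding species, and in total when the full community co-occurs.
#'
#' @return A data frame with one row per species.
#' @export
warbler_community <- function() {
  path <- system.file("extdata", "warbler_community.csv",
                      package = "warblerspace", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default synthetic warbler community profiles
#'
#' Thirty species profiles (19 migrants, 11 breeders) emulating a temperate
#' wood-warbler community during spring migration. Species codes, statuses,
#' and per-species numbers of recorded males follow the published community
#' summary ([warbler_community()], 4-24 males per species); song-trait means
#' are spread deterministically across realistic warbler ranges (duration
#' 1-3 s, 4-24 notes, peak frequency 3.5-8 kHz) so that niches tile the
#' signal space with a mix of overlapping and disjoint pairs. Breeding
#' species arrive between days 96 and 120 and stay past the study window;
#' migrants pass through on staggered 18-26 day stopovers that all end by
#' day 152.
#'
#' @param songs_per_individual Songs per male (default 8, matching typical
#'   recording effort of ~8 songs per male).
#' @return List of [species_profile()] objects.
#' @export
demo_profiles <- function(songs_per_individual = 8) {
  comm <- warbler_community()
  n <- nrow(comm)
  profs <- vector("list", n)
  i_mig <- 0; i_bre <- 0
  n_mig <- sum(comm$status == "migrant"); n_bre <- sum(comm$status == "breeding")
  for (i in seq_len(n)) {
    # deterministic low-discrepancy spread of trait means (coprime strides)
    u1 <- ((7 * i) %% n) / (n - 1)
    u2 <- ((11 * i) %% n) / (n - 1)
    u3 <- ((13 * i) %% n) / (n - 1)
    u4 <- ((3 * i) %% n) / (n - 1)
    u5 <- ((5 * i) %% n) / (n - 1)
    peak <- 3500 + 4500 * u1
    minf <- peak - (600 + 900 * u4)
    maxf <- peak + (600 + 900 * u5)
    mu <- c(1 + 2 * u2, round(4 + 20 * u3), peak, minf, maxf, maxf - minf)
    status <- comm$status[i]
    if (status == "breeding") {
      i_bre <- i_bre + 1
      arr <- 96 + round(24 * (i_bre - 1) / (n_bre - 1))
      dep <- 170
      pdet <- 0.45
    } else {
      i_mig <- i_mig + 1
      arr <- 104 + round(22 * (i_mig - 1) / (n_mig - 1))
      dep <- min(arr + 18 + (i_mig %% 5) * 2, 152)
      pdet <- 0.30
    }
    profs[[i]] <- species_profile(
      code = comm$code[i], status = status, trait_mean = mu,
      trait_sd_between = c(0.4, 3, 320, 340, 340, 420),
      trait_sd_within = c(0.15, 1.5, 120, 130, 130, 160),
      n_individuals = comm$n_individuals[i],
      songs_per_individual = songs_per_individual,
      arrival_day = arr, departure_day = dep, peak_detectability = pdet)
  }
  profs
}
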