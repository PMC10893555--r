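# Synthetic-data generators: song-trait tables, checklists, phylogenies.

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a song-trait table
#'
#' Draws songs under a two-level Gaussian model: each male's trait vector is
#' the species mean plus an individual offset (SD `trait_sd_between`), and
#' each of that male's songs adds a song-level offset (SD `trait_sd_within`).
#' After sampling, the (min, peak, max) frequency triple of each song is
#' sorted so min <= peak <= max, bandwidth is recomputed as max - min, note
#' counts are rounded to integers >= 1, and durations are clamped positive.
#'
#' @param profiles Non-empty list of [species_profile()] objects.
#' @param seed Integer seed; identical seeds and profiles give identical
#'   tables.
#' @return Data frame of song records: `species`, `status`, `individual_id`,
#'   and the six traits (`duration`, `n_notes`, `peak_freq`, `min_freq`,
#'   `max_freq`, `bandwidth`).
#' @export
simulate_traits <- function(profiles, seed) {
  if (length(profiles) == 0) stop("profiles must be non-empty")
  with_seed(seed, {
    rows <- lapply(profiles, function(p) {
      ni <- p$n_individuals; ns <- p$songs_per_individual
      if (ni < 1 || ns < 1) stop("invalid profile: ", p$code)
      ind_off <- matrix(stats::rnorm(ni * 6, 0, rep(p$trait_sd_between, each = ni)),
                        nrow = ni)
      song <- do.call(rbind, lapply(seq_len(ni), function(i) {
        off <- matrix(stats::rnorm(ns * 6, 0, rep(p$trait_sd_within, each = ns)),
                      nrow = ns)
        tr <- sweep(off, 2, p$trait_mean + ind_off[i, ], `+`)
        data.frame(species = p$code, status = p$status,
                   individual_id = sprintf("%s_%02d", p$code, i),
                   duration = tr[, 1], n_notes = tr[, 2], peak_freq = tr[, 3],
                   min_freq = tr[, 4], max_freq = tr[, 5],
                   stringsAsFactors = FALSE)
      }))
      song
    })
    out <- do.call(rbind, rows)
    # enforce min <= peak <= max by sorting the triple, then recompute bandwidth
    fr <- t(apply(cbind(out$min_freq, out$peak_freq, out$max_freq), 1, sort))
    out$min_freq <- fr[, 1]; out$peak_freq <- fr[, 2]; out$max_freq <- fr[, 3]
    out$bandwidth <- out$max_freq - out$min_freq
    out$n_notes <- pmax(1, round(out$n_notes))
    out$duration <- pmax(out$duration, 1e-3)
    rownames(out) <- NULL
    out[, c("species", "status", "individual_id", TRAIT_NAMES)]
  })
}

# phenology curve value in [0, 1] for days d; 0 outside [arr, dep],
# maximal at the midpoint
phenology_curve <- function(d, arr, dep, shape = c("triangular", "gaussian",
                                                   "constant")) {
  shape <- match.arg(shape)
  inside <- d >= arr & d <= dep
  mid <- (arr + dep) / 2
  half <- pmax((dep - arr) / 2, 0.5)
  v <- switch(shape,
    triangular = 1 - abs(d - mid) / half,
    gaussian = exp(-((d - mid)^2) / (2 * (half / 2)^2)),
    constant = rep(1, length(d)))
  ifelse(inside, pmax(v, 0), 0)
}

#' Simulate a checklist table
#'
#' Generates `n_per_day` birding checklists per day over `day_range`. A
#' species is reported on a checklist with probability
#' `peak_detectability * curve(day)`, where the phenology curve is 0 outside
#' the species' `[arrival_day, departure_day]` and maximal at its midpoint.
#' A configurable fraction of checklists violates each checklist-quality
#' filter rule (incomplete, > 10 observers, > 5 h, > 5 km, excluded
#' protocol) so that filtering is exercised.
#'
#' @param profiles Non-empty list of [species_profile()] objects.
#' @param n_per_day Checklists per day (>= 1).
#' @param day_range Integer `(start, end)` day-of-year range, start <= end.
#' @param seed Integer seed.
#' @param curve Phenology curve family: `"triangular"` (default),
#'   `"gaussian"`, or `"constant"` (detectability flat inside the window).
#' @param violation_rates Named numeric vector of per-rule violation
#'   probabilities with names among `incomplete`, `observers`, `duration`,
#'   `distance`, `protocol`; defaults to 0 for all.
#' @return Data frame of checklists: `checklist_id`, `date` (day-of-year),
#'   `protocol`, `complete`, `n_observers`, `duration_h`, `distance_km`, and
#'   the list-column `species_reported` (character vector of codes).
#' @export
simulate_checklists <- function(profiles, n_per_day, day_range, seed,
                                curve = "triangular",
                                violation_rates = c()) {
  if (length(profiles) == 0) stop("profiles must be non-empty")
  if (day_range[1] > day_range[2]) stop("day_range start must be <= end")
  if (n_per_day < 1) stop("n_per_day must be >= 1")
  vr <- c(incomplete = 0, observers = 0, duration = 0, distance = 0, protocol = 0)
  if (length(violation_rates)) vr[names(violation_rates)] <- violation_rates
  days <- rep(seq(day_range[1], day_range[2]), each = n_per_day)
  n <- length(days)
  with_seed(seed, {
    protocol <- sample(c("stationary", "traveling"), n, replace = TRUE)
    distance <- ifelse(protocol == "stationary", 0, stats::runif(n, 0.2, 4))
    cl <- data.frame(
      checklist_id = sprintf("S%06d", seq_len(n)),
      date = days,
      protocol = protocol,
      complete = TRUE,
      n_observers = sample(1:4, n, replace = TRUE),
      duration_h = stats::runif(n, 0.25, 3),
      distance_km = distance,
      stringsAsFactors = FALSE)
    # plant filter-rule violations
    cl$complete[stats::runif(n) < vr["incomplete"]] <- FALSE
    i <- stats::runif(n) < vr["observers"]; cl$n_observers[i] <- sample(11:15, sum(i), TRUE)
    i <- stats::runif(n) < vr["duration"]; cl$duration_h[i] <- stats::runif(sum(i), 5.1, 8)
    i <- stats::runif(n) < vr["distance"]
    cl$distance_km[i] <- stats::runif(sum(i), 5.1, 10)
    cl$protocol[i & cl$protocol == "stationary"] <- "traveling"
    i <- stats::runif(n) < vr["protocol"]; cl$protocol[i] <- "other"
    # detections
    det <- matrix(FALSE, n, length(profiles))
    for (j in seq_along(profiles)) {
      p <- profiles[[j]]
      pr <- p$peak_detectability *
        phenology_curve(days, p$arrival_day, p$departure_day, curve)
      det[, j] <- stats::runif(n) < pr
    }
    codes <- vapply(profiles, `[[`, "", "code")
    cl$species_reported <- lapply(seq_len(n), function(k) codes[det[k, ]])
    cl
  })
}

#' Simulate an ultrametric phylogeny over species codes
#'
#' Draws a pure-birth (Yule) tree over the given tips, optionally evolving a
#' six-trait vector along it by Brownian motion (variance proportional to
#' path length) to induce positive phylogenetic signal.
#'
#' @param codes Character vector of >= 2 species codes (tip labels).
#' @param birth_rate Speciation rate of the Yule process (> 0).
#' @param seed Integer seed.
#' @param brownian If `TRUE`, also return Brownian-motion trait values at the
#'   tips.
#' @param bm_sigma Length-6 Brownian rate SDs used when `brownian = TRUE`.
#' @return List with `tree` (an `ape` `phylo`), `newick` (Newick string),
#'   and `traits` (tip-by-trait matrix, or `NULL`).
#' @export
simulate_tree <- function(codes, birth_rate = 1, seed = 1, brownian = FALSE,
                          bm_sigma = rep(1, 6)) {
  if (length(codes) < 2) stop("need at least 2 species codes")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  with_seed(seed, {
    tr <- ape::rphylo(length(codes), birth = birth_rate, death = 0)
    tr$tip.label <- as.character(codes)
    traits <- NULL
    if (brownian) {
      traits <- vapply(seq_len(6), function(k)
        ape::rTraitCont(tr, model = "BM", sigma = bm_sigma[k]),
        numeric(length(codes)))
      rownames(traits) <- tr$tip.label
      colnames(traits) <- TRAIT_NAMES
    }
    list(tree = tr, newick = ape::write.tree(tr), traits = traits)
  })
}
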