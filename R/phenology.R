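# Time-resolved community reconstruction from checklist occurrence data.

#' Filter checklists by quality rules
#'
#' Keeps complete checklists with stationary or traveling protocols inside
#' the date window, with at most 10 observers, at most 5 hours duration,
#' and at most 5 km distance ("more than" thresholds are strict, so exact
#' boundary values are kept). Exact duplicate checklist ids are dropped
#' first.
#'
#' @param checklists Checklist data frame (see [simulate_checklists()]).
#' @param date_window Integer `(start, end)` day-of-year window kept,
#'   inclusive; default days 91-166 (April 1 to June 15, leap-year
#'   numbering).
#' @return List with `checklists` (the surviving rows) and `rejections`
#'   (named counts per rule; a row can fail several rules and is tallied
#'   under each).
#' @export
filter_checklists <- function(checklists, date_window = c(91, 166)) {
  req <- c("checklist_id", "date", "protocol", "complete", "n_observers",
           "duration_h", "distance_km")
  miss <- setdiff(req, names(checklists))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in req) {
    bad <- which(is.na(checklists[[col]]))
    if (length(bad))
      stop("missing ", col, " in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  dup <- duplicated(checklists$checklist_id)
  cl <- checklists[!dup, , drop = FALSE]
  fail <- cbind(
    incomplete = !cl$complete,
    protocol = !cl$protocol %in% c("stationary", "traveling"),
    date = cl$date < date_window[1] | cl$date > date_window[2],
    observers = cl$n_observers > 10,
    duration = cl$duration_h > 5,
    distance = cl$distance_km > 5)
  keep <- rowSums(fail) == 0
  list(checklists = cl[keep, , drop = FALSE],
       rejections = c(duplicate = sum(dup), colSums(fail),
                      total_rejected = sum(dup) + sum(!keep)))
}

#' Daily occurrence series for one species
#'
#' Occurrence on day d is 100 times the fraction of that day's checklists
#' reporting the species. Days with no checklists yield `NA` (absence of
#' effort is not evidence of absence).
#'
#' When replicate seasons are present (a `year` column), the default pools
#' all years' checklists for each calendar day; `per_year = TRUE` instead
#' computes occurrence per year and averages the yearly percentages. With
#' balanced effort across years the two agree exactly.
#'
#' @param filtered Filtered checklist data frame with list-column
#'   `species_reported`.
#' @param species Species code.
#' @param days Integer days to evaluate (default: observed date range).
#' @param per_year Average per-year occurrence instead of pooling
#'   checklists (requires a `year` column; default `FALSE`).
#' @return Named numeric vector of occurrence percentages indexed by day.
#' @export
occurrence <- function(filtered, species,
                       days = seq(min(filtered$date), max(filtered$date)),
                       per_year = FALSE) {
  if (per_year && is.null(filtered$year))
    stop("per_year averaging requires a 'year' column")
  hit <- vapply(filtered$species_reported, function(s) species %in% s, TRUE)
  out <- stats::setNames(rep(NA_real_, length(days)), days)
  if (per_year) {
    key <- interaction(filtered$date, filtered$year, drop = TRUE)
    p_dy <- 100 * tapply(hit, key, mean)
    day_of <- vapply(strsplit(names(p_dy), "\\."), `[`, "", 1)
    p_day <- tapply(p_dy, day_of, mean)
    have <- intersect(names(p_day), as.character(days))
    out[have] <- p_day[have]
  } else {
    n_day <- tapply(rep(1, nrow(filtered)), filtered$date, sum)
    k_day <- tapply(hit, filtered$date, sum)
    have <- intersect(names(n_day), as.character(days))
    out[have] <- 100 * k_day[have] / n_day[have]
  }
  out
}

#' Average a daily series over consecutive fixed-width windows
#'
#' Partitions `[start_day, end_day]` into consecutive non-overlapping
#' windows of `width` days (the range length must be divisible by the
#' width) and averages the daily values within each window, ignoring
#' missing days.
#'
#' @param series Named numeric daily series (names are day-of-year).
#' @param start_day,end_day Inclusive day range (defaults 96 and 158, the
#'   April 5 - June 6 migratory window, giving 21 windows).
#' @param width Window width in days (default 3).
#' @return Data frame `window_index`, `start`, `end`, `midday`, `mean`.
#' @export
window_average <- function(series, start_day = 96, end_day = 158, width = 3) {
  span <- end_day - start_day + 1
  if (span %% width != 0)
    stop("configuration error: range of ", span, " days not divisible by width ", width)
  starts <- seq(start_day, end_day, by = width)
  means <- vapply(starts, function(s) {
    v <- series[as.character(seq(s, s + width - 1))]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  data.frame(window_index = seq_along(starts), start = starts,
             end = starts + width - 1, midday = starts + (width - 1) / 2,
             mean = means)
}

#' Reconstruct community snapshots from windowed occurrence
#'
#' A species is present in a window when its mean occurrence there is at or
#' above the threshold (default 1.5%, so exactly 1.5 counts as present).
#' Missing window means are treated as below threshold.
#'
#' @param window_means Named list of [window_average()] data frames, one per
#'   species, over identical windows.
#' @param statuses Named status vector (code -> migrant/breeding).
#' @param threshold Presence threshold in percent (default 1.5).
#' @return List of snapshots (class `snapshot_list`); each has
#'   `window_index`, `window_days`, `present_species`, `n_migrants`,
#'   `n_breeders`.
#' @export
reconstruct_communities <- function(window_means, statuses, threshold = 1.5) {
  if (length(window_means) == 0) stop("no species series supplied")
  wi <- window_means[[1]][c("window_index", "start", "end", "midday")]
  for (wm in window_means)
    if (!identical(wm$start, wi$start)) stop("species windows differ")
  snaps <- lapply(seq_len(nrow(wi)), function(w) {
    pres <- names(window_means)[vapply(window_means, function(wm) {
      m <- wm$mean[w]
      !is.na(m) && m >= threshold
    }, TRUE)]
    st <- statuses[pres]
    list(window_index = wi$window_index[w],
         window_days = c(wi$start[w], wi$end[w]), midday = wi$midday[w],
         present_species = pres,
         n_migrants = sum(st == "migrant"), n_breeders = sum(st == "breeding"))
  })
  structure(snaps, class = "snapshot_list")
}

#' @export
print.snapshot_list <- function(x, ...) {
  rich <- vapply(x, function(s) length(s$present_species), 0L)
  cat(sprintf("<snapshot_list> %d windows, richness %d-%d\n",
              length(x), min(rich), max(rich)))
  invisible(x)
}

#' Occurrence matrix and snapshots in one step
#'
#' Convenience wrapper: filters checklists, computes each species' daily
#' occurrence, averages over windows, and reconstructs snapshots.
#'
#' @inheritParams filter_checklists
#' @inheritParams reconstruct_communities
#' @param species Codes to evaluate (default: all reported).
#' @param start_day,end_day,width Window grid (defaults 96, 158, 3).
#' @return List with `filtered`, `rejections`, `window_means`, `snapshots`,
#'   and `occurrence` (species x window matrix of window means).
#' @export
community_phenology <- function(checklists, statuses,
                                species = names(statuses),
                                date_window = c(91, 166),
                                start_day = 96, end_day = 158, width = 3,
                                threshold = 1.5) {
  fl <- filter_checklists(checklists, date_window)
  days <- seq(start_day, end_day)
  wms <- lapply(stats::setNames(species, species), function(sp)
    window_average(occurrence(fl$checklists, sp, days), start_day, end_day, width))
  snaps <- reconstruct_communities(wms, statuses, threshold)
  occ <- do.call(rbind, lapply(wms, `[[`, "mean"))
  colnames(occ) <- wms[[1]]$window_index
  list(filtered = fl$checklists, rejections = fl$rejections,
       window_means = wms, snapshots = snaps, occurrence = occ)
}
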