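# Checklist filtering, occurrence, window averaging, community snapshots.

mk_checklist <- function(n = 1, date = 120, protocol = "stationary",
                         complete = TRUE, n_observers = 2, duration_h = 1,
                         distance_km = 0, species = list(character(0)),
                         id = NULL) {
  data.frame(checklist_id = if (is.null(id)) sprintf("C%03d", seq_len(n)) else id,
             date = date, protocol = protocol, complete = complete,
             n_observers = n_observers, duration_h = duration_h,
             distance_km = distance_km,
             stringsAsFactors = FALSE) |>
    transform(species_reported = I(rep(species, length.out = n)))
}

test_that("filter boundaries follow the strict 'more than' semantics", {
  base <- mk_checklist(6, id = sprintf("B%d", 1:6))
  base$n_observers <- c(10, 11, 2, 2, 2, 2)
  base$duration_h <- c(1, 1, 5, 5.01, 1, 1)
  base$distance_km <- c(0, 0, 0, 0, 5, 5.2)
  base$protocol <- "traveling"
  kept <- filter_checklists(base)$checklists$checklist_id
  expect_setequal(kept, c("B1", "B3", "B5"))  # exactly-at-boundary kept
})

test_that("protocol, completeness, date window, and duplicates are enforced", {
  cl <- rbind(mk_checklist(1, protocol = "other", id = "X1"),
              mk_checklist(1, complete = FALSE, id = "X2"),
              mk_checklist(1, date = 90, id = "X3"),
              mk_checklist(1, date = 167, id = "X4"),
              mk_checklist(1, id = "X5"),
              mk_checklist(1, id = "X5"))
  fl <- filter_checklists(cl)
  expect_equal(fl$checklists$checklist_id, "X5")
  expect_equal(unname(fl$rejections["duplicate"]), 1)
  expect_equal(unname(fl$rejections["protocol"]), 1)
  expect_equal(unname(fl$rejections["incomplete"]), 1)
  expect_equal(unname(fl$rejections["date"]), 2)
  # idempotence
  fl2 <- filter_checklists(fl$checklists)
  expect_identical(fl2$checklists, fl$checklists)
  # missing fields are row-level errors
  bad <- mk_checklist(2); bad$duration_h[2] <- NA
  expect_error(filter_checklists(bad), "duration_h")
})

test_that("daily occurrence is the percentage of checklists reporting", {
  cl <- mk_checklist(4, species = list("AAA", character(0), character(0),
                                       character(0)))
  expect_equal(unname(occurrence(cl, "AAA")), 25)
  cl2 <- mk_checklist(3, species = list(c("AAA", "BBB")))
  expect_equal(unname(occurrence(cl2, "AAA")), 100)
  # day without checklists is missing, not zero
  occ <- occurrence(cl, "AAA", days = 120:121)
  expect_equal(unname(occ), c(25, NA))
})

test_that("adding a non-reporting checklist never increases occurrence", {
  cl <- mk_checklist(4, species = list("AAA", "AAA", character(0), character(0)))
  o1 <- occurrence(cl, "AAA")
  o2 <- occurrence(rbind(cl, mk_checklist(1, id = "EXTRA")), "AAA")
  expect_lte(unname(o2["120"]), unname(o1["120"]))
})

test_that("pooled and per-year occurrence agree under balanced effort", {
  set.seed(3)
  cl <- do.call(rbind, lapply(1:3, function(yr) {
    c1 <- mk_checklist(10, date = rep(120:121, each = 5),
                       id = sprintf("Y%d_%02d", yr, 1:10))
    c1$species_reported <- I(lapply(1:10, function(i)
      if (runif(1) < 0.4) "AAA" else character(0)))
    c1$year <- yr
    c1
  }))
  pooled <- occurrence(cl, "AAA", days = 120:121)
  yearly <- occurrence(cl, "AAA", days = 120:121, per_year = TRUE)
  expect_equal(pooled, yearly)
})

test_that("the study window yields exactly 21 three-day windows", {
  s <- setNames(rep(2, 63), 96:158)
  w <- window_average(s)
  expect_equal(nrow(w), 21)
  expect_equal(w$start[1], 96)
  expect_equal(w$end[21], 158)
  # windows partition the range exactly
  expect_equal(sum(w$end - w$start + 1), 63)
  expect_true(all(w$start[-1] == w$end[-21] + 1))
  expect_equal(w$mean, rep(2, 21))
})

test_that("window means are hand-computable and ranges must divide evenly", {
  s <- setNames(1:9, 1:9)
  w <- window_average(s, 1, 9, 3)
  expect_equal(w$mean, c(2, 5, 8))
  expect_error(window_average(s, 1, 8, 3), "configuration error")
  # missing days are excluded from the mean
  s[2] <- NA
  expect_equal(window_average(s, 1, 9, 3)$mean[1], 2)
})

test_that("presence uses >= threshold and is monotone in the threshold", {
  wm <- list(
    HI = data.frame(window_index = 1:2, start = c(96, 99), end = c(98, 101),
                    midday = c(97, 100), mean = c(1.5, 5)),
    LO = data.frame(window_index = 1:2, start = c(96, 99), end = c(98, 101),
                    midday = c(97, 100), mean = c(1.4999, 0)))
  st <- c(HI = "migrant", LO = "breeding")
  snaps <- reconstruct_communities(wm, st)
  expect_true("HI" %in% snaps[[1]]$present_species)   # exactly 1.5 is present
  expect_false("LO" %in% snaps[[1]]$present_species)  # 1.4999 is not
  expect_equal(snaps[[1]]$n_migrants + snaps[[1]]$n_breeders,
               length(snaps[[1]]$present_species))
  # all-zero series gives empty snapshots
  wm0 <- lapply(wm, function(w) { w$mean <- 0; w })
  expect_true(all(vapply(reconstruct_communities(wm0, st),
                         function(s) length(s$present_species) == 0, TRUE)))
  # raising the threshold never adds species
  for (th in c(0, 1, 2, 6)) {
    lo <- reconstruct_communities(wm, st, threshold = th)
    hi <- reconstruct_communities(wm, st, threshold = th + 1)
    for (w in seq_along(lo))
      expect_true(all(hi[[w]]$present_species %in% lo[[w]]$present_species))
  }
})

test_that("staggered synthetic phenology reconstructs the analytic community", {
  # deterministic detection: p = 1, constant curve -> a species is present in
  # a window iff its [arrival, departure] covers at least one window day with
  # enough coverage to clear the threshold (here any overlap gives 100% or
  # 33.3% >> 1.5%)
  profs <- list(
    species_profile("EARLY", "breeding", c(2, 10, 5000, 4000, 6000, 2000),
                    arrival_day = 96, departure_day = 104, peak_detectability = 1),
    species_profile("LATE", "migrant", c(2, 10, 5000, 4000, 6000, 2000),
                    arrival_day = 105, departure_day = 158, peak_detectability = 1))
  cl <- simulate_checklists(profs, 10, c(96, 158), seed = 2, curve = "constant")
  ph <- community_phenology(cl, profile_statuses(profs))
  pres <- vapply(ph$snapshots, function(s)
    paste(sort(s$present_species), collapse = "+"), "")
  # windows 1-3 cover days 96-104: EARLY only; window 4 (105-107) onwards: LATE
  expect_equal(pres[1:3], rep("EARLY", 3))
  expect_equal(pres[4:21], rep("LATE", 18))
})
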