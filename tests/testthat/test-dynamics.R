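# Windowed overlap dynamics, GLM time-course fits, peak-window comparison.

# hand-built 4-species set: unit squares at known offsets
fixture_niches <- function() {
  n <- list(
    list(species = "B1", status = "breeding", hull = square(0, 0),
         area = 1, centroid = c(0.5, 0.5), n_individuals = 4L),
    list(species = "B2", status = "breeding", hull = square(0.5, 0),
         area = 1, centroid = c(1, 0.5), n_individuals = 4L),
    list(species = "M1", status = "migrant", hull = square(0.25, 0.5),
         area = 1, centroid = c(0.75, 1), n_individuals = 4L),
    list(species = "M2", status = "migrant", hull = square(5, 5),
         area = 1, centroid = c(5.5, 5.5), n_individuals = 4L))
  class(n) <- "niche_set"
  n
}

mk_snaps <- function(present) {
  structure(lapply(seq_along(present), function(i) {
    st <- c(B1 = "breeding", B2 = "breeding", M1 = "migrant", M2 = "migrant")
    p <- present[[i]]
    list(window_index = i, window_days = c(96 + 3 * (i - 1), 98 + 3 * (i - 1)),
         midday = 97 + 3 * (i - 1), present_species = p,
         n_migrants = sum(st[p] == "migrant"),
         n_breeders = sum(st[p] == "breeding"))
  }), class = "snapshot_list")
}

test_that("window overlap counts and proportions match hand computation", {
  niches <- fixture_niches()
  snaps <- mk_snaps(list("B1", c("B1", "B2"), c("B1", "B2", "M1"),
                         c("B1", "B2", "M1", "M2")))
  dyn <- window_overlaps(snaps, niches)
  cnt <- dyn$counts
  # window 1: single species, no pairs
  expect_true(all(cnt$n_overlaps[cnt$window_index == 1] == 0))
  # window 2: only B1-B2, overlap area 0.5 -> one breeding-breeding overlap
  w2 <- cnt[cnt$window_index == 2, ]
  expect_equal(w2$n_overlaps[w2$pair_type == "breeding-breeding"], 1)
  expect_equal(sum(w2$n_overlaps), 1)
  # window 3: adds M1 which overlaps both breeders
  w3 <- cnt[cnt$window_index == 3, ]
  expect_equal(w3$n_overlaps[w3$pair_type == "migrant-breeding"], 2)
  # window 4: M2 is disjoint from everything; counts unchanged
  w4 <- cnt[cnt$window_index == 4, ]
  expect_equal(w4$n_overlaps[w4$pair_type == "migrant-breeding"], 2)
  expect_equal(w4$n_overlaps[w4$pair_type == "migrant-migrant"], 0)
  # proportions window 3, B1: M1 clips [0.25,1]x[0.5,1] = 0.375 of B1;
  # B2 clips [0.5,1]x[0,1] = 0.5; union with M1 piece = 0.5 + 0.375 - 0.25
  pr <- dyn$proportions
  b1w3 <- pr[pr$window_index == 3 & pr$species == "B1", ]
  expect_equal(b1w3$proportion[b1w3$overlap_type == "migrant"], 0.375)
  expect_equal(b1w3$proportion[b1w3$overlap_type == "breeding"], 0.5)
  expect_equal(b1w3$proportion[b1w3$overlap_type == "total"], 0.625)
  # standardized day has mean 0, sd 1
  sd1 <- unique(cnt[c("window_index", "standardized_day")])$standardized_day
  expect_equal(mean(sd1), 0, tolerance = 1e-12)
  expect_equal(sd(sd1), 1, tolerance = 1e-12)
})

test_that("a full-community window reproduces the global overlap counts", {
  sn <- small_niches()
  codes <- vapply(sn$niches, `[[`, "", "species")
  st <- vapply(sn$niches, `[[`, "", "status")
  snaps <- structure(list(list(window_index = 1, window_days = c(96, 98),
                               midday = 97, present_species = codes,
                               n_migrants = sum(st == "migrant"),
                               n_breeders = sum(st == "breeding")),
                          list(window_index = 2, window_days = c(99, 101),
                               midday = 100, present_species = codes[1],
                               n_migrants = 0, n_breeders = 1)),
                     class = "snapshot_list")
  dyn <- window_overlaps(snaps, sn$niches)
  glob <- overlap_table(sn$niches)
  for (tp in unique(dyn$counts$pair_type)) {
    w1 <- dyn$counts[dyn$counts$window_index == 1 & dyn$counts$pair_type == tp, ]
    expect_equal(w1$n_overlaps,
                 sum(glob$pairs$overlaps[glob$pairs$pair_type == tp]))
  }
  expect_error(window_overlaps(mk_snaps(list("B9")), sn$niches),
               "without a niche")
})

test_that("window counts are monotone under snapshot growth", {
  niches <- fixture_niches()
  sets <- list("B1", c("B1", "B2"), c("B1", "B2", "M1"), c("B1", "B2", "M1", "M2"))
  dyn <- window_overlaps(mk_snaps(sets), niches)
  tot <- tapply(dyn$counts$n_overlaps, dyn$counts$window_index, sum)
  expect_true(all(diff(tot) >= 0))
})

test_that("Poisson GLM recovers constant and group-mean structure exactly", {
  types <- rep(c("migrant-breeding", "breeding-breeding", "migrant-migrant"),
               each = 7)
  counts <- data.frame(window_index = rep(1:7, 3), midday = rep(1:7, 3),
                       standardized_day = rep(scale(1:7)[, 1], 3),
                       pair_type = types, n_overlaps = 4, n_possible = 10)
  f <- fit_overlap_poisson(counts, degree = 1)
  expect_equal(unname(coef(f$fit)[1]), log(4), tolerance = 1e-8)
  expect_equal(unname(coef(f$fit)[-1]), rep(0, 5), tolerance = 1e-6)
  # distinct constant counts per type: fitted means equal group means
  counts$n_overlaps <- rep(c(2, 5, 9), each = 7)
  f2 <- fit_overlap_poisson(counts, degree = 1)
  expect_equal(as.numeric(tapply(fitted(f2$fit), counts$pair_type, mean)),
               c(5, 2, 9), tolerance = 1e-6)
})

test_that("time effects are null when the community never changes", {
  counts <- data.frame(window_index = rep(1:21, 3), midday = rep(1:21, 3),
                       standardized_day = rep(scale(1:21)[, 1], 3),
                       pair_type = rep(c("migrant-breeding", "breeding-breeding",
                                         "migrant-migrant"), each = 21),
                       n_overlaps = rep(c(7, 3, 5), each = 21), n_possible = 20)
  f <- fit_overlap_poisson(counts, degree = 3)
  expect_equal(f$interaction_lrt$statistic, 0, tolerance = 1e-8)
})

test_that("binomial GLM handles the flat case and flags separation", {
  d <- data.frame(window_index = rep(1:10, 2), standardized_day = rep(scale(1:10)[, 1], 2),
                  species = "B1",
                  overlap_type = rep(c("migrant", "breeding"), each = 10),
                  proportion = 0.5)
  f <- fit_overlap_binomial(d, degree = 1)
  expect_equal(unname(coef(f$fit)), rep(0, 4), tolerance = 1e-8)
  # perfectly separated 0/1 responses by time
  d2 <- d
  d2$proportion <- rep(c(rep(0, 5), rep(1, 5)), 2)
  f2 <- fit_overlap_binomial(d2, degree = 1)
  expect_true(f2$separation || any(abs(coef(f2$fit)) > 10))
})

test_that("binomial GLM AIC compares quadratic and cubic time terms", {
  sn <- small_niches()
  set.seed(12)
  sday <- scale(1:21)[, 1]
  logit <- function(x) 1 / (1 + exp(-x))
  d <- do.call(rbind, lapply(c("migrant", "breeding"), function(tp) {
    eta <- if (tp == "migrant") 1 - 2 * sday^2 + 0.5 * sday^3 else 0.3 * sday
    data.frame(window_index = 1:21, standardized_day = sday, species = "B1",
               overlap_type = tp, proportion = rbinom(21, 100, logit(eta)) / 100)
  }))
  f <- fit_overlap_binomial(d, degree = 3)
  expect_equal(nrow(f$aic_table), 3)
  expect_true(all(is.finite(f$aic_table$aic)))
  expect_true(is.finite(f$dispersion))
})

test_that("paired t statistic matches hand values and the t.test oracle", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2, p_value = 1, mean_difference = 0))
  r <- paired_t_test(c(2, 2, 2, 0), c(1, 1, 1, 1))  # d = (1,1,1,-1)
  expect_equal(r$t, 1)
  expect_equal(r$df, 3)
  # zero-variance nonzero difference convention
  inf <- paired_t_test(c(2, 2), c(1, 1))
  expect_equal(inf$t, Inf)
  expect_equal(inf$p_value, 0)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    r <- paired_t_test(x, y)
    o <- t.test(x, y, paired = TRUE)
    expect_equal(r$t, unname(o$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, o$p.value, tolerance = 1e-12)
  }
})

test_that("peak window selection and the peak comparison are reproducible", {
  niches <- fixture_niches()
  sets <- list("B1", c("B1", "B2", "M1"), c("B1", "B2", "M1", "M2"), "B2")
  snaps <- mk_snaps(sets)
  pk <- peak_window(snaps)
  expect_equal(pk$window_index, 3)
  dyn <- window_overlaps(snaps, niches)
  pc <- peak_overlap_comparison(dyn, snaps, seed = 1)
  expect_equal(pc$window_index, 3)
  expect_setequal(pc$species, c("B1", "B2"))
  expect_equal(pc$test$df, 1)
  # ties broken deterministically under a fixed seed
  snaps2 <- mk_snaps(list(c("B1", "B2", "M1"), c("B1", "B2", "M2")))
  expect_equal(peak_window(snaps2, seed = 4)$window_index,
               peak_window(snaps2, seed = 4)$window_index)
  expect_setequal(peak_window(snaps2, seed = 4)$ties, 1:2)
})
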