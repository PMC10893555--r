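# Per-male averaging, correlation-matrix PCA, niches, diagnostics.

test_that("per-male means reduce to identities on tiny tables", {
  one <- data.frame(species = "A", status = "breeding", individual_id = "A_1",
                    duration = 1.7, n_notes = 9, peak_freq = 5000,
                    min_freq = 4000, max_freq = 6000, bandwidth = 2000)
  expect_equal(per_male_means(one)[TRAIT_NAMES], one[TRAIT_NAMES])
  two <- rbind(one, one)
  two$duration <- c(1, 3)
  expect_equal(per_male_means(two)$duration, 2)
})

test_that("per-male means equal a brute-force group-and-average oracle", {
  tr <- simulate_traits(small_profiles(), seed = 21)
  tr <- tr[sample(nrow(tr)), ]  # shuffle rows
  m <- per_male_means(tr)
  for (id in unique(tr$individual_id)) {
    sub <- tr[tr$individual_id == id, ]
    for (nm in TRAIT_NAMES)
      expect_equal(m[m$individual_id == id, nm], mean(sub[[nm]]),
                   tolerance = 1e-12)
  }
})

test_that("an individual filed under two species is a data-integrity error", {
  tr <- simulate_traits(small_profiles(), seed = 1)
  tr$species[tr$individual_id == "SP01_01"][1] <- "SP02"
  expect_error(per_male_means(tr), "data integrity")
})

test_that("perfectly correlated traits collapse to one component", {
  base <- rnorm(10, 0, 1)
  d <- data.frame(species = "A", status = "breeding",
                  individual_id = sprintf("A_%02d", 1:10))
  for (nm in TRAIT_NAMES) d[[nm]] <- base  # 6 identical columns
  expect_warning(sp <- build_signal_space(d), "fewer than 2")
  expect_equal(sp$eigenvalues[1], 6, tolerance = 1e-10)
  expect_equal(sp$eigenvalues[-1], rep(0, 5), tolerance = 1e-10)
  expect_equal(sp$explained_fraction, 1)
})

test_that("identity and 2x2 correlation matrices give the closed-form spectra", {
  # exactly uncorrelated unit-variance columns: all eigenvalues 1,
  # zero components retained under the strict > 1 rule
  d <- data.frame(species = "A", status = "breeding",
                  individual_id = sprintf("A_%d", 1:4),
                  t1 = c(1, 1, -1, -1), t2 = c(1, -1, 1, -1))
  expect_warning(sp0 <- build_signal_space(d, traits = c("t1", "t2")),
                 "fewer than 2")
  expect_equal(sp0$eigenvalues, c(1, 1))
  expect_equal(ncol(sp0$scores), 0)
  # sample correlation exactly 0.5: eigenvalues 1.5 and 0.5
  d$t2 <- 0.5 * d$t1 + sqrt(0.75) * c(1, -1, 1, -1)
  expect_warning(sp1 <- build_signal_space(d, traits = c("t1", "t2")))
  expect_equal(sp1$eigenvalues, c(1.5, 0.5), tolerance = 1e-12)
})

test_that("eigenvalues sum to the trait count and scores have the PCA moments", {
  sn <- small_niches()
  sp <- sn$space
  expect_equal(sum(sp$eigenvalues), 6, tolerance = 1e-8)
  expect_equal(colMeans(sp$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-10)
  expect_equal(unname(apply(sp$scores, 2, var)), sp$eigenvalues[1:2],
               tolerance = 1e-8)
  # sign convention: largest-|loading| entry positive
  for (k in 1:2) expect_gt(sp$loadings[which.max(abs(sp$loadings[, k])), k], 0)
})

test_that("projection on all components reconstructs the standardized data", {
  tr <- simulate_traits(small_profiles(), seed = 31)
  m <- per_male_means(tr)
  sp <- suppressWarnings(build_signal_space(m, eigenvalue_threshold = -1))
  Z <- scale(as.matrix(m[TRAIT_NAMES]))
  expect_equal(max(abs(sp$scores %*% t(sp$loadings) - Z)), 0, tolerance = 1e-8)
})

test_that("constant trait columns raise an error naming the column", {
  tr <- simulate_traits(small_profiles(), seed = 2)
  m <- per_male_means(tr)
  m$duration <- 2
  expect_error(build_signal_space(m), "duration")
})

test_that("every individual's score lies inside its species hull", {
  sn <- small_niches()
  for (nc in sn$niches) {
    pts <- sn$space$scores[sn$space$species == nc$species, , drop = FALSE]
    expect_true(all(point_in_convex(pts, nc$hull, tol = 1e-8)))
  }
})

test_that("degenerate niches are errors naming the species", {
  fake <- structure(list(
    scores = cbind(PC1 = c(0, 1, 2, 0, 1, 0.5), PC2 = c(0, 1, 2, 0, 0.5, 1)),
    species = rep(c("LIN", "OK"), each = 3),
    status = rep("breeding", 6)), class = "signal_space")
  expect_error(build_niches(fake), "LIN")
})

test_that("community area follows the hull-of-all-points convention", {
  sn <- small_niches()
  a <- community_area(sn$space)
  expect_gte(a, max(vapply(sn$niches, `[[`, 0, "area")))
  expect_gte(a, community_area(sn$space, method = "union") - 1e-9)
  # two disjoint unit squares: spanning hull covers the gap (11, not 2)
  sq2 <- structure(list(scores = cbind(PC1 = c(0, 1, 1, 0, 10, 11, 11, 10),
                                       PC2 = c(0, 0, 1, 1, 0, 0, 1, 1)),
                        species = rep(c("A", "B"), each = 4),
                        status = rep("breeding", 8)), class = "signal_space")
  expect_equal(community_area(sq2), 11)
  expect_equal(community_area(sq2, method = "union"), 2)
})

test_that("shoelace niche areas agree with Monte-Carlo rejection sampling", {
  sn <- small_niches()
  set.seed(77)
  for (nc in sn$niches[1:4]) {
    bb <- c(range(nc$hull[, 1]), range(nc$hull[, 2]))
    mc <- mc_area(function(px, py) oracle_point_in_poly(px, py, nc$hull),
                  bbox = bb, n = 4e4)
    expect_lt(abs(nc$area - mc$estimate), 4 * mc$se)
  }
})

test_that("sample-size regression recovers a noiseless log-linear law", {
  niches <- lapply(1:10, function(i) list(
    species = paste0("S", i), status = if (i %% 2) "migrant" else "breeding",
    hull = square(), area = exp(-1 + 0.2 * (i + 3)),
    centroid = c(0.5, 0.5), n_individuals = i + 3L))
  class(niches) <- "niche_set"
  r <- sample_size_regression(niches)
  expect_equal(r$slope, 0.2, tolerance = 1e-10)
  expect_equal(r$intercept, -1, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
})

test_that("regression slope CIs cover a known noisy slope in >= 90% of replicates", {
  cover <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n_ind <- sample(4:24, 100, replace = TRUE)
    area <- exp(0.5 + 0.1 * n_ind + rnorm(100, 0, 0.4))
    niches <- lapply(1:100, function(i) list(
      species = paste0("S", i), status = "migrant", hull = square(),
      area = area[i], centroid = c(0.5, 0.5), n_individuals = n_ind[i]))
    class(niches) <- "niche_set"
    ci <- confint(sample_size_regression(niches)$fit)["n_individuals", ]
    ci[1] <= 0.1 && 0.1 <= ci[2]
  }, TRUE)
  expect_gte(sum(cover), 90)
})

test_that("collinear predictors are flagged by unbounded VIF", {
  # status perfectly determined by sample size -> interaction model aliased
  niches <- lapply(1:10, function(i) list(
    species = paste0("S", i),
    status = if (i <= 5) "migrant" else "breeding",
    hull = square(), area = exp(0.1 * i + c(0.01, -0.01)[i %% 2 + 1]),
    centroid = c(0.5, 0.5),
    n_individuals = as.integer(c(4, 5, 6, 7, 8, 40, 41, 42, 43, 44)[i])))
  class(niches) <- "niche_set"
  r <- sample_size_regression(niches)
  expect_true(any(r$vif > 10))
})
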