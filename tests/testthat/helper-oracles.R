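# Independent oracles used to cross-check the package's geometry and
# distance code. Deliberately naive implementations: gift-wrapping for
# hulls, crossing-number point-in-polygon for Monte-Carlo areas, recursive
# path enumeration for patristic distances.

# Jarvis-march (gift wrapping) convex hull; returns vertex matrix
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == 1) setdiff(seq_len(n), cur) else seq_len(n)[-cur]
    nxt <- cand[1]
    for (k in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_k > d_nxt)) nxt <- k
    }
    cur <- nxt
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# crossing-number point-in-polygon (boundary treated as inside-ish; fine
# for Monte-Carlo where the boundary has measure zero)
oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yn[i] > py))
    xi <- x[i] + (py - y[i]) * (xn[i] - x[i]) / (yn[i] - y[i])
    inside <- xor(inside, crosses & (px < xi))
  }
  inside
}

# Monte-Carlo area of a region defined by membership over a bounding box;
# returns estimate and its binomial standard error
mc_area <- function(member, bbox, n = 1e5) {
  px <- stats::runif(n, bbox[1], bbox[2])
  py <- stats::runif(n, bbox[3], bbox[4])
  inb <- member(px, py)
  a_box <- (bbox[2] - bbox[1]) * (bbox[4] - bbox[3])
  p <- mean(inb)
  list(estimate = p * a_box, se = sqrt(p * (1 - p) / n) * a_box)
}

# random convex polygon: hull of k points in a box
random_convex <- function(k = 10, xlim = c(0, 1), ylim = c(0, 1)) {
  warblerspace::convex_hull(cbind(stats::runif(k, xlim[1], xlim[2]),
                                  stats::runif(k, ylim[1], ylim[2])))
}

# patristic distances by explicit root-to-tip path enumeration
oracle_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  parent <- integer(max(tree$edge)); blen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(tip) {
    nodes <- tip
    while (parent[nodes[length(nodes)]] != 0)
      nodes <- c(nodes, parent[nodes[length(nodes)]])
    nodes
  }
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    pi <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi, pj)
    d <- sum(blen[setdiff(pi, shared)]) + sum(blen[setdiff(pj, shared)])
    D[i, j] <- D[j, i] <- d
  }
  D
}

# small synthetic community shared across tests: 8 species, 2 statuses
small_profiles <- function(n_species = 8, n_ind = 6, songs = 4) {
  lapply(seq_len(n_species), function(i) {
    u <- (i - 1) / (n_species - 1)
    peak <- 4000 + 3000 * u
    minf <- peak - 900; maxf <- peak + 900
    species_profile(
      code = sprintf("SP%02d", i),
      status = if (i %% 2 == 0) "migrant" else "breeding",
      trait_mean = c(1.5 + u, 8 + round(6 * u), peak, minf, maxf, maxf - minf),
      trait_sd_between = c(0.3, 2, 300, 300, 300, 380),
      trait_sd_within = c(0.1, 1, 100, 100, 100, 130),
      n_individuals = n_ind, songs_per_individual = songs,
      arrival_day = 100 + 4 * i, departure_day = if (i %% 2 == 0) 120 + 4 * i else 170,
      peak_detectability = 0.5)
  })
}

small_niches <- function(seed = 5) {
  profs <- small_profiles()
  songs <- simulate_traits(profs, seed)
  space <- build_signal_space(per_male_means(songs))
  list(profiles = profs, space = space, niches = build_niches(space))
}

# square polygon helper (CCW)
square <- function(x0 = 0, y0 = 0, w = 1, h = w)
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
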