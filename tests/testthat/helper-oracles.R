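# Independent oracles and instance generators shared across test files.

# Second, independent haversine implementation (atan2 formulation) for
# cross-checking distance_km.
haversine_ref <- function(lat1, lon1, lat2, lon2, r = 6371.0) {
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * r * atan2(sqrt(a), sqrt(1 - a))
}

# Compact facility-row builder for hand-made geometries.
fac_df <- function(id, lat, lon, kind = "clinic", daily_tests = 20,
                   existing = FALSE, candidate = FALSE) {
  data.frame(id = id, name = id, lat = lat, lon = lon, kind = kind,
             daily_tests = daily_tests, is_existing_lab = existing,
             is_candidate_lab = candidate, stringsAsFactors = FALSE)
}

# Exhaustive minimum set cover over all 2^m candidate subsets.
# covered: clusters x candidates logical matrix. Structurally uncoverable
# clusters are excluded (they become POC, not part of the cover).
brute_min_cover <- function(covered) {
  coverable <- rowSums(covered) > 0
  need <- covered[coverable, , drop = FALSE]
  if (nrow(need) == 0L) return(0L)
  m <- ncol(covered)
  stopifnot(nrow(need) <= 30L, m <= 16L)
  cand_mask <- vapply(seq_len(m), function(j) {
    Reduce(bitwOr, as.integer(2^(which(need[, j]) - 1L)), 0L)
  }, integer(1))
  full <- Reduce(bitwOr, as.integer(2^(seq_len(nrow(need)) - 1L)), 0L)
  best <- m
  for (mask in 0:(2^m - 1L)) {
    S <- which(bitwAnd(mask, as.integer(2^(0:(m - 1L)))) > 0L)
    if (length(S) >= best) next
    u <- Reduce(bitwOr, cand_mask[S], 0L)
    if (u == full) best <- length(S)
  }
  best
}

# Random coverage instance: clusters and candidate laboratories scattered
# over a ~300 km box, travel time proportional to distance, threshold
# drawn from the time distribution so instances mix easy and tight cases.
random_instance <- function(seed, max_candidates = 12L) {
  set.seed(seed)
  n_cl <- sample(4:20, 1)
  m <- sample(3:max_candidates, 1)
  lat0 <- -31
  cl_lat <- lat0 + runif(n_cl, 0, 3)
  cl_lon <- 23 + runif(n_cl, 0, 3)
  ca_lat <- lat0 + runif(m, 0, 3)
  ca_lon <- 23 + runif(m, 0, 3)
  d <- outer(seq_len(n_cl), seq_len(m), function(i, j) {
    raclnet::distance_km(cl_lat[i], cl_lon[i], ca_lat[j], ca_lon[j])
  })
  rownames(d) <- paste0("C", sprintf("%02d", seq_len(n_cl)))
  colnames(d) <- paste0("L", sprintf("%02d", seq_len(m)))
  tm <- 0.012 * d
  T <- unname(stats::quantile(tm, runif(1, 0.2, 0.8)))
  demands <- stats::setNames(round(runif(n_cl, 5, 150)), rownames(d))
  list(dist = d, time = tm, T = max(T, 0.05), demands = demands)
}

solve_instance <- function(inst, solver = "exact", capacity = Inf) {
  cfg <- raclnet::scenario_config(T = inst$T, capacity_per_lab = capacity,
                                  solver = solver)
  cov <- raclnet::build_coverage_sets(inst$time, inst$T, inst$demands)
  if (solver == "exact") {
    raclnet::solve_exact(cov, inst$demands, cfg, inst$time, inst$dist)
  } else {
    raclnet::solve_greedy(cov, inst$demands, cfg, inst$time, inst$dist)
  }
}

# shared invariant checks on an allocation
expect_valid_allocation <- function(alloc, inst) {
  all_clusters <- rownames(inst$time)
  assigned <- names(alloc$assignment)
  expect_setequal(c(assigned, alloc$poc_cluster_ids), all_clusters)
  expect_length(intersect(assigned, alloc$poc_cluster_ids), 0)
  for (cl in assigned) {
    expect_lte(inst$time[cl, alloc$assignment[[cl]]], inst$T)
  }
  expect_true(all(alloc$lab_volumes >= 0))
}
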