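test_that("haversine distance matches closed form and an independent implementation", {
  expect_equal(distance_km(12.3, 45.6, 12.3, 45.6), 0)
  # one degree of longitude along the equator on a 6371-km sphere
  expect_equal(distance_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-12)
  expect_equal(round(distance_km(0, 0, 0, 1), 2), 111.19)

  expect_equal(distance_km(-30, 25, -30, 25.05),
               haversine_ref(-30, 25, -30, 25.05), tolerance = 1e-9)
  set.seed(42)
  for (i in 1:50) {
    a <- c(runif(1, -60, 60), runif(1, -170, 170))
    b <- c(runif(1, -60, 60), runif(1, -170, 170))
    expect_equal(distance_km(a[1], a[2], b[1], b[2]),
                 haversine_ref(a[1], a[2], b[1], b[2]), tolerance = 1e-9)
  }
})

test_that("haversine distance agrees with geosphere on a 6371-km sphere", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  for (i in 1:20) {
    a <- c(runif(1, -60, 60), runif(1, -170, 170))
    b <- c(runif(1, -60, 60), runif(1, -170, 170))
    ref <- geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                                    r = 6371000) / 1000
    expect_equal(distance_km(a[1], a[2], b[1], b[2]), ref,
                 tolerance = 1e-9)
  }
})

test_that("distance satisfies the triangle inequality on random triples", {
  set.seed(11)
  for (i in 1:100) {
    p <- matrix(c(runif(3, -60, 60), runif(3, -170, 170)), ncol = 2)
    ab <- distance_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    bc <- distance_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    ac <- distance_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("coordinate and flag validation names the offending facility", {
  f <- fixture_presets("three_towns")$facilities
  bad <- f
  bad$lat[2] <- 123
  expect_error(validate_facilities(bad), "C02")
  dup <- rbind(f, f[1, ])
  expect_error(validate_facilities(dup), "duplicate")
  flag <- f
  flag$is_existing_lab[2] <- TRUE   # existing but not candidate
  expect_error(validate_facilities(flag), "C02")
  expect_error(distance_km(95, 0, 0, 0), "out-of-range")
})

test_that("greedy leader clustering joins within radius and splits beyond it", {
  one <- fac_df("A1", -30, 25, daily_tests = 17)
  cl <- cluster_facilities(one, 5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$demand, 17)
  expect_equal(cl$seed_id, "A1")

  # two facilities separated along a meridian: 4 km joins, 6 km splits
  lat4 <- -30 + 4 / (6371 * pi / 180)
  lat6 <- -30 + 6 / (6371 * pi / 180)
  near <- rbind(fac_df("A1", -30, 25), fac_df("A2", lat4, 25))
  far <- rbind(fac_df("A1", -30, 25), fac_df("A2", lat6, 25))
  expect_equal(nrow(cluster_facilities(near, 5)), 1)
  expect_equal(nrow(cluster_facilities(far, 5)), 2)
})

test_that("co-located town facilities collapse into one cluster", {
  p <- fixture_presets("colesberg_like")
  cl <- cluster_facilities(p$facilities, 5)
  town <- cl[vapply(cl$member_ids, function(m) "K01" %in% m, logical(1)), ]
  expect_setequal(town$member_ids[[1]], c("K01", "K02", "K03", "K04"))
})

test_that("clustering partitions facilities and conserves demand", {
  for (seed in c(3, 9)) {
    net <- generate_network(network_spec(n_facilities = 150, n_towns = 8,
                                         seed = seed))
    cl <- cluster_facilities(net, 5)
    members <- unlist(cl$member_ids)
    expect_setequal(members, net$id)
    expect_equal(length(members), nrow(net))     # no doubles
    expect_equal(sum(cl$demand), sum(net$daily_tests))
    # every member within radius of its cluster leader
    for (i in seq_len(nrow(cl))) {
      rows <- match(cl$member_ids[[i]], net$id)
      d <- distance_km(cl$lat[i], cl$lon[i], net$lat[rows], net$lon[rows])
      expect_true(all(d <= 5 + 1e-9))
    }
  }
})

test_that("re-clustering mutually distant leaders yields singletons", {
  net <- generate_network(network_spec(n_facilities = 120, n_towns = 6,
                                       seed = 4))
  cl <- cluster_facilities(net, 5)
  leaders <- net[match(cl$seed_id, net$id), ]
  # keep only leaders pairwise > 5 km apart, then re-cluster them
  keep <- rep(TRUE, nrow(leaders))
  for (i in seq_len(nrow(leaders))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(leaders))) {
      if (j > i && keep[j] &&
          distance_km(leaders$lat[i], leaders$lon[i],
                      leaders$lat[j], leaders$lon[j]) <= 5) keep[j] <- FALSE
    }
  }
  sub <- leaders[keep, , drop = FALSE]
  re <- cluster_facilities(sub, 5)
  expect_equal(nrow(re), nrow(sub))
  expect_true(all(re$n_members == 1))
})

test_that("distance matrix equals element-wise recomputation", {
  p <- fixture_presets("three_towns")
  cl <- cluster_facilities(p$facilities, 5)
  cand <- p$facilities[p$facilities$is_candidate_lab, ]
  d <- build_distance_matrix(cl, cand)
  expect_equal(dim(d), c(nrow(cl), nrow(cand)))
  for (i in seq_len(nrow(cl))) {
    for (j in seq_len(nrow(cand))) {
      expect_equal(d[i, j], distance_km(cl$lat[i], cl$lon[i],
                                        cand$lat[j], cand$lon[j]))
    }
  }
  # single cluster, single candidate, co-located
  solo <- fac_df("Z1", -29, 24, candidate = TRUE)
  cl1 <- cluster_facilities(solo, 5)
  d1 <- build_distance_matrix(cl1, solo)
  expect_equal(dim(d1), c(1, 1))
  expect_equal(d1[1, 1], 0)
  expect_error(build_distance_matrix(cl1, solo[0, ]),
               "no candidate laboratories")
})
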