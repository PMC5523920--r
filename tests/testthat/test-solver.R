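test_that("coverage sets are an element-wise threshold scan", {
  tm <- matrix(c(0.5, 1.5, 2.5, 3.5,
                 3.0, 1.0, 0.5, 5.0), nrow = 4,
               dimnames = list(paste0("C", 1:4), c("L1", "L2")))
  cov <- build_coverage_sets(tm, T = 2)
  for (i in 1:4) {
    for (j in 1:2) {
      expect_equal(unname(cov$covered[i, j]), tm[i, j] <= 2)
    }
  }
  expect_setequal(cov$sets$L1, c("C1", "C2"))
  expect_setequal(cov$sets$L2, c("C2", "C3"))
  expect_equal(cov$uncoverable, "C4")

  # T above every entry covers everything; T = 0 with positive times
  # covers nothing
  cov_all <- build_coverage_sets(tm, T = 10)
  expect_true(all(cov_all$covered))
  expect_length(cov_all$uncoverable, 0)
  cov_none <- build_coverage_sets(tm, T = 0)
  expect_setequal(cov_none$uncoverable, rownames(tm))

  dem <- setNames(c(10, 20, 30, 40), rownames(tm))
  cov_d <- build_coverage_sets(tm, T = 2, dem)
  expect_equal(unname(cov_d$coverable_demand["L1"]), 30)
  expect_equal(unname(cov_d$coverable_demand["L2"]), 50)
})

test_that("exact solver handles degenerate single-site and all-POC cases", {
  cfg <- scenario_config(T = 1)
  tm1 <- matrix(0, 1, 1, dimnames = list("C1", "L1"))
  dem <- c(C1 = 50)
  a1 <- solve_exact(build_coverage_sets(tm1, 1, dem), dem, cfg, tm1)
  expect_equal(a1$objective, 1)
  expect_equal(a1$selected_lab_ids, "L1")
  expect_length(a1$poc_cluster_ids, 0)

  tm2 <- matrix(c(5, 6, 7, 8), 2, 2,
                dimnames = list(c("C1", "C2"), c("L1", "L2")))
  dem2 <- c(C1 = 10, C2 = 20)
  a2 <- solve_exact(build_coverage_sets(tm2, 1, dem2), dem2, cfg, tm2)
  expect_equal(a2$objective, 0)
  expect_setequal(a2$poc_cluster_ids, c("C1", "C2"))
})

test_that("exact objective equals the exhaustive-enumeration minimum", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    alloc <- solve_instance(inst, "exact")
    oracle <- brute_min_cover(inst$time <= inst$T)
    expect_equal(alloc$objective, oracle, info = paste("seed", seed))
    expect_valid_allocation(alloc, inst)
  }
})

test_that("count-ties are broken by minimum total assigned distance", {
  # both labs alone cover both clusters; L2 is nearer in total
  tm <- matrix(c(1.0, 1.0, 0.4, 0.6), 2, 2,
               dimnames = list(c("C1", "C2"), c("L1", "L2")))
  dm <- tm * 100
  dem <- c(C1 = 10, C2 = 10)
  cfg <- scenario_config(T = 1.5)
  a <- solve_exact(build_coverage_sets(tm, 1.5, dem), dem, cfg, tm, dm)
  expect_equal(a$objective, 1)
  expect_equal(a$selected_lab_ids, "L2")
})

test_that("greedy never beats exact and stays within the ln-n bound", {
  for (seed in 101:140) {
    inst <- random_instance(seed)
    ex <- solve_instance(inst, "exact")
    gr <- solve_instance(inst, "greedy")
    expect_gte(gr$objective, ex$objective)
    n_coverable <- sum(rowSums(inst$time <= inst$T) > 0)
    if (ex$objective > 0) {
      expect_lte(gr$objective, ex$objective * (1 + log(max(1, n_coverable))))
    }
    expect_valid_allocation(gr, inst)
    # determinism
    gr2 <- solve_instance(inst, "greedy")
    expect_identical(gr$selected_lab_ids, gr2$selected_lab_ids)
    expect_identical(gr$assignment, gr2$assignment)
  }
})

test_that("a single candidate covering everything is selected alone by greedy", {
  tm <- matrix(c(0.5, 0.5, 0.5, 2, 9, 2), 3, 2,
               dimnames = list(paste0("C", 1:3), c("L1", "L2")))
  dem <- setNames(c(5, 5, 5), rownames(tm))
  cfg <- scenario_config(T = 1, solver = "greedy")
  a <- solve_greedy(build_coverage_sets(tm, 1, dem), dem, cfg, tm)
  expect_equal(a$selected_lab_ids, "L1")
  expect_equal(a$objective, 1)
})

test_that("finite capacity is respected and infeasibility is reported", {
  tm <- matrix(c(0.1, 0.2, 0.3), 3, 1, dimnames = list(paste0("C", 1:3), "L1"))
  dem <- setNames(c(60, 60, 60), rownames(tm))
  cfg <- scenario_config(T = 1, capacity_per_lab = 130)
  cov <- build_coverage_sets(tm, 1, dem)
  expect_error(solve_exact(cov, dem, cfg, tm), "infeasible under capacity")

  # two labs, capacity forces a split
  tm2 <- cbind(tm, L2 = c(0.2, 0.1, 0.4))
  cov2 <- build_coverage_sets(tm2, 1, dem)
  a <- solve_exact(cov2, dem, cfg, tm2)
  expect_equal(a$objective, 2)
  expect_true(all(a$lab_volumes <= 130))
  expect_length(a$poc_cluster_ids, 0)
})

test_that("laboratory and POC counts are monotone in the travel-time threshold", {
  for (seed in c(201, 202, 203)) {
    inst <- random_instance(seed)
    # nested thresholds with every cluster coverable at the tightest one:
    # the feasible cover sets nest, so the optimal count cannot rise with T
    T_min <- max(apply(inst$time, 1, min))
    objs <- vapply(T_min * c(1, 1.3, 1.6), function(T) {
      i2 <- inst
      i2$T <- T
      solve_instance(i2, "exact")$objective
    }, numeric(1))
    expect_true(all(diff(objs) <= 0))

    # POC count never rises as T grows, whatever the coverage structure
    pocs <- vapply(quantile(inst$time, c(0.2, 0.5, 0.8)), function(T) {
      i2 <- inst
      i2$T <- unname(T)
      length(solve_instance(i2, "exact")$poc_cluster_ids)
    }, numeric(1))
    expect_true(all(diff(pocs) <= 0))
  }
})

test_that("full scenario pipeline solves the three-town fixture optimally", {
  p <- fixture_presets("three_towns")
  cfg <- scenario_config(T = 4, solver = "exact")
  s <- solve_scenario(p$facilities, p$drive_times, cfg)
  expect_s3_class(s, "racl_scenario")
  a <- s$allocation
  expect_gte(a$objective, 1)
  expect_lte(a$objective, 3)
  expect_length(a$poc_cluster_ids, 0)
  oracle <- brute_min_cover(s$time_matrix <= 4)
  expect_equal(a$objective, oracle)
  # manifest carries the recovered (noiseless) truth model
  expect_equal(s$manifest$model$beta1, p$truth[2], tolerance = 1e-8)
  expect_equal(s$manifest$counts$n_labs, a$objective)

  # shrinking T below the inter-town time raises POC count, and the lab
  # count never drops
  cfg_tight <- scenario_config(T = 0.1, solver = "exact")
  s_tight <- solve_scenario(p$facilities, p$drive_times, cfg_tight)
  expect_gte(length(s_tight$allocation$poc_cluster_ids),
             length(a$poc_cluster_ids))
  expect_gte(s_tight$allocation$objective + length(s_tight$allocation$poc_cluster_ids),
             a$objective)
})

test_that("an empty facility table is rejected", {
  p <- fixture_presets("three_towns")
  expect_error(solve_scenario(p$facilities[0, ], p$drive_times,
                              scenario_config(T = 2)),
               "no facilities")
})
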