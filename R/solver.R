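# Capacitated set-covering location-allocation: choose the fewest
# laboratories so that every facility cluster is reachable within the
# travel-time threshold T; clusters no laboratory can reach become
# point-of-care (POC) sites.

#' Scenario configuration
#'
#' @param T travel-time threshold in hours (> 0). The study scenarios are
#'   A: 4 h, B: 3 h, C: 2 h.
#' @param cluster_radius_km facility clustering radius (km).
#' @param capacity_per_lab daily test capacity per laboratory; `Inf`
#'   (default) disables the capacity constraint so platforms scale to
#'   demand, matching worked volumes far above any single current site's
#'   throughput.
#' @param solver `"exact"` (branch-and-bound, optimal) or `"greedy"`
#'   (scalable heuristic).
#' @param seed integer seed recorded in the run manifest.
#' @param exact_limit maximum number of candidates the exact solver will
#'   accept.
#' @return list of class `racl_config`.
#' @export
scenario_config <- function(T, cluster_radius_km = 5,
                            capacity_per_lab = Inf,
                            solver = c("exact", "greedy"),
                            seed = 1L, exact_limit = 20L) {
  solver <- match.arg(solver)
  stopifnot(T > 0, cluster_radius_km > 0, capacity_per_lab > 0)
  structure(list(T = T, cluster_radius_km = cluster_radius_km,
                 capacity_per_lab = capacity_per_lab, solver = solver,
                 seed = as.integer(seed), exact_limit = as.integer(exact_limit)),
            class = "racl_config")
}

#' Build coverage sets for a travel-time threshold
#'
#' A candidate laboratory covers a cluster when the predicted travel time
#' does not exceed `T`. Clusters covered by no candidate are structurally
#' uncoverable and can only be served as POC sites.
#'
#' @param time_matrix travel-time matrix (hours), clusters x candidates.
#' @param T threshold (hours).
#' @param demands optional named vector of cluster demands (tests/day) used
#'   to fill in each candidate's coverable demand.
#' @return object of class `racl_coverage`: the logical coverage matrix,
#'   per-candidate cluster sets, coverable demand, and the uncoverable
#'   cluster ids.
#' @export
build_coverage_sets <- function(time_matrix, T, demands = NULL) {
  stopifnot(T >= 0)
  covered <- time_matrix <= T
  cluster_ids <- rownames(time_matrix)
  candidate_ids <- colnames(time_matrix)
  sets <- lapply(seq_along(candidate_ids),
                 function(j) cluster_ids[covered[, j]])
  names(sets) <- candidate_ids
  coverable_demand <- if (is.null(demands)) {
    vapply(sets, function(s) NA_real_, numeric(1))
  } else {
    vapply(sets, function(s) sum(demands[s]), numeric(1))
  }
  uncoverable <- cluster_ids[rowSums(covered) == 0L]
  structure(list(covered = covered, sets = sets,
                 cluster_ids = cluster_ids, candidate_ids = candidate_ids,
                 coverable_demand = coverable_demand,
                 uncoverable = uncoverable, T = T),
            class = "racl_coverage")
}

# Deterministic allocation of covered clusters to selected laboratories:
# clusters in demand-descending order (id ascending on ties), each to its
# nearest selected laboratory (by time, id ascending on ties) with spare
# capacity. Returns NA assignments where no selected lab can take the
# cluster.
assign_clusters <- function(selected, coverage, time_matrix, demands,
                            capacity) {
  cluster_ids <- coverage$cluster_ids
  coverable <- setdiff(cluster_ids, coverage$uncoverable)
  ord <- coverable[order(-demands[coverable], coverable)]
  remaining <- stats::setNames(rep(capacity, length(selected)), selected)
  assignment <- stats::setNames(rep(NA_character_, length(ord)), ord)
  for (cl in ord) {
    labs <- selected[coverage$covered[cl, selected]]
    if (length(labs) == 0L) next
    labs <- labs[order(time_matrix[cl, labs], labs)]
    ok <- labs[remaining[labs] >= demands[cl]]
    if (length(ok) == 0L) next
    assignment[cl] <- ok[1L]
    remaining[ok[1L]] <- remaining[ok[1L]] - demands[cl]
  }
  assignment
}

# Greedy lower bound on the number of laboratories: size of a set of
# pairwise-incompatible clusters (no candidate covers any two of them),
# each of which needs its own laboratory.
clique_lower_bound <- function(coverage) {
  coverable <- setdiff(coverage$cluster_ids, coverage$uncoverable)
  if (length(coverable) == 0L) return(0L)
  cov <- coverage$covered[coverable, , drop = FALSE]
  chosen <- character(0)
  # visit rarest-covered clusters first; they conflict with most others
  for (cl in coverable[order(rowSums(cov))]) {
    compatible <- any(vapply(chosen, function(o) {
      any(cov[cl, ] & cov[o, ])
    }, logical(1)))
    if (!compatible) chosen <- c(chosen, cl)
  }
  length(chosen)
}

finish_allocation <- function(selected, coverage, time_matrix, dist_matrix,
                              demands, capacity, extra_poc = character(0)) {
  assignment <- assign_clusters(selected, coverage, time_matrix, demands,
                                capacity)
  assigned <- assignment[!is.na(assignment)]
  poc <- sort(unique(c(coverage$uncoverable, extra_poc,
                       names(assignment)[is.na(assignment)])))
  lab_volumes <- stats::setNames(rep(0, length(selected)), selected)
  for (cl in names(assigned)) {
    lab_volumes[assigned[cl]] <- lab_volumes[assigned[cl]] + demands[cl]
  }
  tab <- data.frame(
    cluster_id = coverage$cluster_ids,
    mode = ifelse(coverage$cluster_ids %in% poc, "poc", "lab"),
    assigned_lab_id = NA_character_,
    distance_km = NA_real_,
    time_h = NA_real_,
    stringsAsFactors = FALSE
  )
  for (cl in names(assigned)) {
    i <- match(cl, tab$cluster_id)
    tab$assigned_lab_id[i] <- assigned[cl]
    tab$time_h[i] <- time_matrix[cl, assigned[cl]]
    if (!is.null(dist_matrix)) tab$distance_km[i] <- dist_matrix[cl, assigned[cl]]
  }
  structure(list(selected_lab_ids = selected,
                 assignment = assigned,
                 poc_cluster_ids = poc,
                 objective = length(selected),
                 lab_volumes = lab_volumes,
                 assignment_table = tab,
                 T = coverage$T),
            class = "racl_allocation")
}

#' @export
print.racl_allocation <- function(x, ...) {
  cat(sprintf("RACL allocation (T = %g h): %d laboratories, %d POC clusters, %d assigned clusters\n",
              x$T, x$objective, length(x$poc_cluster_ids), length(x$assignment)))
  invisible(x)
}

#' Exact solver: minimum-cardinality laboratory set
#'
#' Branch-and-bound over candidate subsets by increasing cardinality,
#' starting at a lower bound given by pairwise-incompatible clusters. A
#' subset is feasible when every coverable cluster can be assigned within
#' `T` (and, if capacity is finite, without exceeding it under the
#' deterministic demand-descending / nearest-laboratory assignment rule).
#' Among minimum-cardinality solutions the one with the smallest total
#' assigned distance (time if no distance matrix is supplied) is returned.
#' Structurally uncoverable clusters become POC sites.
#'
#' @param coverage `racl_coverage` object.
#' @param demands named numeric vector of cluster demands (tests/day).
#' @param config `racl_config`.
#' @param time_matrix travel-time matrix used for assignment.
#' @param dist_matrix optional distance matrix (km) for the tie-break
#'   objective and report columns.
#' @return `racl_allocation`.
#' @export
solve_exact <- function(coverage, demands, config, time_matrix,
                        dist_matrix = NULL) {
  candidates <- coverage$candidate_ids
  m <- length(candidates)
  if (m > config$exact_limit) {
    stop("exact solver limited to ", config$exact_limit,
         " candidates (got ", m, "); use the greedy solver", call. = FALSE)
  }
  coverable <- setdiff(coverage$cluster_ids, coverage$uncoverable)
  if (length(coverable) == 0L) {
    return(finish_allocation(character(0), coverage, time_matrix,
                             dist_matrix, demands, config$capacity_per_lab))
  }
  cov <- coverage$covered[coverable, , drop = FALSE]
  # candidates covering nothing can never help
  useful <- candidates[colSums(cov) > 0L]
  cost_matrix <- if (is.null(dist_matrix)) time_matrix else dist_matrix

  feasible_cost <- function(selected) {
    hit <- rowSums(cov[, selected, drop = FALSE]) > 0L
    if (!all(hit)) return(NA_real_)
    assignment <- assign_clusters(selected, coverage, time_matrix, demands,
                                  config$capacity_per_lab)
    if (anyNA(assignment)) return(NA_real_)
    sum(cost_matrix[cbind(names(assignment), unname(assignment))])
  }

  lb <- max(1L, clique_lower_bound(coverage))
  for (k in seq(lb, length(useful))) {
    combos <- utils::combn(useful, k)
    best_cost <- Inf
    best <- NULL
    for (s in seq_len(ncol(combos))) {
      cost <- feasible_cost(combos[, s])
      if (!is.na(cost) && cost < best_cost) {
        best_cost <- cost
        best <- combos[, s]
      }
    }
    if (!is.null(best)) {
      return(finish_allocation(best, coverage, time_matrix, dist_matrix,
                               demands, config$capacity_per_lab))
    }
  }
  # even the full candidate set cannot serve every coverable cluster
  assignment <- assign_clusters(useful, coverage, time_matrix, demands,
                                config$capacity_per_lab)
  binding <- names(assignment)[is.na(assignment)]
  stop("infeasible under capacity ", config$capacity_per_lab,
       " tests/day; unassignable cluster(s): ",
       paste(binding, collapse = ", "), call. = FALSE)
}

#' Greedy solver: largest-uncovered-demand heuristic
#'
#' Repeatedly selects the candidate covering the most currently-uncovered
#' demand (ties: most uncovered clusters, then smallest candidate id) until
#' every coverable cluster is covered, then runs the same deterministic
#' assignment rule as the exact solver. Clusters left unassigned (no
#' covering candidate, or capacity exhausted) become POC sites. The
#' classical set-cover guarantee applies: at most (1 + ln n) times the
#' optimal count on uncapacitated instances.
#'
#' @inheritParams solve_exact
#' @return `racl_allocation`.
#' @export
solve_greedy <- function(coverage, demands, config, time_matrix,
                         dist_matrix = NULL) {
  candidates <- coverage$candidate_ids
  coverable <- setdiff(coverage$cluster_ids, coverage$uncoverable)
  uncovered <- coverable
  selected <- character(0)
  while (length(uncovered) > 0L && length(candidates) > 0L) {
    gain_demand <- vapply(candidates, function(cand) {
      sum(demands[uncovered[coverage$covered[uncovered, cand]]])
    }, numeric(1))
    gain_count <- vapply(candidates, function(cand) {
      sum(coverage$covered[uncovered, cand])
    }, numeric(1))
    if (max(gain_count) == 0L) break
    ord <- order(-gain_demand, -gain_count, candidates)
    pick <- candidates[ord[1L]]
    selected <- c(selected, pick)
    uncovered <- uncovered[!coverage$covered[uncovered, pick]]
    candidates <- setdiff(candidates, pick)
  }
  finish_allocation(sort(selected), coverage, time_matrix, dist_matrix,
                    demands, config$capacity_per_lab)
}

#' Run a full scenario from facility and drive-time tables
#'
#' Composes the pipeline: cluster facilities, build the cluster-to-candidate
#' distance matrix, fit the drive-time model on the supplied sample, convert
#' distances to travel times, build coverage sets and solve. The returned
#' manifest records the configuration, seed, model coefficients and counts
#' so a run can be reproduced from its outputs.
#'
#' @param facilities facility data.frame (see [validate_facilities()]).
#' @param drive_samples data.frame with `distance_km` and `drive_time_h`
#'   columns — the drive-time calibration sample.
#' @param config `racl_config` from [scenario_config()].
#' @return list of class `racl_scenario`: `allocation`, `clusters`,
#'   `model`, `time_matrix`, `dist_matrix`, `manifest`.
#' @export
solve_scenario <- function(facilities, drive_samples, config) {
  stopifnot(inherits(config, "racl_config"))
  facilities <- validate_facilities(facilities)
  clusters <- cluster_facilities(facilities, config$cluster_radius_km)
  candidates <- facilities[facilities$is_candidate_lab, , drop = FALSE]
  dist_matrix <- build_distance_matrix(clusters, candidates)
  model <- fit_time_model(drive_samples)
  time_matrix <- predict_time_matrix(dist_matrix, model)
  demands <- stats::setNames(clusters$demand, clusters$cluster_id)
  coverage <- build_coverage_sets(time_matrix, config$T, demands)
  allocation <- if (config$solver == "exact") {
    solve_exact(coverage, demands, config, time_matrix, dist_matrix)
  } else {
    solve_greedy(coverage, demands, config, time_matrix, dist_matrix)
  }
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    model = list(beta0 = model$beta0, beta1 = model$beta1,
                 n = model$n, r2 = model$r2),
    counts = list(n_facilities = nrow(facilities),
                  n_clusters = nrow(clusters),
                  n_candidates = nrow(candidates),
                  n_labs = allocation$objective,
                  n_poc = length(allocation$poc_cluster_ids))
  )
  structure(list(allocation = allocation, clusters = clusters,
                 model = model, time_matrix = time_matrix,
                 dist_matrix = dist_matrix, manifest = manifest),
            class = "racl_scenario")
}

#' Write allocation outputs
#'
#' Writes `allocation.csv` (cluster_id, mode, assigned_lab_id, distance_km,
#' time_h) and `manifest.json` into `dir`.
#'
#' @param scenario `racl_scenario` from [solve_scenario()].
#' @param dir output directory (created if needed).
#' @export
write_allocation <- function(scenario, dir) {
  stopifnot(inherits(scenario, "racl_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(scenario$allocation$assignment_table,
                   file.path(dir, "allocation.csv"), row.names = FALSE)
  jsonlite::write_json(scenario$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
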