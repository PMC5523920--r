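# Facility tables, radius clustering and the cluster-to-candidate
# distance matrix.

FACILITY_KINDS <- c("clinic", "community_health_centre", "hospital")

#' Validate a facility table
#'
#' Checks the column set, coordinate ranges, demand non-negativity and the
#' rule that an existing laboratory must also be a candidate laboratory.
#' Errors name the offending facility ids so bad rows can be traced back to
#' the source file.
#'
#' @param facilities data.frame with columns `id`, `name`, `lat`, `lon`,
#'   `kind`, `daily_tests`, `is_existing_lab`, `is_candidate_lab`.
#' @return The validated data.frame, with `kind` as character and the two
#'   flag columns coerced to logical.
#' @export
validate_facilities <- function(facilities) {
  required <- c("id", "name", "lat", "lon", "kind", "daily_tests",
                "is_existing_lab", "is_candidate_lab")
  missing_cols <- setdiff(required, names(facilities))
  if (length(missing_cols) > 0L) {
    stop("facility table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(facilities) == 0L) stop("no facilities", call. = FALSE)
  facilities$id <- as.character(facilities$id)
  facilities$kind <- as.character(facilities$kind)
  facilities$is_existing_lab <- as.logical(facilities$is_existing_lab)
  facilities$is_candidate_lab <- as.logical(facilities$is_candidate_lab)

  dup <- facilities$id[duplicated(facilities$id)]
  if (length(dup) > 0L) {
    stop("duplicate facility ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_lat <- facilities$id[is.na(facilities$lat) |
                             facilities$lat < -90 | facilities$lat > 90]
  bad_lon <- facilities$id[is.na(facilities$lon) |
                             facilities$lon < -180 | facilities$lon > 180]
  if (length(bad_lat) > 0L || length(bad_lon) > 0L) {
    stop("out-of-range coordinates for facility id(s): ",
         paste(unique(c(bad_lat, bad_lon)), collapse = ", "), call. = FALSE)
  }
  bad_kind <- facilities$id[!facilities$kind %in% FACILITY_KINDS]
  if (length(bad_kind) > 0L) {
    stop("unknown facility kind for id(s): ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  bad_vol <- facilities$id[is.na(facilities$daily_tests) |
                             facilities$daily_tests < 0]
  if (length(bad_vol) > 0L) {
    stop("negative or missing daily_tests for id(s): ",
         paste(bad_vol, collapse = ", "), call. = FALSE)
  }
  bad_flag <- facilities$id[facilities$is_existing_lab &
                              !facilities$is_candidate_lab]
  if (length(bad_flag) > 0L) {
    stop("existing laboratories must be candidate laboratories; id(s): ",
         paste(bad_flag, collapse = ", "), call. = FALSE)
  }
  facilities
}

#' Read a facility CSV
#'
#' Expected columns: `id,name,lat,lon,kind,daily_tests,is_existing_lab,
#' is_candidate_lab` (header required, UTF-8, flags as 0/1).
#'
#' @param path path to the CSV file.
#' @return validated facility data.frame.
#' @export
read_facilities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"),
                        encoding = "UTF-8")
  validate_facilities(df)
}

#' Great-circle distance between two points, in kilometres
#'
#' Haversine formula on a sphere of radius 6371.0 km. Straight-line
#' geographic distance is the input to the drive-time calibration; planar
#' arithmetic on raw degrees would be meaningless at country scale.
#'
#' @param lat1,lon1 first point, decimal degrees WGS84 (vectorised).
#' @param lat2,lon2 second point, decimal degrees WGS84 (vectorised).
#' @return distance(s) in km.
#' @examples
#' distance_km(0, 0, 0, 1)   # ~111.19 km along the equator
#' @export
distance_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90, abs(lat2) > 90, abs(lon1) > 180, abs(lon2) > 180,
          na.rm = TRUE)) {
    stop("out-of-range coordinates", call. = FALSE)
  }
  r <- 6371.0
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * r * asin(sqrt(a))
}

#' Cluster facilities within a radius (greedy leader clustering)
#'
#' Facilities are visited in ascending id order; each joins the first
#' existing cluster whose leader lies within `radius_km`, otherwise it
#' founds a new cluster with itself as leader. The representative point of
#' a cluster is its leader's coordinates, so every member is within
#' `radius_km` of the representative by construction. Deterministic for a
#' given facility table.
#'
#' @param facilities validated facility data.frame.
#' @param radius_km clustering radius in km (> 0); the leader-to-member
#'   distance bound.
#' @return data.frame with columns `cluster_id`, `seed_id`, `lat`, `lon`,
#'   `n_members`, `demand` and a list column `member_ids`.
#' @export
cluster_facilities <- function(facilities, radius_km = 5) {
  facilities <- validate_facilities(facilities)
  stopifnot(radius_km > 0)
  ord <- order(facilities$id)
  facilities <- facilities[ord, , drop = FALSE]

  n <- nrow(facilities)
  leader_idx <- integer(0)          # row index of each cluster leader
  assignment <- integer(n)          # cluster number per facility
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(leader_idx) > 0L) {
      d <- distance_km(facilities$lat[i], facilities$lon[i],
                       facilities$lat[leader_idx], facilities$lon[leader_idx])
      hit <- which(d <= radius_km)
      if (length(hit) > 0L) {
        assignment[i] <- hit[1L]
        placed <- TRUE
      }
    }
    if (!placed) {
      leader_idx <- c(leader_idx, i)
      assignment[i] <- length(leader_idx)
    }
  }

  members <- split(facilities$id, assignment)
  demand <- vapply(split(facilities$daily_tests, assignment), sum, numeric(1))
  k <- length(leader_idx)
  out <- data.frame(
    cluster_id = paste0("C", formatC(seq_len(k), width = 4, flag = "0")),
    seed_id = facilities$id[leader_idx],
    lat = facilities$lat[leader_idx],
    lon = facilities$lon[leader_idx],
    n_members = as.integer(lengths(members)),
    demand = as.numeric(demand),
    stringsAsFactors = FALSE
  )
  out$member_ids <- unname(members)
  out
}

#' Distance matrix from clusters to candidate laboratories
#'
#' @param clusters cluster table from [cluster_facilities()].
#' @param candidates facility rows with `is_candidate_lab = TRUE`.
#' @return numeric matrix (km); rownames are cluster ids, colnames are
#'   candidate ids, in input order.
#' @export
build_distance_matrix <- function(clusters, candidates) {
  if (nrow(candidates) == 0L) stop("no candidate laboratories", call. = FALSE)
  if (!all(candidates$is_candidate_lab)) {
    stop("all candidates must have is_candidate_lab = TRUE", call. = FALSE)
  }
  d <- outer(seq_len(nrow(clusters)), seq_len(nrow(candidates)),
             function(i, j) distance_km(clusters$lat[i], clusters$lon[i],
                                        candidates$lat[j], candidates$lon[j]))
  dimnames(d) <- list(clusters$cluster_id, candidates$id)
  d
}

#' Write the cluster table as CSV
#'
#' Columns: `cluster_id,seed_id,lat,lon,n_members,demand` (the member list
#' is dropped; it is recoverable from the facility table and the radius).
#'
#' @param clusters cluster table.
#' @param path output path.
#' @export
write_clusters_csv <- function(clusters, path) {
  utils::write.csv(
    clusters[, c("cluster_id", "seed_id", "lat", "lon", "n_members", "demand")],
    path, row.names = FALSE)
  invisible(path)
}
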