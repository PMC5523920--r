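# Seeded synthetic facility networks and drive-time samples so every
# pipeline stage is testable without the (undeposited) national dataset.

#' Specification for a synthetic facility network
#'
#' Defaults emulate the structure of a national CD4 network: ~3200
#' facilities, a candidate-laboratory fraction giving ~62 candidate sites,
#' facility mix dominated by primary-care clinics (67% clinics, 8%
#' community health centres, 25% hospitals), kind-specific Poisson demand
#' (clinic 25, CHC 60, hospital 120 tests/day), and a country-sized
#' bounding box so straight-line distances are realistic for travel-time
#' thresholds of 2-4 hours. The drive-time generating model defaults to
#' 0.2 h fixed delay plus 0.015 h/km (~67 km/h straight-line speed).
#'
#' @param n_facilities number of facilities.
#' @param n_towns number of town centres facilities scatter around.
#' @param town_spread_km Gaussian scatter (sd, km) of facilities around
#'   their town.
#' @param frac_candidates fraction of facilities flagged candidate
#'   laboratories (placed preferentially at hospitals).
#' @param demand_mix named proportions by facility kind (must sum to 1).
#' @param demand_level named mean tests/day by kind (Poisson means).
#' @param road_factor c(intercept h, slope h/km) of the true drive-time
#'   model used by [generate_drive_times()].
#' @param noise_sd drive-time noise sd (hours).
#' @param bbox bounding box c(lat_min, lat_max, lon_min, lon_max).
#' @param seed integer seed.
#' @return list of class `racl_network_spec`.
#' @export
network_spec <- function(n_facilities = 3200, n_towns = 120,
                         town_spread_km = 4,
                         frac_candidates = 62 / 3200,
                         demand_mix = c(clinic = 0.67,
                                        community_health_centre = 0.08,
                                        hospital = 0.25),
                         demand_level = c(clinic = 25,
                                          community_health_centre = 60,
                                          hospital = 120),
                         road_factor = c(0.2, 0.015),
                         noise_sd = 0.05,
                         bbox = c(-35, -22, 16, 33),
                         seed = 1L) {
  stopifnot(abs(sum(demand_mix) - 1) < 1e-9,
            all(demand_level > 0), n_facilities >= 1, n_towns >= 1,
            town_spread_km > 0, frac_candidates > 0, frac_candidates <= 1)
  structure(list(n_facilities = n_facilities, n_towns = n_towns,
                 town_spread_km = town_spread_km,
                 frac_candidates = frac_candidates,
                 demand_mix = demand_mix, demand_level = demand_level,
                 road_factor = road_factor, noise_sd = noise_sd,
                 bbox = bbox, seed = as.integer(seed)),
            class = "racl_network_spec")
}

#' Generate a synthetic facility network
#'
#' Towns are placed uniformly in the bounding box; facilities scatter
#' around a uniformly-chosen town with Gaussian offsets (sd =
#' `town_spread_km`); kinds are drawn from `demand_mix`; daily volumes are
#' Poisson with kind-specific means; candidate laboratories are assigned
#' preferentially to hospitals (then the remaining facilities) and a
#' quarter of candidates are marked as existing laboratories. Output is
#' deterministic per seed.
#'
#' @param spec `racl_network_spec`.
#' @return validated facility data.frame.
#' @export
generate_network <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "racl_network_spec"))
  set.seed(spec$seed)
  n <- spec$n_facilities
  km_per_deg_lat <- 111.19
  mid_lat <- mean(spec$bbox[1:2])
  km_per_deg_lon <- km_per_deg_lat * cos(mid_lat * pi / 180)

  towns_lat <- stats::runif(spec$n_towns, spec$bbox[1], spec$bbox[2])
  towns_lon <- stats::runif(spec$n_towns, spec$bbox[3], spec$bbox[4])
  town_of <- sample.int(spec$n_towns, n, replace = TRUE)
  lat <- towns_lat[town_of] +
    stats::rnorm(n, 0, spec$town_spread_km / km_per_deg_lat)
  lon <- towns_lon[town_of] +
    stats::rnorm(n, 0, spec$town_spread_km / km_per_deg_lon)
  lat <- pmin(pmax(lat, -90), 90)
  lon <- pmin(pmax(lon, -180), 180)

  kinds <- names(spec$demand_mix)
  kind <- sample(kinds, n, replace = TRUE, prob = spec$demand_mix)
  daily_tests <- stats::rpois(n, spec$demand_level[kind])

  n_cand <- max(1L, round(spec$frac_candidates * n))
  hospitals <- which(kind == "hospital")
  pool <- c(sample(hospitals), sample(setdiff(seq_len(n), hospitals)))
  cand_idx <- pool[seq_len(min(n_cand, n))]
  is_candidate <- seq_len(n) %in% cand_idx
  n_existing <- max(1L, round(length(cand_idx) / 4))
  existing_idx <- cand_idx[seq_len(n_existing)]
  is_existing <- seq_len(n) %in% existing_idx

  ids <- paste0("F", formatC(seq_len(n), width = 5, flag = "0"))
  validate_facilities(data.frame(
    id = ids,
    name = paste("Facility", seq_len(n)),
    lat = lat, lon = lon, kind = kind,
    daily_tests = as.numeric(daily_tests),
    is_existing_lab = is_existing,
    is_candidate_lab = is_candidate,
    stringsAsFactors = FALSE
  ))
}

#' Generate a synthetic drive-time calibration sample
#'
#' Draws facility pairs (origins from all facilities, destinations from
#' the candidate laboratories), computes great-circle distances, and emits
#' drive times from the linear truth `beta0 + beta1 * d` plus Gaussian
#' noise, floored at zero.
#'
#' @param network facility data.frame.
#' @param model_truth c(beta0 hours, beta1 hours/km).
#' @param noise_sd noise sd in hours (0 for a noiseless sample).
#' @param n_samples number of pairs (>= 2).
#' @param seed integer seed.
#' @return data.frame: `origin_id`, `dest_id`, `distance_km`,
#'   `drive_time_h`.
#' @export
generate_drive_times <- function(network, model_truth = c(0.2, 0.015),
                                 noise_sd = 0.05, n_samples = 500,
                                 seed = 1L) {
  stopifnot(n_samples >= 2)
  set.seed(seed)
  cands <- network[network$is_candidate_lab, , drop = FALSE]
  if (nrow(cands) == 0L) stop("no candidate laboratories", call. = FALSE)
  oi <- sample.int(nrow(network), n_samples, replace = TRUE)
  di <- sample.int(nrow(cands), n_samples, replace = TRUE)
  d <- distance_km(network$lat[oi], network$lon[oi],
                   cands$lat[di], cands$lon[di])
  t <- model_truth[1] + model_truth[2] * d
  if (noise_sd > 0) t <- t + stats::rnorm(n_samples, 0, noise_sd)
  data.frame(origin_id = network$id[oi], dest_id = cands$id[di],
             distance_km = d, drive_time_h = pmax(0, t),
             stringsAsFactors = FALSE)
}

# helper: a facility row
fac_row <- function(id, name, lat, lon, kind = "clinic", daily_tests = 20,
                    existing = FALSE, candidate = FALSE) {
  data.frame(id = id, name = name, lat = lat, lon = lon, kind = kind,
             daily_tests = daily_tests, is_existing_lab = existing,
             is_candidate_lab = candidate, stringsAsFactors = FALSE)
}

#' Named small fixture networks
#'
#' Hand-built geometries exercising specific pipeline behaviour. All
#' presets ship with a noiseless drive-time sample generated from the
#' stated truth model, so a fitted model reproduces the truth exactly.
#'
#' \describe{
#'   \item{three_towns}{Three well-separated towns, each with a hospital
#'     candidate; small enough for the exact solver and the
#'     subset-enumeration oracle.}
#'   \item{colesberg_like}{A town whose facilities sit within a few km of
#'     each other, so radius-5 km clustering merges them into a single
#'     cluster, plus a distant second town.}
#'   \item{remote_fringe}{Two candidate towns plus a fringe settlement
#'     about 250 km from every candidate: unreachable within T = 2 h under
#'     the truth model (0 h + 0.01 h/km), reachable within T = 4 h.}
#' }
#'
#' @param name preset name.
#' @return list: `facilities`, `drive_times`, `truth` (c(beta0, beta1)).
#' @export
fixture_presets <- function(name = c("three_towns", "colesberg_like",
                                     "remote_fringe")) {
  name <- match.arg(name)
  truth <- c(0, 0.01)   # 0 h delay, 100 km/h straight-line
  facilities <- switch(
    name,
    three_towns = rbind(
      fac_row("H01", "Town1 hospital", -30.0, 24.0, "hospital", 120,
              existing = TRUE, candidate = TRUE),
      fac_row("C02", "Town1 clinic A", -30.02, 24.02, "clinic", 25),
      fac_row("C03", "Town1 clinic B", -29.98, 23.98, "clinic", 30),
      fac_row("H04", "Town2 hospital", -31.5, 26.0, "hospital", 100,
              candidate = TRUE),
      fac_row("C05", "Town2 clinic", -31.52, 26.03, "clinic", 20),
      fac_row("H06", "Town3 hospital", -28.5, 26.5, "hospital", 90,
              candidate = TRUE),
      fac_row("C07", "Town3 clinic A", -28.48, 26.52, "clinic", 15),
      fac_row("C08", "Town3 clinic B", -28.53, 26.47,
              "community_health_centre", 55)
    ),
    colesberg_like = rbind(
      fac_row("K01", "Town hospital", -30.72, 25.10, "hospital", 110,
              existing = TRUE, candidate = TRUE),
      fac_row("K02", "Town clinic A", -30.73, 25.11, "clinic", 30),
      fac_row("K03", "Town clinic B", -30.71, 25.09, "clinic", 25),
      fac_row("K04", "Town CHC", -30.72, 25.12,
              "community_health_centre", 60),
      fac_row("K05", "Far clinic", -32.00, 26.50, "clinic", 20),
      fac_row("K06", "Far hospital", -32.02, 26.52, "hospital", 95,
              candidate = TRUE)
    ),
    remote_fringe = rbind(
      fac_row("R01", "West hospital", -30.0, 22.0, "hospital", 120,
              existing = TRUE, candidate = TRUE),
      fac_row("R02", "West clinic", -30.02, 22.03, "clinic", 25),
      fac_row("R03", "East hospital", -30.0, 27.0, "hospital", 110,
              candidate = TRUE),
      fac_row("R04", "East clinic", -29.97, 27.02, "clinic", 30),
      # ~250 km from both candidates: > 2 h but < 4 h at 0.01 h/km
      fac_row("R05", "Fringe clinic", -32.2, 24.5, "clinic", 15),
      fac_row("R06", "Fringe clinic B", -32.22, 24.52, "clinic", 10)
    )
  )
  facilities <- validate_facilities(facilities)
  drive_times <- generate_drive_times(facilities, model_truth = truth,
                                      noise_sd = 0, n_samples = 40,
                                      seed = 99L)
  list(facilities = facilities, drive_times = drive_times, truth = truth)
}
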