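# Capacity planning: tier classification, platform selection, instrument
# quantities and bench-space requirements for each selected laboratory.

#' Default platform configuration table
#'
#' One row per analyser configuration, from the low-throughput single flow
#' cytometer (XL MCL, up to 150 samples/day) through bundled
#' cell-preparation + cytometer configurations (1+1, 2+1, 2+2). The 2+2
#' planning capacity is two preparation systems at 54 samples/hour over a
#' 10-hour working day = 1080 tests/day; instrument quantities scale in
#' whole configuration units. Volume bands select the configuration for a
#' given daily volume; they partition [0, Inf).
#'
#' @return data.frame with columns `name`, `band_lo`, `band_hi`,
#'   `daily_capacity`, `unit_bench_width_m`.
#' @export
platform_defaults <- function() {
  data.frame(
    name = c("XL_MCL", "CM_MPL_1p1", "CM_MPL_2p1", "CM_MPL_2p2"),
    band_lo = c(0, 200, 430, 551),
    band_hi = c(200, 430, 551, Inf),
    daily_capacity = c(150, 540, 800, daily_throughput(2)),
    unit_bench_width_m = c(3.0, 3.0, 5.27, 6.78),
    stringsAsFactors = FALSE
  )
}

#' Daily throughput of bundled preparation systems
#'
#' @param n_systems number of sample-preparation systems running in
#'   parallel.
#' @param samples_per_hour per-system processing rate (default 54).
#' @param shift_hours working-day length in hours (default 10).
#' @return results per day.
#' @examples
#' daily_throughput(2)  # 1080 results in a 10-hour day
#' @export
daily_throughput <- function(n_systems, samples_per_hour = 54,
                             shift_hours = 10) {
  stopifnot(n_systems >= 1)
  n_systems * samples_per_hour * shift_hours
}

#' Default service-tier bands (tests/day)
#'
#' Six-tier service delivery model: Tier 1 true POC (< 3 tests/day),
#' Tier 2 POC hub (< 10), Tier 3 community laboratory (< 100), Tier 4
#' district laboratory (100-299), Tier 5 high-volume centralised
#' laboratory (300+). Sites at or above `super_threshold` (600/day) are
#' additionally flagged as consolidation ("super-laboratory") candidates.
#'
#' @return list with a `bands` data.frame (`tier`, `lo`, `hi`; half-open
#'   intervals `[lo, hi)`) and `super_threshold`.
#' @export
tier_defaults <- function() {
  list(bands = data.frame(tier = 1:5,
                          lo = c(0, 3, 10, 100, 300),
                          hi = c(3, 10, 100, 300, Inf)),
       super_threshold = 600)
}

#' Classify a daily volume into a service tier
#'
#' @param daily_volume tests/day (vectorised, >= 0).
#' @param tiers tier table from [tier_defaults()].
#' @return integer tier 1-5.
#' @export
classify_tier <- function(daily_volume, tiers = tier_defaults()) {
  stopifnot(all(daily_volume >= 0))
  b <- tiers$bands
  vapply(daily_volume, function(v) {
    b$tier[v >= b$lo & v < b$hi]
  }, integer(1))
}

#' Super-laboratory flag
#'
#' @param daily_volume tests/day.
#' @param tiers tier table from [tier_defaults()].
#' @return logical: volume at or above the consolidation threshold.
#' @export
is_super_laboratory <- function(daily_volume, tiers = tier_defaults()) {
  daily_volume >= tiers$super_threshold
}

#' Select the platform configuration for a daily volume
#'
#' Half-open band lookup in the platform table.
#'
#' @param daily_volume tests/day (vectorised, >= 0).
#' @param platforms platform table from [platform_defaults()].
#' @return character vector of platform names.
#' @export
select_platform <- function(daily_volume, platforms = platform_defaults()) {
  stopifnot(all(daily_volume >= 0))
  vapply(daily_volume, function(v) {
    platforms$name[v >= platforms$band_lo & v < platforms$band_hi]
  }, character(1))
}

#' Number of configuration units required for a daily volume
#'
#' `ceiling(volume / daily_capacity)`, minimum one unit, so provisioned
#' capacity always covers the allocated volume.
#'
#' @param daily_volume tests/day (vectorised, >= 0).
#' @param config single row of the platform table (or its name).
#' @param platforms platform table, used when `config` is a name.
#' @return integer number of units.
#' @export
config_quantity <- function(daily_volume, config,
                            platforms = platform_defaults()) {
  config <- resolve_platform(config, platforms)
  stopifnot(all(daily_volume >= 0))
  pmax(1L, as.integer(ceiling(daily_volume / config$daily_capacity)))
}

#' Bench width for a number of configuration units
#'
#' `quantity * unit_bench_width_m`. Report tables round to the nearest
#' metre, half away from zero; use [round_half_away()] for that view.
#'
#' @param quantity units (>= 1, vectorised).
#' @param config single row of the platform table (or its name).
#' @param platforms platform table, used when `config` is a name.
#' @return width in metres (unrounded).
#' @export
bench_width <- function(quantity, config, platforms = platform_defaults()) {
  config <- resolve_platform(config, platforms)
  stopifnot(all(quantity >= 1))
  quantity * config$unit_bench_width_m
}

resolve_platform <- function(config, platforms) {
  if (is.character(config)) {
    i <- match(config, platforms$name)
    if (is.na(i)) stop("unknown platform: ", config, call. = FALSE)
    config <- platforms[i, , drop = FALSE]
  }
  stopifnot(is.data.frame(config), nrow(config) == 1L)
  config
}

#' Round half away from zero
#'
#' Report-table rounding (6.78 -> 7, 13.56 -> 14), unlike base R's
#' round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Truncate to one decimal place (toward zero)
#'
#' Headline reduction percentages are truncated, not rounded (44/59 ->
#' 74.5%, not 74.6%).
#'
#' @param x numeric.
#' @return truncated values.
#' @export
truncate_1dp <- function(x) {
  trunc(x * 10) / 10
}

#' Percent change of a planned volume against its baseline
#'
#' @param planned tests/day.
#' @param baseline tests/day (> 0).
#' @return `100 * (planned - baseline) / baseline`, unrounded.
#' @export
pct_volume_change <- function(planned, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive", call. = FALSE)
  100 * (planned - baseline) / baseline
}

#' Build per-laboratory capacity plans from an allocation
#'
#' For each selected laboratory: allocated daily volume, service tier,
#' super-laboratory flag, platform configuration, number of configuration
#' units, bench width (unrounded plus nearest-metre report value) and
#' percent volume change against the baseline. Sorted by daily volume
#' descending (id ascending on ties).
#'
#' @param allocation `racl_allocation`.
#' @param baselines named numeric vector: current tests/day per laboratory
#'   id. Laboratories without a baseline get `NA` percent change.
#' @param top_n keep only the busiest `top_n` laboratories (`Inf` for all).
#' @param platforms platform table.
#' @param tiers tier table.
#' @return data.frame of class `racl_lab_plan`.
#' @export
plan_laboratories <- function(allocation, baselines = NULL, top_n = Inf,
                              platforms = platform_defaults(),
                              tiers = tier_defaults()) {
  stopifnot(inherits(allocation, "racl_allocation"))
  labs <- allocation$selected_lab_ids
  vols <- allocation$lab_volumes[labs]
  ord <- order(-vols, labs)
  labs <- labs[ord]
  vols <- unname(vols[ord])
  if (is.finite(top_n)) {
    keep <- seq_len(min(top_n, length(labs)))
    labs <- labs[keep]
    vols <- vols[keep]
  }
  platform <- select_platform(vols, platforms)
  qty <- mapply(function(v, p) config_quantity(v, p, platforms),
                vols, platform)
  width <- mapply(function(q, p) bench_width(q, p, platforms),
                  qty, platform)
  pct <- rep(NA_real_, length(labs))
  if (!is.null(baselines)) {
    has <- labs %in% names(baselines) & !is.na(baselines[labs]) &
      baselines[labs] > 0
    pct[has] <- pct_volume_change(vols[has], unname(baselines[labs[has]]))
  }
  out <- data.frame(
    lab_id = labs,
    daily_volume = vols,
    tier = classify_tier(vols, tiers),
    super_lab = is_super_laboratory(vols, tiers),
    platform = platform,
    qty = as.integer(qty),
    bench_width_m = as.numeric(width),
    bench_width_report_m = round_half_away(as.numeric(width)),
    pct_change = pct,
    stringsAsFactors = FALSE
  )
  class(out) <- c("racl_lab_plan", class(out))
  out
}

#' Write a laboratory plan CSV
#'
#' Columns mirror the scenario report table: scenario label, laboratory,
#' daily volume, platform, quantity, bench width, percent change.
#'
#' @param plans `racl_lab_plan` data.frame.
#' @param path output path.
#' @param scenario scenario label (e.g. "A").
#' @export
write_lab_plan_csv <- function(plans, path, scenario = "") {
  out <- data.frame(scenario = scenario,
                    lab_id = plans$lab_id,
                    daily_vols = plans$daily_volume,
                    platform = plans$platform,
                    qty = plans$qty,
                    bench_width_m = plans$bench_width_report_m,
                    pct_change = round_half_away(plans$pct_change, 1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
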