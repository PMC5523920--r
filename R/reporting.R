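# Scenario reporting: summary tables, sorted volume series and map layers
# (GeoJSON primary, KML optional) replacing the original hosted map tables.

#' Summarise a scenario
#'
#' @param allocation `racl_allocation`, or a list with `n_labs` and `n_poc`
#'   counts when summarising published figures directly.
#' @param current_labs number of laboratories in the current network.
#' @param label scenario label (e.g. "A").
#' @param T travel-time threshold (hours).
#' @return one-row data.frame: `scenario`, `T`, `n_labs`, `n_poc`,
#'   `total_sites` (= n_labs + n_poc), `current_labs`, `lab_change`
#'   (= n_labs - current_labs).
#' @export
summarize_scenario <- function(allocation, current_labs, label = "", T = NA) {
  if (inherits(allocation, "racl_allocation")) {
    n_labs <- allocation$objective
    n_poc <- length(allocation$poc_cluster_ids)
    if (is.na(T)) T <- allocation$T
  } else {
    n_labs <- allocation$n_labs
    n_poc <- allocation$n_poc
  }
  data.frame(scenario = label, T = T,
             n_labs = as.integer(n_labs), n_poc = as.integer(n_poc),
             total_sites = as.integer(n_labs + n_poc),
             current_labs = as.integer(current_labs),
             lab_change = as.integer(n_labs - current_labs),
             stringsAsFactors = FALSE)
}

#' Sorted daily-volume series for the selected laboratories
#'
#' The scenario volume chart plots laboratory volumes sorted from highest
#' to lowest; an optional baseline series (current volumes per laboratory)
#' rides along for comparison.
#'
#' @param plans `racl_lab_plan` data.frame (or anything with `lab_id` and
#'   `daily_volume` columns).
#' @param baselines optional named vector of current volumes.
#' @return data.frame `rank`, `lab_id`, `daily_volume`, and `baseline`
#'   when supplied, sorted by volume descending.
#' @export
volume_distribution <- function(plans, baselines = NULL) {
  ord <- order(-plans$daily_volume, plans$lab_id)
  out <- data.frame(rank = seq_along(ord),
                    lab_id = plans$lab_id[ord],
                    daily_volume = plans$daily_volume[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(baselines)) out$baseline <- unname(baselines[out$lab_id])
  out
}

# colour legend for assignment lines by travel-time threshold
line_colour_for_T <- function(T) {
  if (is.na(T)) return("gray")
  if (T <= 2) "green" else if (T <= 3) "purple" else "orange"
}

# assemble the feature list shared by the GeoJSON and KML writers
map_features <- function(allocation, clusters, facilities = NULL) {
  stopifnot(inherits(allocation, "racl_allocation"))
  cl <- clusters[match(allocation$assignment_table$cluster_id,
                       clusters$cluster_id), , drop = FALSE]
  points <- list()
  # laboratory points: coordinates from the facility table when given,
  # else from the cluster whose seed is the laboratory
  for (lab in allocation$selected_lab_ids) {
    coord <- NULL
    role <- "new_lab"
    if (!is.null(facilities) && lab %in% facilities$id) {
      i <- match(lab, facilities$id)
      coord <- c(facilities$lon[i], facilities$lat[i])
      if (isTRUE(facilities$is_existing_lab[i])) role <- "existing_lab"
    } else if (lab %in% clusters$seed_id) {
      i <- match(lab, clusters$seed_id)
      coord <- c(clusters$lon[i], clusters$lat[i])
    }
    if (is.null(coord)) next
    points[[length(points) + 1L]] <- list(
      id = lab, role = role, lon = coord[1], lat = coord[2])
  }
  for (cl_id in allocation$poc_cluster_ids) {
    i <- match(cl_id, clusters$cluster_id)
    points[[length(points) + 1L]] <- list(
      id = cl_id, role = "poc", lon = clusters$lon[i], lat = clusters$lat[i])
  }
  for (cl_id in setdiff(clusters$cluster_id,
                        c(allocation$poc_cluster_ids))) {
    i <- match(cl_id, clusters$cluster_id)
    points[[length(points) + 1L]] <- list(
      id = cl_id, role = "cluster", lon = clusters$lon[i],
      lat = clusters$lat[i])
  }
  lines <- list()
  colour <- line_colour_for_T(allocation$T)
  for (cl_id in names(allocation$assignment)) {
    lab <- allocation$assignment[[cl_id]]
    i <- match(cl_id, clusters$cluster_id)
    lab_pt <- Filter(function(p) p$id == lab &&
                       p$role %in% c("existing_lab", "new_lab"), points)
    if (length(lab_pt) == 0L) next
    lab_pt <- lab_pt[[1L]]
    d <- distance_km(clusters$lat[i], clusters$lon[i], lab_pt$lat, lab_pt$lon)
    lines[[length(lines) + 1L]] <- list(
      cluster_id = cl_id, lab_id = lab,
      from = c(clusters$lon[i], clusters$lat[i]),
      to = c(lab_pt$lon, lab_pt$lat),
      distance_km = d, T = allocation$T, colour = colour)
  }
  list(points = points, lines = lines)
}

#' Write scenario map layers
#'
#' Emits an RFC 7946 GeoJSON FeatureCollection (WGS84, `[lon, lat]` order):
#' one point feature per laboratory (`role` = `existing_lab` / `new_lab`),
#' POC cluster (`role` = `poc`) and served cluster (`role` = `cluster`),
#' and one line feature per cluster-to-laboratory assignment carrying
#' `distance_km` and a `colour` property encoding the threshold (green
#' T = 2 h, purple T = 3 h, orange T = 4 h). Optionally also writes KML 2.2.
#'
#' @param allocation `racl_allocation`.
#' @param clusters cluster table from [cluster_facilities()].
#' @param path output `.geojson` path.
#' @param facilities optional facility table for exact laboratory
#'   coordinates and existing/new status.
#' @param kml_path optional `.kml` output path.
#' @return invisibly, the GeoJSON path.
#' @export
write_map_layers <- function(allocation, clusters, path, facilities = NULL,
                             kml_path = NULL) {
  fx <- map_features(allocation, clusters, facilities)
  features <- c(
    lapply(fx$points, function(p) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(p$lon, p$lat)),
           properties = list(id = p$id, role = p$role))
    }),
    lapply(fx$lines, function(l) {
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = list(l$from, l$to)),
           properties = list(cluster_id = l$cluster_id, lab_id = l$lab_id,
                             distance_km = l$distance_km,
                             T = l$T, colour = l$colour))
    })
  )
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(kml_path)) write_kml(fx, kml_path)
  invisible(path)
}

# minimal KML 2.2 writer over the shared feature list
write_kml <- function(fx, path) {
  doc <- xml2::xml_new_root("kml", xmlns = "http://www.opengis.net/kml/2.2")
  d <- xml2::xml_add_child(doc, "Document")
  for (p in fx$points) {
    pm <- xml2::xml_add_child(d, "Placemark")
    xml2::xml_add_child(pm, "name", p$id)
    xml2::xml_add_child(pm, "description", p$role)
    pt <- xml2::xml_add_child(pm, "Point")
    xml2::xml_add_child(pt, "coordinates",
                        sprintf("%.6f,%.6f,0", p$lon, p$lat))
  }
  for (l in fx$lines) {
    pm <- xml2::xml_add_child(d, "Placemark")
    xml2::xml_add_child(pm, "name",
                        paste0(l$cluster_id, "->", l$lab_id))
    xml2::xml_add_child(pm, "description", l$colour)
    ls <- xml2::xml_add_child(pm, "LineString")
    xml2::xml_add_child(ls, "coordinates",
                        paste(sprintf("%.6f,%.6f,0", c(l$from[1], l$to[1]),
                                      c(l$from[2], l$to[2])),
                              collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GeoJSON file written by [write_map_layers()]
#'
#' @param path `.geojson` path.
#' @return the parsed FeatureCollection (lists, not data.frames).
#' @export
read_map_layers <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
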