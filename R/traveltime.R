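# Drive-time calibration: a linear map from straight-line distance (km)
# to drive time (hours), fitted on a representative sample of pairs.

#' Sample matrix cells, stratified by distance decile
#'
#' Splits the distance values into deciles and draws (near-)equal counts
#' per decile with a seeded generator, so the sample spans the whole
#' distance range rather than over-representing the dense short-haul part.
#' Matrices with fewer than 10 cells fall back to returning every cell,
#' with a message.
#'
#' @param matrix distance matrix (km).
#' @param fraction proportion of cells to sample, in (0, 1].
#' @param seed integer seed.
#' @param stratified if FALSE, plain simple random sampling.
#' @return data.frame with columns `row`, `col`, `distance_km`.
#' @export
sample_pairs <- function(matrix, fraction, seed, stratified = TRUE) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(matrix)
  all_cells <- data.frame(
    row = rep(seq_len(nrow(matrix)), times = ncol(matrix)),
    col = rep(seq_len(ncol(matrix)), each = nrow(matrix)),
    distance_km = as.vector(matrix)
  )
  if (n < 10L) {
    message("matrix has fewer than 10 cells; taking all of them")
    return(all_cells)
  }
  target <- max(2L, ceiling(fraction * n))
  if (target >= n) return(all_cells)

  set.seed(seed)
  if (!stratified) {
    idx <- sample.int(n, target)
    return(all_cells[sort(idx), , drop = FALSE])
  }
  breaks <- unique(stats::quantile(all_cells$distance_km,
                                   probs = seq(0, 1, 0.1), names = FALSE))
  bin <- cut(all_cells$distance_km, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  per_bin <- split(seq_len(n), bin)
  k <- length(per_bin)
  quota <- ceiling(target / k)
  idx <- unlist(lapply(per_bin, function(cells) {
    if (length(cells) <= quota) cells else sample(cells, quota)
  }), use.names = FALSE)
  all_cells[sort(idx), , drop = FALSE]
}

#' Fit the linear drive-time model
#'
#' Ordinary least squares of drive time (hours) on distance (km), with
#' intercept. The intercept absorbs fixed urban/traffic delay; a negative
#' fitted slope indicates a corrupt sample and is rejected rather than
#' silently producing times that shrink with distance.
#'
#' @param samples data.frame with columns `distance_km` and `drive_time_h`.
#' @return object of class `racl_time_model`: list with `beta0` (h),
#'   `beta1` (h/km), `n`, `r2`, and the underlying `lm` fit.
#' @export
fit_time_model <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("distance_km", "drive_time_h") %in% names(samples)))
  if (nrow(samples) < 2L) stop("need at least two samples", call. = FALSE)
  if (length(unique(samples$distance_km)) < 2L) {
    stop("degenerate design: all distances identical", call. = FALSE)
  }
  if (any(samples$drive_time_h < 0) || any(samples$distance_km < 0)) {
    stop("negative distance or drive time in sample", call. = FALSE)
  }
  fit <- stats::lm(drive_time_h ~ distance_km, data = samples)
  beta <- unname(stats::coef(fit))
  if (beta[2] < 0) {
    stop("negative slope - check sample", call. = FALSE)
  }
  # R^2 computed directly; summary.lm() warns on exactly-linear samples
  sst <- sum((samples$drive_time_h - mean(samples$drive_time_h))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(beta0 = beta[1], beta1 = beta[2],
                 n = nrow(samples), r2 = r2, fit = fit),
            class = "racl_time_model")
}

#' @export
print.racl_time_model <- function(x, ...) {
  cat(sprintf(
    "Drive-time model: t = %.4f + %.5f * d  (n = %d, R^2 = %.3f)\n",
    x$beta0, x$beta1, x$n, x$r2))
  invisible(x)
}

#' Convert a distance matrix to predicted travel times
#'
#' Element-wise affine transform `t = beta0 + beta1 * d`. Negative
#' predictions (possible for very short distances when the intercept is
#' negative) are clipped to zero and counted in a message.
#'
#' @param matrix distance matrix (km).
#' @param model fitted `racl_time_model`.
#' @return matrix of travel times (hours), same shape and dimnames.
#' @export
predict_time_matrix <- function(matrix, model) {
  stopifnot(inherits(model, "racl_time_model"))
  t <- model$beta0 + model$beta1 * matrix
  n_neg <- sum(t < -1e-9)
  if (n_neg > 0) {
    message(n_neg, " predicted time(s) below zero clipped to 0 h")
  }
  t[t < 0] <- 0
  t
}

#' Read a drive-time sample CSV
#'
#' Columns: `origin_id,dest_id,distance_km,drive_time_h`.
#'
#' @param path path to the CSV file.
#' @return data.frame.
#' @export
read_drive_times <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("origin_id", "dest_id", "distance_km", "drive_time_h")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("drive-time table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Serialise a fitted time model as JSON
#'
#' @param model fitted `racl_time_model`.
#' @param path output path; `NULL` returns the JSON string.
#' @param seed optional seed to record alongside the coefficients.
#' @export
write_time_model_json <- function(model, path = NULL, seed = NULL) {
  obj <- list(beta0 = model$beta0, beta1 = model$beta1,
              n = model$n, r2 = model$r2)
  if (!is.null(seed)) obj$seed <- seed
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
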