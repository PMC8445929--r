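# boundary tolerance (km) when testing farms against the dispersal radius
RADIUS_TOL_KM <- 1e-9

#' Corrected elevational shift of one dispersal event
#'
#' Birds dispersing from high-elevation sites have mostly downhill
#' options, so the raw elevation difference of a dispersal event is
#' geometrically biased. The corrected shift nulls this bias: it is the
#' destination elevation minus the mean elevation of all farms available
#' within the realized dispersal distance, i.e. within a disc around the
#' origin farm whose radius is the event's distance. Farms exactly on the
#' boundary are included (so the destination always qualifies).
#'
#' @param event One dispersal event (a single-row data frame or list with
#'   `origin_farm`, `dest_farm`, `distance`, `dispersed`); must be a
#'   dispersed event.
#' @param farms A `farm_table` containing origin and destination.
#' @param include_origin Count the origin farm itself as an available
#'   site (default TRUE; it lies within any radius).
#' @return A list with `radius` (km), `available_farms` (ids),
#'   `mean_available_elevation` (m) and `corrected_shift` (m).
#' @export
corrected_shift <- function(event, farms, include_origin = TRUE) {
  if (!isTRUE(as.logical(event$dispersed)))
    stop("corrected shift is defined for dispersed events only")
  oi <- match(event$origin_farm, farms$farm_id)
  di <- match(event$dest_farm, farms$farm_id)
  if (is.na(oi) || is.na(di))
    stop("origin or destination farm missing from farm table")
  d_km <- sqrt((farms$x - farms$x[oi])^2 + (farms$y - farms$y[oi])^2) / 1000
  radius <- event$distance
  avail <- d_km <= radius + RADIUS_TOL_KM
  if (!include_origin) avail[oi] <- FALSE
  if (!any(avail))
    stop("internal error: empty available set (destination should qualify)")
  mean_elev <- mean(farms$elevation[avail])
  list(event = event, radius = radius,
       available_farms = farms$farm_id[avail],
       mean_available_elevation = mean_elev,
       corrected_shift = farms$elevation[di] - mean_elev)
}

#' Fill the corrected-shift column of an event table
#'
#' @param events A `dispersal_events` data frame.
#' @param farms A `farm_table`.
#' @param include_origin See [corrected_shift()].
#' @return `events` with `corrected_shift` filled for dispersed rows
#'   (non-dispersed rows stay `NA`).
#' @export
add_corrected_shifts <- function(events, farms, include_origin = TRUE) {
  for (k in which(events$dispersed)) {
    events$corrected_shift[k] <-
      corrected_shift(events[k, ], farms, include_origin)$corrected_shift
  }
  events
}

#' Corrected shift versus elevation, by age class
#'
#' Fits the Gaussian shift mixed model and summarizes the expected
#' corrected shift over an elevation grid for juveniles and adults
#' (reference sex male, centre sites, random effects at zero), with
#' simulated-posterior credible bands.
#'
#' @param events Dispersed events with `corrected_shift` filled.
#' @param farms A `farm_table`.
#' @param grid Elevations in meters (default 10 points over the farm
#'   range).
#' @param n_draws,seed Passed to [simulate_posterior()].
#' @return Data frame: `elevation`, `age_class`, `mean`, `lo95`, `hi95`.
#' @export
shift_vs_elevation_summary <- function(events, farms, grid = NULL,
                                       n_draws = 2000L, seed = 1L) {
  events <- events[events$dispersed, , drop = FALSE]
  if (nrow(events) < 1L) stop("need at least one dispersed event")
  if (is.null(grid))
    grid <- seq(min(farms$elevation), max(farms$elevation), length.out = 10L)
  if (var(events$corrected_shift) == 0) {
    # degenerate world (e.g. flat landscape): nothing to fit
    v <- events$corrected_shift[1L]
    return(data.frame(
      elevation = rep(grid, 2L),
      age_class = rep(c("juvenile", "adult"), each = length(grid)),
      mean = v, lo95 = v, hi95 = v))
  }
  design <- build_design(events, "shift", farms)
  fit <- fit_lmm_gaussian(design)
  draws <- simulate_posterior(fit, n_draws = n_draws, seed = seed)$draws
  z <- std_apply(fit$standardizer, grid)
  out <- lapply(c(juvenile = 0, adult = 1), function(adult) {
    # term order: intercept, adult, elev, female, elev:adult, elev:female,
    # adult:female
    X <- cbind(1, adult, z, 0, z * adult, 0, 0)
    eta <- draws %*% t(X)
    data.frame(elevation = grid,
               mean = colMeans(eta),
               lo95 = apply(eta, 2, quantile, 0.025, names = FALSE),
               hi95 = apply(eta, 2, quantile, 0.975, names = FALSE))
  })
  rbind(cbind(age_class = "juvenile", out$juvenile),
        cbind(age_class = "adult", out$adult))[, c("elevation", "age_class",
                                                   "mean", "lo95", "hi95")]
}
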