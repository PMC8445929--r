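#' True coefficients for the dispersal-probability generator
#'
#' Defaults are the point estimates of the study's dispersal-probability
#' model (log-odds scale, standardized elevation, treatment coding with
#' reference juvenile/male/centre), its year random-effect SD, and
#' distance-decay kernels whose scales match the reported mean natal
#' (~4 km) and breeding (~1.25 km) dispersal distances.
#'
#' @param coef Named numeric length-7: `intercept`, `elevation`,
#'   `age_adult`, `sex_female`, `edge`, `elevation_x_female`,
#'   `elevation_x_adult`.
#' @param sd_individual,sd_location,sd_year Random-intercept SDs.
#' @param kernel_natal_km,kernel_breeding_km Scales of the exponential
#'   distance-decay destination kernel, in km.
#' @export
dispersal_params <- function(coef = c(intercept = 1.88, elevation = 0.36,
                                      age_adult = -4.66, sex_female = 0.13,
                                      edge = 0.80, elevation_x_female = 1.75,
                                      elevation_x_adult = 0.07),
                             sd_individual = 0, sd_location = 0,
                             sd_year = 0.34,
                             kernel_natal_km = 4, kernel_breeding_km = 1.25) {
  stopifnot(length(coef) == 7L)
  structure(list(coef = coef, sd_individual = sd_individual,
                 sd_location = sd_location, sd_year = sd_year,
                 kernel_natal_km = kernel_natal_km,
                 kernel_breeding_km = kernel_breeding_km),
            class = "dispersal_params")
}

#' Configuration of the synthetic study
#'
#' The stated world of the generator mirrors the real study design: 63
#' farms over a 10 x 3.5 km valley between 700 and 1430 m a.s.l. (farm
#' abundance declining with elevation, mean calibrated to 1042 m), 15
#' annual occasions, ~89 nestlings and ~13 adults newly ringed per year
#' (~1337 and ~194 in total), a 0.45 male proportion, and the published
#' survival/recapture/dispersal point estimates as true parameter values.
#'
#' @param n_farms Number of farms (>= 2).
#' @param elev_range Increasing length-2 elevation range, m a.s.l.
#' @param study_extent Length-2 planar extent (x, y) in meters.
#' @param years Number of annual occasions.
#' @param start_year First calendar year.
#' @param n_nestlings_per_year,n_adults_per_year Newly ringed per year.
#' @param mean_elevation Calibration target for the mean farm elevation.
#' @param cjs True survival-model parameters ([cjs_params()]; the deviate
#'   vectors are redrawn from the SDs at simulation time).
#' @param dispersal True dispersal parameters ([dispersal_params()]).
#' @param prop_male True proportion of males.
#' @param seed Integer; fully determines every generated table.
#' @export
sim_config <- function(n_farms = 63L, elev_range = c(700, 1430),
                       study_extent = c(10000, 3500),
                       years = 15L, start_year = 1998L,
                       n_nestlings_per_year = 89L, n_adults_per_year = 13L,
                       mean_elevation = 1042,
                       cjs = cjs_params(
                         beta0 = c(adult_male = -0.77, adult_female = -0.89,
                                   juvenile = -2.82),
                         beta1 = c(adult_male = -0.59, adult_female = -0.32,
                                   juvenile = 0.00),
                         beta2 = 0.26,
                         alpha0 = c(adult = 1.02, juvenile_offset = -1.83),
                         alpha1 = c(adult = -0.02, juvenile_offset = -0.28),
                         f_male = 0.45,
                         sigma_delta = 0.20, sigma_gamma = 0.21,
                         sigma_rho = 0.59),
                       dispersal = dispersal_params(),
                       prop_male = 0.45, seed = 1L) {
  stopifnot(n_farms >= 2L || n_farms >= 1L, years >= 2L,
            elev_range[2] > elev_range[1],
            n_nestlings_per_year >= 0L, n_adults_per_year >= 0L,
            prop_male > 0, prop_male < 1)
  structure(list(n_farms = as.integer(n_farms), elev_range = elev_range,
                 study_extent = study_extent, years = as.integer(years),
                 start_year = as.integer(start_year),
                 n_nestlings_per_year = as.integer(n_nestlings_per_year),
                 n_adults_per_year = as.integer(n_adults_per_year),
                 mean_elevation = mean_elevation,
                 cjs = cjs, dispersal = dispersal,
                 prop_male = prop_male, seed = as.integer(seed)),
            class = "sim_config")
}

# Rate of the truncated exponential elevation density such that the mean
# over [0, width] equals the target offset.
trunc_exp_rate <- function(width, target) {
  stopifnot(target > 0, target < width)
  m <- function(r) 1 / r - width * exp(-r * width) / (-expm1(-r * width))
  if (abs(target - width / 2) < 1e-9 * width) return(1e-9)
  if (target > width / 2)
    stop("elevation density must decline with elevation: target mean ",
         "above the range midpoint is unsupported")
  uniroot(function(r) m(r) - target, c(1e-6, 1), tol = 1e-12)$root
}

#' Generate a synthetic farm landscape
#'
#' Farm locations are uniform over the study extent; elevations follow a
#' truncated exponential over the elevation range (farm abundance
#' declines with elevation), with the rate calibrated so the expected
#' elevation equals `mean_elevation`. Farms in the outer 15% band of
#' either planar axis are flagged as edge sites.
#'
#' @param config A [sim_config()].
#' @return A `farm_table`.
#' @export
generate_farms <- function(config) {
  if (config$n_farms < 2L) stop("need at least 2 farms")
  set.seed(config$seed)
  width <- diff(config$elev_range)
  rate <- trunc_exp_rate(width, config$mean_elevation - config$elev_range[1])
  u <- runif(config$n_farms)
  elev <- config$elev_range[1] -
    log(1 - u * (1 - exp(-rate * width))) / rate
  x <- runif(config$n_farms, 0, config$study_extent[1])
  y <- runif(config$n_farms, 0, config$study_extent[2])
  edge <- x < 0.15 * config$study_extent[1] |
    x > 0.85 * config$study_extent[1] |
    y < 0.15 * config$study_extent[2] |
    y > 0.85 * config$study_extent[2]
  as_farm_table(data.frame(
    farm_id = sprintf("F%02d", seq_len(config$n_farms)),
    x = x, y = y, elevation = elev, edge = edge,
    stringsAsFactors = FALSE), elev_range = config$elev_range)
}

farm_dist_km <- function(farms) {
  as.matrix(dist(cbind(farms$x, farms$y))) / 1000
}

dispersal_linpred <- function(dp, selev, adult, female, edge) {
  b <- dp$coef
  b[["intercept"]] + b[["elevation"]] * selev + b[["age_adult"]] * adult +
    b[["sex_female"]] * female + b[["edge"]] * edge +
    b[["elevation_x_female"]] * selev * female +
    b[["elevation_x_adult"]] * selev * adult
}

# destination among the other farms with weight exp(-d / scale_km)
sample_destination <- function(origin_idx, dist_km, scale_km) {
  w <- exp(-dist_km[origin_idx, ] / scale_km)
  w[origin_idx] <- 0
  if (all(w == 0)) return(NA_integer_)
  sample.int(length(w), 1L, prob = w)
}

#' Simulate capture histories from known parameters
#'
#' Forward simulation of the full generative model: each individual
#' enters at its ringing year and site; the latent alive state follows
#' the survival model (with farm/year deviates freshly drawn from their
#' SDs); each year a candidate breeding-site move is drawn from the
#' dispersal-probability model and the distance-decay destination kernel,
#' and detections follow the recapture model evaluated at the candidate
#' site. A move becomes real (and recorded) only when the bird is
#' captured that year; undetected birds keep their last known site, so
#' the carry-forward covariates of the fitted model are exact and every
#' inference stage can be checked by parameter recovery. Sex is drawn
#' Bernoulli(`prop_male`) and reported as unknown exactly for
#' never-recaptured nestlings.
#'
#' @param farms A `farm_table` (normally from [generate_farms()]).
#' @param config A [sim_config()].
#' @return A list with `captures` (a `capture_table`), and `truth`
#'   (true parameters incl. drawn deviates, per-individual sex, latent
#'   alive matrix `z` and site-index matrix `site`).
#' @export
simulate_histories <- function(farms, config) {
  set.seed(config$seed + 1L)
  T <- config$years
  nf <- nrow(farms)
  std <- standardize(farms$elevation)$standardizer
  selev <- std_apply(std, farms$elevation)
  dist_km <- farm_dist_km(farms)
  cj <- config$cjs
  cj$delta <- rnorm(nf, 0, cj$sigma_delta)
  cj$gamma <- rnorm(T, 0, cj$sigma_gamma)
  cj$rho <- rnorm(T, 0, cj$sigma_rho)
  dp <- config$dispersal
  dp_year <- rnorm(T, 0, dp$sd_year)

  n_ind <- (config$n_nestlings_per_year + config$n_adults_per_year) * T
  ring_year <- rep(seq_len(T),
                   each = config$n_nestlings_per_year + config$n_adults_per_year)
  ringed_as <- rep(rep(c("nestling", "adult"),
                       c(config$n_nestlings_per_year, config$n_adults_per_year)),
                   T)
  ring_farm <- sample.int(nf, n_ind, replace = TRUE)
  sex <- ifelse(runif(n_ind) < config$prop_male, "male", "female")

  z <- matrix(0L, n_ind, T)
  site <- matrix(NA_integer_, n_ind, T)
  rows <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    r <- ring_year[i]
    s <- ring_farm[i]
    z[i, r] <- 1L
    site[i, r] <- s
    recap_rows <- list()
    detected_since_ringing <- FALSE
    if (r < T) for (t in seq.int(r + 1L, T)) {
      juv <- ringed_as[i] == "nestling" && t == r + 1L
      cls <- if (juv) "juvenile"
             else if (sex[i] == "male") "adult_male" else "adult_female"
      # survival from the last known (recorded) site: the covariate the
      # fitted model carries forward between detections
      phi <- plogis(survival_logit(cj, cls, selev[s], farms$edge[s], s, t))
      if (runif(1) >= phi) break
      z[i, t] <- 1L
      # detection decided at the last known site (the covariate the model
      # carries forward); a breeding-site move is drawn -- and recorded --
      # only at capture, so between-detection covariates stay exact
      age <- if (juv) "first_year" else "adult"
      p <- plogis(recapture_logit(cj, age, selev[s], t))
      if (runif(1) < p) {
        natal_move <- ringed_as[i] == "nestling" && !detected_since_ringing
        lp <- dispersal_linpred(dp, selev[s], as.numeric(!natal_move),
                                as.numeric(sex[i] == "female"),
                                as.numeric(farms$edge[s])) +
          dp_year[t] + rnorm(1, 0, dp$sd_individual) +
          rnorm(1, 0, dp$sd_location)
        if (runif(1) < plogis(lp)) {
          dest <- sample_destination(
            s, dist_km,
            if (natal_move) dp$kernel_natal_km else dp$kernel_breeding_km)
          if (!is.na(dest)) s <- dest
        }
        recap_rows[[length(recap_rows) + 1L]] <- c(t, s)
        detected_since_ringing <- TRUE
      }
      site[i, t] <- s
    }
    recaptured <- length(recap_rows) > 0L
    sex_known <- ringed_as[i] == "adult" | recaptured
    id <- sprintf("ind%05d", i)
    ring_sex <- if (ringed_as[i] == "adult") sex[i] else "unknown"
    rec <- data.frame(
      individual_id = id, year = config$start_year + r - 1L,
      farm_id = farms$farm_id[ring_farm[i]], age_class = ringed_as[i],
      sex = ring_sex, stringsAsFactors = FALSE)
    if (recaptured) {
      rr <- do.call(rbind, recap_rows)
      rec <- rbind(rec, data.frame(
        individual_id = id, year = config$start_year + rr[, 1] - 1L,
        farm_id = farms$farm_id[rr[, 2]], age_class = "adult",
        sex = sex[i], stringsAsFactors = FALSE))
    }
    rows[[i]] <- rec
  }
  captures <- as_capture_table(
    do.call(rbind, c(rows, list(make.row.names = FALSE))), farms = farms)
  truth <- list(cjs = cj, dispersal = dp, dispersal_year_effects = dp_year,
                sex = sex, ringed_as = ringed_as, ring_year = ring_year,
                ring_farm = ring_farm, z = z, site = site,
                standardizer = std)
  list(captures = captures, truth = truth)
}

#' Simulate dispersal outcomes on a fixed scaffold
#'
#' Given rows of (individual, origin farm, year, age class, sex), draws
#' the dispersed flag from the dispersal-probability model (with random
#' intercepts freshly drawn per level) and, for dispersers, a destination
#' from the distance-decay kernel. Used to create ground-truth data for
#' the dispersal regression stages at any sample size.
#'
#' @param scaffold Data frame with columns `individual_id`,
#'   `origin_farm`, `year`, `age_class` (`juvenile`/`adult`), `sex`
#'   (`male`/`female`).
#' @param farms A `farm_table`.
#' @param dp A [dispersal_params()].
#' @param seed Integer seed.
#' @param standardizer Elevation standardizer; default fitted on `farms`.
#' @return A `dispersal_events`-shaped data frame (non-dispersers have
#'   `dest_farm == origin_farm` and distance 0).
#' @export
simulate_dispersal_outcomes <- function(scaffold, farms, dp, seed = 1L,
                                        standardizer = NULL) {
  set.seed(seed)
  if (is.null(standardizer))
    standardizer <- standardize(farms$elevation)$standardizer
  oi <- match(scaffold$origin_farm, farms$farm_id)
  if (anyNA(oi)) stop("scaffold origin_farm not in farm table")
  selev <- std_apply(standardizer, farms$elevation[oi])
  adult <- as.numeric(scaffold$age_class == "adult")
  female <- as.numeric(scaffold$sex == "female")
  edge <- as.numeric(farms$edge[oi])
  dist_km <- farm_dist_km(farms)

  re <- function(levels, sd_) setNames(rnorm(length(levels), 0, sd_), levels)
  ind_re <- re(unique(scaffold$individual_id), dp$sd_individual)
  loc_re <- re(unique(scaffold$origin_farm), dp$sd_location)
  yr_re <- re(unique(as.character(scaffold$year)), dp$sd_year)

  lp <- dispersal_linpred(dp, selev, adult, female, edge) +
    ind_re[scaffold$individual_id] + loc_re[scaffold$origin_farm] +
    yr_re[as.character(scaffold$year)]
  dispersed <- runif(nrow(scaffold)) < plogis(lp)
  dest <- oi
  for (k in which(dispersed)) {
    d <- sample_destination(
      oi[k], dist_km,
      if (adult[k] == 1) dp$kernel_breeding_km else dp$kernel_natal_km)
    if (is.na(d)) dispersed[k] <- FALSE else dest[k] <- d
  }
  out <- data.frame(
    individual_id = scaffold$individual_id,
    year_from = scaffold$year, year_to = scaffold$year + 1L,
    origin_farm = farms$farm_id[oi], dest_farm = farms$farm_id[dest],
    age_class = scaffold$age_class, sex = scaffold$sex,
    dispersed = dispersed,
    distance = dist_km[cbind(oi, dest)],
    raw_shift = farms$elevation[dest] - farms$elevation[oi],
    corrected_shift = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("dispersal_events", "data.frame")
  out
}
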