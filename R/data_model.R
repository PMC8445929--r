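#' @useDynLib elevcmr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd quantile rnorm runif plogis acf setNames var dnorm
#'   uniroot dist
#' @importFrom utils read.csv write.csv
NULL

SEX_LEVELS <- c("male", "female", "unknown")
AGE_AT_CAPTURE <- c("nestling", "adult")

#' Read a farm table
#'
#' Farms are the breeding sites of the study: a planar location in meters,
#' an elevation in m a.s.l. and a flag marking sites at the edge of the
#' study area (where emigration out of the monitored area is more likely).
#'
#' @param path Path to a CSV file with header columns
#'   `farm_id,x,y,elevation,edge`.
#' @param elev_range Numeric length-2; a warning (not an error) is raised
#'   for elevations outside this range. Default matches a valley study
#'   area spanning 700-1430 m a.s.l.
#' @return A `data.frame` of class `farm_table` with columns `farm_id`
#'   (character), `x`, `y`, `elevation` (numeric, meters) and `edge`
#'   (logical).
#' @export
read_farms <- function(path, elev_range = c(700, 1430)) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("farm_id", "x", "y", "elevation", "edge")
  if (!all(req %in% names(raw)))
    stop("farm table must have columns ", paste(req, collapse = ","))
  as_farm_table(data.frame(
    farm_id = raw$farm_id,
    x = parse_num(raw$x, "x"),
    y = parse_num(raw$y, "y"),
    elevation = parse_num(raw$elevation, "elevation"),
    edge = parse_logical(raw$edge, "edge"),
    stringsAsFactors = FALSE
  ), elev_range = elev_range)
}

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(out))
  if (length(bad))
    stop("non-numeric ", what, " at row ", bad[1L], ": '", x[bad[1L]], "'")
  out
}

parse_logical <- function(x, what) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t")] <- TRUE
  out[x %in% c("0", "false", "f")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    stop("cannot parse ", what, " at row ", bad[1L], ": '", x[bad[1L]], "'")
  out
}

as_farm_table <- function(df, elev_range = c(700, 1430)) {
  dup <- unique(df$farm_id[duplicated(df$farm_id)])
  if (length(dup))
    stop("duplicated farm_id: ", paste(dup, collapse = ", "))
  if (any(!is.finite(df$elevation)))
    stop("non-finite elevation in farm table")
  out_of_range <- df$elevation < elev_range[1] | df$elevation > elev_range[2]
  if (any(out_of_range))
    warning(sum(out_of_range), " farm(s) outside the expected elevation range [",
            elev_range[1], ", ", elev_range[2], "] m a.s.l.")
  rownames(df) <- NULL
  class(df) <- c("farm_table", "data.frame")
  df
}

#' Write a farm table
#' @param farms A `farm_table`.
#' @param path Output CSV path.
#' @export
write_farms <- function(farms, path) {
  out <- as.data.frame(farms)
  out$edge <- as.integer(out$edge)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capture table
#'
#' One row per capture of an individual in a year: the annual detection
#' record of the mark-recapture data. A blank sex field is read as
#' `unknown` (sex can only be determined on adults, so nestlings that are
#' never recaptured stay unsexed).
#'
#' @param path Path to a CSV with header
#'   `individual_id,year,farm_id,age_class,sex`.
#' @param farms Optional `farm_table`; when given, every `farm_id` must
#'   occur in it.
#' @return A `data.frame` of class `capture_table`.
#' @export
read_captures <- function(path, farms = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("individual_id", "year", "farm_id", "age_class", "sex")
  if (!all(req %in% names(raw)))
    stop("capture table must have columns ", paste(req, collapse = ","))
  sex <- tolower(trimws(raw$sex))
  sex[sex == "" | is.na(sex)] <- "unknown"
  df <- data.frame(
    individual_id = raw$individual_id,
    year = as.integer(parse_num(raw$year, "year")),
    farm_id = raw$farm_id,
    age_class = tolower(trimws(raw$age_class)),
    sex = sex,
    stringsAsFactors = FALSE
  )
  as_capture_table(df, farms = farms)
}

as_capture_table <- function(df, farms = NULL) {
  if (!all(df$age_class %in% AGE_AT_CAPTURE))
    stop("age_class must be one of: ", paste(AGE_AT_CAPTURE, collapse = ", "))
  if (!all(df$sex %in% SEX_LEVELS))
    stop("sex must be one of: ", paste(SEX_LEVELS, collapse = ", "))
  key <- paste(df$individual_id, df$year)
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicated (individual_id, year): ", paste(dup, collapse = "; "))
  if (!is.null(farms)) {
    missing <- setdiff(unique(df$farm_id), farms$farm_id)
    if (length(missing))
      stop("farm_id not present in farm table: ", paste(missing, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("capture_table", "data.frame")
  df
}

#' Write a capture table
#' @param captures A `capture_table`; `unknown` sex is written blank.
#' @param path Output CSV path.
#' @export
write_captures <- function(captures, path) {
  out <- as.data.frame(captures)
  out$sex[out$sex == "unknown"] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build capture histories
#'
#' Turns the long capture table into one detection history per individual,
#' the unit of the Cormack-Jolly-Seber likelihood. Conditioning is on first
#' capture (the detection indicator is 1 at the first year by
#' construction). Site covariates (farm, elevation, edge) between
#' detections are carried forward from the most recent detected site, the
#' standard convention for time-varying individual covariates in
#' mark-recapture data. The per-occasion age class is `first_year` only in
#' the year after ringing as a nestling, `adult` afterwards and for all
#' occasions of adult-ringed birds.
#'
#' @param records A `capture_table`.
#' @param farms A `farm_table` covering every `farm_id` in `records`.
#' @param years Inclusive integer range of annual occasions, e.g.
#'   `c(1998, 2012)`.
#' @param standardizer Optional `standardizer` for elevation; defaults to
#'   one fitted on the farm table's elevations.
#' @return A list of `capture_history` objects. Each has `individual_id`,
#'   `first_year`, `sex`, `ringed_as`, a detection vector `y`, and
#'   per-occasion vectors `farm_at`, `elevation_at` (meters),
#'   `std_elevation_at` (model scale), `edge_at`, `age_class_at`, all
#'   indexed by occasion 1..length(years range).
#' @export
build_histories <- function(records, farms, years, standardizer = NULL) {
  if (is.null(standardizer))
    standardizer <- standardize(farms$elevation)$standardizer
  records <- as_capture_table(as.data.frame(records), farms = farms)
  years <- seq.int(years[1], years[length(years)])
  if (!all(records$year %in% years))
    stop("capture year outside the occasion range ",
         years[1], "..", years[length(years)])
  n_occ <- length(years)
  farm_lookup <- setNames(seq_len(nrow(farms)), farms$farm_id)

  split_idx <- split(seq_len(nrow(records)), records$individual_id)
  histories <- lapply(split_idx, function(idx) {
    rec <- records[idx, , drop = FALSE]
    rec <- rec[order(rec$year), , drop = FALSE]
    sexes <- unique(rec$sex[rec$sex != "unknown"])
    if (length(sexes) > 1L)
      stop("individual ", rec$individual_id[1L],
           " has conflicting sex records: ", paste(sexes, collapse = " vs "))
    sex <- if (length(sexes)) sexes else "unknown"
    first_occ <- match(rec$year[1L], years)
    occ <- match(rec$year, years)
    ringed_as <- rec$age_class[1L]

    y <- integer(n_occ)
    y[occ] <- 1L
    farm_at <- rep(NA_character_, n_occ)
    farm_at[occ] <- rec$farm_id
    for (t in seq.int(first_occ, n_occ)) {
      if (t > first_occ && is.na(farm_at[t])) farm_at[t] <- farm_at[t - 1L]
    }
    fidx <- farm_lookup[farm_at]
    age_class_at <- rep(NA_character_, n_occ)
    for (t in seq.int(first_occ, n_occ)) {
      age_class_at[t] <-
        if (ringed_as == "nestling" && t == first_occ + 1L) "first_year"
        else "adult"
    }
    age_class_at[first_occ] <- if (ringed_as == "nestling") "nestling" else "adult"

    structure(list(
      individual_id = rec$individual_id[1L],
      first_year = rec$year[1L],
      first_occ = first_occ,
      years = years,
      sex = sex,
      ringed_as = ringed_as,
      y = y,
      farm_at = farm_at,
      farm_idx = unname(fidx),
      elevation_at = unname(farms$elevation[fidx]),
      std_elevation_at = unname(std_apply(standardizer, farms$elevation[fidx])),
      edge_at = unname(farms$edge[fidx]),
      age_class_at = age_class_at
    ), class = "capture_history")
  })
  unname(histories)
}

#' @export
print.capture_history <- function(x, ...) {
  det <- x$years[x$y == 1L]
  cat("<capture_history> ", x$individual_id, " (", x$ringed_as, ", sex ",
      x$sex, "): detected ", paste(det, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Derive dispersal events from capture histories
#'
#' A dispersal event is a breeding (or first-breeding) attempt at a
#' different farm than the last breeding or fledging site: every pair of
#' consecutive detections within a history yields one event, dispersed or
#' not, regardless of the gap length between the detections. The event is
#' natal (`juvenile`) when it leaves the ringing site of a nestling-ringed
#' bird, breeding (`adult`) otherwise.
#'
#' @param histories List of `capture_history`.
#' @param farms A `farm_table`.
#' @return A `data.frame` with one row per event: `individual_id`,
#'   `year_from`, `year_to`, `origin_farm`, `dest_farm`, `age_class`
#'   (`juvenile`/`adult`), `sex`, `dispersed`, `distance` (planar
#'   Euclidean, km), `raw_shift` (m, destination minus origin elevation)
#'   and `corrected_shift` (NA until filled by [add_corrected_shifts()]).
#' @export
derive_dispersal_events <- function(histories, farms) {
  rows <- lapply(histories, function(h) {
    det <- which(h$y == 1L)
    if (length(det) < 2L) return(NULL)
    from <- det[-length(det)]
    to <- det[-1L]
    origin <- h$farm_at[from]
    dest <- h$farm_at[to]
    oi <- match(origin, farms$farm_id)
    di <- match(dest, farms$farm_id)
    data.frame(
      individual_id = h$individual_id,
      year_from = h$years[from],
      year_to = h$years[to],
      origin_farm = origin,
      dest_farm = dest,
      age_class = ifelse(h$ringed_as == "nestling" & from == h$first_occ,
                         "juvenile", "adult"),
      sex = h$sex,
      dispersed = origin != dest,
      distance = sqrt((farms$x[di] - farms$x[oi])^2 +
                      (farms$y[di] - farms$y[oi])^2) / 1000,
      raw_shift = farms$elevation[di] - farms$elevation[oi],
      corrected_shift = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  if (is.null(out)) {
    out <- data.frame(individual_id = character(), year_from = integer(),
                      year_to = integer(), origin_farm = character(),
                      dest_farm = character(), age_class = character(),
                      sex = character(), dispersed = logical(),
                      distance = numeric(), raw_shift = numeric(),
                      corrected_shift = numeric(), stringsAsFactors = FALSE)
  }
  class(out) <- c("dispersal_events", "data.frame")
  out
}

#' Centre and scale a numeric predictor
#'
#' All numeric predictors of the models are centred and scaled to unit
#' sample variance before fitting; the returned standardizer carries the
#' fitted mean/SD so new values (e.g. a prediction grid in meters) can be
#' mapped onto the model scale and back.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return A list with `values` (the standardized vector) and
#'   `standardizer` (a list with `mean` and `sd`).
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need a numeric vector of length >= 2")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant vector (SD = 0)")
  std <- list(mean = mean(values), sd = s)
  class(std) <- "standardizer"
  list(values = (values - std$mean) / std$sd, standardizer = std)
}

#' Apply a fitted standardizer
#' @param std A `standardizer` from [standardize()].
#' @param x Numeric values on the original scale.
#' @export
std_apply <- function(std, x) (x - std$mean) / std$sd

#' Invert a fitted standardizer
#' @param std A `standardizer`.
#' @param z Values on the standardized scale.
#' @export
std_invert <- function(std, z) z * std$sd + std$mean

#' Write a dispersal-event table
#' @param events A `dispersal_events` data frame.
#' @param path Output CSV path; `corrected_shift` is blank when unfilled.
#' @export
write_events <- function(events, path) {
  out <- as.data.frame(events)
  out$dispersed <- as.integer(out$dispersed)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
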