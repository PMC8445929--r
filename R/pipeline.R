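#' Apparent survival versus elevation with a credible band
#'
#' Pointwise posterior summary of annual apparent survival over an
#' elevation grid for one class (adult male, adult female or juvenile),
#' at centre sites with farm/year deviates at zero.
#'
#' @param posterior A `cjs_posterior` from [fit_cjs()].
#' @param elev_grid Elevations in meters.
#' @param standardizer The elevation standardizer the model was fitted
#'   with.
#' @param class `"adult_male"`, `"adult_female"` or `"juvenile"`.
#' @return Data frame: `elevation`, `median`, `lo95`, `hi95`.
#' @export
predict_survival_curve <- function(posterior, elev_grid, standardizer,
                                   class = c("adult_male", "adult_female",
                                             "juvenile")) {
  class <- match.arg(class)
  z <- std_apply(standardizer, elev_grid)
  col0 <- paste0("phi_intercept_", class)
  col1 <- paste0("phi_elevation_", class)
  b0 <- posterior$draws[, col0]
  b1 <- posterior$draws[, col1]
  phi <- plogis(outer(b0, rep(1, length(z))) + outer(b1, z))
  data.frame(
    elevation = elev_grid,
    median = apply(phi, 2, quantile, 0.5, names = FALSE),
    lo95 = apply(phi, 2, quantile, 0.025, names = FALSE),
    hi95 = apply(phi, 2, quantile, 0.975, names = FALSE))
}

#' Descriptive counts of the mark-recapture data
#'
#' Counts of ringed individuals by ringing age, recaptured individuals,
#' recapture events, dispersal events, and the juvenile/adult dispersal
#' percentages (rounded to the nearest integer, matching the reporting
#' convention of the field).
#'
#' @param histories List of `capture_history`.
#' @param events A `dispersal_events` data frame.
#' @return Data frame with columns `metric` and `value`.
#' @export
summarize_descriptives <- function(histories, events) {
  ringed_as <- vapply(histories, function(h) h$ringed_as, "")
  n_det <- vapply(histories, function(h) sum(h$y), 0L)
  juv <- events$age_class == "juvenile"
  pct <- function(x) if (length(x)) round(100 * mean(x)) else 0
  data.frame(
    metric = c("ringed", "ringed_nestlings", "ringed_adults",
               "recaptured_individuals", "recapture_events",
               "dispersal_events", "juvenile_recaptures",
               "adult_recaptures", "juvenile_dispersal_pct",
               "adult_dispersal_pct"),
    value = c(length(histories), sum(ringed_as == "nestling"),
              sum(ringed_as == "adult"), sum(n_det > 1L), nrow(events),
              sum(events$dispersed), sum(juv), sum(!juv),
              pct(events$dispersed[juv]), pct(events$dispersed[!juv])),
    stringsAsFactors = FALSE)
}

#' Configuration of a full pipeline run
#'
#' @param sim A [sim_config()] used when no input CSVs are given; its
#'   seed is overridden by `seed` so one seed determines the whole run.
#' @param farms_csv,captures_csv Optional paths to observed input tables;
#'   when given, simulation is skipped.
#' @param years Inclusive year range of the occasions; default derived
#'   from `sim`.
#' @param mcmc A [cjs_mcmc_config()].
#' @param priors A [cjs_priors()].
#' @param n_draws Simulated-posterior draws for the regression tables.
#' @param seed Integer master seed for every stochastic stage.
#' @param out_dir Output directory (created if needed).
#' @param make_figures Write PDF figures (default TRUE).
#' @export
run_config <- function(sim = sim_config(), farms_csv = NULL,
                       captures_csv = NULL, years = NULL,
                       mcmc = cjs_mcmc_config(), priors = cjs_priors(),
                       n_draws = 2000L, seed = 1L, out_dir = tempfile("run"),
                       make_figures = TRUE) {
  sim$seed <- as.integer(seed)
  if (is.null(years))
    years <- c(sim$start_year, sim$start_year + sim$years - 1L)
  structure(list(sim = sim, farms_csv = farms_csv,
                 captures_csv = captures_csv, years = years, mcmc = mcmc,
                 priors = priors, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), out_dir = out_dir,
                 make_figures = make_figures),
            class = "run_config")
}

stage <- function(name, counts, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message("[", name, "] ", counts(res))
  res
}

fmt_sd <- function(x) ifelse(x < 0.01, "<0.01", sprintf("%.3f", x))

regression_table <- function(fit, sim_post) {
  fixed <- data.frame(
    parameter = sim_post$table$label,
    estimate = sprintf("%.3f", sim_post$table$estimate),
    lo95 = sprintf("%.3f", sim_post$table$lo95),
    hi95 = sprintf("%.3f", sim_post$table$hi95),
    stringsAsFactors = FALSE)
  re <- data.frame(
    parameter = c("Individual", "Location", "Year"),
    estimate = fmt_sd(unname(fit$ranef_sd)),
    lo95 = "", hi95 = "", stringsAsFactors = FALSE)
  rbind(fixed, re)
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> build histories and events -> fit the survival
#' model -> corrected shifts -> fit the three dispersal models -> write
#' report tables, figures and a machine-readable run log. Any stage
#' failure aborts with the stage name; outputs of completed stages are
#' preserved in the output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects, tables and paths.
#' @export
run_all <- function(config) {
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL

  if (is.null(config$farms_csv)) {
    farms <- stage("simulate-farms", function(f) paste(nrow(f), "farms"),
                   generate_farms(config$sim))
    sim <- stage("simulate-histories",
                 function(s) paste(nrow(s$captures), "capture records"),
                 simulate_histories(farms, config$sim))
    captures <- sim$captures
    truth <- sim$truth
    write_farms(farms, file.path(out, "farms.csv"))
    write_captures(captures, file.path(out, "captures.csv"))
    jsonlite::write_json(
      list(cjs = truth$cjs[c("beta0", "beta1", "beta2", "alpha0", "alpha1",
                             "f_male", "sigma_delta", "sigma_gamma",
                             "sigma_rho", "delta", "gamma", "rho")],
           dispersal = unclass(truth$dispersal),
           dispersal_year_effects = truth$dispersal_year_effects,
           sex = truth$sex, ringed_as = truth$ringed_as,
           ring_year = truth$ring_year, ring_farm = truth$ring_farm,
           z = truth$z, site = truth$site),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    farms <- stage("read-farms", function(f) paste(nrow(f), "farms"),
                   read_farms(config$farms_csv))
    captures <- stage("read-captures",
                      function(cp) paste(nrow(cp), "capture records"),
                      read_captures(config$captures_csv, farms))
  }

  std <- standardize(farms$elevation)$standardizer
  histories <- stage("build-histories",
                     function(h) paste(length(h), "histories"),
                     build_histories(captures, farms, config$years, std))
  events <- stage("derive-events",
                  function(e) paste(nrow(e), "events,",
                                    sum(e$dispersed), "dispersals"),
                  derive_dispersal_events(histories, farms))
  events <- stage("corrected-shift",
                  function(e) paste(sum(!is.na(e$corrected_shift)),
                                    "shifts filled"),
                  add_corrected_shifts(events, farms))
  write_events(events, file.path(out, "events_with_shift.csv"))
  descr <- summarize_descriptives(histories, events)
  write.csv(descr, file.path(out, "descriptives.csv"), row.names = FALSE)

  cjs_dat <- prepare_cjs_data(histories, farms)
  post <- stage("fit-survival",
                function(p) paste(nrow(p$draws), "pooled draws"),
                fit_cjs(cjs_dat, config$mcmc, seed = config$seed,
                        priors = config$priors))
  tab1 <- post$summary[, c("label", "mean", "lo95", "hi95")]
  names(tab1)[1] <- "parameter"
  write.csv(tab1, file.path(out, "table1.csv"), row.names = FALSE)
  write.csv(as.data.frame(post$draws), file.path(out, "survival_draws.csv"),
            row.names = FALSE)

  prob_fit <- stage("fit-dispersal-probability",
                    function(f) paste(length(f$coef), "fixed effects"),
                    fit_glmm_binomial(build_design(events, "probability",
                                                   farms, std)))
  prob_sim <- simulate_posterior(prob_fit, config$n_draws, config$seed)
  write.csv(regression_table(prob_fit, prob_sim),
            file.path(out, "table2.csv"), row.names = FALSE)

  disp <- events[events$dispersed, , drop = FALSE]
  dist_fit <- stage("fit-dispersal-distance",
                    function(f) paste("residual SD", round(f$sigma, 2), "km"),
                    fit_lmm_gaussian(build_design(disp, "distance", farms,
                                                  std)))
  dist_sim <- simulate_posterior(dist_fit, config$n_draws, config$seed)
  shift_fit <- stage("fit-elevational-shift",
                     function(f) paste("residual SD", round(f$sigma), "m"),
                     fit_lmm_gaussian(build_design(disp, "shift", farms,
                                                   std)))
  shift_sim <- simulate_posterior(shift_fit, config$n_draws, config$seed)
  tab3 <- rbind(cbind(model = "distance_km",
                      regression_table(dist_fit, dist_sim)),
                cbind(model = "corrected_shift_m",
                      regression_table(shift_fit, shift_sim)))
  write.csv(tab3, file.path(out, "table3.csv"), row.names = FALSE)

  if (config$make_figures)
    tryCatch(pipeline_figures(out, post, prob_fit, events, farms, std,
                              config),
             error = function(e) warning("figure stage skipped: ",
                                         conditionMessage(e)))

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  run_log <- list(
    seed = config$seed, years = config$years,
    simulated = is.null(config$farms_csv),
    mcmc = config$mcmc, n_draws = config$n_draws,
    counts = setNames(as.list(descr$value), descr$metric),
    cjs_converged = post$converged,
    cjs_min_ess = min(post$summary$ess),
    wall_time_s = elapsed,
    package_version = as.character(utils::packageVersion("elevcmr")))
  jsonlite::write_json(run_log, file.path(out, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[done] ", round(elapsed, 1), " s -> ", out)
  invisible(list(farms = farms, captures = captures, truth = truth,
                 histories = histories, events = events,
                 descriptives = descr, cjs = post, prob_fit = prob_fit,
                 prob_sim = prob_sim, dist_fit = dist_fit,
                 dist_sim = dist_sim, shift_fit = shift_fit,
                 shift_sim = shift_sim, out_dir = out))
}

band_plot <- function(df, ylab, main, ylim = NULL, col = "steelblue") {
  if (is.null(ylim)) ylim <- range(df$lo95, df$hi95)
  yc <- if ("median" %in% names(df)) df$median else df$mean
  plot(df$elevation, yc, type = "n", ylim = ylim,
       xlab = "Elevation (m a.s.l.)", ylab = ylab, main = main)
  graphics::polygon(c(df$elevation, rev(df$elevation)),
                    c(df$lo95, rev(df$hi95)),
                    col = grDevices::adjustcolor(col, 0.3), border = NA)
  graphics::lines(df$elevation, yc, col = col, lwd = 2)
}

pipeline_figures <- function(out, post, prob_fit, events, farms, std,
                             config) {
  grid <- seq(min(farms$elevation), max(farms$elevation), length.out = 50L)
  grDevices::pdf(file.path(out, "survival_vs_elevation.pdf"), 7, 5)
  cols <- c(adult_male = "steelblue", adult_female = "firebrick",
            juvenile = "black")
  first <- TRUE
  for (cls in names(cols)) {
    cv <- predict_survival_curve(post, grid, std, cls)
    if (first) {
      band_plot(cv, "Apparent survival", "Apparent survival vs elevation",
                ylim = c(0, 1), col = cols[[cls]])
      first <- FALSE
    } else {
      graphics::polygon(c(cv$elevation, rev(cv$elevation)),
                        c(cv$lo95, rev(cv$hi95)),
                        col = grDevices::adjustcolor(cols[[cls]], 0.3),
                        border = NA)
      graphics::lines(cv$elevation, cv$median, col = cols[[cls]], lwd = 2)
    }
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2)
  grDevices::dev.off()

  grDevices::pdf(file.path(out, "dispersal_vs_elevation.pdf"), 7, 5)
  classes <- c(adult_male = "steelblue", adult_female = "firebrick",
               juvenile_male = "lightblue3", juvenile_female = "salmon")
  first <- TRUE
  for (cls in names(classes)) {
    cv <- predict_dispersal_curve(prob_fit, grid, cls,
                                  n_draws = config$n_draws,
                                  seed = config$seed)
    if (first) {
      band_plot(cv, "Dispersal probability",
                "Dispersal probability vs elevation", ylim = c(0, 1),
                col = classes[[cls]])
      first <- FALSE
    } else {
      graphics::lines(cv$elevation, cv$median, col = classes[[cls]], lwd = 2)
    }
  }
  graphics::legend("bottomright", legend = names(classes), col = classes,
                   lwd = 2)
  grDevices::dev.off()

  disp <- events[events$dispersed, , drop = FALSE]
  if (nrow(disp) >= 8L) {
    sm <- shift_vs_elevation_summary(disp, farms, grid,
                                     n_draws = config$n_draws,
                                     seed = config$seed)
    grDevices::pdf(file.path(out, "shift_vs_elevation.pdf"), 7, 5)
    juv <- sm[sm$age_class == "juvenile", ]
    ad <- sm[sm$age_class == "adult", ]
    band_plot(juv, "Corrected elevational shift (m)",
              "Corrected shift vs elevation",
              ylim = range(sm$lo95, sm$hi95), col = "darkorange")
    graphics::polygon(c(ad$elevation, rev(ad$elevation)),
                      c(ad$lo95, rev(ad$hi95)),
                      col = grDevices::adjustcolor("darkgreen", 0.3),
                      border = NA)
    graphics::lines(ad$elevation, ad$mean, col = "darkgreen", lwd = 2)
    graphics::abline(h = 0, lty = 2)
    graphics::legend("topright", legend = c("juvenile", "adult"),
                     col = c("darkorange", "darkgreen"), lwd = 2)
    grDevices::dev.off()
  }
  invisible(NULL)
}
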