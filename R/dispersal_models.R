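DISPERSAL_MODELS <- c("probability", "distance", "shift")

PROB_TERMS <- c("intercept", "elevation", "age_adult", "sex_female",
                "edge", "elevation_x_female", "elevation_x_adult")
PROB_LABELS <- c("Intercept", "Elevation (z-transformed)", "Age (adult)",
                 "Sex (female)", "Location within study area",
                 "Elevation x sex (female)", "Elevation x age (adult)")
GAUSS_TERMS <- c("intercept", "age_adult", "elevation", "sex_female",
                 "elevation_x_adult", "elevation_x_female",
                 "adult_x_female")
GAUSS_LABELS <- c("Intercept", "Age (adult)", "Elevation (z-transformed)",
                  "Sex (female)", "Elevation x age (adult)",
                  "Elevation x sex (female)", "Age (adult) x sex (female)")

#' Build the design of a dispersal regression
#'
#' Treatment-coded design (reference cell: juvenile, male, centre) for
#' one of the three dispersal models: `probability` (binary dispersed
#' indicator over all recapture events; includes the edge covariate and
#' the elevation-by-sex and elevation-by-age interactions), `distance`
#' and `shift` (Gaussian responses over dispersal events only; drop edge,
#' add the age-by-sex interaction). Elevation of the origin farm is
#' standardized. Grouping factors for the random intercepts are
#' individual, origin farm (location) and year.
#'
#' @param events A `dispersal_events` data frame; for `distance`/`shift`
#'   every event must have `dispersed = TRUE` (and a filled
#'   `corrected_shift` for `shift`).
#' @param model `"probability"`, `"distance"` or `"shift"`.
#' @param farms The `farm_table` supplying origin elevations and edge.
#' @param standardizer Elevation standardizer; default fitted on the farm
#'   table's elevations.
#' @return A `dispersal_design`: data frame of response, covariate
#'   columns and grouping factors, with the model type and term labels
#'   attached.
#' @export
build_design <- function(events, model = c("probability", "distance", "shift"),
                         farms, standardizer = NULL) {
  model <- match.arg(model)
  if (is.null(standardizer))
    standardizer <- standardize(farms$elevation)$standardizer
  oi <- match(events$origin_farm, farms$farm_id)
  if (anyNA(oi)) stop("origin_farm not present in farm table")
  if (model != "probability" && any(!events$dispersed))
    stop("the ", model, " model is restricted to dispersed events")
  y <- switch(model,
    probability = as.numeric(events$dispersed),
    distance = events$distance,
    shift = {
      if (anyNA(events$corrected_shift))
        stop("corrected_shift missing; run add_corrected_shifts() first")
      events$corrected_shift
    })
  elev <- std_apply(standardizer, farms$elevation[oi])
  adult <- as.numeric(events$age_class == "adult")
  female <- as.numeric(events$sex == "female")
  df <- data.frame(
    y = y, elevation = elev, age_adult = adult, sex_female = female,
    edge = as.numeric(farms$edge[oi]),
    elevation_x_female = elev * female,
    elevation_x_adult = elev * adult,
    adult_x_female = adult * female,
    individual_id = factor(events$individual_id),
    origin_farm = factor(events$origin_farm),
    year = factor(events$year_from),
    stringsAsFactors = FALSE)
  structure(df, class = c("dispersal_design", "data.frame"),
            model = model,
            terms = if (model == "probability") PROB_TERMS else GAUSS_TERMS,
            labels = if (model == "probability") PROB_LABELS else GAUSS_LABELS,
            standardizer = standardizer)
}

GROUPING <- c(individual = "individual_id", location = "origin_farm",
              year = "year")

design_formula <- function(design, groups = GROUPING) {
  fixed <- setdiff(attr(design, "terms"), "intercept")
  stats::reformulate(c(fixed, sprintf("(1 | %s)", groups)), response = "y")
}

ranef_sds <- function(mod) {
  vc <- lme4::VarCorr(mod)
  out <- setNames(numeric(length(GROUPING)), names(GROUPING))
  for (g in names(GROUPING)) {
    v <- vc[[GROUPING[[g]]]]
    if (!is.null(v)) out[g] <- sqrt(v[1, 1])
  }
  out
}

new_mixed_fit <- function(design, coef, vcov, ranef_sd, sigma, flagged,
                          note = NULL, model_obj = NULL) {
  terms <- attr(design, "terms")
  if (length(coef) != length(terms)) {
    const <- setdiff(terms, "intercept")
    const <- const[vapply(const, function(cn) var(design[[cn]]) == 0, TRUE)]
    stop("design is rank deficient (fitted ", length(coef), " of ",
         length(terms), " coefficients",
         if (length(const)) paste0("; constant column(s): ",
                                   paste(const, collapse = ", ")), ")")
  }
  names(coef) <- terms
  dimnames(vcov) <- list(terms, terms)
  structure(list(model = attr(design, "model"), coef = coef, vcov = vcov,
                 ranef_sd = ranef_sd, sigma = sigma,
                 labels = attr(design, "labels"),
                 standardizer = attr(design, "standardizer"),
                 flagged = flagged, note = note, fit = model_obj),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> dispersal ", x$model,
      if (x$flagged) " [FLAGGED]", "\n", sep = "")
  print(round(x$coef, 3))
  cat("random-effect SDs:\n"); print(round(x$ranef_sd, 3))
  invisible(x)
}

#' Fit the binomial dispersal-probability mixed model
#'
#' Laplace-approximation ML fit of the logistic model with Normal random
#' intercepts for individual, origin farm and year. Boundary fits
#' (a variance estimated at zero) are returned as SD 0 without error.
#' Apparent complete separation (non-finite or extreme coefficients) is
#' flagged with a warning and the coefficients are replaced by a weakly
#' ridge-penalized logistic fit (Normal(0, 2.5^2) penalty, random effects
#' dropped) so that finite estimates are always reported.
#'
#' @param design A `dispersal_design` with model `"probability"`.
#' @param theta_zero Force all random-effect SDs to zero (the fit then
#'   reduces to ordinary logistic regression; used by limit checks).
#' @return A `mixed_fit`.
#' @export
fit_glmm_binomial <- function(design, theta_zero = FALSE) {
  stopifnot(attr(design, "model") == "probability")
  if (length(unique(design$y)) < 2L)
    stop("binary response is constant; nothing to fit")
  df <- as.data.frame(design)
  form <- design_formula(design)
  if (theta_zero) {
    fm <- lme4::glFormula(form, data = df, family = stats::binomial())
    devfun <- do.call(lme4::mkGlmerDevfun, fm)
    devfun <- lme4::updateGlmerDevfun(devfun, fm$reTrms)
    nth <- length(fm$reTrms$theta)
    p <- ncol(fm$X)
    obj <- function(beta) devfun(c(rep(0, nth), beta))
    opt <- stats::optim(rep(0, p), obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    H <- stats::optimHess(opt$par, obj)
    vc <- tryCatch(2 * solve(H), error = function(e) diag(NA_real_, p))
    return(new_mixed_fit(design, opt$par, vc,
                         c(individual = 0, location = 0, year = 0),
                         sigma = NA_real_, flagged = FALSE,
                         note = "random-effect variances fixed at zero"))
  }
  glmer_try <- function(groups) suppressMessages(suppressWarnings(
    lme4::glmer(design_formula(design, GROUPING[groups]), data = df,
                family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore"))))
  # With at most a handful of observations per individual, the ML of a
  # group variance on the Bernoulli scale can diverge. Drop any random
  # intercept whose SD runs away and report it on the zero boundary.
  groups <- names(GROUPING)
  mod <- glmer_try(groups)
  repeat {
    sds <- ranef_sds(mod)
    bad <- intersect(groups, names(sds)[sds > 10])
    if (!length(bad)) break
    warning("random-intercept SD for ", paste(bad, collapse = ", "),
            " diverged on the logit scale; refit with the term(s) ",
            "removed and the SD reported at the zero boundary")
    groups <- setdiff(groups, bad)
    if (!length(groups)) {
      fit0 <- fit_glmm_binomial(design, theta_zero = TRUE)
      fit0$ranef_sd[] <- 0
      fit0$flagged <- TRUE
      fit0$note <- "all random-intercept variances diverged; fixed at zero"
      return(fit0)
    }
    mod <- glmer_try(groups)
  }
  sds <- ranef_sds(mod)
  sds[setdiff(names(GROUPING), groups)] <- 0
  beta <- lme4::fixef(mod)
  vc <- as.matrix(stats::vcov(mod))
  separated <- any(!is.finite(beta)) || any(abs(beta) > 15) ||
    any(!is.finite(diag(vc)))
  if (separated) {
    warning("apparent complete separation; reporting ridge-penalized ",
            "logistic coefficients (flagged)")
    X <- cbind(1, as.matrix(df[, setdiff(attr(design, "terms"), "intercept")]))
    pen <- penalized_irls(X, df$y, lambda = 1 / 2.5^2)
    return(new_mixed_fit(design, pen$beta, pen$vcov,
                         sds, sigma = NA_real_, flagged = TRUE,
                         note = "separation fallback: ridge-penalized logistic",
                         model_obj = mod))
  }
  new_mixed_fit(design, unname(beta), vc, sds, sigma = NA_real_,
                flagged = FALSE, model_obj = mod)
}

# ridge-penalized IRLS for the separation fallback
penalized_irls <- function(X, y, lambda = 0.16, max_iter = 200) {
  p <- ncol(X)
  beta <- rep(0, p)
  P <- diag(lambda, p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-10) break
  }
  list(beta = beta, vcov = solve(H))
}

#' Fit a Gaussian dispersal mixed model (distance or shift)
#'
#' REML fit with Normal random intercepts for individual, origin farm
#' and year, plus a residual SD. Singular fits (a variance on the zero
#' boundary) are returned with the near-zero SD and a warning.
#'
#' @param design A `dispersal_design` with model `"distance"` or
#'   `"shift"`.
#' @param theta_zero Force all random-effect SDs to zero (the fit then
#'   reduces to ordinary least squares; used by limit checks).
#' @return A `mixed_fit`.
#' @export
fit_lmm_gaussian <- function(design, theta_zero = FALSE) {
  stopifnot(attr(design, "model") %in% c("distance", "shift"))
  if (nrow(design) < 5L) stop("need at least 5 observations")
  if (any(!is.finite(design$y))) stop("non-finite response")
  df <- as.data.frame(design)
  form <- design_formula(design)
  if (theta_zero) {
    fm <- lme4::lFormula(form, data = df,
                         control = lme4::lmerControl(
                           check.nobs.vs.nlev = "ignore",
                           check.nobs.vs.nRE = "ignore"))
    devfun <- do.call(lme4::mkLmerDevfun, fm)
    devfun(rep(0, length(fm$reTrms$theta)))
    rho <- environment(devfun)
    beta <- rho$pp$beta(1)
    X <- fm$X
    rss <- sum((df$y - as.numeric(X %*% beta))^2)
    s2 <- rss / (nrow(X) - ncol(X))
    vc <- s2 * solve(crossprod(X))
    return(new_mixed_fit(design, beta, vc,
                         c(individual = 0, location = 0, year = 0),
                         sigma = sqrt(s2), flagged = FALSE,
                         note = "random-effect variances fixed at zero"))
  }
  mod <- suppressMessages(lme4::lmer(
    form, data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore")))
  sds <- ranef_sds(mod)
  flagged <- lme4::isSingular(mod, tol = 1e-5)
  if (flagged)
    warning("singular fit: a random-effect variance is on the zero boundary")
  new_mixed_fit(design, unname(lme4::fixef(mod)),
                as.matrix(stats::vcov(mod)), sds,
                sigma = stats::sigma(mod), flagged = flagged,
                model_obj = mod)
}

#' Simulated posterior of the fixed effects
#'
#' Draws from the asymptotic multivariate normal approximation of the
#' posterior of the fixed effects under flat priors (mean = point
#' estimates, covariance = estimated coefficient covariance), and reports
#' the 2.5%/97.5% empirical quantiles of the default 2000 draws as 95%
#' credible intervals. Random-effect uncertainty is not simulated.
#'
#' @param fit A `mixed_fit`.
#' @param n_draws Number of draws (default 2000).
#' @param seed Integer seed.
#' @return A list with `draws` (n_draws x p matrix) and `table` (data
#'   frame: parameter, label, estimate, lo95, hi95).
#' @export
simulate_posterior <- function(fit, n_draws = 2000L, seed = 1L) {
  V <- fit$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || min(ev) < -1e-8 * max(abs(ev)))
    stop("coefficient covariance is not positive definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  L <- chol(V + diag(1e-12 * max(ev), nrow(V)))
  set.seed(seed)
  z <- matrix(rnorm(n_draws * nrow(V)), n_draws)
  draws <- sweep(z %*% L, 2L, fit$coef, "+")
  colnames(draws) <- names(fit$coef)
  tab <- data.frame(
    parameter = names(fit$coef), label = fit$labels,
    estimate = unname(fit$coef),
    lo95 = apply(draws, 2, quantile, 0.025, names = FALSE),
    hi95 = apply(draws, 2, quantile, 0.975, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  list(draws = draws, table = tab)
}

#' Dispersal probability versus elevation with a credible band
#'
#' Pointwise inverse-logit of the linear predictor per posterior draw for
#' one age/sex class at centre sites with random effects at zero; returns
#' the pointwise median and the 2.5%/97.5% band.
#'
#' @param fit A `mixed_fit` for the probability model.
#' @param elev_grid Elevations in meters (converted with the fit's
#'   standardizer).
#' @param class One of `"juvenile_male"`, `"juvenile_female"`,
#'   `"adult_male"`, `"adult_female"`.
#' @param n_draws,seed Passed to [simulate_posterior()].
#' @return Data frame: `elevation`, `median`, `lo95`, `hi95`.
#' @export
predict_dispersal_curve <- function(fit, elev_grid, class, n_draws = 2000L,
                                    seed = 1L) {
  stopifnot(fit$model == "probability")
  classes <- c("juvenile_male", "juvenile_female", "adult_male",
               "adult_female")
  if (!class %in% classes)
    stop("class must be one of: ", paste(classes, collapse = ", "))
  adult <- as.numeric(grepl("^adult", class))
  female <- as.numeric(grepl("female$", class))
  z <- std_apply(fit$standardizer, elev_grid)
  X <- cbind(1, z, adult, female, 0, z * female, z * adult)
  draws <- simulate_posterior(fit, n_draws = n_draws, seed = seed)$draws
  eta <- draws %*% t(X)
  p <- plogis(eta)
  data.frame(
    elevation = elev_grid,
    median = apply(p, 2, quantile, 0.5, names = FALSE),
    lo95 = apply(p, 2, quantile, 0.025, names = FALSE),
    hi95 = apply(p, 2, quantile, 0.975, names = FALSE))
}
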