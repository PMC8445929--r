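SURV_CLASSES <- c("adult_male", "adult_female", "juvenile")

#' Parameters of the hierarchical survival model
#'
#' Container for all parameters of the Cormack-Jolly-Seber model with an
#' integrated categorical sex mixture. Apparent survival is modelled on
#' the log-odds scale per class (adult male, adult female, juvenile --
#' juveniles share parameters across the sexes), with a standardized
#' elevation slope per class, an edge effect, a farm-level random
#' intercept `delta` and a year random intercept `gamma`. Recapture
#' probability has an adult intercept/slope plus first-year offsets and a
#' year random intercept `rho`. `f_male` is the proportion of males in the
#' categorical sex model, which both weights the mixture for unsexed
#' individuals and is informed by the sexed ones.
#'
#' @param beta0,beta1 Named numeric length-3 (`adult_male`,
#'   `adult_female`, `juvenile`): survival intercepts and
#'   standardized-elevation slopes on the log-odds scale.
#' @param beta2 Edge effect on survival (log-odds; centre = 0, edge = 1).
#' @param alpha0,alpha1 Named numeric length-2 (`adult`,
#'   `juvenile_offset`): recapture intercept/slope for adults and the
#'   first-year offsets added to them.
#' @param f_male Proportion of males, in (0, 1).
#' @param sigma_delta,sigma_gamma,sigma_rho Non-negative SDs of the farm
#'   (survival), year (survival) and year (recapture) random intercepts.
#' @param delta,gamma,rho Random-intercept deviates (lengths: number of
#'   farms, of years, of years); all-zero by default.
#' @param n_farms,n_years Lengths used for the default all-zero deviates.
#' @return A `cjs_params` list.
#' @export
cjs_params <- function(beta0 = c(adult_male = 0, adult_female = 0, juvenile = 0),
                       beta1 = c(adult_male = 0, adult_female = 0, juvenile = 0),
                       beta2 = 0,
                       alpha0 = c(adult = 0, juvenile_offset = 0),
                       alpha1 = c(adult = 0, juvenile_offset = 0),
                       f_male = 0.5,
                       sigma_delta = 0, sigma_gamma = 0, sigma_rho = 0,
                       delta = NULL, gamma = NULL, rho = NULL,
                       n_farms = if (is.null(delta)) 1L else length(delta),
                       n_years = if (is.null(gamma)) 1L else length(gamma)) {
  if (is.null(delta)) delta <- numeric(n_farms)
  if (is.null(gamma)) gamma <- numeric(n_years)
  if (is.null(rho)) rho <- numeric(n_years)
  stopifnot(length(beta0) == 3L, length(beta1) == 3L,
            length(alpha0) == 2L, length(alpha1) == 2L,
            length(gamma) == length(rho))
  names(beta0) <- names(beta1) <- SURV_CLASSES
  names(alpha0) <- names(alpha1) <- c("adult", "juvenile_offset")
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 alpha0 = alpha0, alpha1 = alpha1, f_male = f_male,
                 sigma_delta = sigma_delta, sigma_gamma = sigma_gamma,
                 sigma_rho = sigma_rho,
                 delta = delta, gamma = gamma, rho = rho),
            class = "cjs_params")
}

#' Linear predictor of apparent survival
#'
#' Log-odds of surviving (and staying in the study area) over the annual
#' interval ending at the given occasion, for an individual of the given
#' class at a site with the given standardized elevation and edge status.
#'
#' @param params A [cjs_params()].
#' @param class One of `"adult_male"`, `"adult_female"`, `"juvenile"`.
#' @param std_elevation Elevation on the standardized scale.
#' @param edge Logical; site at the edge of the study area.
#' @param farm_index,year_index 1-based indices into the deviate vectors.
#' @return The log-odds; `plogis()` of it is the survival probability.
#' @export
survival_logit <- function(params, class, std_elevation, edge,
                           farm_index = 1L, year_index = 1L) {
  if (!all(class %in% SURV_CLASSES))
    stop("unknown survival class: ", paste(setdiff(class, SURV_CLASSES), collapse = ", "))
  if (any(farm_index < 1L | farm_index > length(params$delta)) ||
      any(year_index < 1L | year_index > length(params$gamma)))
    stop("farm or year index out of range")
  params$beta0[class] + params$beta1[class] * std_elevation +
    params$beta2 * as.numeric(edge) +
    params$delta[farm_index] + params$gamma[year_index]
}

#' Linear predictor of recapture probability
#'
#' @param params A [cjs_params()].
#' @param age `"adult"` or `"first_year"` (adult parameters plus the
#'   first-year offsets).
#' @param std_elevation Standardized elevation of the current site.
#' @param year_index 1-based index into `rho`.
#' @export
recapture_logit <- function(params, age, std_elevation, year_index = 1L) {
  if (!all(age %in% c("adult", "first_year")))
    stop("unknown recapture age class: ", paste(setdiff(age, c("adult", "first_year")), collapse = ", "))
  juv <- as.numeric(age == "first_year")
  params$alpha0[["adult"]] + juv * params$alpha0[["juvenile_offset"]] +
    (params$alpha1[["adult"]] + juv * params$alpha1[["juvenile_offset"]]) *
      std_elevation +
    params$rho[year_index]
}

# Per-occasion survival/recapture probabilities for one history and sex.
# Interval (t-1, t] survival uses the origin site's covariates (occasion
# t-1, carry-forward) and gamma_t; recapture at t uses the site at t.
history_probs <- function(history, params, sex) {
  T <- length(history$y)
  f0 <- history$first_occ
  phi <- rep(NA_real_, T)
  p <- rep(NA_real_, T)
  if (f0 < T) {
    for (t in seq.int(f0 + 1L, T)) {
      cls <- if (history$age_class_at[t] == "first_year") "juvenile"
             else if (sex == "male") "adult_male" else "adult_female"
      phi[t] <- plogis(survival_logit(
        params, cls, history$std_elevation_at[t - 1L],
        history$edge_at[t - 1L], history$farm_idx[t - 1L], t))
      age <- if (history$age_class_at[t] == "first_year") "first_year" else "adult"
      p[t] <- plogis(recapture_logit(
        params, age, history$std_elevation_at[t], t))
    }
  }
  list(phi = phi, p = p)
}

# chi[t]: probability an individual alive at occasion t is never detected
# again. Backward recursion chi[T] = 1, chi[t] = (1 - phi[t+1]) +
# phi[t+1] (1 - p[t+1]) chi[t+1].
chi_recursion <- function(phi, p) {
  T <- length(phi)
  chi <- rep(1, T)
  if (T > 1L) for (t in seq.int(T - 1L, 1L))
    chi[t] <- (1 - phi[t + 1L]) + phi[t + 1L] * (1 - p[t + 1L]) * chi[t + 1L]
  chi
}

#' Sex-conditional log-likelihood of one capture history
#'
#' Exact marginal probability of the detection sequence after first
#' capture, with the latent alive state summed out via the standard CJS
#' decomposition: survival and detection terms up to the last detection
#' times the never-seen-again tail probability chi.
#'
#' @param history A `capture_history`.
#' @param params A [cjs_params()] whose deviate vectors cover the
#'   history's farm and year indices.
#' @param sex `"male"` or `"female"` (conditioning value, regardless of
#'   whether the history's sex is known).
#' @return Log-likelihood (0 for a history first captured at the final
#'   occasion, which carries no information).
#' @export
history_loglik_given_sex <- function(history, params, sex) {
  stopifnot(inherits(history, "capture_history"))
  sex <- match.arg(sex, c("male", "female"))
  f0 <- history$first_occ
  if (any(history$y[seq_len(f0 - 1L)] == 1L))
    stop("detection before first capture year violates CJS conditioning")
  T <- length(history$y)
  if (f0 == T) return(0)
  pr <- history_probs(history, params, sex)
  det <- which(history$y == 1L)
  last <- det[length(det)]
  ll <- 0
  if (last > f0) {
    for (t in seq.int(f0 + 1L, last)) {
      ll <- ll + log(pr$phi[t]) +
        if (history$y[t] == 1L) log(pr$p[t]) else log1p(-pr$p[t])
    }
  }
  chi <- chi_recursion(pr$phi[seq.int(f0, T)], pr$p[seq.int(f0, T)])
  ll + log(chi[last - f0 + 1L])
}

#' Marginal log-likelihood of one capture history
#'
#' For a sexed individual this is the sex-conditional likelihood; for an
#' unsexed one the sex is integrated out against the mixture proportion:
#' `log(f_male * L(male) + (1 - f_male) * L(female))`, computed via
#' log-sum-exp.
#'
#' @inheritParams history_loglik_given_sex
#' @export
history_loglik <- function(history, params) {
  if (history$sex %in% c("male", "female"))
    return(history_loglik_given_sex(history, params, history$sex))
  lm_ <- history_loglik_given_sex(history, params, "male") + log(params$f_male)
  lf_ <- history_loglik_given_sex(history, params, "female") + log1p(-params$f_male)
  m <- max(lm_, lf_)
  m + log(exp(lm_ - m) + exp(lf_ - m))
}

#' Default priors for the survival model
#'
#' Normal(0, `fixed_sd`^2) on all fixed effects, a flat Beta(1, 1) on the
#' male proportion and half-Normal(0, `sd_scale`) on the three
#' random-effect SDs.
#'
#' @param fixed_sd SD of the Normal prior on fixed effects (log-odds).
#' @param sd_scale Scale of the half-Normal prior on random-effect SDs.
#' @export
cjs_priors <- function(fixed_sd = 10, sd_scale = 2.5) {
  list(fixed_sd = fixed_sd, sd_scale = sd_scale)
}

#' Joint log-posterior of the survival model
#'
#' Sum of the marginal history log-likelihoods, the categorical sex
#' likelihood of the sexed individuals, the Normal log-densities of the
#' farm/year deviates given their SDs, and the prior log-densities of the
#' fixed effects, SDs and male proportion. Returns `-Inf` (not an error)
#' at invalid parameter values (SD <= 0, f outside (0,1)).
#'
#' @param data A `cjs_data` from [prepare_cjs_data()] or a list of
#'   `capture_history`.
#' @param params A [cjs_params()].
#' @param priors A [cjs_priors()] list.
#' @export
total_log_posterior <- function(data, params, priors = cjs_priors()) {
  if (params$sigma_delta <= 0 || params$sigma_gamma <= 0 ||
      params$sigma_rho <= 0 || params$f_male <= 0 || params$f_male >= 1)
    return(-Inf)
  ll <- if (inherits(data, "cjs_data")) {
    cjs_data_loglik(data, params)
  } else {
    sexed <- vapply(data, function(h) h$sex, "")
    n_m <- sum(sexed == "male"); n_f <- sum(sexed == "female")
    sum(vapply(data, history_loglik, 0, params = params)) +
      n_m * log(params$f_male) + n_f * log1p(-params$f_male)
  }
  lp <- ll +
    sum(dnorm(params$delta, 0, params$sigma_delta, log = TRUE)) +
    sum(dnorm(params$gamma, 0, params$sigma_gamma, log = TRUE)) +
    sum(dnorm(params$rho, 0, params$sigma_rho, log = TRUE)) +
    sum(dnorm(c(params$beta0, params$beta1, params$beta2,
                params$alpha0, params$alpha1),
              0, priors$fixed_sd, log = TRUE)) +
    half_normal_logpdf(params$sigma_delta, priors$sd_scale) +
    half_normal_logpdf(params$sigma_gamma, priors$sd_scale) +
    half_normal_logpdf(params$sigma_rho, priors$sd_scale)
  if (!is.finite(lp)) -Inf else lp
}

half_normal_logpdf <- function(x, scale) log(2) + dnorm(x, 0, scale, log = TRUE)

#' Pack capture histories into the fast likelihood layout
#'
#' Flattens the histories into integer/numeric matrices consumed by the
#' compiled likelihood, collapsing individuals with identical detection
#' data (same first occasion, detection pattern, site sequence, sex status
#' and ringing age) into one weighted row -- never-recaptured nestlings
#' from the same farm and cohort are interchangeable, which cuts the
#' evaluation cost substantially at study scale.
#'
#' @param histories List of `capture_history` (from [build_histories()]).
#' @param farms The `farm_table` the histories were built against.
#' @return A `cjs_data` list of matrices plus weights.
#' @export
prepare_cjs_data <- function(histories, farms) {
  n <- length(histories)
  if (n == 0L) stop("no histories")
  T <- length(histories[[1L]]$y)
  first <- vapply(histories, function(h) h$first_occ, 0L)
  y <- t(vapply(histories, function(h) h$y, integer(T)))
  farm <- t(vapply(histories, function(h) {
    f <- h$farm_idx; f[is.na(f)] <- 0L; as.integer(f)
  }, integer(T)))
  selev <- t(vapply(histories, function(h) {
    e <- h$std_elevation_at; e[is.na(e)] <- 0; e
  }, numeric(T)))
  edge <- t(vapply(histories, function(h) {
    e <- as.integer(h$edge_at); e[is.na(e)] <- 0L; e
  }, integer(T)))
  firstyear <- t(vapply(histories, function(h) {
    as.integer(!is.na(h$age_class_at) & h$age_class_at == "first_year")
  }, integer(T)))
  sex_code <- vapply(histories, function(h)
    match(h$sex, SEX_LEVELS) - 1L, 0L)

  key <- apply(cbind(first, sex_code, y, farm, firstyear), 1L, paste, collapse = ",")
  keep <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[keep])))
  # matrices are stored transposed (T x n) for the compiled kernel
  structure(list(
    n_total = n, n_years = T, n_farms = nrow(farms),
    first = first[keep], y = t(y[keep, , drop = FALSE]),
    farm = t(farm[keep, , drop = FALSE]),
    selev = t(selev[keep, , drop = FALSE]),
    edge = t(edge[keep, , drop = FALSE]),
    firstyear = t(firstyear[keep, , drop = FALSE]),
    sex_code = sex_code[keep], weight = w,
    n_recaptured = sum(rowSums(y) > 1L)
  ), class = "cjs_data")
}

# Data log-likelihood (incl. categorical sex terms) through the compiled
# kernel; reference R path is total_log_posterior on raw histories.
cjs_data_loglik <- function(data, params) {
  cjs_loglik_cpp(data$first, data$y, data$farm, data$selev, data$edge,
                 data$firstyear, data$sex_code, data$weight,
                 unname(params$beta0), unname(params$beta1), params$beta2,
                 unname(params$alpha0), unname(params$alpha1),
                 params$f_male, params$delta, params$gamma, params$rho)
}
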