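# Independent oracles used across the suite. These deliberately do not
# reuse the package's likelihood/shift code paths: the enumeration oracle
# recomputes its own linear predictors and sums over all binary latent
# alive paths; the IRLS/OLS oracles are hand-rolled; the shift oracle is a
# direct filter-and-average.

# --- brute-force CJS likelihood ------------------------------------------

oracle_probs <- function(history, params, sex) {
  T <- length(history$y)
  f0 <- history$first_occ
  phi <- rep(NA_real_, T); p <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    if (t <= f0) next
    juv <- history$age_class_at[t] == "first_year"
    b0 <- if (juv) params$beta0[["juvenile"]]
          else if (sex == "male") params$beta0[["adult_male"]]
          else params$beta0[["adult_female"]]
    b1 <- if (juv) params$beta1[["juvenile"]]
          else if (sex == "male") params$beta1[["adult_male"]]
          else params$beta1[["adult_female"]]
    lphi <- b0 + b1 * history$std_elevation_at[t - 1] +
      params$beta2 * as.numeric(history$edge_at[t - 1]) +
      params$delta[history$farm_idx[t - 1]] + params$gamma[t]
    lp <- params$alpha0[["adult"]] +
      (if (juv) params$alpha0[["juvenile_offset"]] else 0) +
      (params$alpha1[["adult"]] +
         (if (juv) params$alpha1[["juvenile_offset"]] else 0)) *
        history$std_elevation_at[t] +
      params$rho[t]
    phi[t] <- 1 / (1 + exp(-lphi))
    p[t] <- 1 / (1 + exp(-lp))
  }
  list(phi = phi, p = p)
}

enum_lik_given_sex <- function(history, params, sex) {
  T <- length(history$y)
  f0 <- history$first_occ
  if (f0 == T) return(1)
  pr <- oracle_probs(history, params, sex)
  k <- T - f0
  total <- 0
  for (code in 0:(2^k - 1)) {
    z <- c(1L, as.integer(intToBits(code))[seq_len(k)])
    prob <- 1
    for (j in seq_len(k)) {
      t <- f0 + j
      if (z[j] == 1L) {
        prob <- prob * (if (z[j + 1] == 1L) pr$phi[t] else 1 - pr$phi[t])
      } else if (z[j + 1] == 1L) {
        prob <- 0  # no resurrection
      }
      obs <- if (history$y[t] == 1L) {
        if (z[j + 1] == 1L) pr$p[t] else 0
      } else {
        if (z[j + 1] == 1L) 1 - pr$p[t] else 1
      }
      prob <- prob * obs
      if (prob == 0) break
    }
    total <- total + prob
  }
  total
}

enum_lik <- function(history, params) {
  if (history$sex == "male") return(enum_lik_given_sex(history, params, "male"))
  if (history$sex == "female")
    return(enum_lik_given_sex(history, params, "female"))
  params$f_male * enum_lik_given_sex(history, params, "male") +
    (1 - params$f_male) * enum_lik_given_sex(history, params, "female")
}

# --- regression oracles ---------------------------------------------------

irls_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- 1 / (1 + exp(-as.numeric(X %*% beta)))
    w <- pmax(mu * (1 - mu), 1e-12)
    step <- solve(crossprod(X, X * w), crossprod(X, y - mu))
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

ols_normal_equations <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# --- corrected shift oracle ----------------------------------------------

brute_corrected_shift <- function(event, farms, include_origin = TRUE) {
  keep <- logical(nrow(farms))
  oi <- which(farms$farm_id == event$origin_farm)
  for (j in seq_len(nrow(farms))) {
    d <- sqrt((farms$x[j] - farms$x[oi])^2 +
              (farms$y[j] - farms$y[oi])^2) / 1000
    keep[j] <- d <= event$distance + 1e-9
  }
  if (!include_origin) keep[oi] <- FALSE
  di <- which(farms$farm_id == event$dest_farm)
  farms$elevation[di] - mean(farms$elevation[keep])
}

# --- fixture builders -----------------------------------------------------

toy_farms <- function(n = 5, seed = 42, elev = NULL) {
  set.seed(seed)
  df <- data.frame(
    farm_id = sprintf("F%d", seq_len(n)),
    x = runif(n, 0, 10000), y = runif(n, 0, 3500),
    elevation = if (is.null(elev)) runif(n, 700, 1430) else elev,
    edge = seq_len(n) %% 2 == 0,
    stringsAsFactors = FALSE)
  elevcmr:::as_farm_table(df)
}

capture_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(individual_id = r[[1]], year = as.integer(r[[2]]),
               farm_id = r[[3]], age_class = r[[4]], sex = r[[5]],
               stringsAsFactors = FALSE)))
  df
}

# random short histories (<= `T` occasions) for property tests
random_histories <- function(n, T = 5, farms = toy_farms(), seed = 1) {
  set.seed(seed)
  years <- c(2001L, 2000L + T)
  rows <- list()
  for (i in seq_len(n)) {
    id <- sprintf("r%03d", i)
    first <- sample.int(T, 1)
    ringed_as <- sample(c("nestling", "adult"), 1)
    det <- first
    if (first < T) {
      later <- (first + 1):T
      det <- c(first, later[runif(length(later)) < 0.45])
    }
    sex_known <- ringed_as == "adult" || length(det) > 1
    sex <- if (sex_known) sample(c("male", "female"), 1) else "unknown"
    for (k in seq_along(det)) {
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = id, year = 2000L + det[k],
        farm_id = sample(farms$farm_id, 1),
        age_class = if (k == 1) ringed_as else "adult",
        sex = if (k == 1 && ringed_as == "nestling") "unknown" else sex,
        stringsAsFactors = FALSE)
    }
  }
  build_histories(do.call(rbind, rows), farms, years)
}

random_cjs_params <- function(farms, T, seed) {
  set.seed(seed)
  cjs_params(
    beta0 = rnorm(3, -0.5, 1), beta1 = rnorm(3, 0, 0.7),
    beta2 = rnorm(1, 0, 0.5),
    alpha0 = rnorm(2, 0, 1), alpha1 = rnorm(2, 0, 0.7),
    f_male = runif(1, 0.2, 0.8),
    sigma_delta = 0.3, sigma_gamma = 0.3, sigma_rho = 0.3,
    delta = rnorm(nrow(farms), 0, 0.3), gamma = rnorm(T, 0, 0.3),
    rho = rnorm(T, 0, 0.3))
}
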