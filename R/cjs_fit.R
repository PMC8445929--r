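#' MCMC settings for the survival model
#'
#' Adaptive random-walk Metropolis in five parameter blocks (fixed
#' effects, farm deviates, year survival deviates, year recapture
#' deviates, log SDs). Proposal covariances are estimated per block from
#' the burn-in history and the global step scale is tuned toward an
#' acceptance rate of 0.234; adaptation stops at the end of burn-in.
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Total iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded (and used for adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @export
cjs_mcmc_config <- function(n_chains = 3L, n_iter = 6000L, n_burn = 3000L,
                            thin = 3L) {
  stopifnot(n_iter > n_burn, n_burn >= 200L, thin >= 1L)
  list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
       n_burn = as.integer(n_burn), thin = as.integer(thin))
}

REPORTED_PARAMS <- c(
  "p_intercept", "p_elevation", "p_juvenile", "p_elevation_x_juvenile",
  "p_between_year_sd",
  "phi_intercept_adult_male", "phi_intercept_adult_female",
  "phi_intercept_juvenile",
  "phi_elevation_adult_male", "phi_elevation_adult_female",
  "phi_elevation_juvenile", "phi_edge",
  "phi_between_year_sd", "phi_between_farm_sd",
  "prop_male")

TABLE1_LABELS <- c(
  "Recapture: Intercept", "Recapture: Elevation", "Recapture: Juvenile",
  "Recapture: Elevation x Juvenile", "Recapture: Between-year SD",
  "Survival: Intercept adult males", "Survival: Intercept adult females",
  "Survival: Intercept juveniles", "Survival: Elevation adult males",
  "Survival: Elevation adult females", "Survival: Elevation juveniles",
  "Survival: Location within study area", "Survival: Between-year SD",
  "Survival: Between-farm SD", "Mixture: Proportion of males")

# theta layout on the sampling (unconstrained) scale
theta_layout <- function(n_farms, n_years) {
  i <- 0L
  take <- function(k) { out <- i + seq_len(k); i <<- i + k; out }
  list(fixed = take(12L), delta = take(n_farms), gamma = take(n_years),
       rho = take(n_years), logsig = take(3L))
}

# map a sampled coordinate vector (non-centered deviates) to natural scale
theta_to_params <- function(theta, lay) {
  fx <- theta[lay$fixed]
  sig <- exp(theta[lay$logsig])
  cjs_params(
    beta0 = fx[1:3], beta1 = fx[4:6], beta2 = fx[7],
    alpha0 = fx[8:9], alpha1 = fx[10:11],
    f_male = plogis(fx[12]),
    sigma_delta = sig[1], sigma_gamma = sig[2], sigma_rho = sig[3],
    delta = sig[1] * theta[lay$delta], gamma = sig[2] * theta[lay$gamma],
    rho = sig[3] * theta[lay$rho])
}

# log posterior on the sampling scale: data term (compiled) + random
# effect densities + priors + change-of-variable Jacobians for logit(f)
# and log(sigma). Random effects are non-centered: the chain carries
# standardized deviates u ~ N(0,1) and the likelihood sees sigma * u,
# which avoids the funnel pathology of weakly informed hierarchies.
make_log_post <- function(data, lay, priors, prior_only = FALSE) {
  function(theta) {
    fx <- theta[lay$fixed]
    f <- plogis(fx[12])
    sig <- exp(theta[lay$logsig])
    if (f <= 0 || f >= 1 || any(!is.finite(sig))) return(-Inf)
    u_d <- theta[lay$delta]; u_g <- theta[lay$gamma]; u_r <- theta[lay$rho]
    ll <- if (prior_only) 0 else
      cjs_loglik_cpp(data$first, data$y, data$farm, data$selev, data$edge,
                     data$firstyear, data$sex_code, data$weight,
                     fx[1:3], fx[4:6], fx[7], fx[8:9], fx[10:11],
                     f, sig[1] * u_d, sig[2] * u_g, sig[3] * u_r)
    lp <- ll +
      sum(dnorm(u_d, log = TRUE)) +
      sum(dnorm(u_g, log = TRUE)) +
      sum(dnorm(u_r, log = TRUE)) +
      sum(dnorm(fx[1:11], 0, priors$fixed_sd, log = TRUE)) +
      log(f) + log1p(-f) +                       # flat Beta(1,1) via logit
      sum(half_normal_logpdf(sig, priors$sd_scale) + log(sig))
    if (!is.finite(lp)) -Inf else lp
  }
}

run_chain <- function(log_post, init, lay, n_iter, n_burn, thin) {
  blocks <- lay
  nb <- length(blocks)
  theta <- init
  lp <- log_post(theta)
  if (!is.finite(lp)) stop("non-finite log posterior at initial values")
  d <- vapply(blocks, length, 0L)
  lambda <- 2.38 / sqrt(d)
  chol_list <- lapply(d, function(k) diag(0.1, k))
  run_mean <- lapply(blocks, function(b) theta[b])
  run_cov <- lapply(d, function(k) diag(0.01, k))
  n_seen <- 0L
  acc <- numeric(nb)
  n_keep <- (n_iter - n_burn) %/% thin
  draws <- matrix(NA_real_, n_keep, length(theta))
  k <- 0L
  for (it in seq_len(n_iter)) {
    adapting <- it <= n_burn
    for (b in seq_len(nb)) {
      idx <- blocks[[b]]
      prop <- theta
      prop[idx] <- theta[idx] +
        lambda[b] * as.numeric(chol_list[[b]] %*% rnorm(d[b]))
      lp_prop <- log_post(prop)
      a <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
      if (runif(1) < a) { theta <- prop; lp <- lp_prop; acc[b] <- acc[b] + 1 }
      if (adapting)
        lambda[b] <- lambda[b] * exp(it^-0.6 * (a - 0.234))
    }
    if (adapting) {
      n_seen <- n_seen + 1L
      for (b in seq_len(nb)) {
        idx <- blocks[[b]]
        dlt <- theta[idx] - run_mean[[b]]
        run_mean[[b]] <- run_mean[[b]] + dlt / n_seen
        run_cov[[b]] <- run_cov[[b]] * ((n_seen - 1) / n_seen) +
          tcrossprod(dlt, theta[idx] - run_mean[[b]]) / n_seen
      }
      if (it %% 100L == 0L && it >= 200L) {
        for (b in seq_len(nb)) {
          S <- run_cov[[b]] + diag(1e-6, d[b])
          ch <- tryCatch(t(chol(S)), error = function(e) NULL)
          if (!is.null(ch)) chol_list[[b]] <- ch
        }
      }
    } else if ((it - n_burn) %% thin == 0L) {
      k <- k + 1L
      draws[k, ] <- theta
    }
  }
  list(draws = draws, accept = acc / n_iter)
}

reported_draws <- function(theta_draws, lay) {
  fx <- theta_draws[, lay$fixed, drop = FALSE]
  sig <- exp(theta_draws[, lay$logsig, drop = FALSE])
  out <- cbind(
    fx[, 8], fx[, 10], fx[, 9], fx[, 11], sig[, 3],
    fx[, 1], fx[, 2], fx[, 3], fx[, 4], fx[, 5], fx[, 6], fx[, 7],
    sig[, 2], sig[, 1], plogis(fx[, 12]))
  colnames(out) <- REPORTED_PARAMS
  out
}

ess_one <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(rho < 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

rhat_one <- function(mat) { # iterations x chains
  m <- ncol(mat); n <- nrow(mat)
  if (m < 2L || n < 4L) return(NA_real_)
  mu <- colMeans(mat); v <- apply(mat, 2, var)
  B <- n * var(mu); W <- mean(v)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical survival model by MCMC
#'
#' Samples the joint posterior of the Cormack-Jolly-Seber mixture model
#' with the adaptive Metropolis sampler described in [cjs_mcmc_config()],
#' and summarizes the parameters reported in the standard results table
#' (posterior mean and 2.5%/97.5% quantiles).
#'
#' @param data A `cjs_data` from [prepare_cjs_data()]. Must contain at
#'   least one recaptured individual, otherwise survival and recapture
#'   probability are confounded and an error is raised.
#' @param config A [cjs_mcmc_config()].
#' @param seed Integer seed; draws are reproducible given it.
#' @param priors A [cjs_priors()].
#' @param prior_only Sample the prior instead of the posterior (no data
#'   term; also lifts the recapture requirement). Used for
#'   prior-recovery checks.
#' @return A `cjs_posterior` with elements `summary` (data frame:
#'   parameter, label, mean, lo95, hi95, ess, rhat), `draws` (pooled
#'   post-burn-in draws of the reported parameters), `theta_draws` (all
#'   sampled coordinates), `accept`, `converged`, `config`, `seed`.
#' @export
fit_cjs <- function(data, config = cjs_mcmc_config(), seed = 1L,
                    priors = cjs_priors(), prior_only = FALSE) {
  stopifnot(inherits(data, "cjs_data"))
  if (!prior_only && data$n_recaptured < 1L)
    stop("no recaptured individuals: survival and recapture are confounded")
  lay <- theta_layout(data$n_farms, data$n_years)
  log_post <- make_log_post(data, lay, priors, prior_only = prior_only)
  n_par <- max(lay$logsig)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    init <- numeric(n_par)
    init[lay$fixed] <- rnorm(12, 0, 0.3)
    init[lay$fixed][1:3] <- init[lay$fixed][1:3] - 1  # survival logits < 0
    init[lay$logsig] <- log(0.3) + rnorm(3, 0, 0.1)
    chains[[ch]] <- run_chain(log_post, init, lay,
                              config$n_iter, config$n_burn, config$thin)
  }

  rep_by_chain <- lapply(chains, function(c_) reported_draws(c_$draws, lay))
  pooled <- do.call(rbind, rep_by_chain)
  theta_pooled <- do.call(rbind, lapply(chains, `[[`, "draws"))

  ess <- rowSums(vapply(rep_by_chain, function(m)
    apply(m, 2, ess_one), numeric(length(REPORTED_PARAMS))))
  rhat <- vapply(seq_along(REPORTED_PARAMS), function(j)
    rhat_one(vapply(rep_by_chain, function(m) m[, j],
                    numeric(nrow(rep_by_chain[[1L]])))), 0)

  summary <- data.frame(
    parameter = REPORTED_PARAMS,
    label = TABLE1_LABELS,
    mean = colMeans(pooled),
    lo95 = apply(pooled, 2, quantile, 0.025, names = FALSE),
    hi95 = apply(pooled, 2, quantile, 0.975, names = FALSE),
    ess = ess, rhat = rhat,
    row.names = NULL, stringsAsFactors = FALSE)

  low_ess <- summary$parameter[summary$ess < 100]
  if (length(low_ess))
    warning("effective sample size < 100 for: ",
            paste(low_ess, collapse = ", "))
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged)
    warning("possible non-convergence (split R-hat > 1.1); result flagged")

  structure(list(summary = summary, draws = pooled,
                 theta_draws = theta_pooled, layout = lay,
                 accept = lapply(chains, `[[`, "accept"),
                 converged = converged, config = config, seed = seed),
            class = "cjs_posterior")
}

#' @export
print.cjs_posterior <- function(x, ...) {
  cat("<cjs_posterior> ", nrow(x$draws), " pooled draws, ",
      x$config$n_chains, " chains",
      if (!x$converged) " [NON-CONVERGENCE FLAGGED]", "\n", sep = "")
  print(cbind(x$summary[, c("label"), drop = FALSE],
              round(x$summary[, c("mean", "lo95", "hi95")], 3)))
  invisible(x)
}
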