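make_events <- function(n = 300, farms = toy_farms(30, seed = 6), seed = 2,
                        dp = dispersal_params(sd_year = 0.3)) {
  set.seed(seed)
  scaffold <- data.frame(
    individual_id = sprintf("d%04d", seq_len(n)),
    origin_farm = sample(farms$farm_id, n, replace = TRUE),
    year = sample(2001:2010, n, replace = TRUE),
    age_class = sample(c("juvenile", "adult"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  simulate_dispersal_outcomes(scaffold, farms, dp, seed = seed + 1)
}

test_that("designs carry the published row sets and reference coding", {
  farms <- toy_farms(30, seed = 6)
  ev <- make_events(farms = farms)
  d_prob <- build_design(ev, "probability", farms)
  expect_equal(attr(d_prob, "terms"),
               c("intercept", "elevation", "age_adult", "sex_female",
                 "edge", "elevation_x_female", "elevation_x_adult"))
  expect_equal(nrow(d_prob), nrow(ev))

  disp <- ev[ev$dispersed, ]
  d_dist <- build_design(disp, "distance", farms)
  expect_equal(length(attr(d_dist, "terms")), 7)
  expect_true("adult_x_female" %in% attr(d_dist, "terms"))
  expect_false("edge" %in% attr(d_dist, "terms"))
  expect_error(build_design(ev, "distance", farms), "restricted to dispersed")
  expect_error(build_design(disp, "shift", farms), "corrected_shift")

  # reference cell: juvenile male at mean elevation, centre -> all
  # non-intercept covariates zero
  std <- standardize(farms$elevation)$standardizer
  ref_farm <- farms$farm_id[which.min(abs(farms$elevation - std$mean))]
  ev_ref <- ev[1, ]
  ev_ref$origin_farm <- ref_farm
  ev_ref$age_class <- "juvenile"; ev_ref$sex <- "male"
  fake_std <- list(mean = farms$elevation[farms$farm_id == ref_farm], sd = std$sd)
  d_ref <- build_design(ev_ref, "probability", farms, standardizer = fake_std)
  centre <- !farms$edge[farms$farm_id == ref_farm]
  row <- as.numeric(d_ref[1, c("elevation", "age_adult", "sex_female",
                               "elevation_x_female", "elevation_x_adult")])
  expect_equal(row, rep(0, 5))
  if (centre) expect_equal(d_ref$edge[1], 0)
})

test_that("zero-variance binomial fit matches the hand-rolled IRLS oracle", {
  farms <- toy_farms(30, seed = 6)
  ev <- make_events(n = 400, farms = farms, seed = 9)
  design <- build_design(ev, "probability", farms)
  fit <- fit_glmm_binomial(design, theta_zero = TRUE)
  X <- cbind(1, as.matrix(as.data.frame(design)[, c(
    "elevation", "age_adult", "sex_female", "edge",
    "elevation_x_female", "elevation_x_adult")]))
  beta_irls <- irls_logistic(X, design$y)
  expect_lt(max(abs(unname(fit$coef) - beta_irls)), 1e-6)
  expect_equal(unname(fit$ranef_sd), c(0, 0, 0))
})

test_that("zero-variance Gaussian fit matches the normal-equations oracle", {
  farms <- toy_farms(30, seed = 6)
  ev <- make_events(n = 400, farms = farms, seed = 10)
  disp <- ev[ev$dispersed, ]
  design <- build_design(disp, "distance", farms)
  fit <- fit_lmm_gaussian(design, theta_zero = TRUE)
  X <- cbind(1, as.matrix(as.data.frame(design)[, c(
    "age_adult", "elevation", "sex_female", "elevation_x_adult",
    "elevation_x_female", "adult_x_female")]))
  beta_ols <- ols_normal_equations(X, design$y)
  expect_lt(max(abs(unname(fit$coef) - beta_ols)), 1e-8)
})

test_that("binomial mixed model recovers known coefficients at n = 2000", {
  farms <- toy_farms(40, seed = 12)
  set.seed(31)
  n <- 2000
  scaffold <- data.frame(
    individual_id = sprintf("r%04d", seq_len(n)),
    origin_farm = sample(farms$farm_id, n, replace = TRUE),
    year = sample(2001:2010, n, replace = TRUE),
    age_class = sample(c("juvenile", "adult"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  dp <- dispersal_params(coef = c(
    intercept = 1.2, elevation = 0.4, age_adult = -2.2, sex_female = 0.1,
    edge = 0.8, elevation_x_female = 1.0, elevation_x_adult = 0.1),
    sd_year = 0.3)
  ev <- simulate_dispersal_outcomes(scaffold, farms, dp, seed = 77)
  design <- build_design(ev, "probability", farms)
  fit <- fit_glmm_binomial(design)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coef - dp$coef) < 2.5 * se + 0.25))
  # year SD is estimated in the right region
  expect_lt(abs(fit$ranef_sd[["year"]] - 0.3), 0.25)
})

test_that("Gaussian slope credible intervals are calibrated under the null", {
  farms <- toy_farms(25, seed = 4)
  covered <- logical(60)
  for (r in seq_len(60)) {
    ev <- make_events(n = 70, farms = farms, seed = 300 + r,
                      dp = dispersal_params(coef = c(
                        intercept = 1.6, elevation = 0.3, age_adult = -0.8,
                        sex_female = 0.1, edge = 0.4,
                        elevation_x_female = 0.5, elevation_x_adult = 0.1),
                        sd_year = 0))
    disp <- ev[ev$dispersed, ]
    # response = constant + noise, independent of all covariates
    set.seed(1000 + r)
    disp$distance <- 3 + rnorm(nrow(disp))
    design <- build_design(disp, "distance", farms)
    fit <- suppressWarnings(fit_lmm_gaussian(design))
    tab <- simulate_posterior(fit, n_draws = 500, seed = r)$table
    sl <- tab[tab$parameter == "elevation", ]
    covered[r] <- sl$lo95 <= 0 && 0 <= sl$hi95
  }
  expect_gte(mean(covered), 0.9)
})

test_that("simulated posterior is reproducible and centred on the estimates", {
  farms <- toy_farms(30, seed = 6)
  ev <- make_events(n = 500, farms = farms, seed = 14,
                    dp = dispersal_params(coef = c(
                      intercept = 0.5, elevation = 0.4, age_adult = -1.5,
                      sex_female = 0.1, edge = 0.6,
                      elevation_x_female = 0.8, elevation_x_adult = 0.1),
                      sd_year = 0.2))
  design <- build_design(ev, "probability", farms)
  fit <- fit_glmm_binomial(design)
  s1 <- simulate_posterior(fit, n_draws = 2000, seed = 5)
  s2 <- simulate_posterior(fit, n_draws = 2000, seed = 5)
  expect_identical(s1$table, s2$table)
  expect_equal(nrow(s1$draws), 2000)
  big <- simulate_posterior(fit, n_draws = 1e5, seed = 6)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(colMeans(big$draws) - fit$coef) < 4 * se / sqrt(1e5) + 1e-8))
  # broken covariance errors out naming the eigenvalue
  bad <- fit; bad$vcov[1, 2] <- bad$vcov[2, 1] <- 10
  expect_error(simulate_posterior(bad), "eigenvalue")
})

test_that("dispersal-probability curves respond to the elevation-sex interaction", {
  fitlike <- list(model = "probability",
                  coef = setNames(rep(0, 7), elevcmr:::PROB_TERMS),
                  vcov = diag(1e-12, 7), labels = elevcmr:::PROB_LABELS,
                  standardizer = list(mean = 1042, sd = 224))
  class(fitlike) <- "mixed_fit"
  flat <- predict_dispersal_curve(fitlike, c(800, 1042, 1300), "adult_male",
                                  n_draws = 200, seed = 1)
  expect_equal(flat$median, rep(0.5, 3), tolerance = 1e-5)
  expect_error(predict_dispersal_curve(fitlike, 1000, "chick"), "class")

  # recovery + prediction: strong positive elevation-by-female interaction
  farms <- toy_farms(40, seed = 12)
  set.seed(8)
  n <- 1500
  scaffold <- data.frame(
    individual_id = sprintf("p%04d", seq_len(n)),
    origin_farm = sample(farms$farm_id, n, replace = TRUE),
    year = sample(2001:2010, n, replace = TRUE),
    age_class = sample(c("juvenile", "adult"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  dp <- dispersal_params(coef = c(
    intercept = -1.5, elevation = 0.3, age_adult = 0, sex_female = 0.1,
    edge = 0.5, elevation_x_female = 1.75, elevation_x_adult = 0),
    sd_year = 0.2)
  ev <- simulate_dispersal_outcomes(scaffold, farms, dp, seed = 99)
  fit <- fit_glmm_binomial(build_design(ev, "probability", farms))
  hi <- max(farms$elevation)
  f_hi <- predict_dispersal_curve(fit, hi, "adult_female", seed = 2)
  m_hi <- predict_dispersal_curve(fit, hi, "adult_male", seed = 2)
  expect_gt(f_hi$median, m_hi$median)
  # monotone transform: female curve increases with elevation
  f_curve <- predict_dispersal_curve(fit, c(800, 1100, 1400), "adult_female",
                                     seed = 3)
  expect_true(all(diff(f_curve$median) > 0))
})
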