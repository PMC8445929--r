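test_that("farm generator is deterministic, range-respecting and calibrated", {
  cfg <- sim_config(seed = 7)
  f1 <- generate_farms(cfg)
  f2 <- generate_farms(cfg)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 63)
  expect_true(min(f1$elevation) >= 700 && max(f1$elevation) <= 1430)
  expect_error(generate_farms(sim_config(n_farms = 1)), "at least 2")

  # Monte-Carlo check of the truncated-exponential rate calibration:
  # the mean elevation of a 63-farm landscape stays near 1042 m
  means <- vapply(1:200, function(s)
    mean(generate_farms(sim_config(seed = s))$elevation), 0)
  expect_lt(abs(mean(means) - 1042), 60)
  expect_lt(abs(mean(means) - 1042), 10)
  expect_gt(mean(abs(means - 1042) < 60), 0.9)

  # a standardizer fitted on a generated landscape is study-like:
  # mean near 1042 m and SD of the right order (~224 m reported; the
  # one-parameter exponential is calibrated on the mean only)
  std <- standardize(f1$elevation)$standardizer
  expect_lt(abs(std$mean - 1042), 80)
  expect_gt(std$sd, 160); expect_lt(std$sd, 260)
})

test_that("degenerate survival and detection settings behave as limits", {
  cfg0 <- sim_config(
    n_farms = 10, years = 6, n_nestlings_per_year = 30,
    n_adults_per_year = 5,
    cjs = cjs_params(beta0 = c(adult_male = -50, adult_female = -50,
                               juvenile = -50)),
    seed = 3)
  farms <- generate_farms(cfg0)
  sim0 <- simulate_histories(farms, cfg0)
  # survival forced to ~0: nobody is ever seen after the ringing year
  expect_true(all(table(sim0$captures$individual_id) == 1))

  cfg1 <- sim_config(
    n_farms = 10, years = 6, n_nestlings_per_year = 30,
    n_adults_per_year = 5,
    cjs = cjs_params(beta0 = c(adult_male = 50, adult_female = 50,
                               juvenile = 50),
                     alpha0 = c(adult = 50, juvenile_offset = 0)),
    dispersal = dispersal_params(coef = c(
      intercept = -50, elevation = 0, age_adult = 0, sex_female = 0,
      edge = 0, elevation_x_female = 0, elevation_x_adult = 0),
      sd_year = 0),
    seed = 3)
  sim1 <- simulate_histories(generate_farms(cfg1), cfg1)
  # survival and detection forced to ~1: detected every year after ringing
  counts <- table(sim1$captures$individual_id)
  h <- build_histories(sim1$captures, generate_farms(cfg1),
                       c(cfg1$start_year, cfg1$start_year + cfg1$years - 1))
  for (hh in h)
    expect_equal(sum(hh$y), length(hh$years) - hh$first_occ + 1L)
})

test_that("simulated capture tables pass the validators and mirror the study scale", {
  cfg <- sim_config(seed = 11)
  farms <- generate_farms(cfg)
  sim <- simulate_histories(farms, cfg)
  # generated tables validate unchanged
  expect_s3_class(elevcmr:::as_capture_table(as.data.frame(sim$captures),
                                             farms = farms),
                  "capture_table")
  ids <- unique(sim$captures$individual_id)
  expect_equal(length(ids), (89 + 13) * 15)
  # never-recaptured nestlings are exactly the unknown-sex individuals
  n_caps <- table(sim$captures$individual_id)
  ringing <- sim$captures[!duplicated(sim$captures$individual_id), ]
  unknown <- tapply(sim$captures$sex == "unknown", sim$captures$individual_id,
                    all)
  expect_equal(unname(unknown[ids]),
               unname(n_caps[ids] == 1 & ringing$age_class[match(ids, ringing$individual_id)] == "nestling"))
  # recaptured individuals are of the study's order (tens, not hundreds)
  h <- build_histories(sim$captures, farms,
                       c(cfg$start_year, cfg$start_year + cfg$years - 1))
  n_recap <- sum(vapply(h, function(x) sum(x$y), 0L) > 1L)
  expect_gt(n_recap, 20)
  expect_lt(n_recap, 400)

  # determinism of the full stage
  sim2 <- simulate_histories(farms, cfg)
  expect_identical(sim$captures, sim2$captures)
})

test_that("empirical detection frequency of simulated-alive individuals converges to p", {
  # constant detection probability; many individuals, no dispersal
  p_true <- plogis(0.7)
  cfg <- sim_config(
    n_farms = 5, years = 4, n_nestlings_per_year = 0,
    n_adults_per_year = 2500,
    cjs = cjs_params(beta0 = c(adult_male = 2, adult_female = 2,
                               juvenile = 2),
                     alpha0 = c(adult = 0.7, juvenile_offset = 0)),
    dispersal = dispersal_params(coef = c(
      intercept = -50, elevation = 0, age_adult = 0, sex_female = 0,
      edge = 0, elevation_x_female = 0, elevation_x_adult = 0),
      sd_year = 0),
    seed = 5)
  farms <- generate_farms(cfg)
  sim <- simulate_histories(farms, cfg)
  z <- sim$truth$z
  detected <- matrix(0L, nrow(z), ncol(z))
  occ <- match(sim$captures$year, seq(cfg$start_year, length.out = cfg$years))
  idx <- match(sim$captures$individual_id, sprintf("ind%05d", seq_len(nrow(z))))
  detected[cbind(idx, occ)] <- 1L
  ring <- sim$truth$ring_year
  alive_later <- which(z == 1L & col(z) > ring[row(z)])
  n <- length(alive_later)
  phat <- mean(detected[alive_later])
  expect_gt(n, 10000)
  # 99.9% binomial CI around the truth
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(phat - p_true), 3.3 * se + 1e-9)
})

test_that("dispersal outcome simulator respects limits and kernel ordering", {
  farms <- toy_farms(40, seed = 2)
  scaffold <- data.frame(
    individual_id = sprintf("s%04d", 1:800),
    origin_farm = sample(farms$farm_id, 800, replace = TRUE),
    year = sample(2001:2005, 800, replace = TRUE),
    age_class = rep(c("juvenile", "adult"), 400),
    sex = rep(c("male", "female"), each = 400),
    stringsAsFactors = FALSE)
  dp <- dispersal_params(sd_year = 0)
  ev <- simulate_dispersal_outcomes(scaffold, farms, dp, seed = 4)
  expect_true(all(ev$dispersed == (ev$origin_farm != ev$dest_farm)))
  expect_true(all((ev$distance == 0) == (!ev$dispersed)))
  # adults essentially never disperse when their coefficient is -inf-like
  dp_noadult <- dispersal_params(coef = c(
    intercept = 2, elevation = 0, age_adult = -1000, sex_female = 0,
    edge = 0, elevation_x_female = 0, elevation_x_adult = 0), sd_year = 0)
  ev2 <- simulate_dispersal_outcomes(scaffold, farms, dp_noadult, seed = 4)
  expect_true(all(!ev2$dispersed[ev2$age_class == "adult"]))
  expect_gt(mean(ev2$dispersed[ev2$age_class == "juvenile"]), 0.5)
  # single-farm landscape: no destination exists
  one <- elevcmr:::as_farm_table(data.frame(
    farm_id = "F1", x = 0, y = 0, elevation = 1000, edge = FALSE,
    stringsAsFactors = FALSE))
  sc1 <- data.frame(individual_id = "a", origin_farm = "F1", year = 2001,
                    age_class = "juvenile", sex = "male",
                    stringsAsFactors = FALSE)
  ev3 <- suppressWarnings(
    simulate_dispersal_outcomes(sc1, one, dispersal_params(coef = c(
      intercept = 50, elevation = 0, age_adult = 0, sex_female = 0,
      edge = 0, elevation_x_female = 0, elevation_x_adult = 0),
      sd_year = 0), seed = 1,
      standardizer = list(mean = 1000, sd = 200)))
  expect_false(any(ev3$dispersed))
  # the natal kernel is wider than the breeding kernel
  d_juv <- ev$distance[ev$dispersed & ev$age_class == "juvenile"]
  d_ad <- ev$distance[ev$dispersed & ev$age_class == "adult"]
  expect_gt(mean(d_juv), mean(d_ad))
  expect_gt(mean(d_ad), 0.2); expect_lt(mean(d_ad), 3.5)
  expect_gt(mean(d_juv), 2); expect_lt(mean(d_juv), 6)
})
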