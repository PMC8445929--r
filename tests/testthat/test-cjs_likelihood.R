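test_that("survival and recapture linear predictors match published worked values", {
  p <- cjs_params(beta0 = c(adult_male = -0.77, adult_female = -0.89,
                            juvenile = -2.82),
                  beta1 = c(adult_male = -0.59, adult_female = -0.32,
                            juvenile = 0))
  # all-zero parameters give logit 0, survival 0.5
  p0 <- cjs_params()
  expect_equal(unname(plogis(survival_logit(p0, "adult_male", 0, FALSE))), 0.5)
  # adult male at mean elevation, centre site
  expect_equal(unname(survival_logit(p, "adult_male", 0, FALSE)), -0.77)
  expect_equal(unname(plogis(survival_logit(p, "adult_male", 0, FALSE))),
               plogis(-0.77), tolerance = 1e-12)
  expect_equal(round(plogis(-0.77), 3), 0.316)
  # one SD uphill adds the elevation slope
  expect_equal(unname(survival_logit(p, "adult_male", 1, FALSE)),
               -0.77 - 0.59)
  expect_error(survival_logit(p, "adult", 0, FALSE), "unknown survival class")
  expect_error(recapture_logit(p, "nestling", 0), "unknown recapture age")
})

test_that("chi recursion stays in [0,1] and matches the constant-rate closed form", {
  # chi_t for constant phi, p solves chi = (1-phi) + phi (1-p) chi at the
  # stationary point; with finite horizon it is a finite geometric sum
  phi <- 0.6; p <- 0.3; T <- 12
  chi <- elevcmr:::chi_recursion(rep(phi, T), rep(p, T))
  a <- phi * (1 - p)
  closed <- vapply(seq_len(T), function(t) {
    k <- T - t
    if (k == 0) 1 else (1 - phi) * sum(a^(0:(k - 1))) + a^k
  }, 0)
  expect_equal(chi, closed, tolerance = 1e-12)
  expect_true(all(chi >= 0 & chi <= 1))
  # all future p = 0 means never detected for sure
  chi0 <- elevcmr:::chi_recursion(runif(8), rep(0, 8))
  expect_equal(chi0, rep(1, 8))
})

test_that("two-occasion ring-and-recapture history has likelihood phi * p", {
  farms <- toy_farms(2)
  caps <- capture_df(list("i1", 2001, "F1", "adult", "male"),
                     list("i1", 2002, "F1", "adult", "male"))
  h <- build_histories(caps, farms, c(2001, 2002))[[1]]
  pars <- cjs_params(n_farms = 2, n_years = 2)  # all zeros: phi = p = 0.5
  expect_equal(history_loglik_given_sex(h, pars, "male"), log(0.25),
               tolerance = 1e-12)
  # first captured at the final occasion carries no information
  caps2 <- capture_df(list("i2", 2002, "F1", "adult", "female"))
  h2 <- build_histories(caps2, farms, c(2001, 2002))[[1]]
  expect_equal(history_loglik_given_sex(h2, pars, "female"), 0)
})

test_that("sex mixture collapses and degenerates correctly", {
  farms <- toy_farms(4)
  h <- random_histories(30, T = 5, farms = farms, seed = 3)
  unk <- h[vapply(h, `[[`, "", "sex") == "unknown"]
  expect_gt(length(unk), 0)
  pars <- random_cjs_params(farms, 5, seed = 11)

  # f_male = 1: marginal equals male conditional
  p1 <- pars; p1$f_male <- 1 - 1e-12
  for (hh in unk[1:min(5, length(unk))])
    expect_equal(history_loglik(hh, p1),
                 history_loglik_given_sex(hh, p1, "male"), tolerance = 1e-9)

  # identical male/female parameters: mixture equals either conditional
  p2 <- pars
  p2$beta0[["adult_female"]] <- p2$beta0[["adult_male"]]
  p2$beta1[["adult_female"]] <- p2$beta1[["adult_male"]]
  for (hh in unk[1:min(5, length(unk))])
    expect_equal(history_loglik(hh, p2),
                 history_loglik_given_sex(hh, p2, "female"), tolerance = 1e-12)

  # distinct parameters: equals the hand-computed weighted sum
  hh <- unk[[1]]
  expect_equal(history_loglik(hh, pars),
               log(pars$f_male * exp(history_loglik_given_sex(hh, pars, "male")) +
                   (1 - pars$f_male) *
                     exp(history_loglik_given_sex(hh, pars, "female"))),
               tolerance = 1e-12)
})

test_that("marginalized likelihood matches enumeration and the compiled kernel", {
  farms <- toy_farms(5)
  h <- random_histories(60, T = 5, farms = farms, seed = 21)
  for (s in 1:5) {
    pars <- random_cjs_params(farms, 5, seed = 100 + s)
    for (hh in h[seq(s, length(h), by = 5)]) {
      expect_equal(history_loglik(hh, pars), log(enum_lik(hh, pars)),
                   tolerance = 1e-10)
    }
    # compiled whole-data likelihood = R path + categorical sex terms
    dat <- prepare_cjs_data(h, farms)
    sexes <- vapply(h, `[[`, "", "sex")
    r_total <- sum(vapply(h, history_loglik, 0, params = pars)) +
      sum(sexes == "male") * log(pars$f_male) +
      sum(sexes == "female") * log(1 - pars$f_male)
    expect_equal(elevcmr:::cjs_data_loglik(dat, pars), r_total,
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to farm and year relabeling", {
  farms <- toy_farms(5)
  h <- random_histories(25, T = 5, farms = farms, seed = 8)
  pars <- random_cjs_params(farms, 5, seed = 5)
  perm <- c(3, 1, 5, 2, 4)
  farms2 <- farms[perm, ]
  farms2 <- elevcmr:::as_farm_table(as.data.frame(farms2))
  pars2 <- pars
  pars2$delta <- pars$delta[perm]
  # rebuild histories against the permuted farm table
  recs <- do.call(rbind, lapply(h, function(hh) {
    det <- which(hh$y == 1)
    data.frame(individual_id = hh$individual_id, year = hh$years[det],
               farm_id = hh$farm_at[det],
               age_class = c(hh$ringed_as, rep("adult", length(det) - 1)),
               sex = hh$sex, stringsAsFactors = FALSE)
  }))
  h2 <- build_histories(recs, farms2, range(h[[1]]$years))
  ids <- vapply(h, `[[`, "", "individual_id")
  ids2 <- vapply(h2, `[[`, "", "individual_id")
  h2 <- h2[match(ids, ids2)]
  ll1 <- vapply(h, history_loglik, 0, params = pars)
  ll2 <- vapply(h2, history_loglik, 0, params = pars2)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("joint log posterior is additive in the data and guards bad values", {
  farms <- toy_farms(4)
  h <- random_histories(20, T = 5, farms = farms, seed = 13)
  pars <- random_cjs_params(farms, 5, seed = 2)
  prior <- cjs_priors()
  lp1 <- total_log_posterior(h, pars, prior)
  prior_val <- total_log_posterior(list(), pars, prior)
  # doubling the dataset doubles the data term exactly
  lp2 <- total_log_posterior(c(h, h), pars, prior)
  expect_equal(lp2 - prior_val, 2 * (lp1 - prior_val), tolerance = 1e-8)
  # zero histories leave the prior-only value finite
  expect_true(is.finite(prior_val))
  # invalid parameter values give -Inf, not an error
  bad <- pars; bad$sigma_delta <- 0
  expect_identical(total_log_posterior(h, bad, prior), -Inf)
  bad2 <- pars; bad2$f_male <- 1
  expect_identical(total_log_posterior(h, bad2, prior), -Inf)
  # prepared-data path agrees with the history-list path
  dat <- prepare_cjs_data(h, farms)
  expect_equal(total_log_posterior(dat, pars, prior), lp1, tolerance = 1e-8)
})
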