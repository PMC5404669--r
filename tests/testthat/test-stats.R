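test_that("response transforms hit their closed forms and invert", {
  expect_equal(transform_response(0, "arcsine_sqrt"), 0)
  expect_equal(transform_response(1, "arcsine_sqrt"), pi / 2)
  expect_equal(transform_response(0.25, "arcsine_sqrt"), pi / 6)
  expect_error(transform_response(1.2, "arcsine_sqrt"), "\\[0, 1\\]")
  expect_error(transform_response(-1, "log"), "positive")
  set.seed(2)
  x <- runif(100)
  expect_equal(inverse_transform(transform_response(x, "arcsine_sqrt"),
                                 "arcsine_sqrt"), x, tolerance = 1e-12)
  y <- rlnorm(100)
  expect_equal(inverse_transform(transform_response(y, "log"), "log"), y,
               tolerance = 1e-12)
})

test_that("Akaike weights normalise relative likelihoods", {
  expect_equal(aic_weights(100), 1)
  expect_equal(aic_weights(c(10, 10)), c(0.5, 0.5))
  set.seed(3)
  a <- runif(7, 1000, 1100)
  w <- aic_weights(a)
  expect_equal(sum(w), 1)
  # permutation equivariance
  perm <- sample(7)
  expect_equal(aic_weights(a[perm]), w[perm])
  # invariant to a constant shift
  expect_equal(aic_weights(a + 50), w)
})

test_that("Holm adjustment matches a hand step-down oracle", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(4)
  for (r in 1:1000) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))
  }
})

# Small balanced simulated dataset with optional fixed effects.
sim_glmm_data <- function(n_ind = 30, n_obs = 6, sex_effect = 0,
                          family = "gaussian", sd_ind = 0.5, sd_res = 1,
                          intercept = 0) {
  ind <- rep(sprintf("i%02d", 1:n_ind), each = n_obs)
  sex <- rep(rep(c("female", "male"), length.out = n_ind), each = n_obs)
  year <- rep(rep(2012:2015, length.out = n_ind), each = n_obs)
  colony <- rep(rep(c("A", "B"), length.out = n_ind), each = n_obs)
  eta <- intercept + sex_effect * (sex == "male") +
    rep(rnorm(n_ind, 0, sd_ind), each = n_obs)
  y <- switch(family,
    gaussian = eta + rnorm(length(eta), 0, sd_res),
    poisson = rpois(length(eta), exp(eta)),
    binomial = rbinom(length(eta), 1, plogis(eta))
  )
  tibble::tibble(y = y, sex = sex, individual_id = ind,
                 year = factor(year), colony = colony)
}

test_that("gaussian mixed fits recover a planted effect with honest SEs", {
  set.seed(11)
  hits <- 0
  n_rep <- 40
  delta <- 0.8
  for (r in 1:n_rep) {
    d <- sim_glmm_data(n_ind = 30, n_obs = 6, sex_effect = delta)
    fit <- fit_mixed(d, "y", fixed = "sex", family = "gaussian",
                     random = c("individual_id", "year", "colony"),
                     method = "ML")
    co <- fit$coefficients[fit$coefficients$term == "sexmale", ]
    hits <- hits + (abs(co$estimate - delta) <= 2 * co$std_error)
  }
  # nominal ~95% coverage of +-2 SE
  expect_gte(hits / n_rep, 0.85)
})

test_that("poisson fits back-transform to the planted rate ratio", {
  set.seed(12)
  d <- sim_glmm_data(n_ind = 60, n_obs = 10, sex_effect = log(2),
                     family = "poisson", sd_ind = 0.2, intercept = 1.5)
  fit <- fit_mixed(d, "y", fixed = "sex", family = "poisson")
  co <- fit$coefficients[fit$coefficients$term == "sexmale", ]
  expect_equal(co$back_transformed, 2, tolerance = 0.12)
})

test_that("LRT p-values are uniform under the null", {
  set.seed(13)
  ps <- replicate(120, {
    d <- sim_glmm_data(n_ind = 20, n_obs = 4, sex_effect = 0)
    fit <- suppressMessages(
      fit_mixed(d, "y", fixed = "sex", family = "gaussian",
                random = "individual_id", method = "ML"))
    suppressMessages(lrt_term(fit, "sex")$p_value)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("random factors with a single level are dropped with a warning", {
  d <- sim_glmm_data(n_ind = 10, n_obs = 4)
  d$colony <- "A"
  expect_warning(fit <- fit_mixed(d, "y", fixed = "sex",
                                  random = c("individual_id", "colony")),
                 "dropped")
  expect_equal(fit$random, "individual_id")
})

test_that("backward elimination respects marginality and prunes noise", {
  set.seed(14)
  # planted interaction: both mains must survive regardless of own p
  n_ind <- 40; n_obs <- 8
  ind <- rep(sprintf("i%02d", 1:n_ind), each = n_obs)
  sex <- rep(rep(c("female", "male"), length.out = n_ind), each = n_obs)
  period <- sample(period_levels(), n_ind * n_obs, replace = TRUE)
  y <- 1 + 1.5 * (sex == "male" & period == "nestling") +
    rep(rnorm(n_ind, 0, 0.3), each = n_obs) + rnorm(n_ind * n_obs, 0, 0.8)
  d <- tibble::tibble(y = y, sex = sex,
                      period = factor(period, levels = period_levels()),
                      individual_id = ind, noise = rnorm(n_ind * n_obs))
  res <- backward_stepwise(d, "y", fixed = c("sex * period", "noise"),
                           family = "gaussian", random = "individual_id")
  expect_true("sex:period" %in% res$terms)
  expect_true(all(c("sex", "period") %in% res$terms))
  expect_false("noise" %in% res$terms)

  # pure noise: everything droppable goes, intercept-only survives
  set.seed(15)
  d0 <- tibble::tibble(y = rnorm(400), x1 = rnorm(400), x2 = rnorm(400),
                       individual_id = rep(sprintf("i%02d", 1:40), each = 10))
  res0 <- backward_stepwise(d0, "y", fixed = c("x1", "x2"),
                            family = "gaussian", random = "individual_id")
  expect_equal(res0$terms, character(0))
  # the protected correction factor is never dropped
  resk <- backward_stepwise(d0, "y", fixed = c("x1", "x2"),
                            family = "gaussian", random = "individual_id",
                            keep = "x2")
  expect_true("x2" %in% resk$terms)
})

test_that("penalized smooths shrink to linear under pure noise", {
  set.seed(16)
  d <- tibble::tibble(doy = runif(200, 60, 200), mass = rnorm(200),
                      individual_id = rep(sprintf("i%02d", 1:20), each = 10))
  fit <- fit_smooth(d, "mass", smooth_var = "doy", random = "individual_id")
  expect_lt(fit$edf[["s(doy)"]], 1.6)
})

test_that("AIC prefers the no-sex smooth model when sex is absent", {
  set.seed(17)
  wins <- 0
  for (r in 1:10) {
    d <- simulate_body_mass(body_mass_params(sex_offset_g = 0),
                            seed = 1000 + r)
    f1 <- fit_smooth(d, "mass", fixed = "sex", random = "individual_id")
    f0 <- fit_smooth(d, "mass", random = "individual_id")
    wins <- wins + (f0$AIC < f1$AIC)
  }
  expect_gte(wins, 8)
})

test_that("post-hoc contrasts localise a male-only nestling shift", {
  set.seed(18)
  n_ind <- 40; n_obs <- 12
  ind <- rep(sprintf("i%02d", 1:n_ind), each = n_obs)
  sex <- rep(rep(c("female", "male"), length.out = n_ind), each = n_obs)
  period <- factor(sample(period_levels(), n_ind * n_obs, replace = TRUE),
                   levels = period_levels())
  y <- 1 + 2 * (sex == "male" & period == "nestling") +
    rep(rnorm(n_ind, 0, 0.3), each = n_obs) + rnorm(n_ind * n_obs, 0, 0.7)
  d <- tibble::tibble(y = y, sex = sex, period = period, individual_id = ind)
  fit <- fit_mixed(d, "y", fixed = "sex * period", family = "gaussian",
                   random = "individual_id", method = "REML")
  ct <- posthoc_contrasts(fit)$contrasts
  sex_by_period <- ct[ct$family == "sex_within_period", ]
  expect_true(sex_by_period$p_adj[sex_by_period$group == "nestling"] < 0.05)
  expect_true(all(sex_by_period$p_adj[sex_by_period$group != "nestling"] > 0.05))
  # letters: male nestling mean separates from the other male periods
  lt <- posthoc_contrasts(fit)$letters
  male <- lt[lt$sex == "male", ]
  others <- male$letter[male$period != "nestling"]
  nest <- male$letter[male$period == "nestling"]
  expect_false(any(mapply(function(a, b) any(strsplit(a, "")[[1]] %in%
                                               strsplit(b, "")[[1]]),
                          others, nest)))
})

test_that("compact letters share a letter exactly for non-separated groups", {
  # three groups, only A vs C significant
  lt <- compact_letters(c("A", "B", "C"),
                        c("A - B", "A - C", "B - C"),
                        c(FALSE, TRUE, FALSE), order_by = c(1, 2, 3))
  shares <- function(a, b) any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  expect_true(shares(lt[1], lt[2]))
  expect_true(shares(lt[2], lt[3]))
  expect_false(shares(lt[1], lt[3]))
})

test_that("chi-squared homogeneity matches hand computation", {
  even <- rbind(a = c(10, 20, 30), b = c(10, 20, 30))
  r <- chisq_homogeneity(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2)

  r2 <- suppressWarnings(chisq_homogeneity(rbind(c(10, 20), c(20, 10))))
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(r2$df, 1)

  # a 2 x 9 table has df 8; the chi-square CDF places 9.49 near p = 0.30
  t9 <- simulate_habitat_counts(n_per_sex = 161, seed = 5)
  r9 <- suppressWarnings(chisq_homogeneity(t9))
  expect_equal(r9$df, 8)
  expect_equal(pchisq(9.49, 8, lower.tail = FALSE), 0.30, tolerance = 0.01)
  expect_error(chisq_homogeneity(rbind(c(0, 0), c(0, 0))), "table")
})
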