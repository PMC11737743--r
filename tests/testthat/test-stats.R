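test_that("the AA mixed model recovers known fixed effects and variances", {
  set.seed(301)
  nrep <- 60
  ests <- purrr::map_dfr(seq_len(nrep), function(r) {
    fit <- fit_aa_model(make_aa_data())
    co <- tidy(fit)
    tibble::tibble(
      down = co$estimate[co$term == "concave_down"],
      up = co$estimate[co$term == "concave_up"],
      down_lo = co$conf.low[co$term == "concave_down"],
      down_hi = co$conf.high[co$term == "concave_down"],
      vb = fit$variance_components[["between_participant"]],
      vr = fit$variance_components[["residual"]]
    )
  })
  expect_equal(mean(ests$down), -2.3, tolerance = 0.05)
  expect_equal(mean(ests$up), 2.3, tolerance = 0.05)
  expect_equal(mean(ests$vb), 2.5^2, tolerance = 0.1)
  expect_equal(mean(ests$vr), 2^2, tolerance = 0.1)
  coverage <- mean(ests$down_lo <= -2.3 & -2.3 <= ests$down_hi)
  expect_gt(coverage, 0.85)  # ~95% within binomial error at 60 replicates
})

test_that("AA model output is structured and internally consistent", {
  set.seed(11)
  fit <- fit_aa_model(make_aa_data(n = 20))
  co <- tidy(fit)
  expect_equal(co$comparison,
               c("linear vs concave_down", "linear vs concave_up",
                 "concave_down vs concave_up"))
  expect_true(all(co$conf.low <= co$estimate & co$estimate <= co$conf.high))
  # pairwise contrast is exactly the difference of the two coefficients
  expect_equal(co$estimate[3], co$estimate[2] - co$estimate[1])
  g <- glance(fit)
  expect_equal(g$nobs, 60L)
  expect_true(g$vpc_classic >= 0 && g$vpc_classic <= 1)
})

test_that("equal group means with no clustering give near-zero effects", {
  set.seed(5)
  dat <- make_aa_data(n = 30, delta_down = 0, delta_up = 0, sd_between = 0,
                      sd_resid = 1)
  fit <- suppressMessages(fit_aa_model(dat))
  expect_lt(max(abs(tidy(fit)$estimate)), 0.75)
  expect_lt(fit$variance_components[["between_participant"]], 0.5)
})

test_that("missing shaping-function levels are an informative error", {
  dat <- make_aa_data(n = 10)
  expect_error(fit_aa_model(dplyr::filter(dat,
                                          .data$function_label != "linear")),
               "missing shaping-function level")
  expect_error(fit_aa_model(dat[dat$participant_id == "P01", ]),
               "at least 2 participants")
})

test_that("variance partition reports both decompositions coherently", {
  set.seed(77)
  # sigma_between = sigma_resid and null fixed effects: classic VPC ~ 0.5
  dat <- make_aa_data(n = 120, delta_down = 0, delta_up = 0,
                      sd_between = 2, sd_resid = 2)
  vp <- variance_partition(fit_aa_model(dat))
  expect_equal(attr(vp, "vpc_classic"), 0.5, tolerance = 0.15)
  expect_equal(sum(vp$share_of_total), 1)
  expect_true(all(vp$variance >= 0))
  two <- attr(vp, "two_component_shares")
  expect_equal(sum(two), 1)
  # zero random-intercept variance: VPC collapses to 0
  dat0 <- make_aa_data(n = 40, sd_between = 0, sd_resid = 1)
  vp0 <- variance_partition(suppressMessages(fit_aa_model(dat0)))
  expect_lt(attr(vp0, "vpc_classic"), 0.1)
})

test_that("the count model recovers IRRs with near-nominal coverage", {
  set.seed(302)
  nrep <- 60
  ests <- purrr::map_dfr(seq_len(nrep), function(r) {
    fit <- fit_clicks_model(make_clicks_data(irr_down = 1.10))
    co <- tidy(fit)
    tibble::tibble(irr = co$irr[co$term == "concave_down"],
                   lo = co$irr.conf.low[co$term == "concave_down"],
                   hi = co$irr.conf.high[co$term == "concave_down"])
  })
  expect_equal(mean(ests$irr), 1.10, tolerance = 0.02)
  expect_gt(mean(ests$lo <= 1.10 & 1.10 <= ests$hi), 0.85)
})

test_that("identical count distributions give IRR near 1", {
  set.seed(8)
  dat <- make_clicks_data(irr_down = 1, irr_up = 1)
  fit <- fit_clicks_model(dat)
  expect_equal(tidy(fit)$irr, rep(1, 3), tolerance = 0.08)
  expect_equal(tidy(fit)$irr, exp(tidy(fit)$estimate))
})

test_that("Pearson dispersion separates Poisson from negative-binomial data", {
  set.seed(12)
  pois <- make_clicks_data(theta = 1e9)  # effectively equidispersed
  # glm.nb warns that theta diverges on equidispersed data; expected here
  fit_pois <- suppressWarnings(fit_clicks_model(pois))
  expect_equal(fit_pois$dispersion, 1, tolerance = 0.15)
  nb <- make_clicks_data(theta = 3)
  expect_gt(fit_clicks_model(nb)$dispersion, 3)
})

test_that("non-integer or negative counts are rejected", {
  dat <- make_clicks_data()
  dat$total_clicks[1] <- 2.5
  expect_error(fit_clicks_model(dat), "non-negative integers")
  dat$total_clicks[1] <- -3
  expect_error(fit_clicks_model(dat), "non-negative integers")
})

test_that("changing the referent permutes coefficients but not contrasts", {
  set.seed(44)
  dat <- make_aa_data(n = 30)
  f1 <- tidy(fit_aa_model(dat, referent = "linear"))
  f2 <- tidy(fit_aa_model(dat, referent = "concave_down"))
  # linear -> concave_up effect must equal the (referent = concave_down)
  # difference of concave_up and linear coefficients
  up_vs_lin_1 <- f1$estimate[f1$term == "concave_up"]
  up_vs_lin_2 <- f2$estimate[f2$term == "concave_up"] -
    f2$estimate[f2$term == "linear"]
  expect_equal(up_vs_lin_1, up_vs_lin_2, tolerance = 1e-8)
  dat_c <- make_clicks_data()
  g1 <- tidy(fit_clicks_model(dat_c, referent = "linear"))
  g2 <- tidy(fit_clicks_model(dat_c, referent = "concave_up"))
  d_vs_l_1 <- g1$estimate[g1$term == "concave_down"]
  d_vs_l_2 <- g2$estimate[g2$term == "concave_down"] -
    g2$estimate[g2$term == "linear"]
  expect_equal(d_vs_l_1, d_vs_l_2, tolerance = 1e-8)
})

test_that("residual diagnostics export quantile pairs and densities", {
  set.seed(19)
  fit <- fit_aa_model(make_aa_data(n = 54))
  d <- residual_diagnostics(fit)
  expect_equal(nrow(d$qq), nobs(fit$model))
  expect_false(d$degenerate)
  expect_false(is.unsorted(d$qq$observed))
  # near-normal residuals track the identity line after standardization
  sc <- scale(d$qq$observed)
  expect_lt(max(abs(sc - d$qq$theoretical)), 0.8)
  expect_gt(nrow(d$density), 0)
  fitc <- fit_clicks_model(make_clicks_data())
  dc <- residual_diagnostics(fitc)
  expect_equal(nrow(dc$qq), nobs(fitc$model))
  # constant residuals are flagged as degenerate
  flat <- structure(list(model = lm(rep(5, 20) ~ 1)), class = "aa_fit")
  expect_true(residual_diagnostics(flat)$degenerate)
})

test_that("descriptives table has per-arm and pooled rows", {
  log <- small_cohort_log()
  desc <- outcome_descriptives(aa_table(log), clicks_table(log))
  expect_equal(nrow(desc), 4)
  expect_true("all_functions" %in% desc$function_label)
  expect_true(all(c("aa_mean", "aa_sd", "clicks_mean", "clicks_sd") %in%
                    names(desc)))
  lin <- desc[desc$function_label == "linear", ]
  aa <- aa_table(log)
  expect_equal(lin$aa_mean, mean(aa$aa[aa$function_label == "linear"]))
})
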