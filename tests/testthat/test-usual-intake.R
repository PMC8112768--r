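# Back-transformation, pseudo-population simulation and summaries.

test_that("quadrature back-transform is exact where the inverse is polynomial", {
  # linear inverse (lambda = 1): exact at any node count and any sigma
  for (nn in c(2, 5, 9))
    expect_equal(backtransform_mean(2, transform_spec(1), 4, n_nodes = nn), 3)
  # quadratic inverse (lambda = 0.5): exact from 2 nodes up
  for (nn in 2:9)
    expect_equal(backtransform_mean(2, transform_spec(0.5), 1, n_nodes = nn),
                 4.25, tolerance = 1e-12)
})

test_that("log-transform back-transform matches the lognormal mean closed form", {
  # E[exp(b + e)] = exp(b + s2/2)
  expect_equal(backtransform_mean(1, transform_spec(0), 0.25, n_nodes = 9),
               exp(1.125), tolerance = 1e-4 * exp(1.125))
  for (sig in c(0.2, 0.5, 0.7)) {
    approxv <- backtransform_mean(0.7, transform_spec(0), sig^2, n_nodes = 9)
    exact <- exp(0.7 + sig^2 / 2)
    expect_lt(abs(approxv - exact) / exact, 0.001)
  }
  expect_error(backtransform_mean(NaN, transform_spec(0), 1), "non-finite")
})

test_that("pseudo-population bookkeeping, determinism and stream independence", {
  gp <- generate_population(synthetic_spec(n_persons = 50, seed = 4))
  m <- fit_mixed_model(gp$data, transform = transform_spec(1))
  ps <- simulate_pseudo_population(m, gp$data, m = 100, seed = 9)
  expect_equal(nrow(ps), 5000)
  expect_equal(ps$total_intake,
               ps$usual_food_intake + ps$supplement_contribution)
  # weight shares: each person's m shares sum to the person weight
  shares <- tapply(ps$weight_share, ps$source_person_id, sum)
  w <- gp$data$recalls$weight[!duplicated(gp$data$recalls$person_id)]
  expect_equal(as.numeric(shares[unique(ps$source_person_id)]), unname(w))
  # fixed seed: bit-identical rerun
  ps2 <- simulate_pseudo_population(m, gp$data, m = 100, seed = 9)
  expect_identical(ps, ps2)
  # per-person streams: dropping persons leaves the remaining draws intact
  sub <- gp$data
  keep <- gp$data$recalls$person_id %in% unique(gp$data$recalls$person_id)[1:20]
  sub$recalls <- gp$data$recalls[keep, ]
  ps_sub <- simulate_pseudo_population(m, sub, m = 100, seed = 9)
  expect_equal(ps_sub$usual_food_intake,
               ps$usual_food_intake[ps$source_person_id %in%
                                      ps_sub$source_person_id])
})

test_that("zero between-person variance collapses each person's pseudo-draws", {
  df <- tiny_recalls()
  df$intake <- rep(c(10, 8, 15), each = 2)  # no within-person variation
  d <- recall_data(df, weight = "weight")
  m <- fit_mixed_model(d, transform = transform_spec(1))
  m$sigma2_between <- 0
  ps <- simulate_pseudo_population(m, d, m = 10, seed = 1)
  spread <- tapply(ps$usual_food_intake, ps$source_person_id,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("simulated weighted mean matches the lognormal closed form within 1%", {
  # n chosen so the sampling error of the population mean (sd ~ 0.35%) sits
  # well inside the 1% band
  sp <- synthetic_spec(n_persons = 20000, lambda = 0, beta0 = 1,
                       sigma2_u = 0.25, sigma2_e = 0.25, seed = 12)
  gp <- generate_population(sp)
  m <- fit_mixed_model(gp$data, transform = transform_spec(0))
  ps <- simulate_pseudo_population(m, gp$data, m = 50, seed = 3)
  expect_lt(abs(wmean(ps$total_intake, ps$weight_share) - exp(1.25)) /
              exp(1.25), 0.01)
})

test_that("weighted quantiles follow the stated interpolation convention", {
  expect_equal(weighted_quantile(1:4, rep(1, 4), 0.5), 2.5)
  expect_equal(weighted_quantile(c(1, 2, 3, 4), c(0, 0, 5, 0), c(0.1, 0.9)),
               c(3, 3))
  # monotone in level; invariant to uniform weight rescaling
  set.seed(1)
  x <- rlnorm(200); w <- runif(200)
  p <- seq(0.05, 0.95, by = 0.05)
  q1 <- weighted_quantile(x, w, p)
  expect_true(all(diff(q1) >= 0))
  expect_equal(q1, weighted_quantile(x, 17.3 * w, p))
})

test_that("distribution_summary reports percentiles, cutoffs and subgroups correctly", {
  ps <- make_pseudo(c(1, 2, 3, 4), sex = c("F", "F", "M", "M"))
  s <- distribution_summary(ps, percentiles = c(25, 50, 75),
                            cutoffs_below = c(0.5, 2.5),
                            cutoffs_above = c(3.5))
  expect_equal(s$p50, 2.5)
  expect_true(s$p25 <= s$p50 && s$p50 <= s$p75)
  expect_equal(s$below_0.5, 0)
  expect_equal(s$below_2.5, 50)
  expect_equal(s$above_3.5, 25)
  sg <- distribution_summary(ps, by = "sex")
  expect_equal(sort(sg$subgroup), c("F", "M"))
  expect_equal(sg$mean[sg$subgroup == "F"], 1.5)
})

test_that("doubling m changes summaries only within Monte-Carlo tolerance", {
  gp <- generate_population(synthetic_spec(n_persons = 400, seed = 6))
  m <- fit_mixed_model(gp$data, transform = transform_spec(1))
  s1 <- distribution_summary(
    simulate_pseudo_population(m, gp$data, m = 100, seed = 2))
  s2 <- distribution_summary(
    simulate_pseudo_population(m, gp$data, m = 200, seed = 2))
  expect_equal(s1$mean, s2$mean, tolerance = 0.01)
  expect_equal(s1$p50, s2$p50, tolerance = 0.01)
})

test_that("the orchestrator refuses single-day data without an external ratio", {
  gp <- generate_population(synthetic_spec(n_persons = 60, n_recalls = 1,
                                           seed = 3))
  expect_error(estimate_usual_intake(gp$data, transform = transform_spec(1)),
               "variance_ratio")
  fit <- estimate_usual_intake(gp$data, transform = transform_spec(1),
                               variance_ratio = 2, m = 20, seed = 1)
  expect_s3_class(fit$summary, "distribution_summary")
  expect_true(all(c("mean", "mean_supplement", "p25", "p50", "p75") %in%
                    names(fit$summary)))
})

test_that("pseudo-population round-trips through CSV", {
  gp <- generate_population(synthetic_spec(n_persons = 30, seed = 8))
  fit <- estimate_usual_intake(gp$data, transform = transform_spec(1),
                               m = 10, seed = 2, keep_pseudo = TRUE)
  path <- tempfile(fileext = ".csv")
  write_pseudo_population(fit$pseudo, path)
  back <- read_pseudo_population(path)
  expect_equal(back$total_intake, fit$pseudo$total_intake, tolerance = 1e-12)
  expect_equal(names(back), names(fit$pseudo))
})
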