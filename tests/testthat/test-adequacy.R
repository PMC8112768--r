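# EAR cut-point and full-probability prevalence.

test_that("cut-point prevalence matches the hand-counted fixture", {
  ps <- make_pseudo(c(700, 900, 1100, 2600),
                    sex = rep("F", 4), age = c(30, 30, 60, 60))
  refs <- reference_table(data.frame(
    sex = "F", age_min = c(18, 50), age_max = c(50, 150),
    ear = c(800, 1000), ul = 2500))
  out <- prevalence_cut_point(ps, refs)
  expect_equal(out$inadequate_pct, 25)
  expect_equal(out$excessive_pct, 25)
})

test_that("age-interval matching follows the <=50 / >50 boundary convention", {
  refs <- calcium_refs()
  mr <- match_reference(c("F", "F", "F"), c(50, 51, 55), refs)
  expect_equal(mr$ear, c(800, 1000, 1000))
  expect_equal(mr$ul, c(2500, 2000, 2000))
  expect_error(match_reference("M", 40, refs), "no reference row.*sex=M")
})

test_that("all-adequate populations give zero prevalence both ways", {
  ps <- make_pseudo(c(1200, 1500), sex = c("F", "F"), age = c(30, 40))
  out <- prevalence_cut_point(ps, calcium_refs())
  expect_equal(out$inadequate_pct, 0)
  expect_equal(out$excessive_pct, 0)
})

test_that("risk interpolation follows the tabulated-CDF convention", {
  d <- requirement_distribution(p = c(0.05, 0.50, 0.95), q = c(1, 2, 4),
                                absorption = 0.18)
  # absorbed 0.18 * 8.333 = 1.5 -> F = 0.05 + 0.45 * 0.5 = 0.275
  expect_equal(risk_of_inadequacy(8.333, d), 1 - 0.275, tolerance = 1e-4)
  # outside the table: risk 1 below, 0 above
  expect_equal(risk_of_inadequacy(0, d), 1)
  expect_equal(risk_of_inadequacy(1000, d), 0)
  # degenerate point mass reduces to a cut-point at R
  pm <- requirement_distribution(p = 0.5, q = 2, absorption = 1)
  expect_equal(risk_of_inadequacy(c(1.99, 2, 2.01), pm), c(1, 0, 0))
  expect_error(requirement_distribution(p = c(0.2, 0.1), q = c(1, 2)),
               "strictly increasing")
})

test_that("risk is non-increasing in intake and in absorption, clamped to [0,1]", {
  d <- requirement_distribution(p = c(0.1, 0.5, 0.9), q = c(2, 5, 11))
  y <- seq(0, 100, by = 0.5)
  r <- risk_of_inadequacy(y, d)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r >= 0 & r <= 1))
  for (yy in c(10, 30, 60)) {
    ra <- vapply(c(0.1, 0.18, 0.5, 1), function(a)
      risk_of_inadequacy(yy, requirement_distribution(d$p, d$q, a)),
      numeric(1))
    expect_true(all(diff(ra) <= 0))
  }
})

test_that("full-probability equals cut-point exactly for point-mass requirements", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 40
    ps <- make_pseudo(runif(n, 500, 3000), weight = runif(n, 0.5, 3),
                      sex = rep("F", n), age = round(runif(n, 20, 70)))
    refs <- calcium_refs()
    mr <- match_reference(ps$sex, ps$age, refs)
    ps$agegrp <- ifelse(ps$age <= 50, "le50", "gt50")
    dists <- list(
      le50 = requirement_distribution(p = 0.5, q = 800, absorption = 1),
      gt50 = requirement_distribution(p = 0.5, q = 1000, absorption = 1))
    fp <- prevalence_full_probability(ps, dists, group = "agegrp")
    cp <- prevalence_cut_point(ps, refs)
    expect_equal(fp$inadequate_pct, cp$inadequate_pct, tolerance = 1e-12)
  }
})

test_that("independent uniform intake and requirement give 50% inadequacy", {
  # requirement ~ U(10, 20) tabulated finely; intake ~ U(10, 20)
  pgrid <- seq(0.001, 0.999, by = 0.001)
  d <- requirement_distribution(pgrid, 10 + 10 * pgrid, absorption = 1)
  set.seed(11)
  n <- 20000
  ps <- make_pseudo(runif(n, 10, 20))
  out <- prevalence_full_probability(ps, d)
  # brute-force Monte-Carlo oracle: P(req > intake) for independent draws
  oracle <- 100 * mean(runif(n, 10, 20) > runif(n, 10, 20))
  expect_lt(abs(out$inadequate_pct - 50), 1)
  expect_lt(abs(out$inadequate_pct - oracle), 2)
})

test_that("prevalences are invariant to weight rescaling and row order", {
  set.seed(2)
  n <- 30
  ps <- make_pseudo(runif(n, 400, 2800), weight = runif(n, 1, 4),
                    sex = rep("F", n), age = round(runif(n, 25, 65)))
  refs <- calcium_refs()
  base <- prevalence_cut_point(ps, refs)
  ps2 <- ps; ps2$weight_share <- ps2$weight_share * 100
  expect_equal(prevalence_cut_point(ps2, refs), base)
  perm <- sample(n)
  ps3 <- ps[perm, ]; class(ps3) <- class(ps)
  expect_equal(prevalence_cut_point(ps3, refs)$inadequate_pct,
               base$inadequate_pct)
})

test_that("symmetric narrow requirements: both methods agree within 1 pp", {
  # the cut-point approximation holds for a symmetric requirement whose
  # spread (sd 50) is small relative to the intake spread (sd 300)
  pgrid <- seq(0.005, 0.995, by = 0.005)
  d <- requirement_distribution(pgrid, qnorm(pgrid, 800, 50), absorption = 1)
  set.seed(3)
  n <- 20000
  ps <- make_pseudo(rnorm(n, 900, 300), sex = rep("F", n),
                    age = rep(30, n))
  ps$total_intake <- pmax(ps$total_intake, 1)
  ps$usual_food_intake <- ps$total_intake
  refs <- reference_table(data.frame(sex = "F", age_min = 18, age_max = 150,
                                     ear = 800, ul = 2500))
  fp <- prevalence_full_probability(ps, d)
  cp <- prevalence_cut_point(ps, refs)
  expect_lt(abs(fp$inadequate_pct - cp$inadequate_pct), 1)
})

test_that("missing groups and empty populations raise errors", {
  ps <- make_pseudo(c(10, 20), grp = c("a", "b"))
  d <- list(a = requirement_distribution(0.5, 15, absorption = 1))
  expect_error(prevalence_full_probability(ps, d, group = "grp"),
               "no requirement distribution.*b")
  empty <- ps[0, ]; class(empty) <- class(ps)
  expect_error(prevalence_full_probability(empty, d$a), "empty")
})
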