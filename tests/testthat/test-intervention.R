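# Fortification (add-then-shrink) and additive scenarios (shrink-then-add).

test_that("fortification arithmetic and immutability of the input", {
  df <- data.frame(person_id = "x", recall_index = 1, intake = 100,
                   vehicle_oil = 10)
  d <- recall_data(df, vehicles = "vehicle_oil")
  out <- apply_fortification(d, fortification("vehicle_oil", 12))
  expect_equal(out$recalls$intake, 220)   # 100 + 10 g x 12 ug/g
  expect_equal(d$recalls$intake, 100)     # input untouched
  # zero consumption and zero level are no-ops
  df0 <- df; df0$vehicle_oil <- 0
  d0 <- recall_data(df0, vehicles = "vehicle_oil")
  expect_equal(apply_fortification(d0, fortification("vehicle_oil", 12))$recalls$intake, 100)
  expect_equal(apply_fortification(d, fortification("vehicle_oil", 0))$recalls,
               d$recalls)
  expect_error(apply_fortification(d, fortification("vehicle_x", 1)),
               "vehicle column")
  expect_error(fortification("vehicle_oil", -2), ">= 0")
})

test_that("supplement program hits dose x coverage and respects edge coverages", {
  n <- 10000
  ps <- make_pseudo(rep(100, n))
  sp <- supplement_program(dose = 167, coverage = 0.9)
  out <- add_supplement_program(ps, sp, seed = 42)
  mc <- mean(out$supplement_contribution)
  # Bernoulli sampling error: 3 sd of 167 * sqrt(p(1-p)/n)
  expect_lt(abs(mc - 167 * 0.9), 3 * 167 * sqrt(0.9 * 0.1 / n))
  expect_equal(out$total_intake,
               out$usual_food_intake + out$supplement_contribution)

  out0 <- add_supplement_program(ps, supplement_program(167, 0), seed = 1)
  expect_equal(out0$supplement_contribution, rep(0, n))
  expect_equal(out0$total_intake, ps$total_intake)
  out1 <- add_supplement_program(ps, supplement_program(167, 1), seed = 1)
  expect_equal(out1$total_intake, ps$total_intake + 167)
  expect_error(supplement_program(167, 1.2), "\\[0, 1\\]")
})

test_that("eligibility predicates restrict program assignment", {
  ps <- make_pseudo(rep(10, 100), sex = rep(c("F", "M"), 50))
  sp <- supplement_program(30, 1, eligible = function(d) d$sex == "F")
  out <- add_supplement_program(ps, sp, seed = 3)
  expect_true(all(out$supplement_contribution[out$sex == "F"] == 30))
  expect_true(all(out$supplement_contribution[out$sex == "M"] == 0))
})

test_that("fixed additions map by stratum and by person, erroring on unmapped keys", {
  ps <- make_pseudo(rep(100, 6), stratum = rep(c("North", "South", "Cities"), 2),
                    breastfed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  bm <- fixed_addition(c(North = 550.6, South = 232.2, Cities = 473.2),
                       key = "stratum",
                       eligible = function(d) d$breastfed)
  out <- add_fixed_amounts(ps, bm)
  expect_equal(out$supplement_contribution[1:3], c(550.6, 232.2, 473.2))
  expect_equal(out$supplement_contribution[4:6], c(0, 0, 0))
  expect_equal(out$total_intake[4:6], ps$total_intake[4:6])

  # person-level map
  ps2 <- make_pseudo(c(100, 100))
  pm <- fixed_addition(c(p001 = 30, p002 = 0), key = "source_person_id")
  out2 <- add_fixed_amounts(ps2, pm)
  expect_equal(out2$total_intake, c(130, 100))

  bad <- fixed_addition(c(North = 550.6), key = "stratum")
  expect_error(add_fixed_amounts(ps, bad), "unmapped key.*South|unmapped key.*Cities")
})

test_that("contributions conserve exactly and additive steps commute for fixed seed", {
  ps <- make_pseudo(runif(500, 50, 150), stratum = rep("N", 500))
  sp <- supplement_program(167, 0.6, label = "vita")
  fx <- fixed_addition(c(N = 550.6), key = "stratum")
  a <- add_fixed_amounts(add_supplement_program(ps, sp, seed = 7), fx)
  b <- add_supplement_program(add_fixed_amounts(ps, fx), sp, seed = 7)
  expect_identical(a, b)
  expect_equal(a$total_intake - a$usual_food_intake,
               a$supplement_contribution, tolerance = 0)
  # independent streams: adding a second scenario never perturbs the first
  sp2 <- supplement_program(30, 0.5, label = "iron")
  c1 <- add_supplement_program(ps, sp, seed = 7)
  c2 <- add_supplement_program(add_supplement_program(ps, sp2, seed = 7),
                               sp, seed = 7)
  got_vita_alone <- c1$supplement_contribution > 0
  got_vita_after <- (c2$supplement_contribution -
                       add_supplement_program(ps, sp2, seed = 7)$supplement_contribution) > 0
  expect_identical(got_vita_alone, got_vita_after)
})

test_that("prevalence responds monotonically to dose, coverage and level", {
  gp <- generate_population(synthetic_spec(n_persons = 300, beta0 = 700,
                                           sigma2_u = 10000, sigma2_e = 20000,
                                           seed = 14))
  refs <- reference_table(data.frame(sex = c("F", "M"), age_min = 0,
                                     age_max = 150, ear = 800, ul = 2500))
  fit <- estimate_usual_intake(gp$data, transform = transform_spec(1),
                               m = 50, seed = 2, keep_pseudo = TRUE)
  prev_at <- function(dose, coverage) {
    out <- add_supplement_program(fit$pseudo,
                                  supplement_program(dose, coverage),
                                  seed = 5)
    prevalence_cut_point(out, refs)$inadequate_pct
  }
  prevs_dose <- vapply(c(0, 50, 100, 200), function(d) prev_at(d, 0.9),
                       numeric(1))
  expect_true(all(diff(prevs_dose) <= 0))
  prevs_cov <- vapply(c(0, 0.3, 0.6, 1), function(p) prev_at(100, p),
                      numeric(1))
  expect_true(all(diff(prevs_cov) <= 0))
  prev_fort <- vapply(c(0, 5, 20), function(lv) {
    d2 <- apply_fortification(gp$data, fortification("vehicle_oil", lv))
    f2 <- estimate_usual_intake(d2, transform = transform_spec(1), m = 50,
                                seed = 2, keep_pseudo = TRUE)
    prevalence_cut_point(f2$pseudo, refs)$inadequate_pct
  }, numeric(1))
  expect_true(all(diff(prev_fort) <= 0))
  excess_fort <- vapply(c(0, 50, 200), function(lv) {
    d2 <- apply_fortification(gp$data, fortification("vehicle_oil", lv))
    f2 <- estimate_usual_intake(d2, transform = transform_spec(1), m = 50,
                                seed = 2, keep_pseudo = TRUE)
    prevalence_cut_point(f2$pseudo, refs)$excessive_pct
  }, numeric(1))
  expect_true(all(diff(excess_fort) >= 0))
})

test_that("constant vehicle consumption with identity transform shifts usual intake by v x level", {
  # oracle: with lambda = 1 the model is linear, so adding v x level to every
  # recall of a person adds exactly v x level to that person's usual intake
  gp <- generate_population(synthetic_spec(n_persons = 80, seed = 17))
  d <- gp$data
  d$recalls$vehicle_oil <- 7            # constant across persons and recalls
  f0 <- estimate_usual_intake(d, transform = transform_spec(1), m = 30,
                              seed = 4, keep_pseudo = TRUE)
  d1 <- apply_fortification(d, fortification("vehicle_oil", 12))
  f1 <- estimate_usual_intake(d1, transform = transform_spec(1), m = 30,
                              seed = 4, keep_pseudo = TRUE)
  shift <- f1$pseudo$usual_food_intake - f0$pseudo$usual_food_intake
  expect_equal(shift, rep(7 * 12, length(shift)), tolerance = 1e-6)
})
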