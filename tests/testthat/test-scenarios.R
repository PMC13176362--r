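test_that("the catalog holds the status quo and the ten enhanced scenarios exactly once", {
  cat1 <- build_catalog()
  expect_length(cat1, 11)
  expect_equal(anyDuplicated(names(cat1)), 0)
  expect_equal(names(cat1)[1], "status_quo")
  expect_setequal(names(cat1),
                  c("status_quo", strategies(), "multi1", "multi2", "all"))
  # default combination membership
  expect_setequal(cat1$multi1$enhanced,
                  c("bp", "aspirin", "statin", "smoking"))
  expect_setequal(cat1$multi2$enhanced,
                  c("bp", "aspirin", "statin", "smoking", "weight"))
  expect_setequal(cat1$all$enhanced, strategies())
  # enhanced strategies run at full adherence, others at status quo
  expect_equal(cat1$bp$adherence$bp, 1)
  expect_equal(cat1$bp$adherence$statin,
               population_config()$adherence[["statin"]])
  # empty enhanced set equals the status quo's adherence
  expect_equal(cat1$status_quo$adherence,
               scenario_spec("x", character())$adherence)
})

test_that("improvement fraction one reproduces full implementation", {
  full <- scenario_spec("a", c("bp", "statin"))
  part <- scenario_spec("b", c("bp", "statin"), improvement_fraction = 1)
  expect_equal(part$adherence, full$adherence)
  half <- scenario_spec("c", "bp", improvement_fraction = 0.5,
                        status_quo_adherence = setNames(rep(0.4, 7),
                                                        strategies()))
  expect_equal(half$adherence$bp, 0.7)
  expect_equal(half$adherence$statin, 0.4)
})

test_that("a null contrast under common random numbers is exactly zero", {
  pop <- generate_population(population_config(n = 200), seed = 44)
  sq <- scenario_spec("status_quo", character())
  clone <- scenario_spec("clone", character())     # same adherence
  res <- run_simulation(pop, list(status_quo = sq, clone = clone),
                        R = 3, seed = 5)
  cmp <- compare(res, "clone")
  expect_identical(cmp$strokes_averted, 0)
  expect_identical(cmp$delta_cost, 0)
  expect_identical(cmp$delta_qaly, 0)
  expect_identical(cmp$nhb, 0)
  # self-comparison likewise
  self <- compare(res, "status_quo", "status_quo")
  expect_identical(self$delta_qaly, 0)
})

test_that("doubling every weight doubles all national totals", {
  pop <- generate_population(population_config(n = 150), seed = 3)
  sc <- build_catalog()[["bp"]]
  st <- strokeprev:::make_streams(150, 10, 9)
  a <- simulate_cohort(pop, sc, streams = st)
  pop2 <- pop; pop2$weight <- pop2$weight * 2
  b <- simulate_cohort(pop2, sc, streams = st)
  expect_equal(b$totals, 2 * a$totals)
})

test_that("enhanced smoking cessation quits the configured fraction in year one", {
  n <- 4000
  pop <- make_pop(n = n, age = 60, smoker = TRUE)
  pop$weight <- 1
  sc <- scenario_spec("smoking", "smoking", horizon = 1)
  res <- simulate_cohort(pop, sc, streams = strokeprev:::make_streams(n, 1, 77))
  quit_frac <- mean(!res$final$smoker)
  expect_lt(abs(quit_frac - 0.12), 2 * sqrt(0.12 * 0.88 / n))
})

test_that("the weight programme cuts every above-floor BMI by exactly 5%", {
  reg0 <- no_drift_registry()
  pop <- generate_population(population_config(n = 500), seed = 19)
  sc <- scenario_spec("weight", "weight", horizon = 1)
  res <- simulate_cohort(pop, sc, reg0,
                         streams = strokeprev:::make_streams(500, 1, 6))
  over <- pop$bmi > 25
  expect_equal(res$final$bmi[over], pop$bmi[over] * 0.95)
  expect_equal(res$final$bmi[!over], pop$bmi[!over])
})

test_that("enhanced BP adherence lowers SBP and stroke burden", {
  pop <- generate_population(population_config(n = 3000), seed = 37)
  cat2 <- build_catalog()[c("status_quo", "bp")]
  res <- run_simulation(pop, cat2, R = 5, seed = 13)
  cmp <- compare(res, "bp")
  expect_gt(cmp$strokes_averted, 0)
  # year-5 mean SBP strictly lower under the enhanced scenario
  st <- strokeprev:::make_streams(3000, 10, 13, 1, 1)
  sq5 <- simulate_cohort(pop, build_catalog()$status_quo, streams = st)
  bp5 <- simulate_cohort(pop, build_catalog()$bp, streams = st)
  expect_lt(mean(bp5$final$sbp), mean(sq5$final$sbp))
})

test_that("comparison demands matched designs", {
  pop <- generate_population(population_config(n = 100), seed = 2)
  res <- run_simulation(pop, build_catalog()[c("status_quo", "bp")],
                        R = 2, seed = 4)
  broken <- res[!(res$scenario == "bp" & res$replicate == 2), ]
  class(broken) <- class(res)
  expect_error(compare(broken, "bp"), "mismatched")
  expect_error(compare(res, "nonexistent"), "not in result")
})

test_that("common random numbers narrow the incremental uncertainty interval", {
  pop <- generate_population(population_config(n = 300), seed = 50)
  cat2 <- build_catalog()[c("status_quo", "bp")]
  paired <- run_simulation(pop, cat2, R = 30, seed = 60)
  ind_a <- run_simulation(pop, cat2["status_quo"], R = 30, seed = 61)
  ind_b <- run_simulation(pop, cat2["bp"], R = 30, seed = 62)
  d_paired <- paired[paired$scenario == "bp", "strokes"] -
    paired[paired$scenario == "status_quo", "strokes"]
  d_indep <- ind_b$strokes - ind_a$strokes
  expect_lt(diff(uncertainty_interval(d_paired)),
            diff(uncertainty_interval(d_indep)))
})

test_that("one-way sensitivity rows with degenerate bounds reproduce the base case", {
  pop <- generate_population(population_config(n = 120), seed = 14)
  reg <- default_registry()
  i <- match("hr_sbp", reg$name)
  reg$low[i] <- reg$base[i]; reg$high[i] <- reg$base[i]
  reg <- strokeprev:::validate_registry(as.data.frame(reg))
  sc <- scenario_spec("bp", "bp")
  tab <- run_owsa(pop, sc, "hr_sbp", reg, R = 2, seed = 9,
                  insulin_variant = FALSE)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$delta_qaly[2], tab$delta_qaly[1])
  expect_equal(tab$delta_qaly[3], tab$delta_qaly[1])
  expect_error(run_owsa(pop, sc, "no_such_param", reg, R = 2, seed = 9),
               "without registry bounds")
})

test_that("raising an intervention's medication cost cannot lower its ICER", {
  pop <- generate_population(population_config(n = 400), seed = 26)
  sc <- scenario_spec("aspirin", "aspirin")
  cat2 <- list(status_quo = scenario_spec("status_quo", character()),
               aspirin = sc)
  reg <- default_registry()
  reg_hi <- reg_set(reg, "cost_aspirin", reg_value(reg, "cost_aspirin", "high"))
  a <- compare(run_simulation(pop, cat2, reg, R = 2, seed = 8), "aspirin")
  b <- compare(run_simulation(pop, cat2, reg_hi, R = 2, seed = 8), "aspirin")
  # identical trajectories (costs do not feed dynamics): same health outcomes
  expect_equal(b$strokes_averted, a$strokes_averted)
  expect_equal(b$delta_qaly, a$delta_qaly)
  expect_gt(b$delta_cost, a$delta_cost)
})

test_that("reports round-trip to CSV and JSON with the full column set", {
  pop <- generate_population(population_config(n = 100), seed = 21)
  res <- run_simulation(pop, build_catalog()[c("status_quo", "bp")],
                        R = 2, seed = 31)
  rep <- cea_report(res)
  need <- c("scenario", "strokes_averted", "stroke_deaths_averted",
            "delta_cost", "delta_qaly", "nhb", "icer", "label",
            "nhb_lo", "nhb_hi")
  expect_true(all(need %in% names(rep)))
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_cea(rep, fc); write_cea(rep, fj)
  expect_equal(utils::read.csv(fc)$scenario, rep$scenario)
  expect_equal(jsonlite::read_json(fj)[[1]]$scenario, rep$scenario[1])
  unlink(c(fc, fj))
})
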