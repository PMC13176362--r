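test_that("risk-factor drift is linear and zero-drift leaves only age", {
  reg0 <- no_drift_registry()
  p <- make_pop(age = 60, hba1c = 7.4, sbp = 133, lipid_ratio = 4.2,
                bmi = 29)
  q <- update_risk_factors(p, reg0)
  expect_equal(q$age, 61)
  expect_equal(q[c("hba1c", "sbp", "lipid_ratio", "bmi")],
               p[c("hba1c", "sbp", "lipid_ratio", "bmi")])
  # linear-recurrence oracle: k years of slope s adds exactly k*s
  s <- 0.11; k <- 7
  regs <- reg_set(no_drift_registry(), "drift_hba1c", s)
  r <- p
  for (i in seq_len(k)) r <- update_risk_factors(r, regs)
  expect_equal(r$hba1c, p$hba1c + k * s)
  expect_equal(r$age, p$age + k)
})

test_that("hazards equal baseline for the reference individual and scale by single factors", {
  reg <- default_registry()
  ref <- make_pop()        # age 65? no: 60 -- use explicit reference
  ref$age <- 65
  hz <- annual_hazards(ref, reg)
  expect_equal(hz$stroke, reg_value(reg, "stroke_h0"))
  expect_equal(hz$mi, reg_value(reg, "mi_h0"))
  expect_equal(hz$death_other,
               reg_value(reg, "mort_h0") * reg_value(reg, "mort_dm_mult"))
  # SBP raised 10 mmHg above reference: hazard = baseline * hr_sbp^-1
  hi <- ref; hi$sbp <- 150
  expect_equal(annual_hazards(hi, reg)$stroke,
               reg_value(reg, "stroke_h0") / reg_value(reg, "hr_sbp"))
  # aspirin multiplies by (1 - rrr_aspirin)
  asp <- ref; asp$aspirin <- TRUE
  expect_equal(annual_hazards(asp, reg)$stroke,
               reg_value(reg, "stroke_h0") *
                 (1 - reg_value(reg, "rrr_aspirin")))
  # direct formula oracle for a compound profile
  prof <- ref; prof$hba1c <- 8.5; prof$sbp <- 120; prof$lipid_ratio <- 5
  v <- function(p) reg_value(reg, p)
  oracle <- v("stroke_h0") * v("hr_hba1c")^(7 - 8.5) *
    v("hr_sbp")^((140 - 120) / 10) * v("hr_lipid")^(4 - 5)
  expect_equal(annual_hazards(prof, reg)$stroke, oracle)
})

test_that("raising a protective-HR risk factor raises the event probability", {
  reg <- default_registry()
  base <- make_pop(age = 65)
  event_p <- function(p) {
    hz <- annual_hazards(p, reg)
    H <- hz$stroke + hz$mi + hz$death_other
    (hz$stroke / H) * (1 - exp(-H))
  }
  for (field in c("hba1c", "sbp", "lipid_ratio", "bmi")) {
    lo <- base
    hi <- base; hi[[field]] <- hi[[field]] * 1.2
    expect_gt(event_p(hi), event_p(lo))
  }
})

test_that("null hazards leave the state unchanged with certainty", {
  pop <- make_pop(n = 50)
  hz <- list(stroke = rep(0, 50), mi = rep(0, 50), death_other = rep(0, 50),
             stroke_cf = 0.2, mi_cf = 0.2)
  set.seed(4)
  tr <- transition(pop, hz)
  expect_true(all(tr$pop$state == "stroke_free"))
  expect_false(any(tr$stroke | tr$mi | tr$death))
})

test_that("constant-hazard cumulative incidence matches 1 - exp(-Ht)", {
  n <- 100000; h <- 0.1; years <- 10
  pop <- make_pop(n = n)
  hz <- list(stroke = rep(0, n), mi = rep(0, n), death_other = rep(h, n),
             stroke_cf = 0, mi_cf = 0)
  set.seed(12)
  for (t in seq_len(years)) {
    hz0 <- lapply(hz[1:3], function(x) x)    # constant each year
    tr <- transition(pop, c(hz0, stroke_cf = 0, mi_cf = 0))
    pop <- tr$pop
  }
  inc <- mean(pop$state == "dead_other")
  p_true <- 1 - exp(-h * years)
  expect_lt(abs(inc - p_true), 2 * sqrt(p_true * (1 - p_true) / n))
})

test_that("cause split is proportional to cause-specific hazards", {
  n <- 100000
  pop <- make_pop(n = n)
  hz <- list(stroke = rep(0.05, n), mi = rep(0.05, n),
             death_other = rep(0, n), stroke_cf = 0, mi_cf = 0)
  set.seed(13)
  tr <- transition(pop, hz)
  ev <- sum(tr$stroke) + sum(tr$mi)
  expect_lt(abs(mean(c(tr$stroke[tr$stroke | tr$mi])) - 0.5),
            2 * sqrt(0.25 / ev))
  # total event probability matches the competing-risk closed form
  p_any <- 1 - exp(-0.1)
  expect_lt(abs(ev / n - p_any), 2 * sqrt(p_any * (1 - p_any) / n))
})

test_that("per-cause probabilities and no-event probability sum to one empirically", {
  n <- 300000
  pop <- make_pop(n = n)
  hz <- list(stroke = rep(0.05, n), mi = rep(0.1, n),
             death_other = rep(0.02, n), stroke_cf = 0, mi_cf = 0)
  set.seed(14)
  tr <- transition(pop, hz)
  H <- 0.17
  p_ev <- 1 - exp(-H)
  probs <- c(stroke = 0.05, mi = 0.1, death = 0.02) / H * p_ev
  emp <- c(stroke = mean(tr$stroke), mi = mean(tr$mi),
           death = mean(tr$death))
  # 3 SE: three simultaneous per-cause checks share one draw
  for (k in names(probs))
    expect_lt(abs(emp[[k]] - probs[[k]]),
              3 * sqrt(probs[[k]] * (1 - probs[[k]]) / n))
  expect_equal(sum(probs) + exp(-H), 1)
})

test_that("death is absorbing and the trajectory stops there", {
  reg <- reg_set(null_hazard_registry(), "mort_h0", 50)  # certain death
  sc <- inert_scenario(horizon = 10)
  ind <- make_pop()
  recs <- simulate_individual(ind, sc, reg, seed = 21)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$state, "dead_other")
  expect_equal(recs$utility, 0)                  # death-year utility is zero
})

test_that("identical seeds reproduce identical trajectories", {
  sc <- inert_scenario(horizon = 10)
  ind <- make_pop(age = 72, hba1c = 8.8, sbp = 160)
  a <- simulate_individual(ind, sc, default_registry(), seed = 77)
  b <- simulate_individual(ind, sc, default_registry(), seed = 77)
  expect_identical(a, b)
})

test_that("null dynamics keep the cohort stroke-free for the whole horizon", {
  reg <- no_drift_registry(null_hazard_registry())
  sc <- inert_scenario(horizon = 10)
  recs <- simulate_individual(make_pop(), sc, reg, seed = 5)
  expect_equal(nrow(recs), 10)
  expect_true(all(recs$state == "stroke_free"))
  expect_true(all(!recs$stroke & !recs$mi & !recs$death))
})

test_that("a forced year-3 stroke accrues the hand-computed costs and utilities", {
  # zero drift; stroke hazard only; survives the acute year
  reg <- no_drift_registry(default_registry())
  reg <- reg_set(reg, "mi_h0", 0); reg <- reg_set(reg, "mort_h0", 0)
  rl <- strokeprev:::reg_flatten(reg)
  ind <- make_pop(age = 60, hba1c = 6, sbp = 120, dbp = 70, lipid_ratio = 3,
                  bmi = 24, glycemic_level = 1L)
  horizon <- 6
  ev <- matrix(0.999999, 1, horizon); ev[3] <- 1e-9   # event only in year 3
  streams <- fixed_streams(1, horizon, u_event = 1, u_cf = 1)
  streams$event <- ev
  streams$cause <- matrix(1e-9, 1, horizon)           # cause draw -> stroke
  streams$cf <- matrix(0.999, 1, horizon)             # survives case fatality
  res <- simulate_cohort(ind, inert_scenario(horizon), reg,
                         streams = streams, trajectories = TRUE)
  rec <- res$records
  expect_equal(rec$state, c("stroke_free", "stroke_free", "acute_stroke",
                            rep("post_stroke", 3)))
  med <- rl$cost_glycemic_rung1
  expect_equal(rec$cost,
               c(med, med, med + rl$cost_stroke_acute,
                 rep(med + rl$cost_stroke_annual, 3)))
  expect_equal(rec$utility,
               c(rl$util_baseline, rl$util_baseline,
                 rl$util_baseline - rl$du_stroke_acute,
                 rep(rl$util_baseline - rl$du_post_stroke, 3)))
  # discounted accrual matches the closed form
  pv <- accrue(rec, rate = 0.03)
  expect_equal(unname(pv["cost"]), sum(rec$cost * 1.03^-(0:5)))
  expect_equal(res$per_person$pv_cost, unname(pv["cost"]))
  expect_equal(res$per_person$pv_qaly, unname(pv["qaly"]))
})

test_that("dead states accrue nothing beyond the one-time death cost", {
  reg <- no_drift_registry(default_registry())
  reg <- reg_set(reg, "mi_h0", 0); reg <- reg_set(reg, "stroke_h0", 0)
  reg <- reg_set(reg, "mort_h0", 100)
  rl <- strokeprev:::reg_flatten(reg)
  ind <- make_pop(glycemic_level = 0L)
  res <- simulate_cohort(ind, inert_scenario(4), reg,
                         streams = fixed_streams(1, 4, u_event = 1e-12),
                         trajectories = TRUE)
  expect_equal(nrow(res$records), 1)     # simulation stops at death
  expect_equal(res$per_person$pv_cost,
               rl$cost_glycemic_rung0 + rl$cost_death)
  expect_equal(res$per_person$pv_qaly, 0)
})
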