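# Deterministic in-code fixtures for unit tests.

# A fully specified small population with controllable fields; defaults are
# a healthy 60-year-old male at reference risk-factor levels, untreated.
make_pop <- function(n = 1, age = 60, sex = "male", weight = 1,
                     hba1c = 7, sbp = 140, dbp = 80, lipid_ratio = 4,
                     bmi = 30, smoker = FALSE, mi_history = FALSE,
                     afib = FALSE, ckd = FALSE, family_history_ascvd = FALSE,
                     high_bleeding_risk = FALSE, chf = FALSE,
                     glycemic_level = 0L, bp_level = 0L, acei_arb = FALSE,
                     statin = "none", aspirin = FALSE,
                     anticoagulant = "none", state = "stroke_free") {
  pop <- data.frame(id = seq_len(n), age = age, sex = sex, weight = weight,
                    hba1c = hba1c, sbp = sbp, dbp = dbp,
                    lipid_ratio = lipid_ratio, bmi = bmi, smoker = smoker,
                    mi_history = mi_history, afib = afib, ckd = ckd,
                    family_history_ascvd = family_history_ascvd,
                    high_bleeding_risk = high_bleeding_risk, chf = chf,
                    glycemic_level = as.integer(glycemic_level),
                    bp_level = as.integer(bp_level), acei_arb = acei_arb,
                    statin = statin, aspirin = aspirin,
                    anticoagulant = anticoagulant,
                    stringsAsFactors = FALSE)
  for (s in strategies()) pop[[paste0("adh_", s)]] <- FALSE
  pop$state <- state
  class(pop) <- c("population", "data.frame")
  pop
}

# Registry with every drift slope zeroed (frozen natural history).
no_drift_registry <- function(reg = default_registry()) {
  for (p in c("drift_hba1c", "drift_sbp", "drift_lipid", "drift_bmi"))
    reg <- reg_set(reg, p, 0)
  reg
}

# Registry whose event hazards are all zero (null dynamics).
null_hazard_registry <- function(reg = default_registry()) {
  for (p in c("stroke_h0", "mi_h0", "mort_h0")) reg <- reg_set(reg, p, 0)
  reg
}

# Hand-built CRN streams: no adoption (u = 1), and chosen event draws.
fixed_streams <- function(n, horizon, u_event = 1, u_cause = 1, u_cf = 1,
                          u_adopt = 1, u_quit = 1, u_hypo = 0.5) {
  as_mat <- function(x) {
    m <- matrix(x, n, horizon)
    m
  }
  list(adopt = array(u_adopt, c(n, horizon, 7)),
       quit = as_mat(u_quit), event = as_mat(u_event),
       cause = as_mat(u_cause), cf = as_mat(u_cf), hypo = as_mat(u_hypo))
}

# Status-quo scenario with all-zero adherence (pure natural history).
inert_scenario <- function(horizon = 10, name = "status_quo") {
  scenario_spec(name, character(),
                status_quo_adherence = setNames(rep(0, 7), strategies()),
                horizon = horizon)
}
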