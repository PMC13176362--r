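ALIVE_STATES <- c("stroke_free", "acute_stroke", "post_stroke")
DEAD_STATES <- c("dead_stroke", "dead_other")

#' Annual risk-factor drift and ageing
#'
#' Advances age by one year and applies the registry's annual drift slopes
#' to HbA1c, SBP/DBP, lipid ratio and BMI, reflecting the natural history
#' of each condition. Treatment effects already applied by the policy step
#' are preserved (drift is additive on top of them).
#'
#' @param pop A population (any number of rows).
#' @param registry A \code{parameter_registry} (or a flattened value list).
#' @return The updated population.
#' @export
update_risk_factors <- function(pop, registry = default_registry()) {
  rl <- if (is.list(registry) && !is.data.frame(registry)) registry
        else reg_flatten(registry)
  pop$age <- pop$age + 1
  pop$hba1c <- pmin(pmax(pop$hba1c + rl$drift_hba1c, 3.5), 19)
  pop$sbp <- pmin(pmax(pop$sbp + rl$drift_sbp, 85), 240)
  pop$dbp <- pmin(pmax(pop$dbp + 0.5 * rl$drift_sbp, 45), 140)
  pop$lipid_ratio <- pmin(pmax(pop$lipid_ratio + rl$drift_lipid, 1.5), 12)
  pop$bmi <- pmin(pmax(pop$bmi + rl$drift_bmi, 15), 75)
  pop
}

#' Cause-specific annual hazards
#'
#' Computes, for every (alive) row, the annual hazards of stroke, MI and
#' other-cause death. The stroke hazard is the baseline hazard (log-linear
#' in age, sex-adjusted, AFib- and MI-history-adjusted, multiplied by the
#' recurrence factor in the post-stroke state) times per-unit hazard-ratio
#' terms for HbA1c, SBP, lipid ratio and BMI distance from reference,
#' times (1 - relative risk reduction) for aspirin, NOAC (in AFib) and
#' statin. Each hazard ratio is defined per unit *decrease*, so a risk
#' factor above reference multiplies the hazard by hr^-(excess/unit).
#' The MI hazard has the same structure with its own coefficients;
#' other-cause death follows a Gompertz life table times the diabetes
#' multiplier (and a post-stroke multiplier).
#'
#' @param pop A population.
#' @param registry A \code{parameter_registry} (or flattened value list).
#' @return A list of numeric vectors \code{stroke}, \code{mi},
#'   \code{death_other}, plus scalar case-fatality probabilities
#'   \code{stroke_cf} and \code{mi_cf}.
#' @export
annual_hazards <- function(pop, registry = default_registry()) {
  rl <- if (is.list(registry) && !is.data.frame(registry)) registry
        else reg_flatten(registry)
  female <- pop$sex == "female"
  post <- pop$state == "post_stroke" | pop$state == "acute_stroke"
  on_statin <- pop$statin != "none"
  on_noac <- pop$anticoagulant == "noac" & pop$afib
  on_warf <- pop$anticoagulant == "warfarin" & pop$afib

  rf_mult <- function(hr_hba1c, hr_sbp, hr_lipid, hr_bmi) {
    hr_hba1c^((rl$ref_hba1c - pop$hba1c) / 1) *
      hr_sbp^((rl$ref_sbp - pop$sbp) / 10) *
      hr_lipid^((rl$ref_lipid - pop$lipid_ratio) / 1) *
      hr_bmi^((rl$ref_bmi - pop$bmi) / 1)
  }

  # scalar-or-1 multipliers written as 1 + (k - 1) * flag (ifelse is slow)
  h_stroke <- rl$stroke_h0 * exp(rl$stroke_age_slope * (pop$age - 65)) *
    (1 + (rl$stroke_female_hr - 1) * female) *
    (1 + (rl$stroke_afib_hr - 1) * pop$afib) *
    (1 + (rl$stroke_mi_history_hr - 1) * pop$mi_history) *
    (1 + (rl$stroke_recurrence_mult - 1) * post) *
    rf_mult(rl$hr_hba1c, rl$hr_sbp, rl$hr_lipid, rl$hr_bmi) *
    (1 - rl$rrr_aspirin * pop$aspirin) *
    (1 - rl$rrr_noac * on_noac) *
    (1 - rl$rrr_noac * 0.9 * on_warf) *      # warfarin slightly less effective
    (1 - rl$rrr_statin_direct * on_statin)

  h_mi <- rl$mi_h0 * exp(rl$mi_age_slope * (pop$age - 65)) *
    (1 + (rl$mi_female_hr - 1) * female) *
    (1 + (rl$mi_history_mult - 1) * pop$mi_history) *
    rf_mult(rl$mi_hr_hba1c, rl$mi_hr_sbp, rl$mi_hr_lipid, rl$mi_hr_bmi) *
    (1 - rl$rrr_aspirin_mi * pop$aspirin) *
    (1 - rl$rrr_statin_mi * on_statin)

  h_death <- rl$mort_h0 * exp(rl$mort_age_slope * (pop$age - 65)) *
    rl$mort_dm_mult * (1 + (rl$mort_post_stroke_mult - 1) * post)

  list(stroke = h_stroke, mi = h_mi, death_other = h_death,
       stroke_cf = rl$stroke_case_fatality, mi_cf = rl$mi_case_fatality)
}

#' Competing-risk annual transition
#'
#' With total hazard H, any event occurs with probability 1 - exp(-H);
#' given an event, the cause is drawn proportionally to its cause-specific
#' hazard. A stroke event routes through acute case fatality (death from
#' stroke with the case-fatality probability, else the acute/post-stroke
#' pathway); an MI event routes through MI case fatality; at most one
#' transition event per year; dead states are absorbing.
#'
#' @param pop A population.
#' @param hazards Output of \code{\link{annual_hazards}}.
#' @param u_event,u_cause,u_cf Uniform draws, one per row (pass fixed
#'   streams for common-random-number pairing; defaults draw fresh).
#' @return A list with the updated population and logical event vectors
#'   \code{stroke}, \code{mi}, \code{death}.
#' @export
transition <- function(pop, hazards,
                       u_event = runif(length(pop$id)),
                       u_cause = runif(length(pop$id)),
                       u_cf = runif(length(pop$id))) {
  n <- length(pop$id)
  alive <- pop$state %in% ALIVE_STATES
  # graduate last year's acute strokes into the chronic post-stroke state
  pop$state[pop$state == "acute_stroke"] <- "post_stroke"
  h_s <- hazards$stroke * alive
  h_m <- hazards$mi * alive
  h_d <- hazards$death_other * alive
  H <- h_s + h_m + h_d
  p_event <- 1 - exp(-H)
  ev <- alive & u_event < p_event & H > 0
  # cause split proportional to cause-specific hazards
  Hs <- pmax(H, .Machine$double.xmin)
  frac_s <- h_s / Hs
  frac_m <- h_m / Hs
  cause_stroke <- ev & u_cause < frac_s
  cause_mi <- ev & !cause_stroke & u_cause < frac_s + frac_m
  cause_death <- ev & !cause_stroke & !cause_mi

  stroke_dead <- cause_stroke & u_cf < hazards$stroke_cf
  pop$state[cause_stroke & !stroke_dead] <- "acute_stroke"
  pop$state[stroke_dead] <- "dead_stroke"

  mi_dead <- cause_mi & u_cf < hazards$mi_cf
  pop$mi_history[cause_mi] <- TRUE
  pop$state[mi_dead] <- "dead_other"
  pop$state[cause_death] <- "dead_other"

  list(pop = pop, stroke = cause_stroke, mi = cause_mi,
       death = stroke_dead | mi_dead | cause_death,
       death_stroke = stroke_dead)
}

# Common-random-number streams for one (imputation, replicate) pair.
# Fixed-shape uniform arrays indexed by (individual row, year, use-slot),
# identical across scenarios, so scenario contrasts are paired.
make_streams <- function(n, horizon, seed, m = 1, r = 1) {
  s <- (as.numeric(seed) * 2654435761 + m * 97561 + r * 1013) %% 2147483647
  set.seed(as.integer(s))
  u <- runif(n * horizon * 12)
  dim(u) <- c(n, horizon, 12)
  slab <- function(k) {
    m <- u[, , k, drop = FALSE]
    dim(m) <- c(n, horizon)
    m
  }
  list(adopt = u[, , 1:7, drop = FALSE], quit = slab(8), event = slab(9),
       cause = slab(10), cf = slab(11), hypo = slab(12))
}

# Per-year cost vector for the cohort (medication + events + programmes).
year_costs <- function(pop, alive, rl, stroke_ev, mi_ev, death_ev, adopted) {
  gly_cost <- c(rl$cost_glycemic_rung0, rl$cost_glycemic_rung1,
                rl$cost_glycemic_rung2, rl$cost_glycemic_rung3,
                rl$cost_glycemic_rung4)[pop$glycemic_level + 1L]
  med <- gly_cost + rl$cost_bp_per_rung * pop$bp_level +
    rl$cost_statin_high * (pop$statin == "high") +
    rl$cost_statin_moderate * (pop$statin == "moderate") +
    rl$cost_aspirin * pop$aspirin +
    rl$cost_noac * (pop$anticoagulant == "noac") +
    rl$cost_warfarin * (pop$anticoagulant == "warfarin")
  chronic <- rl$cost_stroke_annual * (pop$state == "post_stroke") +
    rl$cost_mi_annual * (pop$mi_history & pop$state %in% ALIVE_STATES)
  cost <- (med + chronic) * alive
  cost <- cost + stroke_ev * rl$cost_stroke_acute + mi_ev * rl$cost_mi_acute +
    death_ev * rl$cost_death +
    adopted[, "smoking"] * rl$cost_smoking_program +
    adopted[, "weight"] * rl$cost_weight_program
  cost
}

# Per-year utility vector: baseline minus decrements, floored at 0; the
# death year and dead states contribute 0.
year_utilities <- function(pop, alive_end, rl, stroke_ev, mi_ev, hypo_n) {
  u <- rl$util_baseline -
    rl$du_stroke_acute * (pop$state == "acute_stroke") -
    rl$du_post_stroke * (pop$state == "post_stroke") -
    rl$du_post_mi * (pop$mi_history | mi_ev) -
    rl$du_insulin_basal * (pop$glycemic_level == 3) -
    rl$du_insulin_intensive * (pop$glycemic_level == 4) -
    rl$du_hypo_episode * hypo_n
  pmax(u, 0) * alive_end
}

#' Simulate a cohort under one scenario
#'
#' Runs the annual cycle over the horizon. Each year, in order: (1) the
#' policy module issues recommendations for the scenario's active
#' strategies and individuals adopt them stochastically at the scenario's
#' adherence; (2) risk factors drift and age advances; (3) cause-specific
#' hazards are computed and the competing-risk transition is drawn;
#' (4) costs and utilities accrue. Simulation of an individual stops at
#' death; dead states emit no further events and no costs beyond the
#' one-time death cost.
#'
#' @param pop Baseline population.
#' @param scenario A \code{\link{scenario_spec}}.
#' @param registry A \code{parameter_registry} (or flattened value list).
#' @param gspec A \code{\link{guideline_spec}}.
#' @param streams Uniform streams from the common-random-number generator
#'   (internal); pass the same streams across scenarios to pair contrasts.
#' @param seed Used to build streams when \code{streams} is NULL.
#' @param trajectories Also return the per-person-year record table.
#' @return A list with \code{totals} (weighted national stroke events,
#'   stroke deaths, MI events, discounted cost, discounted QALYs),
#'   \code{per_person} (undiscounted-by-weight person-level PVs) and
#'   optionally \code{records}.
#' @export
simulate_cohort <- function(pop, scenario, registry = default_registry(),
                            gspec = guideline_spec(), streams = NULL,
                            seed = 1, trajectories = FALSE) {
  rl <- if (is.list(registry) && !is.data.frame(registry)) registry
        else reg_flatten(registry)
  horizon <- scenario$horizon
  n <- length(pop$id)
  if (is.null(streams)) streams <- make_streams(n, horizon, seed)
  weight <- pop$weight
  pop <- lapply(as.data.frame(pop), identity)   # plain vectors: fast loop
  adherence <- scenario$adherence
  rate <- scenario$discount_rate
  disc <- (1 + rate)^-(seq_len(horizon) - 1)

  strokes <- integer(n); mis <- integer(n)
  died_stroke <- logical(n)
  pv_cost <- numeric(n); pv_qaly <- numeric(n)
  rec_list <- if (trajectories) vector("list", horizon) else NULL

  for (t in seq_len(horizon)) {
    alive <- pop$state %in% ALIVE_STATES
    if (!any(alive)) break

    # (1) policy: recommend + adherence (alive only)
    masks <- recommend_masks(pop, scenario$active, gspec, t)
    for (s in STRATEGIES) masks[[s]] <- masks[[s]] & alive
    adopt_t <- streams$adopt[, t, , drop = FALSE]
    dim(adopt_t) <- c(n, 7)
    st <- apply_adherence_vec(pop, masks, adherence, rl, gspec,
                              adopt_t, streams$quit[, t])
    pop <- st$pop
    adopted <- st$adopted

    # (2) drift + ageing (alive only; dead rows frozen)
    drifted <- update_risk_factors(pop, rl)
    for (cl in c("age", "hba1c", "sbp", "dbp", "lipid_ratio", "bmi"))
      pop[[cl]][alive] <- drifted[[cl]][alive]

    # (3) hazards + competing-risk transition
    hz <- annual_hazards(pop, rl)
    tr <- transition(pop, hz, streams$event[, t], streams$cause[, t],
                     streams$cf[, t])
    pop <- tr$pop
    strokes <- strokes + tr$stroke
    mis <- mis + tr$mi
    died_stroke <- died_stroke | tr$death_stroke

    # hypoglycemia under insulin (disutility only)
    lam <- rl$hypo_rate_intensive * (pop$glycemic_level == 4) +
      rl$hypo_rate_basal * (pop$glycemic_level == 3)
    hypo_n <- numeric(n)
    ih <- which(alive & lam > 0)
    if (length(ih)) hypo_n[ih] <- qpois(streams$hypo[ih, t], lam[ih])

    # (4) accrual
    alive_end <- pop$state %in% ALIVE_STATES
    cost_t <- year_costs(pop, alive, rl, tr$stroke, tr$mi, tr$death, adopted)
    util_t <- year_utilities(pop, alive_end, rl, tr$stroke, tr$mi, hypo_n)
    pv_cost <- pv_cost + disc[t] * cost_t
    pv_qaly <- pv_qaly + disc[t] * util_t

    if (trajectories) {
      rec_list[[t]] <- data.frame(
        id = pop$id, year = t, state = pop$state,
        stroke = tr$stroke, mi = tr$mi, death = tr$death,
        hypoglycemia = hypo_n,
        hba1c = pop$hba1c, sbp = pop$sbp, dbp = pop$dbp,
        lipid_ratio = pop$lipid_ratio, bmi = pop$bmi,
        glycemic_level = pop$glycemic_level, bp_level = pop$bp_level,
        statin = pop$statin, aspirin = pop$aspirin,
        anticoagulant = pop$anticoagulant, smoker = pop$smoker,
        cost = cost_t, utility = util_t,
        alive_at_entry = alive, stringsAsFactors = FALSE)
      rec_list[[t]] <- rec_list[[t]][alive, ]
    }
  }

  w <- weight
  totals <- c(strokes = sum(w * strokes),
              stroke_deaths = sum(w * died_stroke),
              mi_events = sum(w * mis),
              cost = sum(w * pv_cost),
              qalys = sum(w * pv_qaly))
  out <- list(totals = totals,
              per_person = data.frame(id = pop$id, weight = w,
                                      strokes = strokes, mi = mis,
                                      died_stroke = died_stroke,
                                      pv_cost = pv_cost, pv_qaly = pv_qaly),
              final = data.frame(pop, stringsAsFactors = FALSE))
  if (trajectories) out$records <- do.call(rbind, rec_list)
  out
}

#' Simulate one individual's annual trajectory
#'
#' Convenience wrapper around the cohort engine for a single individual,
#' returning one record per simulated year (the trajectory stops at death
#' or the horizon).
#'
#' @param individual One-row population data frame.
#' @param scenario A \code{\link{scenario_spec}}.
#' @param registry A \code{parameter_registry}.
#' @param gspec A \code{\link{guideline_spec}}.
#' @param seed Integer seed for the individual's stream.
#' @return A data frame of annual records (year, state, events, risk
#'   factors, treatment levels, cost, utility).
#' @export
simulate_individual <- function(individual, scenario,
                                registry = default_registry(),
                                gspec = guideline_spec(), seed = 1) {
  stopifnot(nrow(individual) == 1, scenario$horizon >= 1)
  res <- simulate_cohort(individual, scenario, registry, gspec,
                         streams = make_streams(1, scenario$horizon, seed),
                         trajectories = TRUE)
  res$records
}
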