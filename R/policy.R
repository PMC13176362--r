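#' Guideline thresholds and policy constants
#'
#' Encodes the tunable thresholds of the guideline rules: the age-specific
#' HbA1c targets, the BP target, the aspirin primary-prevention age window,
#' the CHA2DS2-VASc threshold gating anticoagulation, the one-time
#' behavioural quit-success probability, and the weight-loss programme
#' parameters.
#'
#' @param hba1c_target_under65 HbA1c target (\%) for ages 45-64.
#' @param hba1c_target_65plus HbA1c target (\%) for ages >= 65.
#' @param bp_target Numeric pair (SBP, DBP) in mmHg.
#' @param aspirin_age_range Numeric pair of ages bounding aspirin
#'   primary-prevention eligibility (inclusive).
#' @param chads_vasc_threshold Minimum CHA2DS2-VASc score for
#'   anticoagulation in AFib.
#' @param quit_success Probability a referred smoker quits.
#' @param weight_loss_fraction One-time fractional body-weight loss in the
#'   weight programme.
#' @param weight_loss_bmi_floor BMI (kg/m2) below which the weight
#'   programme is not recommended; also the "well-controlled BMI" cut.
#' @param dyslipidemia_ratio_cut Total-cholesterol/HDL ratio above which
#'   dyslipidemia counts as a major risk factor.
#' @return A \code{guideline_spec} list.
#' @export
guideline_spec <- function(hba1c_target_under65 = 7.0,
                           hba1c_target_65plus = 7.5,
                           bp_target = c(140, 90),
                           aspirin_age_range = c(50, 70),
                           chads_vasc_threshold = 2,
                           quit_success = 0.12,
                           weight_loss_fraction = 0.05,
                           weight_loss_bmi_floor = 25,
                           dyslipidemia_ratio_cut = 4.5) {
  stopifnot(hba1c_target_under65 > 0, hba1c_target_65plus > 0,
            all(bp_target > 0), length(bp_target) == 2,
            length(aspirin_age_range) == 2,
            aspirin_age_range[1] <= aspirin_age_range[2],
            chads_vasc_threshold >= 0,
            quit_success >= 0, quit_success <= 1,
            weight_loss_fraction >= 0, weight_loss_fraction <= 1)
  structure(list(hba1c_target_under65 = hba1c_target_under65,
                 hba1c_target_65plus = hba1c_target_65plus,
                 bp_target = bp_target,
                 aspirin_age_range = aspirin_age_range,
                 chads_vasc_threshold = chads_vasc_threshold,
                 quit_success = quit_success,
                 weight_loss_fraction = weight_loss_fraction,
                 weight_loss_bmi_floor = weight_loss_bmi_floor,
                 dyslipidemia_ratio_cut = dyslipidemia_ratio_cut),
            class = "guideline_spec")
}

# Age-appropriate HbA1c target (vectorised over age).
hba1c_target <- function(age, gspec = guideline_spec()) {
  ifelse(age < 65, gspec$hba1c_target_under65, gspec$hba1c_target_65plus)
}

# Hypertension for risk-factor purposes: above BP target or on medication.
hypertensive_vec <- function(sbp, dbp, bp_level, gspec) {
  sbp >= gspec$bp_target[1] | dbp >= gspec$bp_target[2] | bp_level > 0
}

chads_vasc_vec <- function(age, sex, sbp, dbp, bp_level, mi_history,
                           prior_stroke, chf,
                           gspec = guideline_spec()) {
  chf + hypertensive_vec(sbp, dbp, bp_level, gspec) +
    2L * (age >= 75) + 1L +                       # diabetes: whole cohort
    2L * prior_stroke + mi_history +              # vascular disease = MI
    1L * (age >= 65 & age < 75) + (sex == "female")
}

#' CHA2DS2-VASc stroke-risk score
#'
#' Component sum: congestive heart failure (1), hypertension (1), age >= 75
#' (2), diabetes (1, always in this cohort), prior stroke (2), vascular
#' disease / MI history (1), age 65-74 (1), female sex (1). Range 0..9;
#' here at least 1 because every individual has T2D.
#'
#' @param individual A one-row population data frame (or a population; the
#'   score is vectorised over rows).
#' @param gspec A \code{\link{guideline_spec}}.
#' @return Integer score(s).
#' @export
chads_vasc <- function(individual, gspec = guideline_spec()) {
  as.integer(chads_vasc_vec(individual$age, individual$sex, individual$sbp,
                            individual$dbp, individual$bp_level,
                            individual$mi_history,
                            individual$state %in%
                              c("acute_stroke", "post_stroke"),
                            individual$chf, gspec))
}

aspirin_eligible_vec <- function(age, sbp, dbp, bp_level, lipid_ratio,
                                 smoker, ckd, family_history_ascvd,
                                 high_bleeding_risk,
                                 gspec = guideline_spec()) {
  risk <- family_history_ascvd |
    hypertensive_vec(sbp, dbp, bp_level, gspec) |
    lipid_ratio > gspec$dyslipidemia_ratio_cut | smoker | ckd
  age >= gspec$aspirin_age_range[1] & age <= gspec$aspirin_age_range[2] &
    risk & !high_bleeding_risk
}

#' Aspirin primary-prevention eligibility
#'
#' True for individuals inside the configured age window with at least one
#' additional major ASCVD risk factor (family history of premature ASCVD,
#' hypertension, dyslipidemia, smoking, or CKD/albuminuria) and no high
#' bleeding risk.
#'
#' @inheritParams chads_vasc
#' @return Logical (vectorised over rows).
#' @export
aspirin_eligible <- function(individual, gspec = guideline_spec()) {
  aspirin_eligible_vec(individual$age, individual$sbp, individual$dbp,
                       individual$bp_level, individual$lipid_ratio,
                       individual$smoker, individual$ckd,
                       individual$family_history_ascvd,
                       individual$high_bleeding_risk, gspec)
}

# Guideline statin intensity: high for ages 50-70 or multiple ASCVD risk
# factors; moderate for >= 75 and everyone else.
recommended_statin_intensity <- function(age, smoker, sbp, dbp, bp_level,
                                         lipid_ratio, family_history_ascvd,
                                         ckd, gspec = guideline_spec()) {
  nrf <- smoker + hypertensive_vec(sbp, dbp, bp_level, gspec) +
    (lipid_ratio > gspec$dyslipidemia_ratio_cut) + family_history_ascvd + ckd
  ifelse(age >= 75, "moderate",
         ifelse((age >= 50 & age <= 70) | nrf >= 2, "high", "moderate"))
}

GLYCEMIC_MAX <- 4L
BP_MAX <- 6L

# Vectorised recommendation masks for a cohort. Returns a list of logical
# vectors, one per strategy active in `active`; year is 1-based (smoking
# referral and the weight programme fire in year 1 only).
recommend_masks <- function(pop, active, gspec, year) {
  unknown <- setdiff(active, STRATEGIES)
  if (length(unknown))
    stop("unknown strategy name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- length(pop$id)
  m <- list()
  for (s in STRATEGIES) m[[s]] <- rep(FALSE, n)
  if ("glycemic" %in% active)
    m$glycemic <- pop$hba1c >= hba1c_target(pop$age, gspec) &
      pop$glycemic_level < GLYCEMIC_MAX
  if ("bp" %in% active)
    m$bp <- (pop$sbp >= gspec$bp_target[1] | pop$dbp >= gspec$bp_target[2]) &
      pop$bp_level < BP_MAX
  if ("statin" %in% active) {
    rec <- recommended_statin_intensity(pop$age, pop$smoker, pop$sbp,
                                        pop$dbp, pop$bp_level,
                                        pop$lipid_ratio,
                                        pop$family_history_ascvd, pop$ckd,
                                        gspec)
    m$statin <- !(pop$statin == rec | pop$statin == "high")
  }
  if ("aspirin" %in% active)
    m$aspirin <- !pop$aspirin & aspirin_eligible(pop, gspec)
  if ("smoking" %in% active && year == 1)
    m$smoking <- pop$smoker
  if ("weight" %in% active && year == 1)
    m$weight <- pop$bmi > gspec$weight_loss_bmi_floor
  if ("anticoagulant" %in% active)
    m$anticoagulant <- pop$afib & pop$anticoagulant == "none" &
      chads_vasc(pop, gspec) >= gspec$chads_vasc_threshold
  m
}

#' Guideline treatment recommendations for one individual
#'
#' Applies the scenario's active strategy rules to a single individual and
#' returns the resulting recommendations: escalate the glycemic or BP
#' ladder one rung when the risk factor is above target and the ladder is
#' not exhausted, initiate or switch statin to the recommended intensity,
#' initiate aspirin when eligible, refer smokers to the behavioural
#' intervention (year 1 only), enrol BMI above the floor in the one-time
#' weight programme (year 1 only), and start a NOAC for untreated
#' high-risk AFib.
#'
#' @param individual One-row population data frame.
#' @param active Character vector of active strategy names (a scenario's
#'   enhanced set, or all seven in the status quo).
#' @param gspec A \code{\link{guideline_spec}}.
#' @param year 1-based simulation year.
#' @return A data frame with columns \code{strategy}, \code{action},
#'   \code{detail} (empty when nothing is recommended).
#' @export
recommend <- function(individual, active = STRATEGIES,
                      gspec = guideline_spec(), year = 1) {
  stopifnot(nrow(individual) == 1)
  if (!individual$state %in% c("stroke_free", "acute_stroke", "post_stroke"))
    stop("individual must be alive", call. = FALSE)
  m <- recommend_masks(individual, active, gspec, year)
  out <- data.frame(strategy = character(), action = character(),
                    detail = character(), stringsAsFactors = FALSE)
  add <- function(s, a, d) rbind(out, data.frame(strategy = s, action = a,
                                                 detail = d,
                                                 stringsAsFactors = FALSE))
  if (m$glycemic)
    out <- add("glycemic", "escalate",
               paste0("rung ", individual$glycemic_level + 1L))
  if (m$bp)
    out <- add("bp", "escalate", paste0("rung ", individual$bp_level + 1L))
  if (m$statin) {
    rec <- recommended_statin_intensity(individual$age, individual$smoker,
                                        individual$sbp, individual$dbp,
                                        individual$bp_level,
                                        individual$lipid_ratio,
                                        individual$family_history_ascvd,
                                        individual$ckd, gspec)
    out <- add("statin", if (individual$statin == "none") "initiate"
               else "switch", rec)
  }
  if (m$aspirin) out <- add("aspirin", "initiate", "low-dose aspirin")
  if (m$smoking) out <- add("smoking", "initiate", "behavioural referral")
  if (m$weight) out <- add("weight", "initiate",
                           paste0(100 * gspec$weight_loss_fraction,
                                  "% weight loss"))
  if (m$anticoagulant) out <- add("anticoagulant", "initiate", "noac")
  out
}

# Vectorised adherence application. `masks` from recommend_masks;
# `adherence` named over strategies; `u` an n x 7 uniform matrix (columns
# in STRATEGIES order) and `u_quit` an n-vector for the quit-success draw.
# Returns list(pop = updated population, adopted = n x 7 logical matrix,
# program_cost mask info via adopted).
apply_adherence_vec <- function(pop, masks, adherence, rl, gspec, u, u_quit) {
  n <- length(pop$id)
  adopted <- matrix(FALSE, n, 7, dimnames = list(NULL, STRATEGIES))
  for (j in seq_along(STRATEGIES)) {
    s <- STRATEGIES[j]
    a <- adherence[[s]]
    if (is.null(a) || a <= 0) next
    adopted[, j] <- masks[[s]] & u[, j] < a
  }
  g <- adopted[, "glycemic"]
  if (any(g)) {
    pop$glycemic_level[g] <- pop$glycemic_level[g] + 1L
    pop$hba1c[g] <- pmax(pop$hba1c[g] - rl$eff_hba1c_per_rung, 4.5)
  }
  b <- adopted[, "bp"]
  if (any(b)) {
    pop$bp_level[b] <- pop$bp_level[b] + 1L
    pop$acei_arb[b] <- TRUE                      # first-line ACEi/ARB
    pop$sbp[b] <- pmax(pop$sbp[b] - rl$eff_sbp_per_rung, 85)
    pop$dbp[b] <- pmax(pop$dbp[b] - rl$eff_dbp_per_rung, 45)
  }
  st <- adopted[, "statin"]
  if (any(st)) {
    rec <- recommended_statin_intensity(pop$age, pop$smoker, pop$sbp,
                                        pop$dbp, pop$bp_level,
                                        pop$lipid_ratio,
                                        pop$family_history_ascvd, pop$ckd,
                                        gspec)
    drop_new <- ifelse(rec == "high", rl$eff_lipid_statin_high,
                       rl$eff_lipid_statin_moderate)
    drop_old <- ifelse(pop$statin == "high", rl$eff_lipid_statin_high,
                       ifelse(pop$statin == "moderate",
                              rl$eff_lipid_statin_moderate, 0))
    inc <- pmax(drop_new - drop_old, 0)
    pop$lipid_ratio[st] <- pmax(pop$lipid_ratio[st] - inc[st], 1.5)
    pop$statin[st] <- rec[st]
  }
  asp <- adopted[, "aspirin"]
  if (any(asp)) pop$aspirin[asp] <- TRUE
  sm <- adopted[, "smoking"]
  if (any(sm)) {
    quit <- sm & u_quit < gspec$quit_success
    pop$smoker[quit] <- FALSE
  }
  wt <- adopted[, "weight"]
  if (any(wt))
    pop$bmi[wt] <- pmax(pop$bmi[wt] * (1 - gspec$weight_loss_fraction), 15)
  ac <- adopted[, "anticoagulant"]
  if (any(ac)) pop$anticoagulant[ac] <- "noac"
  list(pop = pop, adopted = adopted)
}

#' Apply stochastic adherence to recommendations (single individual)
#'
#' Each recommendation is adopted independently with its strategy's
#' adherence probability. Adopted ladder escalations increment the rung and
#' apply the registry's per-rung risk-factor reduction; an adopted smoking
#' referral leads to quitting with the configured quit-success probability;
#' an adopted weight programme multiplies BMI by
#' (1 - \code{weight_loss_fraction}).
#'
#' @param individual One-row population data frame.
#' @param recs Recommendations from \code{\link{recommend}}.
#' @param adherence Named per-strategy adoption probabilities in [0, 1].
#' @param registry A \code{parameter_registry}.
#' @param gspec A \code{\link{guideline_spec}}.
#' @return The updated one-row individual.
#' @export
apply_adherence <- function(individual, recs, adherence,
                            registry = default_registry(),
                            gspec = guideline_spec()) {
  stopifnot(nrow(individual) == 1)
  stopifnot(all(unlist(adherence) >= 0), all(unlist(adherence) <= 1))
  rl <- reg_flatten(registry)
  masks <- setNames(as.list(STRATEGIES %in% recs$strategy), STRATEGIES)
  u <- matrix(runif(7), 1, 7)
  apply_adherence_vec(individual, masks, adherence, rl, gspec, u,
                      runif(1))$pop
}
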