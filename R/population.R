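#' @importFrom stats pnorm qnorm dnorm plnorm qlnorm runif rbinom setNames
#'   quantile rnorm optim qpois
NULL

# Canonical strategy order used throughout the package.
STRATEGIES <- c("glycemic", "bp", "statin", "aspirin", "smoking",
                "weight", "anticoagulant")

#' Seven guideline prevention strategies
#'
#' Returns the canonical machine names of the seven prevention strategies,
#' in the fixed order used for adherence vectors and achievement targets:
#' glycemic control, blood-pressure control, statin treatment, aspirin
#' treatment, non-smoking, weight (BMI) control, and anticoagulant
#' treatment for atrial fibrillation.
#'
#' @return Character vector of length 7.
#' @export
strategies <- function() STRATEGIES

#' Cohort generator configuration
#'
#' Describes the synthetic survey-weighted cohort: size, national weight
#' total, demographic and risk-factor marginals, the correlation structure
#' tying risk factors together, comorbidity prevalences, the seven baseline
#' strategy-achievement proportions the generator targets, per-field
#' missingness rates, and status-quo adherence defaults.
#'
#' Risk factors (age, HbA1c, SBP, lipid ratio, BMI) are drawn from a
#' Gaussian copula with configurable marginals. Age is truncated at the
#' cohort entry age of 45; the generator moment-matches the underlying
#' normal so the *truncated* distribution has the configured mean and SD.
#'
#' @param n Cohort size.
#' @param total_weight Total survey weight (persons represented nationally).
#' @param age_mean,age_sd Target mean/SD of age in the truncated (>= 45)
#'   cohort, years.
#' @param male_fraction Fraction male.
#' @param hba1c_meanlog,hba1c_sdlog Log-normal HbA1c marginal (percent).
#' @param sbp_mean,sbp_sd Normal SBP marginal (mmHg).
#' @param lipid_meanlog,lipid_sdlog Log-normal total-cholesterol/HDL ratio.
#' @param bmi_meanlog,bmi_sdlog Log-normal BMI (kg/m2).
#' @param corr 5x5 correlation matrix over (age, hba1c, sbp, lipid, bmi).
#' @param mi_prev,ckd_prev,famhx_prev,bleed_prev,chf_prev Comorbidity
#'   prevalences.
#' @param afib_prev_by_age Named vector of AFib prevalence for age bands
#'   \code{<65}, \code{65-74}, \code{>=75}.
#' @param target_proportions Named vector over \code{strategies()} of the
#'   baseline weighted achievement proportions the generator reproduces,
#'   or \code{NULL} to draw risk factors from the plain copula with no
#'   achievement constraints.
#' @param missingness_rates Named per-field MCAR rates for
#'   \code{hba1c, sbp, lipid_ratio, bmi}.
#' @param adherence Named status-quo per-strategy adherence probabilities.
#' @param M Default number of imputations.
#' @return A \code{population_config} list.
#' @export
population_config <- function(n = 1232,
                              total_weight = 3.7e6,
                              age_mean = 65.1, age_sd = 9.8,
                              male_fraction = 0.558,
                              hba1c_meanlog = log(7.3), hba1c_sdlog = 0.18,
                              sbp_mean = 131, sbp_sd = 18,
                              lipid_meanlog = log(3.9), lipid_sdlog = 0.30,
                              bmi_meanlog = log(31.5), bmi_sdlog = 0.21,
                              corr = default_risk_corr(),
                              mi_prev = 0.12, ckd_prev = 0.25,
                              famhx_prev = 0.15, bleed_prev = 0.07,
                              chf_prev = 0.05,
                              afib_prev_by_age = c("<65" = 0.03,
                                                   "65-74" = 0.06,
                                                   ">=75" = 0.10),
                              target_proportions = default_target_proportions(),
                              missingness_rates = c(hba1c = 0.05, sbp = 0.03,
                                                    lipid_ratio = 0.08,
                                                    bmi = 0.02),
                              adherence = c(glycemic = 0.5, bp = 0.5,
                                            statin = 0.3, aspirin = 0.05,
                                            smoking = 0, weight = 0,
                                            anticoagulant = 0.3),
                              M = 10) {
  cfg <- list(n = n, total_weight = total_weight,
              age_mean = age_mean, age_sd = age_sd,
              male_fraction = male_fraction,
              hba1c_meanlog = hba1c_meanlog, hba1c_sdlog = hba1c_sdlog,
              sbp_mean = sbp_mean, sbp_sd = sbp_sd,
              lipid_meanlog = lipid_meanlog, lipid_sdlog = lipid_sdlog,
              bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog,
              corr = corr,
              mi_prev = mi_prev, ckd_prev = ckd_prev,
              famhx_prev = famhx_prev, bleed_prev = bleed_prev,
              chf_prev = chf_prev,
              afib_prev_by_age = afib_prev_by_age,
              target_proportions = target_proportions,
              missingness_rates = missingness_rates,
              adherence = adherence, M = M)
  validate_population_config(cfg)
}

#' Baseline achievement proportions (national survey, 2015-2018)
#'
#' The weighted proportions of the national T2D population (age >= 45, no
#' stroke history) achieving each of the seven prevention strategies at
#' baseline, used as generator targets and calibration inputs.
#'
#' @return Named numeric vector over \code{strategies()}.
#' @export
default_target_proportions <- function() {
  c(glycemic = 0.576, bp = 0.707, statin = 0.600, aspirin = 0.079,
    smoking = 0.811, weight = 0.108, anticoagulant = 0.524)
}

#' @rdname population_config
#' @export
default_risk_corr <- function() {
  m <- diag(5)
  dimnames(m) <- list(RISK_FIELDS5, RISK_FIELDS5)
  # age-hba1c slightly negative (older adults hold lower HbA1c), classic
  # metabolic-syndrome positive block among hba1c/sbp/lipid/bmi
  m["age", "hba1c"] <- m["hba1c", "age"] <- -0.10
  m["age", "sbp"] <- m["sbp", "age"] <- 0.25
  m["age", "bmi"] <- m["bmi", "age"] <- -0.10
  m["hba1c", "sbp"] <- m["sbp", "hba1c"] <- 0.10
  m["hba1c", "lipid_ratio"] <- m["lipid_ratio", "hba1c"] <- 0.15
  m["hba1c", "bmi"] <- m["bmi", "hba1c"] <- 0.15
  m["sbp", "bmi"] <- m["bmi", "sbp"] <- 0.15
  m["lipid_ratio", "bmi"] <- m["bmi", "lipid_ratio"] <- 0.20
  m
}

RISK_FIELDS5 <- c("age", "hba1c", "sbp", "lipid_ratio", "bmi")

validate_population_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 0 ||
      cfg$n != floor(cfg$n))
    stop("n must be a non-negative integer", call. = FALSE)
  if (cfg$total_weight <= 0)
    stop("total_weight must be positive", call. = FALSE)
  fr <- c(cfg$male_fraction, cfg$mi_prev, cfg$ckd_prev, cfg$famhx_prev,
          cfg$bleed_prev, cfg$chf_prev, cfg$afib_prev_by_age,
          cfg$missingness_rates, cfg$adherence)
  if (!is.null(cfg$target_proportions)) {
    if (!all(STRATEGIES %in% names(cfg$target_proportions)))
      stop("target_proportions must be named over strategies()",
           call. = FALSE)
    fr <- c(fr, cfg$target_proportions)
  }
  if (any(fr < 0 | fr > 1))
    stop("all fractions/prevalences must lie in [0, 1]", call. = FALSE)
  ev <- eigen(cfg$corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("corr must be positive semi-definite", call. = FALSE)
  class(cfg) <- "population_config"
  cfg
}

#' Load a cohort configuration from YAML
#'
#' Reads a nested key/value configuration file, fills unspecified entries
#' with the package defaults, and validates the result.
#'
#' @param path Path to a YAML file; keys match the arguments of
#'   \code{\link{population_config}} (the correlation matrix is given as a
#'   list of rows).
#' @return A validated \code{population_config}.
#' @export
load_population_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  if (!is.null(raw$corr)) raw$corr <- do.call(rbind, raw$corr)
  for (nm in c("afib_prev_by_age", "target_proportions",
               "missingness_rates", "adherence"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$corr)) dimnames(raw$corr) <- list(RISK_FIELDS5, RISK_FIELDS5)
  known <- names(formals(population_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(population_config, raw)
}

# Moments of N(mu, sigma) truncated to [a, Inf).
trunc_norm_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + alpha * lambda - lambda^2)
  c(mean = m, sd = sqrt(v))
}

# Solve for the untruncated (mu, sigma) whose >= a truncation has the
# requested mean and SD.
match_trunc_norm <- function(target_mean, target_sd, a) {
  obj <- function(p) {
    mo <- trunc_norm_moments(p[1], exp(p[2]), a)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF sample of N(mu, sigma) truncated to [a, Inf) at uniform u.
qtnorm_lower <- function(u, mu, sigma, a) {
  pa <- pnorm(a, mu, sigma)
  qnorm(pa + u * (1 - pa), mu, sigma)
}

#' Generate a synthetic survey-weighted cohort
#'
#' Draws \code{n} individuals from the configured joint model: a Gaussian
#' copula over (age, HbA1c, SBP, lipid ratio, BMI) with age truncated at
#' 45, Bernoulli comorbidities (MI history, CKD, family history of
#' premature ASCVD, high bleeding risk, congestive heart failure) and
#' age-banded atrial fibrillation. When \code{target_proportions} is set,
#' baseline strategy-achievement indicators are drawn at the configured
#' rates and risk factors / treatment states are made consistent with them
#' (e.g. individuals achieving BP control have SBP/DBP under target and an
#' ACEi/ARB-containing regimen), so the weighted achievement proportions
#' converge to the targets.
#'
#' Every individual receives weight \code{total_weight / n}; the cohort
#' enters stroke-free.
#'
#' @param config A \code{\link{population_config}}.
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   cohorts.
#' @return A \code{population}: a data frame with one row per individual,
#'   carrying the generating config as attribute \code{"config"}.
#' @export
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n
  if (n == 0) {
    pop <- empty_population()
    attr(pop, "config") <- config
    return(pop)
  }
  set.seed(as.integer(seed))
  gs <- guideline_spec()

  # Gaussian copula over the five continuous risk fields
  L <- chol(config$corr + diag(1e-10, 5))
  Z <- matrix(rnorm(n * 5), n, 5) %*% L
  U <- pnorm(Z)
  colnames(U) <- RISK_FIELDS5

  ap <- match_trunc_norm(config$age_mean, config$age_sd, 45)
  age <- qtnorm_lower(U[, "age"], ap["mu"], ap["sigma"], 45)

  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")

  tp <- config$target_proportions
  flags <- list()
  for (s in STRATEGIES) {
    flags[[s]] <- if (is.null(tp)) rep(FALSE, n) else runif(n) < tp[[s]]
  }

  # HbA1c: flagged-at-goal individuals truncated below the age target,
  # others above it (achievement exactly equals the flag).
  hb_target <- hba1c_target(age, gs)
  hba1c <- if (is.null(tp)) {
    qlnorm(U[, "hba1c"], config$hba1c_meanlog, config$hba1c_sdlog)
  } else {
    pt <- plnorm(hb_target, config$hba1c_meanlog, config$hba1c_sdlog)
    u2 <- ifelse(flags$glycemic, U[, "hba1c"] * pt,
                 pt + U[, "hba1c"] * (1 - pt))
    qlnorm(u2, config$hba1c_meanlog, config$hba1c_sdlog)
  }
  hba1c <- pmin(pmax(hba1c, 3.5), 19)

  # SBP: BP-controlled individuals truncated below the systolic target.
  sbp <- if (is.null(tp)) {
    qnorm(U[, "sbp"], config$sbp_mean, config$sbp_sd)
  } else {
    pt <- pnorm(gs$bp_target[1], config$sbp_mean, config$sbp_sd)
    u2 <- ifelse(flags$bp, U[, "sbp"] * pt, U[, "sbp"])
    qnorm(u2, config$sbp_mean, config$sbp_sd)
  }
  sbp <- pmin(pmax(sbp, 85), 240)
  dbp <- 0.55 * sbp + rnorm(n, 0, 6)
  dbp <- pmin(pmax(dbp, 45), 140)
  if (!is.null(tp)) dbp[flags$bp] <- pmin(dbp[flags$bp], gs$bp_target[2] - 1)

  lipid_ratio <- qlnorm(U[, "lipid_ratio"], config$lipid_meanlog,
                        config$lipid_sdlog)
  lipid_ratio <- pmin(pmax(lipid_ratio, 1.5), 12)

  # BMI: weight-controlled individuals truncated below 25 kg/m2.
  bmi <- if (is.null(tp)) {
    qlnorm(U[, "bmi"], config$bmi_meanlog, config$bmi_sdlog)
  } else {
    pt <- plnorm(gs$weight_loss_bmi_floor, config$bmi_meanlog,
                 config$bmi_sdlog)
    u2 <- ifelse(flags$weight, U[, "bmi"] * pt,
                 pt + U[, "bmi"] * (1 - pt))
    qlnorm(u2, config$bmi_meanlog, config$bmi_sdlog)
  }
  bmi <- pmin(pmax(bmi, 15), 75)

  smoker <- if (is.null(tp)) runif(n) < 0.2 else !flags$smoking

  mi_history <- runif(n) < config$mi_prev
  ckd <- runif(n) < config$ckd_prev
  family_history_ascvd <- runif(n) < config$famhx_prev
  high_bleeding_risk <- runif(n) < config$bleed_prev
  chf <- runif(n) < config$chf_prev
  afib_p <- ifelse(age < 65, config$afib_prev_by_age[["<65"]],
                   ifelse(age < 75, config$afib_prev_by_age[["65-74"]],
                          config$afib_prev_by_age[[">=75"]]))
  afib <- runif(n) < afib_p

  # Treatment states, jointly with the achievement flags
  glycemic_level <- sample(0:4, n, replace = TRUE,
                           prob = c(0.15, 0.30, 0.30, 0.18, 0.07))
  bp_level <- integer(n)
  acei_arb <- rep(FALSE, n)
  if (!is.null(tp)) {
    # BP-controlled: on at least one rung with ACEi/ARB first line
    nb <- sum(flags$bp)
    bp_level[flags$bp] <- sample(1:6, nb, replace = TRUE,
                                 prob = c(0.1, 0.25, 0.25, 0.2, 0.12, 0.08))
    acei_arb[flags$bp] <- TRUE
    # uncontrolled-or-untreated: rungs possible when hypertensive, never
    # an ACEi-based controlled regimen (criterion stays false)
    unc <- !flags$bp & sbp >= gs$bp_target[1]
    bp_level[unc] <- sample(0:6, sum(unc), replace = TRUE,
                            prob = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.06, 0.04))
    acei_arb[unc] <- runif(sum(unc)) < 0.5
  }

  statin <- rep("none", n)
  if (!is.null(tp)) {
    recs <- recommended_statin_intensity(age, smoker, sbp, dbp, bp_level,
                                         lipid_ratio, family_history_ascvd,
                                         ckd, gs)
    statin[flags$statin] <- recs[flags$statin]
  }

  # Aspirin achievement is only possible for the eligible subgroup; assign
  # among the eligible at the rate that yields the population target.
  aspirin <- rep(FALSE, n)
  if (!is.null(tp)) {
    elig <- aspirin_eligible_vec(age, sbp, dbp, bp_level, lipid_ratio,
                                 smoker, ckd, family_history_ascvd,
                                 high_bleeding_risk, gs)
    fe <- mean(elig)
    if (fe > 0) {
      p_assign <- min(1, tp[["aspirin"]] / fe)
      if (tp[["aspirin"]] > fe)
        warning("aspirin target exceeds the eligible fraction (",
                signif(fe, 3), "); capped at full eligible coverage")
      aspirin[elig] <- runif(sum(elig)) < p_assign
    }
  }

  # Anticoagulation among AFib patients at high stroke risk
  anticoagulant <- rep("none", n)
  if (!is.null(tp)) {
    score <- chads_vasc_vec(age, sex, sbp, dbp, bp_level, mi_history,
                            rep(FALSE, n), chf)
    hi <- afib & score >= gs$chads_vasc_threshold
    on_ac <- hi & runif(n) < tp[["anticoagulant"]]
    anticoagulant[on_ac] <- ifelse(runif(sum(on_ac)) < 0.5,
                                   "warfarin", "noac")
  }

  adh <- matrix(FALSE, n, 7, dimnames = list(NULL, paste0("adh_", STRATEGIES)))
  for (j in seq_along(STRATEGIES))
    adh[, j] <- runif(n) < config$adherence[[STRATEGIES[j]]]

  pop <- data.frame(
    id = seq_len(n),
    age = age, sex = sex,
    weight = rep(config$total_weight / n, n),
    hba1c = hba1c, sbp = sbp, dbp = dbp,
    lipid_ratio = lipid_ratio, bmi = bmi,
    smoker = smoker, mi_history = mi_history, afib = afib, ckd = ckd,
    family_history_ascvd = family_history_ascvd,
    high_bleeding_risk = high_bleeding_risk, chf = chf,
    glycemic_level = glycemic_level, bp_level = bp_level,
    acei_arb = acei_arb, statin = statin, aspirin = aspirin,
    anticoagulant = anticoagulant,
    adh, state = rep("stroke_free", n),
    stringsAsFactors = FALSE)
  class(pop) <- c("population", "data.frame")
  attr(pop, "config") <- config
  validate_population(pop)
}

empty_population <- function() {
  pop <- data.frame(id = integer(), age = numeric(), sex = character(),
                    weight = numeric(), hba1c = numeric(), sbp = numeric(),
                    dbp = numeric(), lipid_ratio = numeric(),
                    bmi = numeric(), smoker = logical(),
                    mi_history = logical(), afib = logical(),
                    ckd = logical(), family_history_ascvd = logical(),
                    high_bleeding_risk = logical(), chf = logical(),
                    glycemic_level = integer(), bp_level = integer(),
                    acei_arb = logical(), statin = character(),
                    aspirin = logical(), anticoagulant = character(),
                    stringsAsFactors = FALSE)
  for (s in STRATEGIES) pop[[paste0("adh_", s)]] <- logical()
  pop$state <- character()
  class(pop) <- c("population", "data.frame")
  pop
}

#' Validate a population table
#'
#' Checks the schema and the domain invariants: positive weights, age at
#' least 45 at baseline, ladder rungs in range, risk factors in plausible
#' physiological bounds, and a stroke-free baseline state.
#'
#' @param pop A population data frame.
#' @return The population, invisibly classed, or an error.
#' @export
validate_population <- function(pop) {
  need <- names(empty_population())
  miss <- setdiff(need, names(pop))
  if (length(miss))
    stop("population is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(pop) == 0) return(pop)
  if (any(pop$weight <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(pop$age < 45)) stop("ages must be >= 45 at baseline", call. = FALSE)
  ok_na <- function(x, lo, hi) all(is.na(x) | (x > lo & x < hi))
  if (!ok_na(pop$hba1c, 3, 20)) stop("hba1c out of (3, 20)", call. = FALSE)
  if (!ok_na(pop$sbp, 70, 260)) stop("sbp out of (70, 260)", call. = FALSE)
  if (!ok_na(pop$bmi, 12, 80)) stop("bmi out of (12, 80)", call. = FALSE)
  if (any(pop$glycemic_level < 0 | pop$glycemic_level > 4))
    stop("glycemic_level out of 0..4", call. = FALSE)
  if (any(pop$bp_level < 0 | pop$bp_level > 6))
    stop("bp_level out of 0..6", call. = FALSE)
  if (!all(pop$statin %in% c("none", "moderate", "high")))
    stop("invalid statin level", call. = FALSE)
  if (!all(pop$anticoagulant %in% c("none", "warfarin", "noac")))
    stop("invalid anticoagulant", call. = FALSE)
  if (!all(pop$state == "stroke_free"))
    stop("baseline state must be stroke_free", call. = FALSE)
  if (!inherits(pop, "population")) class(pop) <- c("population", "data.frame")
  pop
}

#' @export
print.population <- function(x, ...) {
  cat("<population> n = ", nrow(x),
      ", total weight = ", format(sum(x$weight), big.mark = ","), "\n",
      sep = "")
  if (nrow(x) > 0)
    cat("  weighted mean age ", round(weighted_mean(x$age, x$weight), 1),
        ", male ", round(100 * weighted_mean(x$sex == "male", x$weight), 1),
        "%\n", sep = "")
  invisible(x)
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

#' Weighted achievement proportion for a prevention strategy
#'
#' Evaluates the baseline criterion of a strategy over a population and
#' returns the survey-weighted proportion achieving it. The anticoagulant
#' criterion is evaluated within its eligible subgroup (AFib with
#' CHA2DS2-VASc at or above threshold); all other strategies over the whole
#' cohort.
#'
#' @param pop A population.
#' @param strategy One of \code{strategies()}.
#' @param gspec A \code{\link{guideline_spec}}.
#' @return Weighted proportion in [0, 1] (NA for an empty denominator).
#' @export
measure_achievement <- function(pop, strategy, gspec = guideline_spec()) {
  strategy <- match.arg(strategy, STRATEGIES)
  if (nrow(pop) == 0) return(NA_real_)
  ach <- achievement_flags(pop, gspec)[[strategy]]
  if (strategy == "anticoagulant") {
    den <- attr(ach, "denominator")
    if (!any(den)) return(NA_real_)
    return(weighted_mean(ach[den], pop$weight[den]))
  }
  weighted_mean(ach, pop$weight)
}

# All seven achievement indicators at once (list of logical vectors).
achievement_flags <- function(pop, gspec = guideline_spec()) {
  out <- list()
  out$glycemic <- pop$hba1c < hba1c_target(pop$age, gspec)
  out$bp <- pop$sbp < gspec$bp_target[1] & pop$dbp < gspec$bp_target[2] &
    pop$bp_level >= 1 & pop$acei_arb
  rec <- recommended_statin_intensity(pop$age, pop$smoker, pop$sbp, pop$dbp,
                                      pop$bp_level, pop$lipid_ratio,
                                      pop$family_history_ascvd, pop$ckd,
                                      gspec)
  out$statin <- pop$statin == "high" | (pop$statin == "moderate" &
                                          rec == "moderate")
  elig <- aspirin_eligible_vec(pop$age, pop$sbp, pop$dbp, pop$bp_level,
                               pop$lipid_ratio, pop$smoker, pop$ckd,
                               pop$family_history_ascvd,
                               pop$high_bleeding_risk, gspec)
  out$aspirin <- pop$aspirin & elig
  out$smoking <- !pop$smoker
  out$weight <- pop$bmi < gspec$weight_loss_bmi_floor
  score <- chads_vasc_vec(pop$age, pop$sex, pop$sbp, pop$dbp, pop$bp_level,
                          pop$mi_history, pop$state %in%
                            c("acute_stroke", "post_stroke"), pop$chf)
  den <- pop$afib & score >= gspec$chads_vasc_threshold
  ac <- den & pop$anticoagulant != "none"
  attr(ac, "denominator") <- den
  out$anticoagulant <- ac
  out
}

#' Read/write a population as CSV
#'
#' One row per individual, header names matching the population schema;
#' missing values are written as empty cells.
#'
#' @param pop A population.
#' @param path File path.
#' @return \code{write_population} returns the path invisibly;
#'   \code{read_population} returns a validated population.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  logical_cols <- c("smoker", "mi_history", "afib", "ckd",
                    "family_history_ascvd", "high_bleeding_risk", "chf",
                    "acei_arb", "aspirin", paste0("adh_", STRATEGIES))
  for (cl in intersect(logical_cols, names(pop)))
    pop[[cl]] <- as.logical(pop[[cl]])
  validate_population(pop)
}
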