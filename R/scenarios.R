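#' Close a fraction of the adherence gap
#'
#' Partial-implementation scaling: moving fraction \code{f} of the way
#' from status-quo adherence \code{a} to full implementation gives
#' a + f (1 - a).
#'
#' @param a Status-quo adherence in [0, 1] (vectorised).
#' @param f Improvement fraction in [0, 1].
#' @return Scaled adherence.
#' @export
scale_adherence <- function(a, f) {
  stopifnot(all(a >= 0 & a <= 1), all(f >= 0 & f <= 1))
  a + f * (1 - a)
}

#' Scenario specification
#'
#' Names the strategies whose adherence is enhanced, resolves the
#' per-strategy adherence vector (status quo for unenhanced strategies;
#' full implementation, or partial implementation via
#' \code{improvement_fraction}, for enhanced ones), and fixes the horizon,
#' discount rate and cost-effectiveness thresholds.
#'
#' @param name Scenario name.
#' @param enhanced Character subset of \code{strategies()} (empty for the
#'   status quo).
#' @param status_quo_adherence Named per-strategy baseline adherence.
#' @param improvement_fraction Optional f in [0, 1]; enhanced strategies
#'   get \code{scale_adherence(a, f)} instead of 1.
#' @param adherence_overrides Optional named per-strategy values applied
#'   last.
#' @param horizon Simulation years (10 in the base case; 50 for a
#'   lifetime horizon).
#' @param discount_rate Annual discount rate.
#' @param lambda Cost-effectiveness threshold ($/QALY).
#' @param highly Highly-cost-effective cut ($/QALY).
#' @return A \code{scenario_spec}.
#' @export
scenario_spec <- function(name, enhanced = character(),
                          status_quo_adherence = population_config()$adherence,
                          improvement_fraction = NULL,
                          adherence_overrides = NULL,
                          horizon = 10, discount_rate = 0.03,
                          lambda = 1e5, highly = 5e4) {
  unknown <- setdiff(enhanced, STRATEGIES)
  if (length(unknown))
    stop("unknown strategy name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stopifnot(horizon >= 1)
  if (!is.null(improvement_fraction))
    stopifnot(improvement_fraction >= 0, improvement_fraction <= 1)
  adh <- as.list(status_quo_adherence[STRATEGIES])
  names(adh) <- STRATEGIES
  for (s in enhanced)
    adh[[s]] <- if (is.null(improvement_fraction)) 1
                else scale_adherence(adh[[s]], improvement_fraction)
  for (s in names(adherence_overrides)) {
    s <- match.arg(s, STRATEGIES)
    adh[[s]] <- adherence_overrides[[s]]
  }
  stopifnot(all(unlist(adh) >= 0), all(unlist(adh) <= 1))
  structure(list(name = name, enhanced = enhanced,
                 active = STRATEGIES, adherence = adh,
                 improvement_fraction = improvement_fraction,
                 horizon = horizon, discount_rate = discount_rate,
                 lambda = lambda, highly = highly),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, "\n  enhanced: ",
      if (length(x$enhanced)) paste(x$enhanced, collapse = ", ") else "(none)",
      "\n  horizon: ", x$horizon, " y, discount ",
      100 * x$discount_rate, "%\n", sep = "")
  invisible(x)
}

#' Scenario catalog: status quo plus the ten enhanced scenarios
#'
#' One status-quo scenario, seven single-strategy enhancements, two
#' combination scenarios and an all-strategies scenario. Combination
#' membership is declared in configuration (defaulting to the strategies
#' found individually cost-saving or highly cost-effective for
#' \code{multi1}, adding the cost-effective weight-loss strategy for
#' \code{multi2}) so the catalog is static and testable.
#'
#' @param status_quo_adherence Named per-strategy baseline adherence.
#' @param combo1,combo2 Strategy membership of the two combination
#'   scenarios.
#' @param improvement_fraction Optional partial-implementation fraction
#'   applied to every enhanced scenario.
#' @param horizon,discount_rate,lambda,highly Passed to
#'   \code{\link{scenario_spec}}.
#' @return Named list of 11 \code{scenario_spec}s (status quo first).
#' @export
build_catalog <- function(status_quo_adherence = population_config()$adherence,
                          combo1 = c("bp", "aspirin", "statin", "smoking"),
                          combo2 = c("bp", "aspirin", "statin", "smoking",
                                     "weight"),
                          improvement_fraction = NULL,
                          horizon = 10, discount_rate = 0.03,
                          lambda = 1e5, highly = 5e4) {
  mk <- function(name, enh)
    scenario_spec(name, enh, status_quo_adherence, improvement_fraction,
                  horizon = horizon, discount_rate = discount_rate,
                  lambda = lambda, highly = highly)
  singles <- lapply(STRATEGIES, function(s) mk(s, s))
  names(singles) <- STRATEGIES
  c(list(status_quo = mk("status_quo", character())),
    singles,
    list(multi1 = mk("multi1", combo1),
         multi2 = mk("multi2", combo2),
         all = mk("all", STRATEGIES)))
}

#' Run the scenario catalog over imputations and replicates
#'
#' For every scenario, imputation m and replicate r, simulates the full
#' cohort with the common-random-number stream indexed by (m, r) shared
#' across scenarios (so scenario contrasts are paired), and records the
#' survey-weighted national totals.
#'
#' @param populations An \code{imputed_population_set} (or a single
#'   population, treated as M = 1).
#' @param catalog Scenario list from \code{\link{build_catalog}}.
#' @param registry A \code{parameter_registry}.
#' @param gspec A \code{\link{guideline_spec}}.
#' @param R Replicates per imputation (>= 1).
#' @param seed Master integer seed.
#' @param progress Print per-scenario progress.
#' @return A \code{simulation_result}: a data frame with one row per
#'   scenario x imputation x replicate (weighted totals of stroke events,
#'   stroke deaths, MI events, discounted cost and QALYs), with design
#'   metadata in attributes.
#' @export
run_simulation <- function(populations, catalog,
                           registry = default_registry(),
                           gspec = guideline_spec(), R = 50, seed = 1,
                           progress = FALSE) {
  stopifnot(R >= 1)
  if (inherits(populations, "population"))
    populations <- imputed_population_set(list(populations))
  stopifnot(inherits(populations, "imputed_population_set"))
  M <- populations$M
  rl <- reg_flatten(registry)
  horizon <- max(vapply(catalog, `[[`, numeric(1), "horizon"))
  n <- nrow(populations$imputations[[1]])
  rows <- vector("list", length(catalog) * M * R)
  k <- 0
  for (m in seq_len(M)) {
    pop_m <- populations$imputations[[m]]
    for (r in seq_len(R)) {
      streams <- make_streams(n, horizon, seed, m, r)
      for (sc in catalog) {
        res <- simulate_cohort(pop_m, sc, rl, gspec, streams = streams)
        k <- k + 1
        rows[[k]] <- data.frame(scenario = sc$name, imputation = m,
                                replicate = r, t(res$totals),
                                stringsAsFactors = FALSE)
      }
    }
    if (progress)
      message("imputation ", m, "/", M, " done (", R, " replicates x ",
              length(catalog), " scenarios)")
  }
  out <- do.call(rbind, rows)
  attr(out, "design") <- list(n = n, M = M, R = R, seed = seed,
                              horizon = horizon,
                              scenarios = vapply(catalog, `[[`,
                                                 character(1), "name"))
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' Compare a scenario to the status quo
#'
#' Incremental outcomes (scenario minus status quo) are formed within each
#' (imputation, replicate) pair — valid because both arms share common
#' random numbers — then averaged. Uncertainty intervals are the 2.5th and
#' 97.5th percentiles of the paired incremental outcomes pooled over
#' imputations and replicates. NHB, ICER and the cost-effectiveness label
#' come from the economics module.
#'
#' @param result A \code{simulation_result}.
#' @param scenario Scenario name to compare.
#' @param status_quo Comparator name (default \code{"status_quo"}).
#' @param lambda Threshold for NHB and the cost-effective label.
#' @param highly Highly-cost-effective cut.
#' @return A one-row \code{cea_result} data frame: strokes averted, stroke
#'   deaths averted, incremental cost, incremental QALYs, NHB, ICER type/
#'   ratio, label, and 95\% UI bounds for each incremental quantity.
#' @export
compare <- function(result, scenario, status_quo = "status_quo",
                    lambda = 1e5, highly = 5e4) {
  a <- result[result$scenario == scenario, ]
  b <- result[result$scenario == status_quo, ]
  if (!nrow(a)) stop("scenario not in result: ", scenario, call. = FALSE)
  if (!nrow(b)) stop("comparator not in result: ", status_quo, call. = FALSE)
  key <- function(d) paste(d$imputation, d$replicate)
  if (!identical(sort(key(a)), sort(key(b))) || nrow(a) != nrow(b))
    stop("mismatched designs between scenario and comparator", call. = FALSE)
  a <- a[order(a$imputation, a$replicate), ]
  b <- b[order(b$imputation, b$replicate), ]
  d_strokes <- b$strokes - a$strokes            # averted = comparator - scenario
  d_deaths <- b$stroke_deaths - a$stroke_deaths
  d_cost <- a$cost - b$cost
  d_qaly <- a$qalys - b$qalys
  d_nhb <- nhb(d_qaly, d_cost, lambda)
  ic <- icer(mean(d_cost), mean(d_qaly))
  ui <- function(x) if (length(x) >= 2) uncertainty_interval(x)
        else c(lower = NA_real_, upper = NA_real_)
  out <- data.frame(
    scenario = scenario, comparator = status_quo,
    strokes_averted = mean(d_strokes),
    strokes_averted_lo = ui(d_strokes)[1], strokes_averted_hi = ui(d_strokes)[2],
    stroke_deaths_averted = mean(d_deaths),
    stroke_deaths_averted_lo = ui(d_deaths)[1],
    stroke_deaths_averted_hi = ui(d_deaths)[2],
    delta_cost = mean(d_cost),
    delta_cost_lo = ui(d_cost)[1], delta_cost_hi = ui(d_cost)[2],
    delta_qaly = mean(d_qaly),
    delta_qaly_lo = ui(d_qaly)[1], delta_qaly_hi = ui(d_qaly)[2],
    nhb = mean(d_nhb), nhb_lo = ui(d_nhb)[1], nhb_hi = ui(d_nhb)[2],
    icer_type = ic$type, icer = ic$ratio,
    label = classify_cost_effectiveness(ic, lambda, highly),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("cea_result", "data.frame")
  out
}

#' Full cost-effectiveness report for a simulation result
#'
#' Applies \code{\link{compare}} to every non-comparator scenario and
#' stacks the rows into one table with the standard column set (events
#' averted, deaths averted, incremental cost, incremental QALYs, NHB,
#' ICER/classification and 95\% UIs).
#'
#' @inheritParams compare
#' @return A \code{cea_result} data frame, one row per scenario.
#' @export
cea_report <- function(result, status_quo = "status_quo", lambda = 1e5,
                       highly = 5e4) {
  sc <- setdiff(unique(result$scenario), status_quo)
  out <- do.call(rbind, lapply(sc, compare, result = result,
                               status_quo = status_quo, lambda = lambda,
                               highly = highly))
  class(out) <- c("cea_result", "data.frame")
  out
}

#' Write a cost-effectiveness report
#'
#' @param cea A \code{cea_result} table.
#' @param path Output path; format from the extension (\code{.csv} or
#'   \code{.json}).
#' @return The path, invisibly.
#' @export
write_cea <- function(cea, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(cea), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(cea), path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' One-way sensitivity analysis
#'
#' Re-runs a scenario-vs-status-quo comparison with one registry parameter
#' pinned at its lower or upper uncertainty bound, all else at base, one
#' row per (parameter, bound). Optionally appends the reduced
#' insulin-price variant as a cost-schedule swap.
#'
#' @param populations An \code{imputed_population_set} or population.
#' @param scenario A \code{scenario_spec} to contrast with the status quo.
#' @param parameters Character vector of registry parameter names to swing.
#' @param registry A \code{parameter_registry}.
#' @param status_quo_adherence Baseline adherence for the comparator.
#' @param gspec A \code{\link{guideline_spec}}.
#' @param R Replicates per imputation.
#' @param seed Master seed.
#' @param insulin_variant Include the reduced insulin-price row.
#' @return Data frame of \code{cea_result} rows with \code{parameter} and
#'   \code{bound} columns (first row: all parameters at base).
#' @export
run_owsa <- function(populations, scenario, parameters,
                     registry = default_registry(),
                     status_quo_adherence = population_config()$adherence,
                     gspec = guideline_spec(), R = 10, seed = 1,
                     insulin_variant = TRUE) {
  missing_p <- setdiff(parameters, registry$name)
  if (length(missing_p))
    stop("parameters without registry bounds: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  sq <- scenario_spec("status_quo", character(), status_quo_adherence,
                      horizon = scenario$horizon,
                      discount_rate = scenario$discount_rate,
                      lambda = scenario$lambda, highly = scenario$highly)
  catalog <- list(status_quo = sq, scenario = scenario)
  one <- function(reg, parameter, bound) {
    res <- run_simulation(populations, catalog, reg, gspec, R = R,
                          seed = seed)
    row <- compare(res, scenario$name, "status_quo", scenario$lambda,
                   scenario$highly)
    cbind(data.frame(parameter = parameter, bound = bound,
                     stringsAsFactors = FALSE), row)
  }
  rows <- list(one(registry, "(all)", "base"))
  for (p in parameters) {
    for (bd in c("low", "high")) {
      reg <- reg_set(registry, p, reg_value(registry, p, bd))
      rows[[length(rows) + 1]] <- one(reg, p, bd)
    }
  }
  if (insulin_variant)
    rows[[length(rows) + 1]] <- one(reduced_insulin_registry(registry),
                                    "insulin_price", "reduced")
  do.call(rbind, rows)
}
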