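#' Calibrate a strategy's adherence to a target achievement proportion
#'
#' Finds the adherence probability a for one strategy such that, after one
#' status-quo policy cycle (recommendations issued and adopted with
#' probability a), the survey-weighted proportion achieving the strategy's
#' criterion is within \code{tol} of the target. Adoption uses a single
#' fixed set of per-individual uniform draws, making the achieved
#' proportion an exactly nondecreasing step function of a, so bisection is
#' valid and deterministic.
#'
#' If the target lies below the proportion already achieved with a = 0, or
#' above the proportion achievable with a = 1, the target is infeasible
#' and the error names the feasible range.
#'
#' @param pop A population.
#' @param strategy One of \code{strategies()}.
#' @param target_proportion Target in [0, 1].
#' @param registry A \code{parameter_registry}.
#' @param gspec A \code{\link{guideline_spec}}.
#' @param tol Achievement tolerance (> 0); must be coarser than one
#'   individual's weight share for a hit to be guaranteed.
#' @param seed Seed for the fixed adoption draws.
#' @return Adherence in [0, 1], with the achieved proportion in attribute
#'   \code{"achieved"}.
#' @export
calibrate_adherence <- function(pop, strategy, target_proportion,
                                registry = default_registry(),
                                gspec = guideline_spec(), tol = 0.005,
                                seed = 1) {
  strategy <- match.arg(strategy, STRATEGIES)
  stopifnot(target_proportion >= 0, target_proportion <= 1, tol > 0)
  rl <- reg_flatten(registry)
  n <- nrow(pop)
  set.seed(as.integer(seed))
  u_adopt <- runif(n)
  u_quit <- runif(n)
  masks <- recommend_masks(pop, strategy, gspec, year = 1)
  adherence <- as.list(setNames(rep(0, 7), STRATEGIES))
  j <- match(strategy, STRATEGIES)

  achieved_at <- function(a) {
    u <- matrix(1, n, 7)
    u[, j] <- u_adopt
    adherence[[strategy]] <- a
    st <- apply_adherence_vec(pop, masks, adherence, rl, gspec, u, u_quit)
    measure_achievement(st$pop, strategy, gspec)
  }

  f0 <- achieved_at(0)
  f1 <- achieved_at(1)
  if (is.na(f0) || is.na(f1))
    stop("infeasible target for strategy '", strategy,
         "': its eligible subgroup is empty in this population",
         call. = FALSE)
  if (target_proportion < f0 - tol || target_proportion > f1 + tol)
    stop(sprintf(
      "infeasible target %.4f for strategy '%s': feasible range [%.4f, %.4f]",
      target_proportion, strategy, f0, f1), call. = FALSE)
  if (abs(f0 - target_proportion) <= tol)
    return(structure(0, achieved = f0))
  if (f1 <= target_proportion)
    return(structure(1, achieved = f1))

  lo <- 0; hi <- 1
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    fm <- achieved_at(mid)
    if (abs(fm - target_proportion) <= tol)
      return(structure(mid, achieved = fm))
    if (fm < target_proportion) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  mid <- (lo + hi) / 2
  structure(mid, achieved = achieved_at(mid))
}

#' Calibrate all seven strategies to their targets
#'
#' Runs \code{\link{calibrate_adherence}} per strategy against a named
#' target vector (skipping strategies whose target is already achieved at
#' zero adherence, for which it returns 0).
#'
#' In a finite cohort the baseline achieved proportion fluctuates around
#' its target, so a sampled cohort can sit slightly above a national
#' target, making it strictly infeasible. With
#' \code{on_infeasible = "clamp"} such strategies return the nearest
#' boundary (0 below the feasible range, 1 above) with a warning instead
#' of an error.
#'
#' @param pop A population.
#' @param targets Named target proportions over \code{strategies()}.
#' @param on_infeasible \code{"error"} (default) or \code{"clamp"}.
#' @param ... Passed to \code{\link{calibrate_adherence}}.
#' @return Named numeric vector of adherence values in [0, 1].
#' @export
calibrate_all <- function(pop, targets = default_target_proportions(),
                          on_infeasible = c("error", "clamp"), ...) {
  on_infeasible <- match.arg(on_infeasible)
  vapply(STRATEGIES, function(s) {
    tryCatch(as.numeric(calibrate_adherence(pop, s, targets[[s]], ...)),
             error = function(e) {
               if (on_infeasible == "error" ||
                   !grepl("infeasible", conditionMessage(e)))
                 stop(e)
               f0 <- measure_achievement(pop, s)
               a <- if (!is.na(f0) && targets[[s]] < f0) 0 else 1
               warning("strategy '", s, "': ", conditionMessage(e),
                       "; clamped to ", a, call. = FALSE)
               a
             })
  }, numeric(1))
}
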