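#' Present value of an annual stream
#'
#' Discounts a per-year stream at the given annual rate with the
#' convention that the first simulation year is undiscounted (t = 0):
#' PV = sum_t stream[t] (1 + rate)^-(t-1).
#'
#' @param stream Numeric vector of per-year amounts (year 1 first).
#' @param rate Annual discount rate (>= 0); default 3\%.
#' @return The present value.
#' @export
discount <- function(stream, rate = 0.03) {
  stopifnot(rate >= 0)
  if (!length(stream)) return(0)
  sum(stream * (1 + rate)^-(seq_along(stream) - 1))
}

#' Discounted cost and QALY accrual over a trajectory
#'
#' Sums one individual's per-year costs and utilities (as recorded by the
#' simulation engine: medication costs by treatment rung/intensity, acute
#' and chronic event costs, programme and death costs; baseline utility
#' minus state, treatment and hypoglycemia decrements, floored at zero,
#' with zero utility in the death year) and discounts both streams.
#'
#' @param records Annual record table for one individual (from
#'   \code{\link{simulate_individual}}), with \code{cost} and
#'   \code{utility} columns in year order.
#' @param rate Annual discount rate.
#' @return Named numeric vector \code{c(cost = , qaly = )}.
#' @export
accrue <- function(records, rate = 0.03) {
  stopifnot(all(c("cost", "utility") %in% names(records)))
  records <- records[order(records$year), ]
  c(cost = discount(records$cost, rate),
    qaly = discount(records$utility, rate))
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' An intervention with lower cost and more QALYs than its comparator is
#' cost-saving; one with higher cost and fewer QALYs is dominated (no
#' meaningful ratio); zero incremental QALYs leave the ratio undefined;
#' otherwise the ICER is the cost per QALY gained.
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @return A list with \code{type} in
#'   \{\code{"cost_saving"}, \code{"dominated"}, \code{"undefined"},
#'   \code{"ratio"}\} and \code{ratio} (the $/QALY value, or NA).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0)
    return(list(type = "undefined", ratio = NA_real_))
  if (delta_cost < 0 && delta_qaly > 0)
    return(list(type = "cost_saving", ratio = NA_real_))
  if (delta_cost > 0 && delta_qaly < 0)
    return(list(type = "dominated", ratio = NA_real_))
  list(type = "ratio", ratio = delta_cost / delta_qaly)
}

#' Net health benefit
#'
#' NHB = incremental QALYs minus incremental cost divided by the
#' willingness-to-pay threshold: the QALYs gained net of the QALYs the
#' additional spending displaces elsewhere.
#'
#' @param delta_qaly Incremental QALYs.
#' @param delta_cost Incremental cost.
#' @param lambda Cost-effectiveness threshold in $/QALY (> 0); default
#'   $100,000.
#' @return NHB in QALYs.
#' @export
nhb <- function(delta_qaly, delta_cost, lambda = 1e5) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  delta_qaly - delta_cost / lambda
}

#' Percentile uncertainty interval from replicate outcomes
#'
#' Empirical 2.5th and 97.5th percentiles (linear interpolation) across
#' replicate simulation values.
#'
#' @param replicate_values Numeric vector (at least 2 values).
#' @return Numeric \code{c(lower, upper)}.
#' @export
uncertainty_interval <- function(replicate_values) {
  if (length(replicate_values) < 2)
    stop("need at least 2 replicate values", call. = FALSE)
  stats::setNames(quantile(replicate_values, c(0.025, 0.975), names = FALSE,
                           type = 7),
                  c("lower", "upper"))
}

#' Cost-effectiveness label
#'
#' Maps an \code{\link{icer}} result to the reporting label: cost-saving;
#' highly cost-effective (ICER below the highly-cost-effective cut,
#' default $50,000/QALY); cost-effective (below the threshold, default
#' $100,000/QALY); otherwise (including dominated or undefined) not
#' cost-effective.
#'
#' @param icer_result Result of \code{\link{icer}}.
#' @param threshold Cost-effectiveness threshold ($/QALY).
#' @param highly Highly-cost-effective cut ($/QALY).
#' @return One of \code{"cost-saving"}, \code{"highly cost-effective"},
#'   \code{"cost-effective"}, \code{"not cost-effective"}.
#' @export
classify_cost_effectiveness <- function(icer_result, threshold = 1e5,
                                        highly = 5e4) {
  if (icer_result$type == "cost_saving") return("cost-saving")
  if (icer_result$type %in% c("dominated", "undefined"))
    return("not cost-effective")
  r <- icer_result$ratio
  if (r < highly) "highly cost-effective"
  else if (r < threshold) "cost-effective"
  else "not cost-effective"
}
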