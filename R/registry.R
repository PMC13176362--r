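#' Parameter registry
#'
#' The registry holds every numeric model input as a named record with a
#' base value and lower/upper uncertainty bounds: baseline annual hazards,
#' hazard ratios per risk-factor unit, relative risk reductions for aspirin,
#' NOAC and statin therapy, per-rung treatment effects, annual drift slopes,
#' hypoglycemia rates, costs (2022 USD) and utility decrements. One-way
#' sensitivity analysis swings a single entry to its low or high bound.
#'
#' @param path Path to a registry CSV with columns
#'   \code{name,base,low,high,units,note}. Defaults to the versioned
#'   parameter file shipped with the package.
#' @return A \code{parameter_registry}: a data frame with one row per
#'   parameter, validated so that \code{low <= base <= high}, hazards and
#'   costs are non-negative, hazard ratios positive, and relative risk
#'   reductions in [0, 1).
#' @export
load_registry <- function(path = system.file("extdata", "parameters.csv",
                                             package = "strokeprev")) {
  stopifnot(nzchar(path), file.exists(path))
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_registry(reg)
}

#' @rdname load_registry
#' @export
default_registry <- function() load_registry()

validate_registry <- function(reg) {
  needed <- c("name", "base", "low", "high")
  if (!all(needed %in% names(reg)))
    stop("registry must have columns name, base, low, high", call. = FALSE)
  if (anyDuplicated(reg$name))
    stop("duplicate registry parameter names", call. = FALSE)
  bad <- !(reg$low <= reg$base & reg$base <= reg$high)
  if (any(bad))
    stop("registry bounds violated (need low <= base <= high) for: ",
         paste(reg$name[bad], collapse = ", "), call. = FALSE)
  haz <- grep("^(stroke|mi|mort)_", reg$name)
  if (any(reg$low[haz] < 0))
    stop("hazard parameters must be non-negative", call. = FALSE)
  hr <- grep("^(hr_|mi_hr_|.*_hr$)", reg$name)
  if (any(reg$low[hr] <= 0))
    stop("hazard ratios must be positive", call. = FALSE)
  rrr <- grep("^rrr_", reg$name)
  if (any(reg$low[rrr] < 0 | reg$high[rrr] >= 1))
    stop("relative risk reductions must lie in [0, 1)", call. = FALSE)
  cost <- grep("^cost_", reg$name)
  if (any(reg$low[cost] < 0))
    stop("costs must be non-negative", call. = FALSE)
  class(reg) <- c("parameter_registry", "data.frame")
  reg
}

#' Read a registry value
#'
#' @param reg A \code{parameter_registry}.
#' @param name Parameter name.
#' @param which One of \code{"base"}, \code{"low"}, \code{"high"}.
#' @return The scalar value.
#' @export
reg_value <- function(reg, name, which = "base") {
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown registry parameter: ", name, call. = FALSE)
  which <- match.arg(which, c("base", "low", "high"))
  reg[[which]][i]
}

#' Override a registry base value
#'
#' Used by one-way sensitivity analysis to pin a parameter at a bound.
#'
#' @inheritParams reg_value
#' @param value New base value (must lie inside the parameter's bounds
#'   unless \code{relax = TRUE}).
#' @param relax Skip the bounds check.
#' @return The modified registry.
#' @export
reg_set <- function(reg, name, value, relax = FALSE) {
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown registry parameter: ", name, call. = FALSE)
  reg$base[i] <- value
  if (!relax) {
    reg$low[i] <- min(reg$low[i], value)
    reg$high[i] <- max(reg$high[i], value)
  }
  validate_registry(as.data.frame(reg))
}

# Flatten to a named list of scalars for the simulation hot path.
# `which` may be a single bound for all parameters, or a named character
# vector of per-parameter overrides (OWSA).
reg_flatten <- function(reg, which = "base", overrides = NULL) {
  vals <- reg$base
  names(vals) <- reg$name
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, reg$name)
      if (is.na(i)) stop("unknown registry parameter: ", nm, call. = FALSE)
      vals[i] <- reg[[match.arg(overrides[[nm]], c("base", "low", "high"))]][i]
    }
  }
  as.list(vals)
}

#' Apply the reduced insulin price variant
#'
#' Replaces the basal/intensive insulin annual costs with the reduced
#' list-price entries, for the insulin-price sensitivity analysis.
#'
#' @param reg A \code{parameter_registry}.
#' @return The modified registry.
#' @export
reduced_insulin_registry <- function(reg) {
  reg <- reg_set(reg, "cost_glycemic_rung3",
                 reg_value(reg, "cost_glycemic_rung3_reduced"))
  reg_set(reg, "cost_glycemic_rung4",
          reg_value(reg, "cost_glycemic_rung4_reduced"))
}

#' @export
print.parameter_registry <- function(x, ...) {
  cat("<parameter_registry> ", nrow(x), " parameters\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
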