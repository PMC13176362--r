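# Fields that live in the Gaussian copula and may go missing.
IMPUTABLE_FIELDS <- c("hba1c", "sbp", "lipid_ratio", "bmi")

# Marginal CDF / quantile for each copula coordinate under a config.
marginal_p <- function(field, x, cfg) {
  switch(field,
         age = {
           ap <- match_trunc_norm(cfg$age_mean, cfg$age_sd, 45)
           pa <- pnorm(45, ap["mu"], ap["sigma"])
           (pnorm(x, ap["mu"], ap["sigma"]) - pa) / (1 - pa)
         },
         hba1c = plnorm(x, cfg$hba1c_meanlog, cfg$hba1c_sdlog),
         sbp = pnorm(x, cfg$sbp_mean, cfg$sbp_sd),
         lipid_ratio = plnorm(x, cfg$lipid_meanlog, cfg$lipid_sdlog),
         bmi = plnorm(x, cfg$bmi_meanlog, cfg$bmi_sdlog),
         stop("no marginal for field ", field, call. = FALSE))
}

marginal_q <- function(field, u, cfg) {
  switch(field,
         hba1c = pmin(pmax(qlnorm(u, cfg$hba1c_meanlog, cfg$hba1c_sdlog),
                           3.5), 19),
         sbp = pmin(pmax(qnorm(u, cfg$sbp_mean, cfg$sbp_sd), 85), 240),
         lipid_ratio = pmin(pmax(qlnorm(u, cfg$lipid_meanlog,
                                        cfg$lipid_sdlog), 1.5), 12),
         bmi = pmin(pmax(qlnorm(u, cfg$bmi_meanlog, cfg$bmi_sdlog), 15), 75),
         stop("no quantile for field ", field, call. = FALSE))
}

#' Apply missing-completely-at-random missingness
#'
#' Sets each imputable risk-factor field (\code{hba1c}, \code{sbp},
#' \code{lipid_ratio}, \code{bmi}) to missing independently at the
#' configured per-field rate.
#'
#' @param pop A population.
#' @param rates Named per-field missingness fractions (defaults from the
#'   population's generating config).
#' @param seed Integer seed.
#' @return The population with NAs introduced.
#' @export
apply_missingness <- function(pop, rates = NULL, seed = 1) {
  cfg <- attr(pop, "config")
  if (is.null(rates)) rates <- cfg$missingness_rates
  set.seed(as.integer(seed))
  for (f in intersect(names(rates), IMPUTABLE_FIELDS)) {
    if (rates[[f]] <= 0) next
    pop[[f]][runif(nrow(pop)) < rates[[f]]] <- NA_real_
  }
  pop
}

#' Multiply impute missing risk factors
#'
#' Produces M complete copies of the population. Missing copula fields are
#' redrawn from the Gaussian-copula conditional distribution given the
#' individual's observed copula fields (age is always observed): observed
#' values are mapped to normal scores through their marginals, the missing
#' scores are drawn from the conditional multivariate normal, and mapped
#' back. Non-missing fields are identical across imputations. With no
#' missing data the imputations are exact copies.
#'
#' @param pop A population, possibly with NAs in imputable fields.
#' @param M Number of imputations (>= 1).
#' @param seed Integer seed.
#' @param config Generating \code{population_config} (defaults to the one
#'   attached to \code{pop}).
#' @return An \code{imputed_population_set}.
#' @export
impute_population <- function(pop, M = 10, seed = 1,
                              config = attr(pop, "config")) {
  if (M < 1) stop("M must be at least 1", call. = FALSE)
  if (is.null(config))
    stop("population carries no config; pass `config`", call. = FALSE)
  set.seed(as.integer(seed))
  obs_na <- is.na(as.matrix(pop[IMPUTABLE_FIELDS]))
  any_na <- rowSums(obs_na) > 0
  imps <- vector("list", M)
  if (!any(any_na)) {
    for (m in seq_len(M)) imps[[m]] <- pop
    return(imputed_population_set(imps))
  }
  Sigma <- config$corr
  idx <- which(any_na)
  # z-scores of the observed copula coordinates (age never missing)
  zmat <- matrix(NA_real_, nrow(pop), 5,
                 dimnames = list(NULL, RISK_FIELDS5))
  zmat[, "age"] <- qnorm(pmin(pmax(
    marginal_p("age", pop$age, config), 1e-12), 1 - 1e-12))
  for (f in IMPUTABLE_FIELDS) {
    ok <- !is.na(pop[[f]])
    zmat[ok, f] <- qnorm(pmin(pmax(
      marginal_p(f, pop[[f]][ok], config), 1e-12), 1 - 1e-12))
  }
  for (m in seq_len(M)) {
    imp <- pop
    for (i in idx) {
      mis <- RISK_FIELDS5[is.na(zmat[i, ])]
      obs <- setdiff(RISK_FIELDS5, mis)
      Soo <- Sigma[obs, obs, drop = FALSE]
      Smo <- Sigma[mis, obs, drop = FALSE]
      Smm <- Sigma[mis, mis, drop = FALSE]
      K <- Smo %*% solve(Soo)
      mu_c <- as.vector(K %*% zmat[i, obs])
      S_c <- Smm - K %*% t(Smo)
      S_c <- (S_c + t(S_c)) / 2
      L <- chol(S_c + diag(1e-10, nrow(S_c)))
      z_draw <- mu_c + as.vector(t(L) %*% rnorm(length(mis)))
      u_draw <- pmin(pmax(pnorm(z_draw), 1e-12), 1 - 1e-12)
      for (k in seq_along(mis))
        imp[[mis[k]]][i] <- marginal_q(mis[k], u_draw[k], config)
    }
    imps[[m]] <- imp
  }
  imputed_population_set(imps)
}

#' Apply missingness and impute in one step
#'
#' Introduces MCAR missingness at the configured rates, then multiply
#' imputes, returning M complete populations that share ids, weights and
#' all originally non-missing values.
#'
#' @inheritParams impute_population
#' @return An \code{imputed_population_set}.
#' @export
apply_missingness_and_impute <- function(pop, M = 10, seed = 1) {
  if (M < 1) stop("M must be at least 1", call. = FALSE)
  withNA <- apply_missingness(pop, seed = seed)
  impute_population(withNA, M = M, seed = seed + 1,
                    config = attr(pop, "config"))
}

#' Container for M imputed populations
#'
#' @param imputations List of complete populations sharing ids and weights.
#' @return An \code{imputed_population_set} with elements
#'   \code{imputations} and \code{M}.
#' @export
imputed_population_set <- function(imputations) {
  M <- length(imputations)
  if (M < 1) stop("need at least one imputation", call. = FALSE)
  ref <- imputations[[1]]
  for (m in seq_len(M)) {
    im <- imputations[[m]]
    if (anyNA(im[IMPUTABLE_FIELDS]))
      stop("imputation ", m, " is not complete", call. = FALSE)
    if (!identical(im$id, ref$id) ||
        !isTRUE(all.equal(im$weight, ref$weight)))
      stop("imputations must share ids and weights", call. = FALSE)
  }
  structure(list(imputations = imputations, M = M),
            class = "imputed_population_set")
}

#' @export
print.imputed_population_set <- function(x, ...) {
  cat("<imputed_population_set> M = ", x$M, ", n = ",
      nrow(x$imputations[[1]]), "\n", sep = "")
  invisible(x)
}
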