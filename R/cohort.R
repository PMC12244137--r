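## Synthetic cohort generation: covariates, hormones with left-censoring,
## latent factor, regional binding outcomes, HAMD items.

stage_seed <- function(seed, stage) {
  ## deterministic per-stage child seed below 2^31
  as.integer((as.double(seed) * 7919 + stage * 1000003) %% 2147483647)
}

rtruncnorm_left <- function(n, mean, sd, lower) {
  ## exact inverse-CDF sampler for a left-truncated normal
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Generate a synthetic PET cohort
#'
#' Draws a subject-level table with the generative structure assumed by the
#' latent-variable models in this package: covariates (age, injected tracer
#' dose per kg, scanner), per-group testosterone, estradiol linearly coupled
#' to testosterone, a global latent factor
#' \deqn{\eta = \gamma_G G + \gamma_1(G) T + \gamma_2(G) E^* + \zeta}
#' driven by group and by the *uncensored* estradiol \eqn{E^*}, and four
#' regional binding potentials
#' \deqn{Y_r = \nu_r + \lambda_r \eta + \beta_r' x + \epsilon_r}
#' with an optional extra hippocampus-amygdala residual covariance. Estradiol
#' is then left-censored at the limit of quantification: censored rows store
#' the LOQ in `estradiol` with `estradiol_censored = TRUE`; the uncensored
#' draw is kept in `estradiol_true` so that oracle tests can condition on it.
#'
#' Because outcomes are generated from the uncensored estradiol, the
#' structural model is literally true in the simulated population.
#'
#' @param params a [default_params()] object.
#' @param seed integer seed; defaults to `params$seed`. The same seed yields a
#'   bit-identical table. Per-stage child streams are derived from it.
#' @param hamd fill HAMD items for MDD subjects via [generate_hamd()].
#' @return A `data.frame` of class `"cohort_table"`; one row per subject with
#'   columns `id`, `group` (`"MDD"`/`"HC"`), `age` (years), `dose` (ug/kg),
#'   `scanner` (`"HRRT"`/`"GE"`), `bp_neostriatum`, `bp_hippocampus`,
#'   `bp_amygdala`, `bp_prefrontal`, `testosterone` (nM), `estradiol` (nM),
#'   `estradiol_censored`, `estradiol_true`, `hamd_1` ... `hamd_17`.
#' @examples
#' cohort <- generate_cohort(default_params(), seed = 1)
#' table(cohort$group, cohort$estradiol_censored)
#' @export
generate_cohort <- function(params, seed = params$seed, hamd = TRUE) {
  validate_params(params)
  n_mdd <- as.integer(params$n_mdd)
  n_hc <- as.integer(params$n_hc)
  n <- n_mdd + n_hc
  group <- c(rep("MDD", n_mdd), rep("HC", n_hc))
  g <- as.numeric(group == "MDD")
  key <- ifelse(g == 1, "mdd", "hc")

  set.seed(stage_seed(seed, 1L)) # covariates
  age <- stats::rnorm(n, params$mu_age[key], params$sigma_age[key])
  dose <- rtruncnorm_left(n, params$mu_dose[key], params$sigma_dose[key], 0)
  scanner <- rep("HRRT", n)
  hc_ge <- stats::runif(n) < params$ge_fraction_hc
  allow_ge <- group == "HC" | isTRUE(params$mdd_on_ge)
  scanner[hc_ge & allow_ge] <- "GE"
  ge <- as.numeric(scanner == "GE")

  set.seed(stage_seed(seed, 2L)) # hormones
  testo <- rtruncnorm_left(n, params$mu_t[key], params$sigma_t[key], 0)
  e_true <- params$alpha_e + params$gamma3 * testo +
    stats::rnorm(n, 0, params$sigma_e)
  censored <- e_true <= params$loq
  estradiol <- ifelse(censored, params$loq, e_true)

  set.seed(stage_seed(seed, 3L)) # latent factor + measurement noise
  gamma1 <- ifelse(g == 1, params$gamma1_mdd, params$gamma1_hc)
  gamma2 <- ifelse(g == 1, params$gamma2_mdd, params$gamma2_hc)
  eta <- params$gamma_group * g + gamma1 * testo + gamma2 * e_true +
    stats::rnorm(n, 0, params$sigma_zeta)
  psi <- residual_cov(params$sigma_region, params$cov_hipp_amyg, params$regions)
  eps <- if (all(psi == 0)) {
    matrix(0, n, 4L)
  } else {
    MASS::mvrnorm(n, mu = rep(0, 4L), Sigma = psi)
  }
  y <- matrix(params$nu, n, 4L, byrow = TRUE) +
    outer(eta, params$lambda) +
    outer(age, params$beta_age) +
    outer(dose, params$beta_dose) +
    outer(ge, params$beta_scanner) +
    eps
  colnames(y) <- paste0("bp_", params$regions)

  cohort <- data.frame(
    id = seq_len(n), group = group, age = age, dose = dose, scanner = scanner,
    y,
    testosterone = testo, estradiol = estradiol,
    estradiol_censored = censored, estradiol_true = e_true,
    stringsAsFactors = FALSE
  )
  for (i in 1:17) cohort[[paste0("hamd_", i)]] <- NA_integer_
  class(cohort) <- c("cohort_table", "data.frame")
  if (hamd && n_mdd > 0) {
    cohort <- generate_hamd(params, cohort, seed = stage_seed(seed, 4L))
  }
  cohort
}

residual_cov <- function(sigma_region, cov_hipp_amyg, regions) {
  psi <- diag(sigma_region^2, nrow = length(regions))
  dimnames(psi) <- list(regions, regions)
  ih <- match("hippocampus", regions)
  ia <- match("amygdala", regions)
  if (!is.na(ih) && !is.na(ia)) {
    psi[ih, ia] <- psi[ia, ih] <- cov_hipp_amyg
  }
  psi
}

#' Fill HAMD-17 items for the depressed subjects
#'
#' Items are drawn by thresholding latent standard-normal scores. The
#' vegetative items (initial, middle and delayed insomnia 4-6,
#' gastrointestinal 12, weight loss 16) share a configurable loading
#' (`params$hamd_params$vegetative_loading`) on the subject's standardized
#' testosterone; the remaining items, including the six core-depression
#' (HAMD6) items, are independent of hormones. Thresholds are set so each
#' item's marginal distribution is binomial with success probability
#' `params$hamd_params$severity` over its standard range (0-4 or 0-2).
#'
#' @param params a [default_params()] object.
#' @param cohort a cohort table with MDD subjects.
#' @param seed integer seed.
#' @return The cohort with `hamd_1` ... `hamd_17` filled for MDD rows.
#' @export
generate_hamd <- function(params, cohort, seed = params$seed) {
  idx <- which(cohort$group == "MDD")
  if (!length(idx)) stop("cohort contains no MDD subjects")
  hp <- params$hamd_params
  item_max <- hp$item_max
  stopifnot(length(item_max) == 17L)
  loading <- rep(0, 17L)
  loading[c(4L, 5L, 6L, 12L, 16L)] <- hp$vegetative_loading
  stopifnot(all(abs(loading) < 1))

  set.seed(stage_seed(seed, 5L))
  t_std <- as.numeric(scale(cohort$testosterone[idx]))
  if (length(idx) < 2L || stats::sd(cohort$testosterone[idx]) == 0) {
    t_std <- rep(0, length(idx))
  }
  for (i in 1:17) {
    z <- loading[i] * t_std +
      sqrt(1 - loading[i]^2) * stats::rnorm(length(idx))
    probs <- stats::dbinom(0:item_max[i], item_max[i], hp$severity)
    cuts <- stats::qnorm(cumsum(probs)[-length(probs)])
    cohort[[paste0("hamd_", i)]][idx] <-
      as.integer(findInterval(z, cuts))
  }
  cohort
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "Synthetic PET cohort: %d subjects (%d MDD, %d HC), %d estradiol values censored\n",
    nrow(x), sum(x$group == "MDD"), sum(x$group == "HC"),
    sum(x$estradiol_censored)
  ))
  print.data.frame(utils::head(as.data.frame(x)[, 1:12]), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

cohort_columns <- function() {
  c(
    "id", "group", "age", "dose", "scanner",
    "bp_neostriatum", "bp_hippocampus", "bp_amygdala", "bp_prefrontal",
    "testosterone", "estradiol", "estradiol_censored"
  )
}

#' Validate a cohort table
#'
#' Checks the invariants every downstream stage relies on: finite binding
#' potentials, non-negative testosterone, censoring flag consistent with the
#' stored estradiol value, group and scanner labels in their domains, and
#' HAMD items within their standard ranges. All row-level problems are
#' collected and reported together.
#'
#' @param cohort a data frame with the documented columns.
#' @param loq censoring limit used for the flag/value consistency check.
#' @return the validated cohort, invisibly; errors on any violation.
#' @export
validate_cohort <- function(cohort, loq = 0.09) {
  problems <- character()
  need <- cohort_columns()
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bp <- as.matrix(cohort[, paste0("bp_", c("neostriatum", "hippocampus",
                                           "amygdala", "prefrontal"))])
  if (!is.numeric(bp)) problems <- c(problems, "non-numeric BP_ND columns")
  else if (any(!is.finite(bp))) {
    problems <- c(problems, sprintf("non-finite BP_ND in row(s) %s",
                                    paste(which(rowSums(!is.finite(bp)) > 0), collapse = ",")))
  }
  if (!all(cohort$group %in% c("MDD", "HC"))) {
    problems <- c(problems, "group labels outside {MDD, HC}")
  }
  if (!all(cohort$scanner %in% c("HRRT", "GE"))) {
    problems <- c(problems, "scanner labels outside {HRRT, GE}")
  }
  if (any(cohort$testosterone < 0, na.rm = TRUE)) {
    problems <- c(problems, "negative testosterone")
  }
  cens <- cohort$estradiol_censored
  if (!all(cens %in% c(TRUE, FALSE, 0L, 1L))) {
    problems <- c(problems, "estradiol_censored not boolean/0-1")
  } else if (any(as.logical(cens) & cohort$estradiol > loq + 1e-12)) {
    problems <- c(problems, "censored estradiol stored above the LOQ")
  }
  hamd_cols <- paste0("hamd_", 1:17)
  if (all(hamd_cols %in% names(cohort))) {
    im <- hamd_item_max()
    for (i in 1:17) {
      v <- cohort[[hamd_cols[i]]]
      bad <- !is.na(v) & (v < 0 | v > im[i])
      if (any(bad)) {
        problems <- c(problems, sprintf("hamd_%d outside 0-%d in row(s) %s",
                                        i, im[i], paste(which(bad), collapse = ",")))
      }
    }
  }
  if (length(problems)) {
    stop("invalid cohort table:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(cohort)
}
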