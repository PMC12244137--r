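#' Generator parameters for synthetic cohorts
#'
#' Builds the default parameter set used by [generate_cohort()]. The defaults
#' reproduce the statistical structure of a two-group (MDD vs healthy control)
#' PET cohort in which four regional 5-HT4 receptor binding potentials
#' (neostriatum, hippocampus, amygdala, prefrontal cortex) load on a single
#' global latent factor, the latent factor carries a group effect and
#' group-specific testosterone and estradiol effects, estradiol is linearly
#' coupled to testosterone and left-censored at the assay limit of
#' quantification (LOQ), and depressive-symptom items correlate with
#' testosterone through the vegetative items.
#'
#' Structural coefficients, hormone moments and the LOQ default to the values
#' the source study reports (group effect on the latent factor -0.07;
#' testosterone effect in controls -0.0074 and in MDD 0.0001; estradiol effect
#' 1.74 and 0.64; testosterone-to-estradiol slope 0.003; LOQ 0.09 nM;
#' per-group testosterone mean/SD 17.9/5.7 and 16.7/7.4 nM). Regional
#' intercepts, loadings and residual SDs are not reported there; the defaults
#' are free choices on the typical BP_ND scale of this tracer, ordered
#' high (neostriatum) > intermediate (hippocampus, amygdala) > low (prefrontal
#' cortex).
#'
#' @param ... named overrides for any default field.
#'
#' @return An object of class `"generator_params"`: a named list with fields
#'   `n_mdd`, `n_hc`, `regions`, `nu`, `lambda`, `beta_age`, `beta_dose`,
#'   `beta_scanner`, `sigma_region`, `cov_hipp_amyg`, `gamma_group`,
#'   `gamma1_hc`, `gamma1_mdd`, `gamma2_hc`, `gamma2_mdd`, `gamma3`,
#'   `alpha_e`, `sigma_e`, `mu_t`, `sigma_t` (per-group, named `hc`/`mdd`),
#'   `loq`, `sigma_zeta`, covariate distributions (`mu_age`, `sigma_age`,
#'   `mu_dose`, `sigma_dose`, `ge_fraction_hc`), `hamd_params` and `seed`.
#' @examples
#' p <- default_params()
#' p$gamma_group
#' p2 <- default_params(n_mdd = 100, n_hc = 100)
#' @export
default_params <- function(...) {
  regions <- c("neostriatum", "hippocampus", "amygdala", "prefrontal")
  p <- list(
    n_mdd = 25L,
    n_hc = 52L,
    regions = regions,
    ## measurement model (free choices, not printed in the study)
    nu = stats::setNames(c(3.60, 1.10, 1.00, 0.65), regions),
    lambda = stats::setNames(c(1.00, 0.45, 0.40, 0.30), regions),
    beta_age = stats::setNames(c(-0.010, -0.004, -0.004, -0.002), regions),
    beta_dose = stats::setNames(c(-5.0, -2.0, -2.0, -1.0), regions),
    beta_scanner = stats::setNames(c(0.10, 0.05, 0.05, 0.03), regions),
    sigma_region = stats::setNames(c(0.30, 0.15, 0.15, 0.10), regions),
    cov_hipp_amyg = 0.006,
    ## structural model (study-reported values)
    gamma_group = -0.07,
    gamma1_hc = -0.0074,
    gamma1_mdd = 0.0001,
    gamma2_hc = 1.74,
    gamma2_mdd = 0.64,
    gamma3 = 0.003,
    sigma_zeta = 0.35,
    ## hormone submodel: E = alpha_e + gamma3 * T + eps, censored at loq
    alpha_e = 0.050,
    sigma_e = 0.020,
    mu_t = c(hc = 17.9, mdd = 16.7),
    sigma_t = c(hc = 5.7, mdd = 7.4),
    loq = 0.09,
    ## covariates (Table-1 scale)
    mu_age = c(hc = 26.5, mdd = 27.2),
    sigma_age = c(hc = 5.9, mdd = 7.9),
    mu_dose = c(hc = 0.019, mdd = 0.012),
    sigma_dose = c(hc = 0.009, mdd = 0.007),
    ge_fraction_hc = 6 / 52,
    mdd_on_ge = FALSE,
    ## HAMD item generator: vegetative items load on standardized testosterone
    hamd_params = list(
      vegetative_loading = 0.4,
      item_max = hamd_item_max(),
      severity = 0.42
    ),
    seed = 20260920L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  class(p) <- "generator_params"
  validate_params(p)
  p
}

#' @keywords internal
hamd_item_max <- function() {
  ## 17-item Hamilton scale: items 4-6, 12-14, 16, 17 score 0-2, rest 0-4
  m <- rep(4L, 17L)
  m[c(4L, 5L, 6L, 12L, 13L, 14L, 16L, 17L)] <- 2L
  m
}

validate_params <- function(p) {
  stopifnot(
    p$n_mdd >= 0, p$n_hc >= 0,
    all(is.finite(p$lambda)), all(is.finite(p$nu)),
    all(p$sigma_region > 0) || all(p$sigma_region == 0),
    p$sigma_zeta >= 0, p$sigma_e >= 0,
    all(p$sigma_t > 0), p$loq > 0
  )
  if (any(p$sigma_region < 0)) stop("sigma_region must be non-negative")
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic cohort generator parameters\n")
  cat(sprintf("  n: %d MDD, %d HC; seed %d\n", x$n_mdd, x$n_hc, x$seed))
  cat(sprintf("  group effect on latent factor: %g\n", x$gamma_group))
  cat(sprintf("  testosterone -> latent: HC %g, MDD %g\n", x$gamma1_hc, x$gamma1_mdd))
  cat(sprintf("  estradiol -> latent:    HC %g, MDD %g\n", x$gamma2_hc, x$gamma2_mdd))
  cat(sprintf("  testosterone -> estradiol: %g; LOQ %g nM\n", x$gamma3, x$loq))
  invisible(x)
}

#' Read and write generator parameters as YAML
#'
#' `write_params()` serializes a [default_params()]-style list to a YAML file;
#' `read_params()` reads it back, restoring names and integer types so the
#' round trip is value-identical.
#'
#' @param params a `generator_params` object.
#' @param path file path.
#' @return `read_params()` returns a `generator_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "generator_params"))
  x <- unclass(params)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  p <- default_params()
  for (nm in names(x)) {
    v <- x[[nm]]
    tmpl <- p[[nm]]
    if (is.list(v) && !is.list(tmpl)) v <- unlist(v)
    if (!is.null(tmpl) && !is.list(tmpl) && !is.null(names(tmpl)) &&
        is.null(names(v)) && length(v) == length(tmpl)) {
      names(v) <- names(tmpl)
    }
    if (is.integer(tmpl) && is.numeric(v)) v <- as.integer(v)
    p[[nm]] <- v
  }
  if (is.list(p$hamd_params) && !is.null(p$hamd_params$item_max)) {
    p$hamd_params$item_max <- as.integer(unlist(p$hamd_params$item_max))
  }
  class(p) <- "generator_params"
  validate_params(p)
  p
}
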