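#' Build a latent-variable model specification
#'
#' Two models are supported. `"group_only"` regresses a global latent factor,
#' on which the four regional binding potentials load, on group (MDD vs HC):
#' \deqn{Y_r = \nu_r + \lambda_r \eta + \beta_r' x + \epsilon_r, \qquad
#'       \eta = \gamma_G G + \zeta.}
#' `"hormones"` adds group-specific testosterone and estradiol effects on the
#' latent factor plus a linear testosterone-to-estradiol submodel shared
#' across groups:
#' \deqn{\eta = \gamma_G G + (\gamma_1 + \Delta\gamma_1 G) T +
#'       (\gamma_2 + \Delta\gamma_2 G) E + \zeta, \qquad
#'       E = \alpha_E + \gamma_3 T + \epsilon_E.}
#' Covariates adjust the measurement equations only; group and hormones enter
#' the structural equation only. Estradiol values below the limit of
#' quantification are handled by integrating the likelihood below the LOQ
#' (see [log_likelihood()]).
#'
#' @param model `"group_only"` or `"hormones"`.
#' @param regions outcome names, first region's loading fixed to 1 under the
#'   default normalization.
#' @param covariates per-region adjustment variables.
#' @param extra_covariances list of length-2 character vectors naming region
#'   pairs with a free residual covariance (off by default; added by
#'   [refine_covariance()]).
#' @param censoring_mode how left-censored estradiol enters the likelihood:
#'   `"integrate_main_only"` integrates the censored value through the main
#'   estradiol effect with the interaction covariate plugged in at the LOQ
#'   (the simplification used when the full model has estimation problems);
#'   `"integrate_full"` integrates within each group (exact, since the model
#'   is linear-Gaussian per group); `"plugin"` treats censored values as
#'   observed at the LOQ; `"none"` expects no censored rows.
#' @param loq limit of quantification (nM).
#' @param normalization `"loading"` fixes the first loading at 1 with free
#'   latent disturbance SD; `"variance"` fixes the latent disturbance SD at 1
#'   with all loadings free.
#' @param sigma_param internal scale for SD parameters (`"log"` default).
#' @param include_group_main keep the group main effect in the hormones model.
#' @return An object of class `"lvm_spec"`.
#' @examples
#' build_lvm_spec("group_only")
#' build_lvm_spec("hormones",
#'   extra_covariances = list(c("hippocampus", "amygdala")))
#' @export
build_lvm_spec <- function(model = c("group_only", "hormones"),
                           regions = c("neostriatum", "hippocampus",
                                       "amygdala", "prefrontal"),
                           covariates = c("age", "dose", "scanner"),
                           extra_covariances = list(),
                           censoring_mode = c("integrate_main_only",
                                              "integrate_full", "plugin",
                                              "none"),
                           loq = 0.09,
                           normalization = c("loading", "variance"),
                           sigma_param = c("log", "sd"),
                           include_group_main = TRUE) {
  model <- match.arg(model)
  censoring_mode <- match.arg(censoring_mode)
  normalization <- match.arg(normalization)
  sigma_param <- match.arg(sigma_param)
  stopifnot(length(regions) >= 2L, !anyDuplicated(regions))
  if (model == "group_only") censoring_mode <- "none"
  extra_covariances <- lapply(extra_covariances, function(pr) {
    pr <- as.character(pr)
    stopifnot(length(pr) == 2L, all(pr %in% regions), pr[1] != pr[2])
    regions[sort(match(pr, regions))] # canonical order
  })
  if (anyDuplicated(vapply(extra_covariances, paste, "", collapse = ":"))) {
    stop("duplicate extra covariance pair")
  }
  spec <- structure(list(
    model = model, regions = regions, covariates = covariates,
    extra_covariances = extra_covariances,
    censoring = list(variable = "estradiol", loq = loq, mode = censoring_mode),
    normalization = normalization, sigma_param = sigma_param,
    include_group_main = include_group_main
  ), class = "lvm_spec")
  spec
}

#' @export
print.lvm_spec <- function(x, ...) {
  cat(sprintf("LVM spec '%s': %d regions (%s)\n", x$model,
              length(x$regions), paste(x$regions, collapse = ", ")))
  cat(sprintf("  covariates: %s\n", paste(x$covariates, collapse = ", ")))
  st <- if (x$model == "hormones") {
    "group, T, TxG, E, ExG (+ E ~ T submodel)"
  } else "group"
  cat(sprintf("  structural terms: %s\n", st))
  if (length(x$extra_covariances)) {
    cat(sprintf("  extra residual covariances: %s\n",
                paste(vapply(x$extra_covariances, paste, "", collapse = "~"),
                      collapse = ", ")))
  }
  cat(sprintf("  censoring: %s (LOQ %g)\n", x$censoring$mode, x$censoring$loq))
  cat(sprintf("  normalization: %s\n", x$normalization))
  invisible(x)
}

## ordered free-parameter names for a spec
param_names <- function(spec) {
  r <- spec$regions
  nm <- paste0("nu.", r)
  if (spec$normalization == "loading") {
    nm <- c(nm, paste0("lambda.", r[-1]))
  } else {
    nm <- c(nm, paste0("lambda.", r))
  }
  for (cv in spec$covariates) nm <- c(nm, paste0("beta.", r, ".", cv))
  sig <- if (spec$sigma_param == "log") "lsigma." else "sigma."
  nm <- c(nm, paste0(sig, r))
  for (pr in spec$extra_covariances) nm <- c(nm, paste0("cov.", pr[1], ".", pr[2]))
  if (spec$normalization == "loading") nm <- c(nm, paste0(sig, "zeta"))
  if (spec$model == "group_only" || spec$include_group_main) {
    nm <- c(nm, "gamma.group")
  }
  if (spec$model == "hormones") {
    nm <- c(nm, "gamma1", "dgamma1", "gamma2", "dgamma2",
            "alpha.e", "gamma3", paste0(sig, "e"))
  }
  nm
}

## positional index map from the free-parameter vector to model components;
## computed once per spec so repeated likelihood evaluations avoid name
## lookups
par_map <- function(spec) {
  nm <- param_names(spec)
  r <- spec$regions
  sig <- if (spec$sigma_param == "log") "lsigma." else "sigma."
  idx <- function(x) match(x, nm)
  m <- list(
    names = nm,
    nu = idx(paste0("nu.", r)),
    lambda = if (spec$normalization == "loading") {
      idx(paste0("lambda.", r[-1]))
    } else idx(paste0("lambda.", r)),
    beta = vapply(spec$covariates,
                  function(cv) idx(paste0("beta.", r, ".", cv)),
                  integer(length(r))),
    sigma = idx(paste0(sig, r)),
    covs = if (length(spec$extra_covariances)) {
      vapply(spec$extra_covariances,
             function(pr) idx(paste0("cov.", pr[1], ".", pr[2])), 1L)
    } else integer(0),
    cov_rows = vapply(spec$extra_covariances,
                      function(pr) match(pr[1], r), 1L),
    cov_cols = vapply(spec$extra_covariances,
                      function(pr) match(pr[2], r), 1L),
    zeta = if (spec$normalization == "loading") idx(paste0(sig, "zeta")) else NA_integer_,
    gamma_group = idx("gamma.group"),
    log_sigma = spec$sigma_param == "log"
  )
  if (spec$model == "hormones") {
    m$horm <- idx(c("gamma1", "dgamma1", "gamma2", "dgamma2",
                    "alpha.e", "gamma3", paste0(sig, "e")))
  }
  m
}

## map a free-parameter vector to natural-scale components
theta_to_pars <- function(theta, spec, pmap = par_map(spec)) {
  r <- spec$regions
  p <- length(r)
  theta <- unname(theta)
  tosd <- if (pmap$log_sigma) exp else abs
  lambda <- if (spec$normalization == "loading") {
    c(1, theta[pmap$lambda])
  } else theta[pmap$lambda]
  sigma_r <- tosd(theta[pmap$sigma])
  psi <- diag(sigma_r^2, p)
  if (length(pmap$covs)) {
    for (k in seq_along(pmap$covs)) {
      psi[pmap$cov_rows[k], pmap$cov_cols[k]] <-
        psi[pmap$cov_cols[k], pmap$cov_rows[k]] <- theta[pmap$covs[k]]
    }
  }
  B <- matrix(theta[pmap$beta], p, length(spec$covariates))
  s2z <- if (!is.na(pmap$zeta)) tosd(theta[pmap$zeta])^2 else 1
  gg <- if (!is.na(pmap$gamma_group)) theta[pmap$gamma_group] else 0
  pars <- list(
    nu = theta[pmap$nu], lambda = lambda, B = B, psi = psi,
    s2z = s2z, gamma_group = gg
  )
  if (spec$model == "hormones") {
    h <- theta[pmap$horm]
    pars$gamma1 <- h[1]; pars$dgamma1 <- h[2]
    pars$gamma2 <- h[3]; pars$dgamma2 <- h[4]
    pars$alpha_e <- h[5]; pars$gamma3 <- h[6]
    pars$s2e <- tosd(h[7])^2
  }
  pars
}
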