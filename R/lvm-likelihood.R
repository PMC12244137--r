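## Model-implied moments and the (censoring-aware) log-likelihood.
##
## Within each group the model is linear-Gaussian given testosterone, group
## and covariates, so the observable vector (4 regional outcomes, plus
## estradiol under the hormones model) is exactly multivariate normal and the
## likelihood of a left-censored estradiol value has a closed form:
## the marginal density of the outcomes times the conditional-Gaussian
## probability that estradiol lies at or below the LOQ.

## build the internal model frame used by all likelihood computations
lvm_frame <- function(spec, data) {
  need <- c(paste0("bp_", spec$regions), "group", spec$covariates)
  if (spec$model == "hormones") {
    need <- c(need, "testosterone", "estradiol")
    if (spec$censoring$mode != "none") need <- c(need, "estradiol_censored")
  }
  need <- setdiff(unique(need), "scanner")
  missing_cols <- setdiff(need, names(data))
  if ("scanner" %in% spec$covariates && !"scanner" %in% names(data)) {
    missing_cols <- c(missing_cols, "scanner")
  }
  if (length(missing_cols)) {
    stop("data is missing model column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(data)
  cols <- unique(c(need, if ("scanner" %in% spec$covariates) "scanner"))
  keep <- stats::complete.cases(df[, cols, drop = FALSE])
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("dropping %d row(s) with missing model variables", dropped))
    df <- df[keep, , drop = FALSE]
  }
  Y <- as.matrix(df[, paste0("bp_", spec$regions)])
  colnames(Y) <- spec$regions
  X <- matrix(0, nrow(df), length(spec$covariates),
              dimnames = list(NULL, spec$covariates))
  for (cv in spec$covariates) {
    X[, cv] <- if (cv == "scanner") as.numeric(df$scanner == "GE")
               else as.numeric(df[[cv]])
  }
  fr <- list(
    Y = Y, X = X, g = as.numeric(df$group == "MDD"),
    n = nrow(df), dropped = dropped
  )
  if (spec$model == "hormones") {
    fr$testo <- as.numeric(df$testosterone)
    fr$e <- as.numeric(df$estradiol)
    fr$cens <- if (spec$censoring$mode %in% c("none", "plugin") &&
                   !"estradiol_censored" %in% names(df)) {
      rep(FALSE, nrow(df))
    } else {
      as.logical(df$estradiol_censored)
    }
    if (spec$censoring$mode == "none" && any(fr$cens)) {
      warning("censored estradiol rows present but censoring mode is 'none'; ",
              "stored values treated as observed")
    }
    ## precomputed (group x censoring-status) blocks; censoring is resolved
    ## here so the per-evaluation likelihood only loops over blocks
    cens_eff <- if (spec$censoring$mode %in% c("none", "plugin")) {
      rep(FALSE, fr$n)
    } else fr$cens
    blocks <- list()
    for (gv in sort(unique(fr$g))) {
      for (cv in c(FALSE, TRUE)) {
        rows <- which(fr$g == gv & cens_eff == cv)
        if (length(rows)) {
          blocks[[length(blocks) + 1L]] <- list(
            g = gv, censored = cv, rows = rows,
            X = fr$X[rows, , drop = FALSE],
            Y = fr$Y[rows, , drop = FALSE],
            YE = cbind(fr$Y[rows, , drop = FALSE], fr$e[rows]),
            testo = fr$testo[rows]
          )
        }
      }
    }
    fr$blocks <- blocks
  }
  fr
}

## implied joint moments of the observables for a set of subjects in group g.
## Returns mean matrix (n x d) and covariance (d x d); d = 4 regions, plus
## estradiol appended when the hormones submodel is active.
## `gamma2_eff` / `eta_shift` implement the main-effect-only censoring
## simplification: the latent-estradiol pathway uses gamma2_eff and the latent
## mean picks up a fixed shift (interaction covariate plugged in at the LOQ).
block_moments <- function(pars, spec, g, X, testo = NULL,
                          gamma2_eff = NULL, eta_shift = 0, names = FALSE) {
  lam <- pars$lambda
  p <- length(lam)
  xb <- X %*% t(pars$B)
  if (spec$model == "group_only") {
    mu_eta <- pars$gamma_group * g
    mu <- outer(mu_eta + eta_shift, lam) + xb
    mu <- mu + rep(pars$nu, each = nrow(mu))
    Sigma <- tcrossprod(lam) * pars$s2z + pars$psi
    if (names) {
      colnames(mu) <- spec$regions
      dimnames(Sigma) <- list(spec$regions, spec$regions)
    }
    return(list(mean = mu, cov = Sigma))
  }
  g1 <- pars$gamma1 + pars$dgamma1 * g
  g2 <- pars$gamma2 + pars$dgamma2 * g
  if (is.null(gamma2_eff)) gamma2_eff <- g2
  mu_e <- pars$alpha_e + pars$gamma3 * testo
  mu_eta <- pars$gamma_group * g + g1 * testo + gamma2_eff * mu_e + eta_shift
  mu_y <- outer(mu_eta, lam) + xb
  mu_y <- mu_y + rep(pars$nu, each = nrow(mu_y))
  v_eta <- gamma2_eff^2 * pars$s2e + pars$s2z
  Sigma <- matrix(0, p + 1L, p + 1L)
  Sigma[1:p, 1:p] <- tcrossprod(lam) * v_eta + pars$psi
  Sigma_ye <- lam * gamma2_eff * pars$s2e
  Sigma[p + 1L, 1:p] <- Sigma[1:p, p + 1L] <- Sigma_ye
  Sigma[p + 1L, p + 1L] <- pars$s2e
  mu <- cbind(mu_y, mu_e)
  if (names) {
    nms <- c(spec$regions, "estradiol")
    colnames(mu) <- nms
    dimnames(Sigma) <- list(nms, nms)
  }
  list(mean = mu, cov = Sigma)
}

#' Model-implied moments of the observable vector
#'
#' Returns the mean and covariance of the observables implied by a parameter
#' vector, conditional on group, covariates and (for the hormones model)
#' testosterone. Within a group the model is linear-Gaussian, so the joint
#' distribution is exactly multivariate normal with these moments.
#'
#' @param theta named free-parameter vector (see [param_names] ordering via
#'   [fit_lvm()] output).
#' @param spec an [build_lvm_spec()] object.
#' @param covariate_row named list/vector with the covariate values (and
#'   `testosterone` for the hormones model).
#' @param group `"HC"`/`"MDD"` (or 0/1).
#' @return list with `mean` (named vector) and `cov` (matrix) over the four
#'   regions, plus estradiol for the hormones model.
#' @examples
#' spec <- build_lvm_spec("group_only", covariates = "age")
#' theta <- c(nu.neostriatum = 3.6, nu.hippocampus = 1.1, nu.amygdala = 1,
#'   nu.prefrontal = 0.65, lambda.hippocampus = 0.45, lambda.amygdala = 0.4,
#'   lambda.prefrontal = 0.3, beta.neostriatum.age = 0,
#'   beta.hippocampus.age = 0, beta.amygdala.age = 0, beta.prefrontal.age = 0,
#'   lsigma.neostriatum = log(0.25), lsigma.hippocampus = log(0.12),
#'   lsigma.amygdala = log(0.12), lsigma.prefrontal = log(0.08),
#'   lsigma.zeta = log(0.1), gamma.group = -0.07)
#' model_moments(theta, spec, covariate_row = list(age = 25), group = "MDD")
#' @export
model_moments <- function(theta, spec, covariate_row, group) {
  pars <- theta_to_pars(theta, spec)
  g <- if (is.character(group) || is.factor(group)) {
    as.numeric(as.character(group) == "MDD")
  } else as.numeric(group)
  x <- matrix(0, 1, length(spec$covariates),
              dimnames = list(NULL, spec$covariates))
  for (cv in spec$covariates) {
    v <- covariate_row[[cv]]
    x[, cv] <- if (cv == "scanner" && is.character(v)) as.numeric(v == "GE")
               else as.numeric(v)
  }
  testo <- if (spec$model == "hormones") {
    as.numeric(covariate_row[["testosterone"]])
  } else NULL
  mm <- block_moments(pars, spec, g, x, testo, names = TRUE)
  ev <- eigen(mm$cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("implied covariance matrix is not positive definite")
  }
  list(mean = stats::setNames(drop(mm$mean), colnames(mm$cov) %||% spec$regions),
       cov = mm$cov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## log-density of rows of Y ~ N(Mu, Sigma); returns sum, or -Inf when Sigma
## is not positive definite
mvn_loglik <- function(Y, Mu, Sigma) {
  R <- Y - Mu
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Sinv <- chol2inv(ch)
  -0.5 * nrow(R) * ncol(R) * log(2 * pi) - nrow(R) * sum(log(diag(ch))) -
    0.5 * sum((R %*% Sinv) * R)
}

## censored-row contribution: marginal density of Y times the conditional
## Gaussian probability that estradiol <= loq
censored_loglik <- function(Y, mm, loq, p) {
  idx <- seq_len(p)
  Sigma_ye <- mm$cov[idx, p + 1L]
  s_ee <- mm$cov[p + 1L, p + 1L]
  ch <- tryCatch(chol(mm$cov[idx, idx, drop = FALSE]),
                 error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Sinv <- chol2inv(ch)
  R <- Y - mm$mean[, idx, drop = FALSE]
  RS <- R %*% Sinv
  ll_y <- -0.5 * nrow(R) * p * log(2 * pi) - nrow(R) * sum(log(diag(ch))) -
    0.5 * sum(RS * R)
  a <- Sinv %*% Sigma_ye
  condvar <- s_ee - sum(Sigma_ye * a)
  if (condvar <= 0) return(-Inf)
  mu_cond <- mm$mean[, p + 1L] + as.numeric(R %*% a)
  ll_y + sum(stats::pnorm(loq, mu_cond, sqrt(condvar), log.p = TRUE))
}

ll_frame <- function(theta, spec, frame, pmap = par_map(spec)) {
  pars <- theta_to_pars(theta, spec, pmap)
  if (!all(is.finite(pars$nu)) || !all(is.finite(pars$lambda)) ||
      !is.finite(pars$s2z)) {
    return(-Inf)
  }
  p <- length(spec$regions)
  if (spec$model == "group_only") {
    mm <- block_moments(pars, spec, frame$g, frame$X)
    return(mvn_loglik(frame$Y, mm$mean, mm$cov))
  }
  mode <- spec$censoring$mode
  loq <- spec$censoring$loq
  ll <- 0
  for (blk in frame$blocks) {
    if (!blk$censored) {
      mm <- block_moments(pars, spec, blk$g, blk$X, blk$testo)
      ll <- ll + mvn_loglik(blk$YE, mm$mean, mm$cov)
    } else if (mode == "integrate_main_only") {
      ## latent pathway through the main estradiol effect only; the
      ## interaction covariate is plugged in at the LOQ
      mm <- block_moments(pars, spec, blk$g, blk$X, blk$testo,
                          gamma2_eff = pars$gamma2,
                          eta_shift = pars$dgamma2 * blk$g * loq)
      ll <- ll + censored_loglik(blk$Y, mm, loq, p)
    } else {
      mm <- block_moments(pars, spec, blk$g, blk$X, blk$testo)
      ll <- ll + censored_loglik(blk$Y, mm, loq, p)
    }
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

#' Log-likelihood of a cohort under an LVM specification
#'
#' Uncensored subjects contribute the joint Gaussian log-density of the
#' regional outcomes and estradiol given testosterone, group and covariates.
#' Subjects whose estradiol is left-censored at the LOQ contribute
#' \deqn{\log\left[\phi_Y(y)\,\Phi\!\left(\frac{LOQ - \mu_{E|Y}}
#'   {\sigma_{E|Y}}\right)\right],}
#' the closed form of integrating the joint likelihood over estradiol values
#' below the LOQ. Under `censoring_mode = "integrate_main_only"` the
#' integration runs through the main estradiol effect only, with the
#' interaction covariate plugged in at the LOQ; `"integrate_full"` integrates
#' within each group, which is exact because the model is linear-Gaussian per
#' group.
#'
#' @param theta named free-parameter vector.
#' @param spec an [build_lvm_spec()] object.
#' @param data a cohort table whose columns match the spec.
#' @return scalar log-likelihood (`-Inf` for a degenerate implied covariance).
#' @export
log_likelihood <- function(theta, spec, data) {
  ll_frame(theta, spec, lvm_frame(spec, data))
}
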