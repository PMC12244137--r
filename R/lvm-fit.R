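## Maximum-likelihood fitting of the latent-variable models.

## moment-based starting values: per-region least squares for intercepts and
## covariate slopes, triad ratios of the residual covariance for loadings,
## and a least-squares regression of the first region's residual (loading 1)
## on the structural predictors.
start_values <- function(spec, frame) {
  r <- spec$regions
  p <- length(r)
  nm <- param_names(spec)
  theta <- stats::setNames(numeric(length(nm)), nm)
  X1 <- cbind(1, frame$X)
  res <- matrix(0, frame$n, p)
  for (j in seq_len(p)) {
    fitj <- stats::lm.fit(X1, frame$Y[, j])
    cf <- fitj$coefficients
    cf[is.na(cf)] <- 0
    theta[paste0("nu.", r[j])] <- cf[1]
    for (cv in spec$covariates) {
      theta[paste0("beta.", r[j], ".", cv)] <- cf[match(cv, colnames(frame$X)) + 1L]
    }
    res[, j] <- fitj$residuals
  }
  S <- stats::cov(res)
  s_eta2 <- if (p >= 3L) S[1, 2] * S[1, 3] / S[2, 3] else S[1, 2]
  if (!is.finite(s_eta2) || s_eta2 <= 0 || s_eta2 > S[1, 1]) {
    s_eta2 <- 0.5 * S[1, 1]
  }
  lambda <- pmax(pmin(S[1, ] / s_eta2, 25), -25)
  lambda[1] <- 1
  sig2 <- pmax(diag(S) - lambda^2 * s_eta2, 0.2 * diag(S))
  tosig <- if (spec$sigma_param == "log") function(x) 0.5 * log(x) else sqrt
  sigpre <- if (spec$sigma_param == "log") "lsigma." else "sigma."
  if (spec$normalization == "loading") {
    theta[paste0("lambda.", r[-1])] <- lambda[-1]
    theta[paste0(sigpre, "zeta")] <- tosig(s_eta2)
  } else {
    theta[paste0("lambda.", r)] <- lambda * sqrt(s_eta2)
  }
  theta[paste0(sigpre, r)] <- tosig(sig2)
  for (pr in spec$extra_covariances) {
    i <- match(pr[1], r); j <- match(pr[2], r)
    theta[paste0("cov.", pr[1], ".", pr[2])] <- S[i, j] - lambda[i] * lambda[j] * s_eta2
  }
  ## structural starts from the first region's residual (loading fixed at 1)
  eta_hat <- res[, 1]
  sc <- if (spec$normalization == "loading") 1 else sqrt(s_eta2)
  if (spec$model == "group_only") {
    cf <- stats::coef(stats::lm(eta_hat ~ frame$g))
    theta["gamma.group"] <- ifelse(is.na(cf[2]), 0, cf[2]) / sc
  } else {
    e_star <- frame$e
    gg <- frame$g
    tt <- frame$testo
    dd <- data.frame(eta_hat, gg, tt, e_star)
    cf <- tryCatch(
      stats::coef(stats::lm(eta_hat ~ gg + tt + tt:gg + e_star + e_star:gg,
                            data = dd)),
      error = function(e) NULL
    )
    if (!is.null(cf) && !anyNA(cf)) {
      if ("gamma.group" %in% nm) theta["gamma.group"] <- cf["gg"] / sc
      theta["gamma1"] <- cf["tt"] / sc
      theta["dgamma1"] <- cf["gg:tt"] / sc
      theta["gamma2"] <- cf["e_star"] / sc
      theta["dgamma2"] <- cf["gg:e_star"] / sc
    }
    unc <- !frame$cens
    hf <- stats::lm(frame$e[unc] ~ frame$testo[unc])
    theta["alpha.e"] <- stats::coef(hf)[1]
    theta["gamma3"] <- ifelse(is.na(stats::coef(hf)[2]), 0, stats::coef(hf)[2])
    theta[paste0(sigpre, "e")] <- tosig(max(stats::var(stats::resid(hf)), 1e-6))
  }
  theta
}

## central-difference Hessian with per-coordinate steps scaled to the
## parameter magnitude (observed information at the optimum)
fd_hessian <- function(f, x, rel_step = 1e-3) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 0.01)
  H <- matrix(0, k, k)
  f0 <- f(x)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    fp[i] <- f(xp); fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
      xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
      ## cross term from the 4-point stencil using the stored axial values
      H[i, j] <- H[j, i] <-
        (f(xpp) + f(xmm) + 2 * f0 - fp[i] - fm[i] - fp[j] - fm[j]) /
        (2 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

#' Fit a latent-variable model by maximum likelihood
#'
#' Maximizes [log_likelihood()] by quasi-Newton (BFGS) from moment-based
#' starting values (per-region least squares, triad loading ratios, and a
#' least-squares pass over the structural predictors). Standard errors come
#' from the inverse observed information (numerical Hessian at the optimum);
#' Wald two-sided p-values and 95 percent confidence intervals are reported
#' for every free parameter. Estimates are only reported when the optimizer
#' converged.
#'
#' @param spec an [build_lvm_spec()] object.
#' @param data cohort table. Rows missing any model variable are dropped
#'   listwise with a message.
#' @param control list: `start` (named vector overriding the automatic
#'   starting values), `reltol` (default 1e-8), `maxit` (default 500),
#'   `hessian` (default TRUE; set FALSE to skip standard errors).
#' @return An object of class `"lvm_fit"` with elements `spec`, `estimates`
#'   (named free-parameter vector), `vcov`, `loglik`, `n_obs`, `dropped`,
#'   `converged`, `start`, and optimizer `counts`/`message`.
#' @examples
#' cohort <- generate_cohort(default_params(n_mdd = 60, n_hc = 60), seed = 7)
#' fit <- fit_lvm(build_lvm_spec("group_only"), cohort)
#' coef(fit)["gamma.group"]
#' @export
fit_lvm <- function(spec, data, control = list()) {
  ctrl <- utils::modifyList(
    list(start = NULL, reltol = 1e-8, maxit = 500L, hessian = TRUE), control
  )
  frame <- lvm_frame(spec, data)
  if (frame$n < length(param_names(spec))) {
    stop("fewer observations than free parameters")
  }
  if (any(apply(frame$Y, 2, stats::sd) == 0)) stop("degenerate outcome column")
  if (spec$model == "group_only" || spec$include_group_main) {
    if (length(unique(frame$g)) < 2L) {
      stop("both groups required for group terms")
    }
  }
  start <- ctrl$start %||% start_values(spec, frame)
  stopifnot(identical(names(start), param_names(spec)))
  pmap <- par_map(spec)
  negll <- function(th) {
    v <- ll_frame(th, spec, frame, pmap)
    if (!is.finite(v)) return(1e10)
    -v
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(reltol = ctrl$reltol, maxit = ctrl$maxit,
                                     parscale = pmax(abs(start), 1e-3)))
  ## polish: restart quasi-Newton from the solution until no further gain
  ## (BFGS line searches can halt early on strongly correlated parameters)
  for (round in 1:3) {
    if (opt$convergence != 0L) break
    opt2 <- stats::optim(opt$par, negll, method = "BFGS",
                         control = list(reltol = ctrl$reltol,
                                        maxit = ctrl$maxit,
                                        parscale = pmax(abs(opt$par), 1e-3)))
    gain <- opt$value - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    if (!is.finite(gain) || gain < 1e-7 * max(1, abs(opt$value))) break
  }
  converged <- opt$convergence == 0L && is.finite(opt$value) && opt$value < 1e9
  vc <- NULL
  se_ok <- FALSE
  if (converged && isTRUE(ctrl$hessian)) {
    H <- tryCatch(fd_hessian(negll, opt$par), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc) && all(is.finite(vc)) && all(diag(vc) > 0)) {
        se_ok <- TRUE
        dimnames(vc) <- list(names(start), names(start))
      } else vc <- NULL
    }
  }
  est <- opt$par
  names(est) <- names(start)
  structure(list(
    spec = spec, estimates = est, vcov = vc, se_available = se_ok,
    loglik = -opt$value, n_obs = frame$n, dropped = frame$dropped,
    converged = converged, counts = opt$counts, message = opt$message,
    start = start, frame = frame
  ), class = "lvm_fit")
}

#' @export
coef.lvm_fit <- function(object, ...) {
  if (!object$converged) stop("model did not converge; estimates withheld")
  object$estimates
}

#' @export
vcov.lvm_fit <- function(object, ...) object$vcov

#' @export
logLik.lvm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = object$n_obs, class = "logLik")
}

#' Parameter table for a fitted LVM
#'
#' Natural-scale estimates with Wald standard errors, 95 percent confidence
#' intervals and two-sided p-values. SD parameters fitted on the log scale
#' are back-transformed with delta-method standard errors.
#'
#' @param fit an `lvm_fit` object.
#' @return data.frame with columns `parameter`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "lvm_fit"))
  est <- coef(fit)
  se <- if (fit$se_available) sqrt(diag(fit$vcov)) else rep(NA_real_, length(est))
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    se = unname(se), stringsAsFactors = FALSE)
  is_ls <- startsWith(out$parameter, "lsigma.")
  if (any(is_ls)) {
    out$estimate[is_ls] <- exp(out$estimate[is_ls])
    out$se[is_ls] <- out$estimate[is_ls] * out$se[is_ls]
    out$parameter[is_ls] <- sub("^lsigma\\.", "sigma.", out$parameter[is_ls])
  }
  out$ci_low <- out$estimate - stats::qnorm(0.975) * out$se
  out$ci_high <- out$estimate + stats::qnorm(0.975) * out$se
  out$p <- 2 * stats::pnorm(-abs(out$estimate / out$se))
  out
}

#' @export
print.lvm_fit <- function(x, ...) {
  cat(sprintf("LVM fit ('%s'): n = %d, logLik = %.3f, %s\n", x$spec$model,
              x$n_obs, x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (x$converged) {
    keep <- grepl("^(gamma|dgamma|cov\\.)", names(x$estimates))
    print(round(x$estimates[keep], 5))
  }
  invisible(x)
}

#' @export
summary.lvm_fit <- function(object, ...) {
  tab <- parameter_table(object)
  structure(list(fit = object, table = tab), class = "summary.lvm_fit")
}

#' @export
print.summary.lvm_fit <- function(x, ...) {
  print(x$fit)
  tt <- x$table
  tt[, -1] <- lapply(tt[, -1], function(v) signif(v, 4))
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Standardized conditional residuals of a fitted LVM
#'
#' Residuals \eqn{Y - E[Y \mid \text{covariates, structural predictors,
#' group}]} standardized by the implied conditional SDs. For the hormones
#' model the observed estradiol is conditioned on directly (censored rows use
#' the LOQ value), so with all noise terms at zero the residuals vanish
#' exactly.
#'
#' @param object a converged `lvm_fit`.
#' @param newdata optional cohort table; defaults to the fitting data.
#' @param ... unused.
#' @return n x 4 matrix of standardized residuals (columns = regions).
#' @export
residuals.lvm_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("model did not converge")
  spec <- object$spec
  frame <- if (is.null(newdata)) object$frame else lvm_frame(spec, newdata)
  pars <- theta_to_pars(object$estimates, spec)
  lam <- pars$lambda
  xb <- frame$X %*% t(pars$B)
  if (spec$model == "group_only") {
    mu_eta <- pars$gamma_group * frame$g
  } else {
    g1 <- pars$gamma1 + pars$dgamma1 * frame$g
    g2 <- pars$gamma2 + pars$dgamma2 * frame$g
    mu_eta <- pars$gamma_group * frame$g + g1 * frame$testo + g2 * frame$e
  }
  mu <- matrix(pars$nu, frame$n, length(lam), byrow = TRUE) +
    outer(mu_eta, lam) + xb
  sds <- sqrt(diag(tcrossprod(lam) * pars$s2z + pars$psi))
  res <- sweep(frame$Y - mu, 2, sds, "/")
  colnames(res) <- spec$regions
  res
}
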