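regions4 <- c("neostriatum", "hippocampus", "amygdala", "prefrontal")

test_that("spec construction matches the two model layouts", {
  s1 <- build_lvm_spec("group_only")
  expect_identical(s1$model, "group_only")
  expect_length(s1$regions, 4L)
  expect_identical(s1$censoring$mode, "none")
  expect_true("gamma.group" %in% petlvm:::param_names(s1))
  expect_false("gamma1" %in% petlvm:::param_names(s1))

  s2 <- build_lvm_spec("hormones")
  nm <- petlvm:::param_names(s2)
  expect_true(all(c("gamma.group", "gamma1", "dgamma1", "gamma2", "dgamma2",
                    "alpha.e", "gamma3", "lsigma.e") %in% nm))
  s3 <- build_lvm_spec("hormones",
                       extra_covariances = list(c("hippocampus", "amygdala")))
  expect_length(s3$extra_covariances, 1L)
  expect_true("cov.hippocampus.amygdala" %in% petlvm:::param_names(s3))
  expect_error(build_lvm_spec("bogus"))
  expect_error(build_lvm_spec("group_only",
    extra_covariances = list(c("hippocampus", "hippocampus"))))
})

test_that("implied covariance reduces to the factor-model identity", {
  spec <- build_lvm_spec("group_only", covariates = "age")
  th <- make_theta(spec, c(
    lambda.hippocampus = 1, lambda.amygdala = 1, lambda.prefrontal = 1,
    lsigma.neostriatum = 0, lsigma.hippocampus = 0, lsigma.amygdala = 0,
    lsigma.prefrontal = 0, lsigma.zeta = 0
  ))
  mm <- model_moments(th, spec, covariate_row = list(age = 0), group = "HC")
  expect_equal(unname(mm$cov), matrix(1, 4, 4) + diag(4), tolerance = 1e-12)

  ## extra covariance enters the off-diagonal additively
  spec2 <- build_lvm_spec("group_only", covariates = "age",
                          extra_covariances = list(c("hippocampus",
                                                     "amygdala")))
  th2 <- make_theta(spec2, c(
    lambda.hippocampus = 0.5, lambda.amygdala = 0.4, lambda.prefrontal = 0.3,
    lsigma.neostriatum = log(0.3), lsigma.hippocampus = log(0.2),
    lsigma.amygdala = log(0.2), lsigma.prefrontal = log(0.1),
    lsigma.zeta = log(0.4), cov.hippocampus.amygdala = 0.011
  ))
  mm2 <- model_moments(th2, spec2, covariate_row = list(age = 0), group = "HC")
  expect_equal(mm2$cov["hippocampus", "amygdala"],
               0.5 * 0.4 * 0.4^2 + 0.011, tolerance = 1e-12)
})

test_that("implied moments match Monte-Carlo draws from the generative equations", {
  spec <- build_lvm_spec("hormones", covariates = c("age", "dose"))
  th <- make_theta(spec, c(
    nu.neostriatum = 3.5, nu.hippocampus = 1.2, nu.amygdala = 1.0,
    nu.prefrontal = 0.6, lambda.hippocampus = 0.5, lambda.amygdala = 0.45,
    lambda.prefrontal = 0.25,
    beta.neostriatum.age = -0.01, beta.hippocampus.age = -0.004,
    beta.amygdala.age = -0.004, beta.prefrontal.age = -0.002,
    beta.neostriatum.dose = -4, beta.hippocampus.dose = -2,
    beta.amygdala.dose = -1.5, beta.prefrontal.dose = -1,
    lsigma.neostriatum = log(0.3), lsigma.hippocampus = log(0.16),
    lsigma.amygdala = log(0.15), lsigma.prefrontal = log(0.1),
    lsigma.zeta = log(0.33), gamma.group = -0.07,
    gamma1 = -0.0074, dgamma1 = 0.0075, gamma2 = 1.74, dgamma2 = -1.1,
    alpha.e = 0.05, gamma3 = 0.003, lsigma.e = log(0.02)
  ))
  pars <- petlvm:::theta_to_pars(th, spec)
  g <- 1; testo <- 15; x <- c(age = 30, dose = 0.015)
  mm <- model_moments(th, spec,
                      covariate_row = list(age = 30, dose = 0.015,
                                           testosterone = testo),
                      group = "MDD")

  set.seed(9)
  n <- 1e6
  eps_e <- rnorm(n, 0, 0.02)
  zeta <- rnorm(n, 0, 0.33)
  E <- 0.05 + 0.003 * testo + eps_e
  eta <- -0.07 * g + (-0.0074 + 0.0075 * g) * testo +
    (1.74 - 1.1 * g) * E + zeta
  lam <- pars$lambda
  eps <- MASS::mvrnorm(n, rep(0, 4), pars$psi)
  Y <- matrix(pars$nu, n, 4, byrow = TRUE) + outer(eta, lam) +
    matrix(rep(as.numeric(pars$B %*% x), each = n), n, 4) + eps
  obs <- cbind(Y, E)
  emp_mean <- colMeans(obs)
  emp_cov <- cov(obs)
  for (j in 1:5) {
    expect_lt(abs(emp_mean[j] - mm$mean[j]), 3 * sd(obs[, j]) / sqrt(n))
  }
  for (j in 1:5) {
    for (k in j:5) {
      prod_jk <- (obs[, j] - mm$mean[j]) * (obs[, k] - mm$mean[k])
      expect_lt(abs(emp_cov[j, k] - mm$cov[j, k]),
                3 * sd(prod_jk) / sqrt(n))
    }
  }
})

test_that("censoring modes agree when nothing is censored", {
  p <- default_params(n_mdd = 60, n_hc = 60, alpha_e = 0.4) # far above LOQ
  co <- generate_cohort(p, seed = 3)
  expect_true(!any(co$estradiol_censored))
  th <- NULL
  lls <- sapply(c("integrate_full", "integrate_main_only", "plugin", "none"),
                function(mode) {
    spec <- build_lvm_spec("hormones", censoring_mode = mode)
    if (is.null(th)) th <<- petlvm:::start_values(spec, petlvm:::lvm_frame(spec, co))
    log_likelihood(th, spec, co)
  })
  expect_lt(max(lls) - min(lls), 1e-10)
})

test_that("the closed-form censored contribution equals adaptive quadrature", {
  spec <- build_lvm_spec("hormones", censoring_mode = "integrate_full",
                         covariates = "age", loq = 0.09)
  set.seed(14)
  for (rep in 1:10) {
    vals <- c(
      nu.neostriatum = runif(1, 3, 4), nu.hippocampus = runif(1, 1, 1.5),
      nu.amygdala = runif(1, 0.8, 1.2), nu.prefrontal = runif(1, 0.5, 0.8),
      lambda.hippocampus = runif(1, 0.3, 0.7),
      lambda.amygdala = runif(1, 0.3, 0.7),
      lambda.prefrontal = runif(1, 0.1, 0.5),
      beta.neostriatum.age = runif(1, -0.02, 0),
      beta.hippocampus.age = runif(1, -0.01, 0),
      beta.amygdala.age = runif(1, -0.01, 0),
      beta.prefrontal.age = runif(1, -0.01, 0),
      lsigma.neostriatum = log(runif(1, 0.2, 0.4)),
      lsigma.hippocampus = log(runif(1, 0.1, 0.25)),
      lsigma.amygdala = log(runif(1, 0.1, 0.25)),
      lsigma.prefrontal = log(runif(1, 0.05, 0.15)),
      lsigma.zeta = log(runif(1, 0.2, 0.5)),
      gamma.group = runif(1, -0.15, 0),
      gamma1 = runif(1, -0.02, 0.02), dgamma1 = runif(1, -0.02, 0.02),
      gamma2 = runif(1, -2, 2), dgamma2 = runif(1, -2, 2),
      alpha.e = runif(1, 0.04, 0.12), gamma3 = runif(1, 0, 0.006),
      lsigma.e = log(runif(1, 0.01, 0.05))
    )
    th <- make_theta(spec, vals)
    pars <- petlvm:::theta_to_pars(th, spec)
    g <- rbinom(1, 1, 0.5)
    testo <- runif(1, 5, 30)
    age <- runif(1, 20, 45)
    row <- data.frame(
      group = ifelse(g == 1, "MDD", "HC"), age = age,
      bp_neostriatum = rnorm(1, 3.5, 0.4),
      bp_hippocampus = rnorm(1, 1.2, 0.2),
      bp_amygdala = rnorm(1, 1, 0.2), bp_prefrontal = rnorm(1, 0.6, 0.1),
      testosterone = testo, estradiol = 0.09, estradiol_censored = TRUE
    )
    ll <- log_likelihood(th, spec, row)
    mm <- oracle_hormone_moments(pars, g, testo, c(age = age))
    y <- as.numeric(row[1, paste0("bp_", spec$regions)])
    ll_oracle <- oracle_censored_loglik_quadrature(y, mm, 0.09)
    expect_lt(abs(ll - ll_oracle), 1e-8)
  }
})

test_that("as the LOQ grows the censored term converges to the marginal density of Y", {
  spec_small <- build_lvm_spec("hormones", censoring_mode = "integrate_full",
                               covariates = "age", loq = 0.09)
  th <- make_theta(spec_small, c(
    nu.neostriatum = 3.6, nu.hippocampus = 1.1, nu.amygdala = 1,
    nu.prefrontal = 0.65, lambda.hippocampus = 0.45, lambda.amygdala = 0.4,
    lambda.prefrontal = 0.3, lsigma.neostriatum = log(0.3),
    lsigma.hippocampus = log(0.15), lsigma.amygdala = log(0.15),
    lsigma.prefrontal = log(0.1), lsigma.zeta = log(0.35),
    gamma.group = -0.07, gamma1 = -0.0074, dgamma1 = 0.0075, gamma2 = 1.74,
    dgamma2 = -1.1, alpha.e = 0.05, gamma3 = 0.003, lsigma.e = log(0.02)
  ))
  row <- data.frame(
    group = "HC", age = 25, bp_neostriatum = 3.4, bp_hippocampus = 1.2,
    bp_amygdala = 0.9, bp_prefrontal = 0.7, testosterone = 18,
    estradiol = 0.09, estradiol_censored = TRUE
  )
  spec_huge <- build_lvm_spec("hormones", censoring_mode = "integrate_full",
                              covariates = "age", loq = 10)
  ll_huge <- log_likelihood(th, spec_huge, row)
  pars <- petlvm:::theta_to_pars(th, spec_huge)
  mm <- oracle_hormone_moments(pars, 0, 18, c(age = 25))
  y <- as.numeric(row[1, paste0("bp_", spec_huge$regions)])
  ll_marg <- oracle_dmvnorm_log(y, mm$mean[1:4], mm$cov[1:4, 1:4])
  expect_equal(ll_huge, ll_marg, tolerance = 1e-10)
})

test_that("maximized likelihood matches an independent brute-force optimizer", {
  ## two-region toy, uncensored, independent objective written from scratch
  p <- group_only_params(n_mdd = 80, n_hc = 80)
  co <- generate_cohort(p, seed = 8)
  spec <- build_lvm_spec("group_only",
                         regions = c("neostriatum", "hippocampus"),
                         covariates = "age")
  ## two regions leave a flat ridge in the covariance parameters, so the
  ## optimum is compared at tight tolerance on the (well-defined) maximum
  fit <- fit_lvm(spec, co, control = list(hessian = FALSE, reltol = 1e-13,
                                          maxit = 5000))
  y <- as.matrix(co[, c("bp_neostriatum", "bp_hippocampus")])
  oracle_negll <- function(par) {
    nu <- par[1:2]; lam <- c(1, par[3]); beta <- par[4:5]
    sig <- par[6:7]; sz <- par[8]; gg <- par[9]
    if (any(sig <= 0) || sz <= 0) return(1e10)
    Sigma <- tcrossprod(lam) * sz^2 + diag(sig^2)
    g <- as.numeric(co$group == "MDD")
    ll <- 0
    for (i in seq_len(nrow(co))) {
      mu <- nu + lam * (gg * g[i]) + beta * co$age[i]
      ll <- ll + oracle_dmvnorm_log(y[i, ], mu, Sigma)
    }
    -ll
  }
  start <- c(3.6, 1.1, 0.5, 0, 0, 0.3, 0.15, 0.35, 0)
  o <- stats::nlminb(start, oracle_negll,
                     control = list(rel.tol = 1e-12, iter.max = 1000))
  expect_lt(abs(fit$loglik - (-o$objective)), 1e-6)
})

test_that("log-SD and SD parameterizations reach the same maximum", {
  p <- group_only_params(n_mdd = 150, n_hc = 150)
  co <- generate_cohort(p, seed = 15)
  f_log <- fit_lvm(build_lvm_spec("group_only", sigma_param = "log"), co,
                   control = list(hessian = FALSE))
  f_sd <- fit_lvm(build_lvm_spec("group_only", sigma_param = "sd"), co,
                  control = list(hessian = FALSE))
  expect_true(f_log$converged && f_sd$converged)
  expect_equal(f_log$loglik, f_sd$loglik, tolerance = 1e-7)
})

test_that("loading and variance normalizations imply the same fitted moments", {
  p <- group_only_params(n_mdd = 150, n_hc = 150)
  co <- generate_cohort(p, seed = 16)
  spec_l <- build_lvm_spec("group_only", normalization = "loading")
  fit_l <- fit_lvm(spec_l, co, control = list(hessian = FALSE))
  ## map the loading-normalized optimum into the variance normalization and
  ## polish from there: the two must describe identical distributions
  spec_v <- build_lvm_spec("group_only", normalization = "variance")
  th_l <- coef(fit_l)
  sz <- exp(th_l[["lsigma.zeta"]])
  start_v <- make_theta(spec_v, c(
    th_l[grep("^(nu|beta|lsigma\\.(neo|hip|amy|pre))", names(th_l))],
    setNames(c(1, th_l[paste0("lambda.", spec_l$regions[-1])]) * sz,
             paste0("lambda.", spec_l$regions)),
    gamma.group = th_l[["gamma.group"]] / sz
  ))
  fit_v <- fit_lvm(spec_v, co, control = list(start = start_v,
                                              hessian = FALSE))
  expect_equal(fit_l$loglik, fit_v$loglik, tolerance = 1e-7)
  row <- list(age = 30, dose = 0.015, scanner = "HRRT")
  mm_l <- model_moments(coef(fit_l), spec_l, row, "MDD")
  mm_v <- model_moments(coef(fit_v), spec_v, row, "MDD")
  expect_equal(mm_l$cov, mm_v$cov, tolerance = 1e-6)
  expect_equal(mm_l$mean, mm_v$mean, tolerance = 1e-6)
})

test_that("fitting recovers generating values and maximizes the likelihood", {
  fit <- fixture_hormone_fit()
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  truth <- c(gamma.group = -0.07, gamma1 = -0.0074, dgamma1 = 0.0075,
             gamma2 = 1.74, dgamma2 = -1.10, gamma3 = 0.003)
  for (k in names(truth)) {
    expect_lt(abs(coef(fit)[[k]] - truth[[k]]), 4 * se[[k]])
  }
  ## ML definition: fitted value beats the generating parameters
  th_true <- make_theta(fit$spec, c(
    nu.neostriatum = 3.6, nu.hippocampus = 1.1, nu.amygdala = 1,
    nu.prefrontal = 0.65, lambda.hippocampus = 0.45, lambda.amygdala = 0.4,
    lambda.prefrontal = 0.3,
    beta.neostriatum.age = -0.010, beta.hippocampus.age = -0.004,
    beta.amygdala.age = -0.004, beta.prefrontal.age = -0.002,
    beta.neostriatum.dose = -5, beta.hippocampus.dose = -2,
    beta.amygdala.dose = -2, beta.prefrontal.dose = -1,
    beta.neostriatum.scanner = 0.10, beta.hippocampus.scanner = 0.05,
    beta.amygdala.scanner = 0.05, beta.prefrontal.scanner = 0.03,
    lsigma.neostriatum = log(0.30), lsigma.hippocampus = log(0.15),
    lsigma.amygdala = log(0.15), lsigma.prefrontal = log(0.10),
    cov.hippocampus.amygdala = 0.006, lsigma.zeta = log(0.35),
    gamma.group = -0.07, gamma1 = -0.0074, dgamma1 = 0.0075,
    gamma2 = 1.74, dgamma2 = -1.10, alpha.e = 0.05, gamma3 = 0.003,
    lsigma.e = log(0.02)
  ))
  co <- generate_cohort(default_params(n_mdd = 400, n_hc = 400), seed = 42)
  expect_gte(fit$loglik, log_likelihood(th_true, fit$spec, co))
})

test_that("non-converged fits withhold estimates", {
  p <- group_only_params(n_mdd = 100, n_hc = 100)
  co <- generate_cohort(p, seed = 18)
  fit <- suppressWarnings(
    fit_lvm(build_lvm_spec("group_only"), co, control = list(maxit = 1L))
  )
  expect_false(fit$converged)
  expect_error(coef(fit), "did not converge")
})

test_that("residuals vanish on noise-free data and standardize correctly", {
  regions <- default_params()$regions
  p0 <- group_only_params(
    n_mdd = 50, n_hc = 50, sigma_zeta = 1e-8,
    sigma_region = setNames(rep(1e-8, 4), regions), cov_hipp_amyg = 0
  )
  co0 <- generate_cohort(p0, seed = 19)
  ## with (numerically) zero noise the conditional means reproduce the data:
  ## evaluate residuals at the generating parameters via a fixed "fit"
  spec <- build_lvm_spec("group_only")
  th <- make_theta(spec, c(
    nu.neostriatum = 3.6, nu.hippocampus = 1.1, nu.amygdala = 1,
    nu.prefrontal = 0.65, lambda.hippocampus = 0.45, lambda.amygdala = 0.4,
    lambda.prefrontal = 0.3,
    beta.neostriatum.age = -0.010, beta.hippocampus.age = -0.004,
    beta.amygdala.age = -0.004, beta.prefrontal.age = -0.002,
    beta.neostriatum.dose = -5, beta.hippocampus.dose = -2,
    beta.amygdala.dose = -2, beta.prefrontal.dose = -1,
    beta.neostriatum.scanner = 0.10, beta.hippocampus.scanner = 0.05,
    beta.amygdala.scanner = 0.05, beta.prefrontal.scanner = 0.03,
    lsigma.neostriatum = log(1), lsigma.hippocampus = log(1),
    lsigma.amygdala = log(1), lsigma.prefrontal = log(1),
    lsigma.zeta = log(1e-8), gamma.group = -0.07
  ))
  fake_fit <- structure(list(spec = spec, estimates = th, converged = TRUE,
                             frame = petlvm:::lvm_frame(spec, co0)),
                        class = "lvm_fit")
  res <- residuals(fake_fit)
  expect_lt(max(abs(res)), 1e-6)

  ## correctly specified model at n = 5000: unit variance, zero mean, normal
  p <- group_only_params(n_mdd = 2500, n_hc = 2500, cov_hipp_amyg = 0)
  co <- generate_cohort(p, seed = 20, hamd = FALSE)
  fit <- fit_lvm(build_lvm_spec("group_only"), co,
                 control = list(hessian = FALSE))
  res <- residuals(fit)
  n <- nrow(res)
  for (j in 1:4) {
    expect_lt(abs(mean(res[, j])), 3 / sqrt(n))
    expect_lt(abs(var(res[, j]) - 1), 3 * sd(res[, j]^2) / sqrt(n))
    expect_gt(ks.test(res[, j], "pnorm")$p.value, 0.01)
  }
})
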