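# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately written without using the package's own computational path:
# densities via base linear algebra, pairwise scores via nested loops,
# moments via explicit linear-system algebra.

## multivariate normal log-density (oracle)
oracle_dmvnorm_log <- function(x, mu, Sigma) {
  d <- length(mu)
  r <- as.numeric(x - mu)
  -0.5 * d * log(2 * pi) -
    0.5 * as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) -
    0.5 * sum(r * solve(Sigma, r))
}

## implied joint moments of (Y1..Y4, E) for the hormones model, derived
## independently as an explicit linear map of the error vector
## u = (zeta, eps_E, eps_1..eps_4):
##   E   = alpha_e + gamma3 T + eps_E
##   eta = gamma_g G + gamma1(G) T + gamma2(G) E + zeta
##   Y   = nu + lambda eta + B x + eps
oracle_hormone_moments <- function(pars, g, testo, x) {
  lam <- pars$lambda
  p <- length(lam)
  g1 <- pars$gamma1 + pars$dgamma1 * g
  g2 <- pars$gamma2 + pars$dgamma2 * g
  ## rows: (Y1..Yp, E); cols of A: (zeta, eps_E, eps_1..eps_p)
  A <- matrix(0, p + 1, p + 2)
  A[1:p, 1] <- lam                # zeta -> Y via eta
  A[1:p, 2] <- lam * g2           # eps_E -> E -> eta -> Y
  A[1:p, 2 + 1:p] <- diag(p)      # eps_r -> Y_r
  A[p + 1, 2] <- 1                # eps_E -> E
  D <- matrix(0, p + 2, p + 2)
  D[1, 1] <- pars$s2z
  D[2, 2] <- pars$s2e
  D[2 + 1:p, 2 + 1:p] <- pars$psi
  mu_e <- pars$alpha_e + pars$gamma3 * testo
  mu_eta <- pars$gamma_group * g + g1 * testo + g2 * mu_e
  mu <- c(pars$nu + lam * mu_eta + as.numeric(pars$B %*% x), mu_e)
  list(mean = mu, cov = A %*% D %*% t(A))
}

## adaptive-quadrature oracle for one left-censored subject: integrates the
## joint density of (Y, E) over E in (-Inf, loq]
oracle_censored_loglik_quadrature <- function(y, mm, loq, rel.tol = 1e-12) {
  p <- length(y)
  ## conditional distribution of E given Y locates the mass of the integrand
  ## below the LOQ; integrate over that window with a log offset so that far
  ## tails (tiny censoring probabilities) do not underflow
  Syy <- mm$cov[1:p, 1:p]
  sye <- mm$cov[1:p, p + 1]
  mu_c <- mm$mean[p + 1] + sum(sye * solve(Syy, y - mm$mean[1:p]))
  sd_c <- sqrt(mm$cov[p + 1, p + 1] - sum(sye * solve(Syy, sye)))
  logf <- function(e) oracle_dmvnorm_log(c(y, e), mm$mean, mm$cov)
  top <- min(mu_c, loq)
  m <- logf(top)
  f <- Vectorize(function(e) exp(logf(e) - m))
  lower <- top - 15 * sd_c
  v <- stats::integrate(f, lower, loq, rel.tol = rel.tol, abs.tol = 0)$value
  m + log(v)
}

## brute-force Gehan statistic by explicit nested loops (left censoring)
oracle_gehan_statistic <- function(values, censored, group) {
  lv <- levels(factor(group))
  ia <- which(group == lv[1])
  ib <- which(group == lv[2])
  s <- 0
  for (i in ia) {
    for (j in ib) {
      gt <- !censored[i] && values[i] > values[j]
      lt <- !censored[j] && values[j] > values[i]
      s <- s + as.numeric(gt) - as.numeric(lt)
    }
  }
  s
}

## left-truncated normal moments (oracle for generator hormone moments)
oracle_tnorm_mean <- function(mu, sd, lower = 0) {
  a <- (lower - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}
oracle_tnorm_var <- function(mu, sd, lower = 0) {
  a <- (lower - mu) / sd
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  sd^2 * (1 + a * lam - lam^2)
}

## named free-parameter vector for a spec, filled from a list of values
make_theta <- function(spec, values) {
  nm <- petlvm:::param_names(spec)
  th <- stats::setNames(numeric(length(nm)), nm)
  for (k in names(values)) {
    stopifnot(k %in% nm)
    th[k] <- values[k]
  }
  th
}

## generator parameters whose structural model matches the group-only LVM
## (hormone effects on the latent factor switched off)
group_only_params <- function(...) {
  default_params(gamma1_hc = 0, gamma1_mdd = 0, gamma2_hc = 0,
                 gamma2_mdd = 0, ...)
}

## stub fitted object carrying chosen coefficients (for effect arithmetic)
stub_hormone_fit <- function(coefs, vcov = NULL) {
  spec <- build_lvm_spec("hormones")
  nm <- petlvm:::param_names(spec)
  est <- stats::setNames(numeric(length(nm)), nm)
  est[names(coefs)] <- coefs
  if (!is.null(vcov)) dimnames(vcov) <- list(names(coefs), names(coefs))
  vc <- NULL
  if (!is.null(vcov)) {
    vc <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
    vc[rownames(vcov), colnames(vcov)] <- vcov
  }
  structure(list(spec = spec, estimates = est, vcov = vc,
                 se_available = !is.null(vc), converged = TRUE),
            class = "lvm_fit")
}

## shared expensive fixtures, computed once per test run
.fixtures <- new.env(parent = emptyenv())

fixture_hormone_fit <- function() {
  if (is.null(.fixtures$hfit)) {
    co <- generate_cohort(default_params(n_mdd = 400, n_hc = 400), seed = 42)
    spec <- build_lvm_spec("hormones", censoring_mode = "integrate_full",
                           extra_covariances = list(c("hippocampus",
                                                      "amygdala")))
    .fixtures$hfit <- fit_lvm(spec, co)
  }
  .fixtures$hfit
}
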