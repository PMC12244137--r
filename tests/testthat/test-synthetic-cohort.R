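test_that("generation is deterministic and internally consistent", {
  p <- default_params(n_mdd = 40, n_hc = 60)
  a <- generate_cohort(p, seed = 11)
  b <- generate_cohort(p, seed = 11)
  expect_identical(a, b)
  c2 <- generate_cohort(p, seed = 12)
  expect_false(identical(a, c2))

  expect_silent(validate_cohort(a, loq = p$loq))
  expect_true(all(a$testosterone >= 0))
  ## censoring flag and stored value consistent on every row
  expect_true(all(a$estradiol[a$estradiol_censored] == p$loq))
  expect_true(all(a$estradiol_true[a$estradiol_censored] <= p$loq))
  expect_true(all(a$estradiol_true[!a$estradiol_censored] > p$loq))
  ## GE scanner only among controls by default
  expect_true(all(a$scanner[a$group == "MDD"] == "HRRT"))
  ## HAMD only for MDD, within ranges
  expect_true(all(is.na(a$hamd_1[a$group == "HC"])))
  expect_true(all(!is.na(a$hamd_1[a$group == "MDD"])))
})

test_that("with all noise at zero the measurement equations hold exactly", {
  p <- default_params(
    n_mdd = 30, n_hc = 30,
    sigma_zeta = 0, sigma_region = setNames(rep(0, 4), default_params()$regions),
    cov_hipp_amyg = 0,
    beta_age = setNames(rep(0, 4), default_params()$regions),
    beta_dose = setNames(rep(0, 4), default_params()$regions),
    beta_scanner = setNames(rep(0, 4), default_params()$regions)
  )
  co <- generate_cohort(p, seed = 5)
  g <- as.numeric(co$group == "MDD")
  g1 <- ifelse(g == 1, p$gamma1_mdd, p$gamma1_hc)
  g2 <- ifelse(g == 1, p$gamma2_mdd, p$gamma2_hc)
  eta <- p$gamma_group * g + g1 * co$testosterone + g2 * co$estradiol_true
  for (r in seq_along(p$regions)) {
    expect_equal(co[[paste0("bp_", p$regions[r])]],
                 p$nu[r] + p$lambda[r] * eta,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("empirical censoring fraction matches the analytic normal probability", {
  p <- default_params(n_mdd = 2500, n_hc = 2500)
  co <- generate_cohort(p, seed = 21, hamd = FALSE)
  for (grp in c("hc", "mdd")) {
    rows <- co$group == toupper(grp)
    mu_e <- p$alpha_e + p$gamma3 * p$mu_t[grp]
    sd_e <- sqrt(p$sigma_e^2 + p$gamma3^2 * p$sigma_t[grp]^2)
    prob <- pnorm(p$loq, mu_e, sd_e)
    n <- sum(rows)
    band <- 2.576 * sqrt(prob * (1 - prob) / n)
    expect_lt(abs(mean(co$estradiol_censored[rows]) - prob), band + 0.005)
  }
})

test_that("empirical hormone and outcome moments match analytic moments", {
  n <- 1e5
  p <- default_params(n_mdd = 0, n_hc = n, ge_fraction_hc = 6 / 52)
  co <- generate_cohort(p, seed = 31, hamd = FALSE)
  ## testosterone: left-truncated normal at zero
  mt <- oracle_tnorm_mean(p$mu_t["hc"], p$sigma_t["hc"])
  vt <- oracle_tnorm_var(p$mu_t["hc"], p$sigma_t["hc"])
  expect_lt(abs(mean(co$testosterone) - mt), 3 * sd(co$testosterone) / sqrt(n))
  expect_lt(abs(var(co$testosterone) - vt),
            3 * sd((co$testosterone - mt)^2) / sqrt(n))
  ## uncensored estradiol: linear in T plus noise
  me <- p$alpha_e + p$gamma3 * mt
  ve <- p$gamma3^2 * vt + p$sigma_e^2
  expect_lt(abs(mean(co$estradiol_true) - me),
            3 * sd(co$estradiol_true) / sqrt(n))
  expect_lt(abs(var(co$estradiol_true) - ve),
            3 * sd((co$estradiol_true - me)^2) / sqrt(n))
  ## regional outcome means and variances (HC group, independent covariates)
  md <- oracle_tnorm_mean(p$mu_dose["hc"], p$sigma_dose["hc"])
  vd <- oracle_tnorm_var(p$mu_dose["hc"], p$sigma_dose["hc"])
  pge <- p$ge_fraction_hc
  slope_t <- p$gamma1_hc + p$gamma2_hc * p$gamma3 # T pathway incl. mediation
  v_eta <- slope_t^2 * vt + p$gamma2_hc^2 * p$sigma_e^2 + p$sigma_zeta^2
  mu_eta <- p$gamma1_hc * mt + p$gamma2_hc * me
  for (r in seq_along(p$regions)) {
    y <- co[[paste0("bp_", p$regions[r])]]
    m_y <- p$nu[r] + p$lambda[r] * mu_eta + p$beta_age[r] * p$mu_age["hc"] +
      p$beta_dose[r] * md + p$beta_scanner[r] * pge
    v_y <- p$lambda[r]^2 * v_eta + p$beta_age[r]^2 * p$sigma_age["hc"]^2 +
      p$beta_dose[r]^2 * vd + p$beta_scanner[r]^2 * pge * (1 - pge) +
      p$sigma_region[r]^2
    expect_lt(abs(mean(y) - m_y), 3 * sd(y) / sqrt(n))
    expect_lt(abs(var(y) - v_y), 3 * sd((y - m_y)^2) / sqrt(n))
  }
  ## binding ordering: high neostriatum, intermediate limbic, low prefrontal
  expect_gt(mean(co$bp_neostriatum), mean(co$bp_hippocampus))
  expect_gt(mean(co$bp_hippocampus), mean(co$bp_prefrontal))
  expect_true(all(co$bp_neostriatum > 0))
})

test_that("HAMD generator couples vegetative items to testosterone as configured", {
  ## zero loading: correlation in the null band
  p0 <- default_params(n_mdd = 2000, n_hc = 0,
                       hamd_params = list(vegetative_loading = 0,
                                          item_max = petlvm:::hamd_item_max(),
                                          severity = 0.42))
  co0 <- generate_cohort(p0, seed = 41)
  veg <- co0$hamd_4 + co0$hamd_5 + co0$hamd_6 + co0$hamd_12 + co0$hamd_16
  r0 <- cor(veg, co0$testosterone)
  expect_lt(abs(r0), 2.576 / sqrt(2000))
  ## positive loading: detected
  p5 <- default_params(n_mdd = 1000, n_hc = 0,
                       hamd_params = list(vegetative_loading = 0.5,
                                          item_max = petlvm:::hamd_item_max(),
                                          severity = 0.42))
  co5 <- generate_cohort(p5, seed = 43)
  veg5 <- co5$hamd_4 + co5$hamd_5 + co5$hamd_6 + co5$hamd_12 + co5$hamd_16
  ct <- cor.test(veg5, co5$testosterone, alternative = "greater")
  expect_lt(ct$p.value, 0.01)
  ## core items independent of testosterone either way
  core <- co5$hamd_1 + co5$hamd_2 + co5$hamd_7 + co5$hamd_8 + co5$hamd_10 +
    co5$hamd_13
  expect_lt(abs(cor(core, co5$testosterone)), 3 / sqrt(1000))
  ## marginal item frequencies follow the configured binomial distribution
  im <- petlvm:::hamd_item_max()
  for (i in c(1, 4, 16)) {
    v <- co0[[paste0("hamd_", i)]]
    probs <- dbinom(0:im[i], im[i], 0.42)
    for (kk in 0:im[i]) {
      band <- 2.576 * sqrt(probs[kk + 1] * (1 - probs[kk + 1]) / 2000)
      expect_lt(abs(mean(v == kk) - probs[kk + 1]), band + 0.01)
    }
  }
})

test_that("generator parameters round-trip through YAML", {
  p <- default_params(n_mdd = 7L, gamma_group = -0.123, seed = 99L)
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(q, p, tolerance = 1e-12)
  expect_identical(q$n_mdd, 7L)
  expect_identical(names(q$mu_t), names(p$mu_t))
})

test_that("malformed generator parameters are rejected", {
  expect_error(default_params(bogus_field = 1), "unknown generator parameter")
  p <- default_params()
  p$sigma_t <- c(hc = -1, mdd = 2)
  expect_error(petlvm:::validate_params(p))
})
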