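## Residual-covariance misspecification diagnostics: Rao score tests over the
## region pairs without a free covariance, and the stepwise Holm-Bonferroni
## refinement that adds covariance parameters until none is significant.

## expected (Fisher) information of the free-parameter vector, assembled from
## numerical derivatives of the model-implied moments. For Gaussian blocks
## the per-subject information is exact:
##   I_jk = sum_i dmu_i' Sigma^-1 dmu_k,i + (n/2) tr(Sigma^-1 dSigma_j
##          Sigma^-1 dSigma_k);
## rows with a censored estradiol value contribute the outer product of their
## per-subject numerical score vectors (a consistent, PSD estimate of their
## expected information). Unlike the observed Hessian, the result is positive
## semi-definite at any evaluation point, which keeps Rao score statistics
## non-negative even under strong misspecification.
expected_information <- function(theta, spec, frame, pmap = par_map(spec)) {
  k <- length(theta)
  h <- 1e-5 * pmax(abs(theta), 0.01)
  blocks <- if (spec$model == "group_only") {
    list(list(g = frame$g, X = frame$X, testo = NULL, censored = FALSE,
              rows = seq_len(frame$n)))
  } else frame$blocks
  mode <- spec$censoring$mode
  loq <- spec$censoring$loq
  blk_mm <- function(th, blk) {
    pars <- theta_to_pars(th, spec, pmap)
    if (isTRUE(blk$censored) && mode == "integrate_main_only") {
      block_moments(pars, spec, blk$g, blk$X, blk$testo,
                    gamma2_eff = pars$gamma2,
                    eta_shift = pars$dgamma2 * blk$g * loq)
    } else {
      block_moments(pars, spec, blk$g, blk$X, blk$testo)
    }
  }
  info <- matrix(0, k, k)
  for (blk in blocks) {
    if (isTRUE(blk$censored)) {
      ## per-subject numerical scores -> outer-product information
      n_b <- nrow(blk$Y)
      G <- matrix(0, n_b, k)
      lli <- function(th) {
        mm <- blk_mm(th, blk)
        per_subject_censored_loglik(blk$Y, mm, loq, length(spec$regions))
      }
      for (j in seq_len(k)) {
        tp <- theta; tp[j] <- theta[j] + h[j]
        tm <- theta; tm[j] <- theta[j] - h[j]
        G[, j] <- (lli(tp) - lli(tm)) / (2 * h[j])
      }
      info <- info + crossprod(G)
    } else {
      mm0 <- blk_mm(theta, blk)
      d <- ncol(mm0$cov)
      n_b <- nrow(mm0$mean)
      Sinv <- solve(mm0$cov)
      ch <- chol(Sinv)
      Zs <- vector("list", k)
      Ws <- vector("list", k)
      for (j in seq_len(k)) {
        tp <- theta; tp[j] <- theta[j] + h[j]
        tm <- theta; tm[j] <- theta[j] - h[j]
        mp <- blk_mm(tp, blk); mmn <- blk_mm(tm, blk)
        dMu <- (mp$mean - mmn$mean) / (2 * h[j])
        dSg <- (mp$cov - mmn$cov) / (2 * h[j])
        Zs[[j]] <- dMu %*% t(ch)
        Ws[[j]] <- Sinv %*% dSg
      }
      for (j in seq_len(k)) {
        for (l in j:k) {
          v <- sum(Zs[[j]] * Zs[[l]]) +
            0.5 * n_b * sum(Ws[[j]] * t(Ws[[l]]))
          info[j, l] <- info[j, l] + v
          if (l > j) info[l, j] <- info[j, l]
        }
      }
    }
  }
  info
}

## vector of per-subject censored-row log-likelihood contributions
per_subject_censored_loglik <- function(Y, mm, loq, p) {
  idx <- seq_len(p)
  ch <- chol(mm$cov[idx, idx, drop = FALSE])
  R <- Y - mm$mean[, idx, drop = FALSE]
  Z <- R %*% backsolve(ch, diag(p))
  ll_y <- -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * rowSums(Z * Z)
  Sigma_ye <- mm$cov[idx, p + 1L]
  a <- backsolve(ch, backsolve(ch, Sigma_ye, transpose = TRUE))
  condvar <- mm$cov[p + 1L, p + 1L] - sum(Sigma_ye * a)
  mu_cond <- mm$mean[, p + 1L] + as.numeric(R %*% a)
  ll_y + stats::pnorm(loq, mu_cond, sqrt(condvar), log.p = TRUE)
}

candidate_pairs <- function(spec) {
  r <- spec$regions
  free <- vapply(spec$extra_covariances, paste, "", collapse = ":")
  out <- list()
  for (i in seq_along(r)) {
    for (j in seq_along(r)) {
      if (j <= i) next
      if (paste(r[i], r[j], sep = ":") %in% free) next
      out[[length(out) + 1L]] <- c(r[i], r[j])
    }
  }
  out
}

#' Score tests for omitted residual covariances
#'
#' For every region pair without a free residual covariance, evaluates the
#' Rao score statistic of the extended model (candidate covariance fixed at
#' zero) at the restricted maximum-likelihood estimate. The gradient and
#' observed information are computed numerically on the extended parameter
#' vector; the statistic is referred to a chi-square distribution with one
#' degree of freedom. Holm-adjusted p-values are computed over the candidate
#' family.
#'
#' @param fit a converged `lvm_fit`.
#' @param data optional cohort table (defaults to the fitting data).
#' @return data.frame of class `"score_test_table"`, sorted by raw p, with
#'   columns `region1`, `region2`, `statistic`, `df`, `p`, `p_holm`,
#'   `testable`.
#' @examples
#' cohort <- generate_cohort(default_params(n_mdd = 80, n_hc = 80), seed = 3)
#' fit <- fit_lvm(build_lvm_spec("group_only"), cohort)
#' score_tests(fit)
#' @export
score_tests <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "lvm_fit"))
  if (!fit$converged) stop("score tests require a converged fit")
  spec <- fit$spec
  frame <- if (is.null(data)) fit$frame else lvm_frame(spec, data)
  cand <- candidate_pairs(spec)
  if (!length(cand)) {
    return(empty_score_table())
  }
  ## one joint extension: all candidates appended at zero; each candidate's
  ## score test uses the (theta, candidate) sub-blocks of the shared gradient
  ## and observed information
  ext <- spec
  ext$extra_covariances <- c(spec$extra_covariances, cand)
  base_names <- param_names(spec)
  ext_names <- param_names(ext)
  theta_ext <- stats::setNames(numeric(length(ext_names)), ext_names)
  theta_ext[base_names] <- fit$estimates[base_names]
  pmap_ext <- par_map(ext)
  negll <- function(th) {
    v <- ll_frame(th, spec = ext, frame = frame, pmap = pmap_ext)
    if (!is.finite(v)) return(1e10)
    -v
  }
  gr <- pracma::grad(negll, theta_ext)
  I_exp <- expected_information(theta_ext, ext, frame, pmap_ext)
  base_idx <- match(base_names, ext_names)
  rows <- lapply(cand, function(pr) {
    ci <- match(paste0("cov.", pr[1], ".", pr[2]), ext_names)
    idx <- c(base_idx, ci)
    U <- -gr[idx]
    stat <- tryCatch({
      s <- drop(t(U) %*% solve(I_exp[idx, idx], U))
      if (!is.finite(s) || s < 0) NA_real_ else s
    }, error = function(e) NA_real_)
    data.frame(region1 = pr[1], region2 = pr[2], statistic = stat, df = 1L,
               p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
               testable = is.finite(stat), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_holm <- NA_real_
  ok <- tab$testable
  tab$p_holm[ok] <- stats::p.adjust(tab$p[ok], method = "holm")
  tab <- tab[order(tab$p), c("region1", "region2", "statistic", "df",
                             "p", "p_holm", "testable")]
  rownames(tab) <- NULL
  class(tab) <- c("score_test_table", "data.frame")
  tab
}

empty_score_table <- function() {
  structure(
    data.frame(region1 = character(), region2 = character(),
               statistic = numeric(), df = integer(), p = numeric(),
               p_holm = numeric(), testable = logical()),
    class = c("score_test_table", "data.frame")
  )
}

#' Stepwise covariance refinement with Holm-Bonferroni control
#'
#' Fits the model, runs [score_tests()], Holm-adjusts over the current
#' candidate family, and adds the smallest-p candidate covariance when its
#' adjusted p-value falls below `alpha`; the loop repeats on the extended
#' model until no candidate reaches significance. Adjustment is per round
#' (the family shrinks as parameters are added); ties in the smallest raw p
#' are broken by region-pair lexicographic order, which [score_tests()]
#' already imposes via its stable sort.
#'
#' @param spec starting [build_lvm_spec()] object.
#' @param data cohort table.
#' @param alpha familywise significance level (default 0.05).
#' @param control passed to [fit_lvm()].
#' @return list with `fit` (final `lvm_fit`), `spec` (final spec) and `log`
#'   (data.frame of added pairs with their statistics and p-values, in order).
#' @export
refine_covariance <- function(spec, data, alpha = 0.05, control = list()) {
  stopifnot(alpha >= 0, alpha <= 1)
  frame_data <- data
  log_rows <- list()
  repeat {
    fit <- fit_lvm(spec, frame_data, control = control)
    if (!fit$converged) {
      stop("refinement aborted: model fit did not converge after adding ",
           length(log_rows), " parameter(s)")
    }
    if (alpha == 0) break
    tab <- score_tests(fit)
    tab <- tab[tab$testable, , drop = FALSE]
    if (!nrow(tab) || is.na(tab$p_holm[1]) || tab$p_holm[1] >= alpha) break
    add <- c(tab$region1[1], tab$region2[1])
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = length(log_rows) + 1L, region1 = add[1], region2 = add[2],
      statistic = tab$statistic[1], p = tab$p[1], p_holm = tab$p_holm[1],
      stringsAsFactors = FALSE
    )
    spec$extra_covariances <- c(spec$extra_covariances, list(add))
    if (!length(candidate_pairs(spec))) {
      fit <- fit_lvm(spec, frame_data, control = control)
      break
    }
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), region1 = character(), region2 = character(),
               statistic = numeric(), p = numeric(), p_holm = numeric())
  list(fit = fit, spec = spec, log = log_df)
}

#' Normal QQ coordinates for residual matrices
#'
#' Standard-normal theoretical quantiles at rankit positions
#' \eqn{(i - 0.5)/n} against the sorted residuals, per region, for QQ-plot
#' checks of residual normality.
#'
#' @param res numeric matrix (columns = regions) or vector of residuals.
#' @return data.frame with columns `region`, `theoretical`, `empirical`.
#' @export
qq_points <- function(res) {
  if (is.null(dim(res))) res <- matrix(res, ncol = 1,
                                       dimnames = list(NULL, "residual"))
  stopifnot(nrow(res) >= 3L)
  out <- lapply(colnames(res) %||% paste0("V", seq_len(ncol(res))), function(cn) {
    v <- res[, cn]
    v <- v[is.finite(v)]
    n <- length(v)
    if (stats::sd(v) == 0) {
      warning(sprintf("degenerate spread in '%s': constant residuals", cn))
    }
    data.frame(region = cn,
               theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
               empirical = sort(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
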