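## Symptom-hormone-receptor network: covariate residualization, HAMD
## subscales, EBIC-selected graphical lasso, and node centrality.

#' Residualize variables on covariates
#'
#' Replaces each named variable by the residuals of an ordinary least-squares
#' fit on its covariates (plus intercept); unnamed variables pass through
#' untouched. Binary variables are residualized the same way
#' (linear-probability residuals), which keeps the downstream correlation
#' matrix well defined.
#'
#' @param table data.frame.
#' @param adjustments named list: `variable = c("covariate", ...)`.
#' @return the table with the named columns replaced by residuals.
#' @examples
#' d <- data.frame(y = rnorm(20), age = rnorm(20))
#' r <- residualize(d, list(y = "age"))
#' cor(r$y, d$age) # ~ 0
#' @export
residualize <- function(table, adjustments) {
  stopifnot(is.list(adjustments), !is.null(names(adjustments)))
  for (v in names(adjustments)) {
    covs <- adjustments[[v]]
    miss <- setdiff(c(v, covs), names(table))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    X <- cbind(1, as.matrix(table[, covs, drop = FALSE]))
    if (qr(X)$rank < ncol(X)) {
      warning(sprintf("collinear covariates when adjusting '%s'", v))
    }
    fit <- stats::lm.fit(X, as.numeric(table[[v]]))
    table[[v]] <- fit$residuals
  }
  table
}

#' HAMD-17 subscale scores
#'
#' Computes the Bech HAMD6 core-depression subscale (sum of items 1, 2, 7, 8,
#' 10, 13) and returns the five vegetative items individually: initial
#' insomnia (item 4), middle insomnia (5), delayed insomnia (6),
#' gastrointestinal somatic symptoms (12) and weight loss (16).
#'
#' @param hamd_items a length-17 vector, a 17-column matrix, or a data.frame
#'   with columns `hamd_1` ... `hamd_17`.
#' @return data.frame with columns `hamd6`, `initial_insomnia`,
#'   `middle_insomnia`, `delayed_insomnia`, `gastrointestinal`, `weight_loss`.
#' @examples
#' hamd_subscales(c(2, 2, 0, 0, 0, 0, 2, 2, 0, 2, 0, 0, 2, 0, 0, 0, 0))
#' @export
hamd_subscales <- function(hamd_items) {
  if (is.data.frame(hamd_items)) {
    cols <- paste0("hamd_", 1:17)
    stopifnot(all(cols %in% names(hamd_items)))
    m <- as.matrix(hamd_items[, cols])
  } else if (is.null(dim(hamd_items))) {
    stopifnot(length(hamd_items) == 17L)
    m <- matrix(hamd_items, nrow = 1)
  } else {
    stopifnot(ncol(hamd_items) == 17L)
    m <- as.matrix(hamd_items)
  }
  im <- hamd_item_max()
  for (i in 1:17) {
    bad <- !is.na(m[, i]) & (m[, i] < 0 | m[, i] > im[i])
    if (any(bad)) stop(sprintf("item %d outside its 0-%d range", i, im[i]))
  }
  data.frame(
    hamd6 = rowSums(m[, c(1, 2, 7, 8, 10, 13), drop = FALSE]),
    initial_insomnia = m[, 4], middle_insomnia = m[, 5],
    delayed_insomnia = m[, 6], gastrointestinal = m[, 12],
    weight_loss = m[, 16]
  )
}

## graphical lasso via block coordinate descent (Friedman-style): maximizes
## log det(Theta) - tr(S Theta) - rho * sum_{i != j} |theta_ij|
## (off-diagonal penalty). Returns the precision matrix Theta and covariance
## estimate W = Theta^{-1}.
glasso_fit <- function(S, rho, tol = 1e-7, maxit = 500L, W_init = NULL,
                       zero = NULL) {
  p <- ncol(S)
  stopifnot(rho >= 0, isSymmetric(unname(S)))
  if (rho == 0 && is.null(zero)) {
    Theta <- solve(S)
    return(list(Theta = (Theta + t(Theta)) / 2, W = S, iters = 0L))
  }
  W <- if (is.null(W_init)) S else W_init
  diag(W) <- diag(S) # diagonal unpenalized
  Beta <- matrix(0, p - 1L, p)
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- Beta[, j]
      ## lasso coordinate descent on 0.5 b'W11 b - s12'b + rho |b|_1;
      ## with a fixed zero pattern ('zero') the excluded coordinates are
      ## pinned at 0 and the rest are unpenalized (support-restricted MLE)
      zj <- if (is.null(zero)) NULL else zero[idx, j]
      for (inner in 1:200) {
        b_old <- beta
        for (k in seq_len(p - 1L)) {
          if (!is.null(zj) && zj[k]) { beta[k] <- 0; next }
          r_k <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          beta[k] <- sign(r_k) * max(abs(r_k) - rho, 0) / W11[k, k]
        }
        if (max(abs(beta - b_old)) < tol) break
      }
      Beta[, j] <- beta
      W[idx, j] <- W[j, idx] <- W11 %*% beta
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(S - diag(diag(S)) )) ||
        max(abs(W - W_old)) < tol) break
  }
  ## recover Theta from W and the regression coefficients
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    t22 <- 1 / (W[j, j] - sum(W[idx, j] * Beta[, j]))
    Theta[j, j] <- t22
    Theta[idx, j] <- -Beta[, j] * t22
  }
  Theta <- (Theta + t(Theta)) / 2
  ## exact zeros from the lasso solution
  Zero <- matrix(FALSE, p, p)
  for (j in seq_len(p)) Zero[setdiff(seq_len(p), j), j] <- Beta[, j] == 0
  Theta[Zero & t(Zero)] <- 0
  dimnames(Theta) <- dimnames(W) <- dimnames(S)
  list(Theta = Theta, W = W, iters = it)
}

nearest_pd_correlation <- function(S, eps = 1e-4) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% diag(vals) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(R)))
  R <- D %*% R %*% D
  dimnames(R) <- dimnames(S)
  (R + t(R)) / 2
}

#' EBIC-selected graphical-lasso network
#'
#' Estimates a sparse Gaussian graphical model over the columns of `data`:
#' the precision matrix is fitted by L1-penalized Gaussian likelihood on a
#' logarithmic penalty grid and the penalty minimizing the extended Bayesian
#' information criterion
#' \deqn{EBIC = -2\,\ell + k \log n + 4 k \gamma \log p}
#' is selected, where \eqn{k} counts nonzero upper-triangle precision entries
#' and \eqn{\gamma} is the `tuning` hyperparameter (0.5 by default). Edges
#' are reported as partial correlations
#' \eqn{-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}}.
#'
#' @param data numeric data.frame or matrix (columns = nodes).
#' @param tuning EBIC gamma (0 = plain BIC; 0.5 is the common conservative
#'   default for psychometric networks).
#' @param n_lambda grid size (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   absolute off-diagonal correlation (default 0.01).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param small_sample_ack set `TRUE` to acknowledge and allow estimation
#'   with fewer than 3 observations per node, where the network is unstable.
#' @return object of class `"network_result"`: `nodes`, `adjacency` (partial
#'   correlations, zero diagonal), `precision`, `lambda`, `lambda_grid`,
#'   `ebic` (per grid point), `ebic_min`, `n`, `tuning`, `repaired`
#'   (whether the input correlation needed a positive-definite repair).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(500 * 4), ncol = 4)
#' net <- ebic_glasso(x)
#' net$adjacency
#' @export
ebic_glasso <- function(data, tuning = 0.5, n_lambda = 100L,
                        lambda_min_ratio = 0.01,
                        cor_method = c("pearson", "spearman"),
                        small_sample_ack = FALSE) {
  cor_method <- match.arg(cor_method)
  x <- as.matrix(data)
  stopifnot(is.numeric(x), ncol(x) >= 3L, nrow(x) > 3L)
  n <- nrow(x)
  p <- ncol(x)
  nodes <- colnames(x) %||% paste0("V", seq_len(p))
  if (n < 3 * p && !isTRUE(small_sample_ack)) {
    stop(sprintf(
      "n = %d is below 3 observations per node (p = %d); the regularized
network is unstable at this size. Pass small_sample_ack = TRUE to proceed.",
      n, p))
  }
  S <- stats::cor(x, method = cor_method)
  repaired <- FALSE
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    warning("input correlation matrix is not positive definite; ",
            "applying nearest-PD repair")
    S <- nearest_pd_correlation(S)
    repaired <- TRUE
  }
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- 0.1
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  ebic <- numeric(n_lambda)
  fits <- vector("list", n_lambda)
  W_warm <- NULL
  refit_cache <- new.env(parent = emptyenv())
  for (i in seq_along(grid)) {
    fit <- glasso_fit(S, grid[i], W_init = W_warm)
    W_warm <- fit$W
    Theta <- fit$Theta
    ## EBIC on the support-restricted unpenalized MLE, so that model choice is
    ## not confounded by lasso shrinkage of the retained edges; distinct
    ## supports along the path are refit once
    zero_pat <- Theta == 0
    key <- paste(which(zero_pat[upper.tri(zero_pat)]), collapse = ",")
    ll <- refit_cache[[paste0("k", key)]]
    if (is.null(ll)) {
      Theta_mle <- glasso_fit(S, 0, zero = zero_pat)$Theta
      ll <- (n / 2) * (as.numeric(determinant(Theta_mle,
                                              logarithm = TRUE)$modulus) -
                         sum(S * Theta_mle))
      refit_cache[[paste0("k", key)]] <- ll
    }
    k <- sum(Theta[upper.tri(Theta)] != 0)
    ebic[i] <- -2 * ll + k * log(n) + 4 * k * tuning * log(p)
    fits[[i]] <- Theta
  }
  best <- which.min(ebic)
  Theta <- fits[[best]]
  D <- 1 / sqrt(diag(Theta))
  A <- -Theta * outer(D, D)
  diag(A) <- 0
  dimnames(A) <- list(nodes, nodes)
  structure(list(
    nodes = nodes, adjacency = A, precision = Theta,
    lambda = grid[best], lambda_grid = grid, ebic = ebic,
    ebic_min = ebic[best], n = n, tuning = tuning, repaired = repaired
  ), class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  k <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf(
    "EBIC-glasso network: %d nodes, %d edges (lambda = %.4g, tuning = %g)\n",
    length(x$nodes), k, x$lambda, x$tuning))
  invisible(x)
}

#' Node centrality of a weighted network
#'
#' Strength is the sum of absolute incident edge weights; betweenness counts
#' weighted shortest paths through each node with edge length `1/|weight|`.
#' Both are also z-scored across nodes. Disconnected nodes get strength and
#' betweenness zero.
#'
#' @param network a `network_result` or a symmetric weighted adjacency matrix
#'   with zero diagonal.
#' @return data.frame with columns `node`, `strength`, `betweenness`,
#'   `strength_z`, `betweenness_z`.
#' @examples
#' A <- matrix(c(0, 0.5, 0, 0.5, 0, 0.5, 0, 0.5, 0), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' net_centrality(A)
#' @export
net_centrality <- function(network) {
  A <- if (inherits(network, "network_result")) network$adjacency else network
  stopifnot(is.matrix(A), isSymmetric(unname(A)), all(diag(A) == 0))
  nodes <- rownames(A) %||% paste0("V", seq_len(ncol(A)))
  strength <- rowSums(abs(A))
  gA <- abs(A)
  g <- igraph::graph_from_adjacency_matrix(gA, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  btw <- if (igraph::ecount(g) > 0) {
    igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  } else rep(0, length(nodes))
  zs <- function(v) if (stats::sd(v) == 0) rep(0, length(v)) else
    as.numeric(scale(v))
  data.frame(node = nodes, strength = unname(strength),
             betweenness = unname(btw),
             strength_z = zs(unname(strength)),
             betweenness_z = zs(unname(btw)),
             stringsAsFactors = FALSE)
}
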