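## Group comparisons under left-censoring: Gehan's generalized Wilcoxon test,
## Welch's t-test, and censoring-proportion summaries.

## pairwise score matrix: w[i, j] = +1 if observation i is unambiguously
## greater than j, -1 if unambiguously smaller, 0 if indeterminate.
## Left-censoring semantics: a censored value at c means "<= c", so i > j is
## determinate only when i is uncensored and its value exceeds j's value (or
## j's censoring bound); two censored values never separate; ties score 0.
gehan_score_matrix <- function(values, censored) {
  greater <- (!censored) * outer(values, values, ">")
  greater - t(greater)
}

#' Gehan's generalized Wilcoxon test for left-censored samples
#'
#' Scores every between-group pair +1 / -1 / 0 according to whether the
#' ordering of the two (possibly censored) values is unambiguous, and sums the
#' scores. Inference is by group-label permutation — exact enumeration for
#' small samples, seeded Monte-Carlo otherwise — or by the asymptotic normal
#' approximation with the permutation variance.
#'
#' @param values numeric concentrations (censored rows store their bound).
#' @param censored logical; `TRUE` means the value is known only to be at or
#'   below the stored bound.
#' @param group two-level grouping; the statistic sums scores of the first
#'   level against the second, so swapping labels negates it.
#' @param inference `"permutation"` (default) or `"asymptotic"`.
#' @param n_perm Monte-Carlo permutations (>= 100); ignored when the total
#'   sample size is at most `exact_n`, where all label assignments are
#'   enumerated.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param exact_n largest total n for exact enumeration (default 10).
#' @return list of class `"gehan_test"`: `statistic`, `p`, `method`,
#'   `n_perm`, `seed`.
#' @examples
#' gehan_test(c(0.09, 0.12, 0.10, 0.13), c(TRUE, FALSE, FALSE, FALSE),
#'            c("A", "A", "B", "B"))
#' @export
gehan_test <- function(values, censored, group,
                       inference = c("permutation", "asymptotic"),
                       n_perm = 10000L, seed = 1L, exact_n = 10L) {
  inference <- match.arg(inference)
  stopifnot(length(values) == length(censored),
            length(values) == length(group), all(is.finite(values)))
  censored <- as.logical(censored)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(table(group) == 0L)) stop("one group is empty")
  n <- length(values)
  w <- gehan_score_matrix(values, censored)
  h <- rowSums(w)
  in_a <- group == levels(group)[1]
  n_a <- sum(in_a)
  stat <- sum(h[in_a]) # within-group terms cancel by antisymmetry
  eps <- 1e-9
  if (inference == "asymptotic") {
    v <- n_a * (n - n_a) / (n * (n - 1)) * sum(h^2)
    p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs(stat) / sqrt(v))
    method <- "asymptotic"
    n_perm <- NA_integer_
  } else if (n <= exact_n) {
    combs <- utils::combn(n, n_a)
    stats_all <- apply(combs, 2, function(idx) sum(h[idx]))
    p <- mean(abs(stats_all) >= abs(stat) - eps)
    method <- "exact permutation"
    n_perm <- ncol(combs)
  } else {
    if (n_perm < 100L) stop("n_perm must be at least 100")
    set.seed(as.integer(seed))
    stats_mc <- replicate(n_perm, sum(h[sample.int(n, n_a)]))
    p <- (1 + sum(abs(stats_mc) >= abs(stat) - eps)) / (n_perm + 1)
    method <- "Monte-Carlo permutation"
  }
  structure(list(statistic = stat, p = p, method = method,
                 n_perm = n_perm, seed = seed,
                 groups = levels(group)), class = "gehan_test")
}

#' @export
print.gehan_test <- function(x, ...) {
  cat(sprintf("Gehan's generalized Wilcoxon test (%s vs %s)\n",
              x$groups[1], x$groups[2]))
  cat(sprintf("  statistic = %g, p = %.4g (%s)\n", x$statistic, x$p, x$method))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] with unequal variances
#' (Satterthwaite degrees of freedom), returning the statistic triple used in
#' the pipeline's descriptives.
#'
#' @param values numeric vector.
#' @param group two-level grouping.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(values, group) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L)
  if (any(table(group) < 2L)) stop("at least two values per group required")
  tt <- stats::t.test(values ~ group, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Per-group censoring summary
#'
#' Counts and percentages of censored values per group; percentages are also
#' reported rounded to integer percent, the precision used in cohort tables.
#'
#' @param censored logical vector (or 0/1).
#' @param group grouping vector.
#' @return data.frame with columns `group`, `n`, `n_censored`, `percent`
#'   (exact) and `percent_rounded`.
#' @examples
#' censoring_summary(c(rep(TRUE, 14), rep(FALSE, 11)), rep("MDD", 25))
#' @export
censoring_summary <- function(censored, group) {
  censored <- as.logical(censored)
  out <- do.call(rbind, lapply(split(censored, group), function(v) {
    data.frame(n = length(v), n_censored = sum(v),
               percent = 100 * mean(v))
  }))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$percent_rounded <- as.integer(round(out$percent))
  out
}

#' Percent reduction of a group mean relative to a reference
#'
#' Reporting helper for descriptives such as "the injected tracer dose was
#' 37 percent lower": `100 * (reference - value) / reference`, rounded to
#' integer percent.
#'
#' @param reference reference-group value.
#' @param value comparison-group value.
#' @param digits rounding digits (default 0).
#' @return percent reduction.
#' @examples
#' percent_reduction(0.019, 0.012)
#' @export
percent_reduction <- function(reference, value, digits = 0) {
  round(100 * (reference - value) / reference, digits)
}
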