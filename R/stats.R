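# Shared statistical kernels: paired and pooled-variance t tests, min-max
# scaling, Spearman correlation with a t-approximation p value,
# Benjamini-Hochberg FDR, and the cohort-table correlation driver.
# Classical tests are delegated to stats::t.test / stats::cor /
# stats::p.adjust; only the surrounding conventions live here.

#' Paired t test
#'
#' @param x,y Equal-length numeric vectors (within-subject pairs).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#'   for the mean of `x - y`.
#' @return List with `t`, `df`, `p`, `mean_diff`, and `ci95` (two-sided
#'   interval of the mean difference).
#' @export
paired_t <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y))
    stop_entrainr("length_mismatch", "x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop_entrainr("bad_spec", "need n >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    p <- switch(alternative,
                greater = if (all(d > 0)) 0 else if (all(d < 0)) 1 else 0.5,
                less    = if (all(d < 0)) 0 else if (all(d > 0)) 1 else 0.5,
                if (all(d == 0)) 1 else 0)
    tval <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
    return(list(t = tval, df = n - 1L, p = p, mean_diff = mean(d),
                ci95 = c(mean(d), mean(d))))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  ci <- stats::t.test(x, y, paired = TRUE)$conf.int
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), ci95 = as.numeric(ci))
}

#' Independent-samples t test (pooled variance)
#'
#' Classical Student t with `df = n_x + n_y - 2`, two-tailed; used for the
#' between-group behavioral comparisons.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
independent_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_entrainr("bad_spec", "need n >= 2 per group")
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0)
    stop_entrainr("zero_variance", "both groups are constant")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Min-max scaling to \[0, 1\]
#'
#' @param x Numeric vector of length >= 2.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_scale <- function(x) {
  if (length(x) < 2L) stop_entrainr("bad_spec", "need length >= 2")
  r <- range(x)
  if (r[1] == r[2])
    stop_entrainr("constant_vector", "cannot min-max scale a constant vector")
  (x - r[1]) / (r[2] - r[1])
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive mean ranks). The p
#' value uses the t approximation with `n - 2` degrees of freedom,
#' two-sided; for `n <= 10` an exact permutation p value is available.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param labels Optional length-2 character vector naming the pair.
#' @param exact Use the exact permutation null distribution (only for
#'   `n <= 10`; default `FALSE`).
#' @return A `correlation_result` list: `labels`, `rho`, `n`, `p`.
#' @export
spearman_cor <- function(x, y, labels = c("x", "y"), exact = FALSE) {
  if (length(x) != length(y))
    stop_entrainr("length_mismatch", "x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_entrainr("bad_spec", "need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_entrainr("constant_vector", "correlation undefined for constant input")
  rho <- stats::cor(x, y, method = "spearman")
  if (exact) {
    if (n > 10L)
      stop_entrainr("bad_spec", "exact permutation p only supported for n <= 10")
    rx <- rank(x); ry <- rank(y)
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  }
  structure(list(labels = labels, rho = rho, n = n, p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman %s ~ %s: rho = %.3f (n = %d), p = %.4g\n",
              x$labels[1], x$labels[2], x$rho, x$n, x$p))
  invisible(x)
}

# all permutations of 1:n (n small), rows = permutations
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      block <- sub
      block <- cbind(block[, seq_len(pos - 1L), drop = FALSE], n,
                     block[, pos:(n - 1L), drop = FALSE])
    }
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up FDR control at level `q` over a family of p values.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_entrainr("bad_spec", "p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Correlate cohort measures
#'
#' Min-max scales each requested column, then computes pairwise Spearman
#' correlations. Scaling is order-preserving, so it leaves the rank
#' correlations unchanged; it is applied to mirror the standard reporting
#' convention. Rows with missing values in a pair are dropped.
#'
#' @param table Cohort data frame.
#' @param pairs List of length-2 character vectors of column names;
#'   defaults to sentential tracking against the listening score, the
#'   late-window N400 effect, and the comprehension rating.
#' @return List of `correlation_result` objects.
#' @export
correlate_measures <- function(table,
                               pairs = list(
                                 c("sentential_db", "listening_score"),
                                 c("sentential_db", "n400_late_uv"),
                                 c("sentential_db", "comprehension_rating"))) {
  lapply(pairs, function(pr) {
    if (!all(pr %in% names(table)))
      stop_entrainr("missing_column",
                    paste("columns absent from cohort table:",
                          paste(setdiff(pr, names(table)), collapse = ", ")))
    ok <- stats::complete.cases(table[, pr])
    if (sum(ok) < 3L)
      stop_entrainr("bad_spec", "fewer than 3 complete cases")
    x <- minmax_scale(table[[pr[1]]][ok])
    y <- minmax_scale(table[[pr[2]]][ok])
    spearman_cor(x, y, labels = pr)
  })
}
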