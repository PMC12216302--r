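# Morphological typing (two-cluster K-means on arbor size and complexity)
# and the statistical machinery used throughout: Wilcoxon rank-sum (exact
# by enumeration for small untied samples), pooled two-sample t-test,
# Benjamini-Hochberg FDR, and Pearson correlation. The tests are
# implemented directly from their definitions; the suite cross-checks them
# against the base-R equivalents as independent oracles.

#' Statistical test result container
#'
#' @param statistic test statistic; @param df degrees of freedom or `NA`;
#' @param p_value two-sided p; @param method descriptive method string;
#' @param estimate optional effect estimate (e.g. Pearson r).
#' @return object of class `stat_result`.
#' @export
stat_result <- function(statistic, df = NA_real_, p_value, method,
                        estimate = NA_real_) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, df = df,
                 p_value = min(p_value, 1), p_adjusted = NA_real_,
                 method = method, estimate = estimate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$method, ": statistic = ", sprintf("%.4g", x$statistic),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", sprintf("%.4g", x$p_value),
      if (!is.na(x$p_adjusted)) paste0(", p.adj = ", sprintf("%.4g", x$p_adjusted)),
      "\n", sep = "")
  invisible(x)
}

#' Two-type K-means classification of neurons
#'
#' Classifies neurons into two morphological types from arbor size (total
#' dendritic length) and complexity (branch count). Features are z-scored
#' per column; k = 2 K-means is run with `restarts` random initializations
#' and the best within-cluster sum of squares kept, deterministically given
#' `seed`. Type 1 is the more populous cluster (tie broken toward the
#' smaller mean length, matching the convention that Type 1 neurons are the
#' smaller, less branched majority).
#'
#' @param features data.frame or matrix with columns `total_length` and
#'   `branch_count` (additional columns ignored).
#' @param seed integer seed.
#' @param restarts number of random initializations (default 50).
#' @return object of class `type_assignment`: list with `type` (integer
#'   vector, 1 or 2, named by rowname/label when available),
#'   `cluster_means` (data.frame: type, mean_total_length,
#'   mean_branch_count, size), `seed`.
#' @export
kmeans_two_types <- function(features, seed = 1L, restarts = 50L) {
  X <- as.matrix(as.data.frame(features)[, c("total_length", "branch_count")])
  if (nrow(unique(X)) < 2L) .fail("need at least 2 distinct feature vectors")
  Z <- scale(X)
  Z[, apply(X, 2, stats::sd) == 0] <- 0
  set.seed(seed)
  if (nrow(Z) == 2L) {
    ## stats::kmeans refuses k = n; two distinct points are their own clusters
    km <- list(cluster = 1:2)
  } else {
    km <- stats::kmeans(Z, centers = 2L, nstart = restarts, iter.max = 100L)
  }
  sizes <- tabulate(km$cluster, 2L)
  meanlen <- tapply(X[, "total_length"], km$cluster, mean)
  ## type 1 = more populous; tie -> smaller mean length
  first <- if (sizes[1] != sizes[2]) which.max(sizes) else which.min(meanlen)
  map <- integer(2); map[first] <- 1L; map[-first] <- 2L
  type <- map[km$cluster]
  labs <- rownames(as.data.frame(features))
  if (!is.null(labs)) names(type) <- labs
  cm <- data.frame(
    type = 1:2,
    mean_total_length = as.numeric(tapply(X[, "total_length"], type, mean)),
    mean_branch_count = as.numeric(tapply(X[, "branch_count"], type, mean)),
    size = as.integer(tabulate(type, 2L))
  )
  structure(list(type = type, cluster_means = cm, seed = as.integer(seed)),
            class = "type_assignment")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' For independent samples. When the combined sample size is at most 12 and
#' there are no ties, the exact null distribution of the rank sum is
#' enumerated over all assignments of ranks to the first sample and the
#' two-sided p is twice the smaller tail (capped at 1). Otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The statistic reported is W, the Mann-Whitney count for the first
#' sample.
#'
#' @param a,b numeric samples.
#' @return a [stat_result()].
#' @export
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) .fail("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  Wr <- sum(r[seq_len(na)])                   # rank sum of a
  U <- Wr - na * (na + 1) / 2                 # Mann-Whitney U
  ties <- any(duplicated(c(a, b)))
  if (n <= 12L && !ties) {
    combos <- utils::combn(n, na)
    Wdist <- colSums(matrix(seq_len(n)[combos], nrow = na))
    p <- min(1, 2 * min(mean(Wdist <= Wr), mean(Wdist >= Wr)))
    return(stat_result(U, p_value = p,
                       method = "Wilcoxon rank sum (exact enumeration)"))
  }
  mu <- na * nb / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- na * nb / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(stat_result(U, p_value = 1,
                                 method = "Wilcoxon rank sum (degenerate)"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)   # continuity corrected
  p <- 2 * stats::pnorm(-abs(z))
  stat_result(U, p_value = min(1, p),
              method = "Wilcoxon rank sum (normal approximation)")
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided, with df = n_a + n_b - 2 (so a 27 vs 45 comparison reports
#' df = 70).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return a [stat_result()].
#' @export
pooled_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) .fail("each sample needs n >= 2")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) .fail("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  stat_result(t, df = df, p_value = p, method = "pooled two-sample t-test")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, returned in the input
#' order.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) .fail("p-values must be in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))                # enforce step-up monotonicity
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pearson correlation with two-sided p
#'
#' Sample Pearson r, with p from the t-transform t = r sqrt((n-2)/(1-r^2)),
#' df = n - 2. Perfect correlation reports p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return a [stat_result()] with `estimate` = r and `statistic` = t.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y) || n < 3L) .fail("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) .fail("zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  if (abs(r) >= 1 - 1e-15) {
    return(stat_result(sign(r) * Inf, df = df, p_value = 0,
                       method = "Pearson correlation", estimate = sign(r)))
  }
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  stat_result(t, df = df, p_value = p, method = "Pearson correlation",
              estimate = r)
}
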