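# Cohort-level statistics: Spearman rank correlation of mechanical metrics
# with aortic dilatation, strength labelling, and group summaries.

# n! x n matrix of all permutations of 1:n (n <= 8 kept cheap)
.perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- .perm_matrix(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  r <- 0L
  for (i in seq_len(n)) {
    out[r + seq_len(nrow(p)), ] <- cbind(i, p + (p >= i))
    r <- r + nrow(p)
  }
  out
}

#' Spearman rank-order correlation
#'
#' `rs` is the Pearson correlation of mid-ranks (average ranks for ties).
#' The p-value is computed from the t approximation
#' `t = rs * sqrt((n-2)/(1-rs^2))` on `n - 2` degrees of freedom, or by
#' exhaustive enumeration of all `n!` rank permutations (two-sided, exact)
#' for small samples. The default `"auto"` uses the exact enumeration for
#' `n <= 8`, where the t approximation can flip borderline decisions, and
#' the t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @param method `"auto"`, `"t"`, or `"exact"` (exact requires `n <= 8`).
#' @return Object of class `correlation_result`: `rs`, `p_value`, `n`,
#'   `strength` (see [correlation_strength()]), `direction`, `method`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))  # rs = 0.8
#' @export
spearman_cor <- function(x, y, method = c("auto", "t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("spearman_cor: input lengths differ")
  n <- length(x)
  if (n < 4) stop("spearman_cor: need n >= 4")
  if (anyNA(x) || anyNA(y)) stop("spearman_cor: missing values not supported")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("spearman_cor: undefined correlation for constant input")
  rs <- stats::cor(rx, ry)
  if (method == "auto") method <- if (n <= 8) "exact" else "t"
  p <- if (method == "exact") {
    if (n > 8) stop("spearman_cor: exact enumeration limited to n <= 8")
    P <- .perm_matrix(n)
    rperm <- matrix(ry[P], nrow(P), n)
    zx <- rx - mean(rx); zx <- zx / sqrt(sum(zx^2))
    zr <- rperm - rowMeans(rperm)
    zr <- zr / sqrt(rowSums(zr^2))
    rs_all <- as.vector(zr %*% zx)
    mean(abs(rs_all) >= abs(rs) - 1e-12)
  } else {
    if (abs(rs) >= 1) 0 else {
      t <- rs * sqrt((n - 2) / (1 - rs^2))
      2 * pt(-abs(t), n - 2)
    }
  }
  structure(list(rs = rs, p_value = p, n = n,
                 strength = correlation_strength(rs),
                 direction = if (rs >= 0) "positive" else "negative",
                 method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rs = %.3f (%s, %s), p = %.4g, n = %d [%s]\n",
              x$rs, x$strength, x$direction, x$p_value, x$n, x$method))
  invisible(x)
}

#' Correlation strength label
#'
#' Maps `|rs|` to the conventional strength bands: mild for `|rs| <= 0.5`,
#' moderate for `0.5 < |rs| <= 0.75`, strong for `|rs| > 0.75` (boundaries
#' inclusive on the weaker side); `rs = 0` is labelled `"none"`.
#'
#' @param rs Correlation coefficient in `[-1, 1]`.
#' @return Character label among `"none"`, `"mild"`, `"moderate"`, `"strong"`.
#' @export
correlation_strength <- function(rs) {
  if (any(abs(rs) > 1)) stop("correlation_strength: |rs| must be <= 1")
  ifelse(rs == 0, "none",
         ifelse(abs(rs) <= 0.5, "mild",
                ifelse(abs(rs) <= 0.75, "moderate", "strong")))
}

#' Per-group mean and standard error of the mean
#'
#' @param data Data frame of cohort metrics.
#' @param group Name of the grouping column (default `"genotype"`).
#' @param metrics Character vector of metric columns; defaults to all numeric
#'   columns except the grouping column.
#' @return Long data frame: `metric`, `group`, `n`, `mean`, `sem`. SEM is
#'   `sd/sqrt(n)`; reported as `NA` (missing, not zero) for singleton groups.
#' @export
group_summary <- function(data, group = "genotype", metrics = NULL) {
  if (is.null(metrics))
    metrics <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], group)
  out <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(split(data[[m]], data[[group]]), function(v) {
      v <- v[is.finite(v)]
      data.frame(n = length(v), mean = mean(v),
                 sem = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_)
    }))
  }))
  out <- cbind(metric = rep(metrics, each = length(unique(data[[group]]))),
               group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Correlate mechanical metrics with aortic dilatation
#'
#' Spearman correlation of each metric against the normalized diameter, the
#' cohort-level association table of the analysis. No multiple-testing
#' correction is applied (correlations are reported per metric); this is
#' recorded in the `p_adjust` attribute of the result.
#'
#' @param metrics_df Cohort metrics table carrying a `normalized_diameter`
#'   column (see [compute_invivo_metrics()] and [classify_vessel()]).
#' @param metrics Metric columns to correlate; defaults to the in-vivo
#'   metric set.
#' @param ... Passed to [spearman_cor()].
#' @return Data frame: `metric`, `rs`, `p_value`, `n`, `strength`,
#'   `direction`.
#' @export
correlate_with_dilatation <- function(metrics_df,
                                      metrics = c("lam_theta_sys", "lam_z_iv",
                                                  "sigma_theta_sys", "sigma_z_sys",
                                                  "C_tttt_sys", "C_zzzz_sys",
                                                  "W_sys", "distensibility"),
                                      ...) {
  if (!"normalized_diameter" %in% names(metrics_df))
    stop("correlate_with_dilatation: metrics_df lacks normalized_diameter")
  out <- do.call(rbind, lapply(metrics, function(m) {
    r <- spearman_cor(metrics_df[[m]], metrics_df$normalized_diameter, ...)
    data.frame(metric = m, rs = r$rs, p_value = r$p_value, n = r$n,
               strength = r$strength, direction = r$direction,
               stringsAsFactors = FALSE)
  }))
  attr(out, "p_adjust") <- "none"
  out
}

#' Group comparison by one-way ANOVA with Tukey HSD
#'
#' Convenience wrapper around the routine normality / ANOVA / post-hoc chain
#' ([stats::shapiro.test()], [stats::aov()], [stats::TukeyHSD()]) for a
#' single metric across genotype groups.
#'
#' @param data Cohort metrics data frame.
#' @param metric Metric column name.
#' @param group Grouping column name.
#' @return List with `shapiro_p`, `anova_p`, and the Tukey table.
#' @export
compare_groups <- function(data, metric, group = "genotype") {
  v <- data[[metric]]; g <- factor(data[[group]])
  fit <- aov(v ~ g)
  list(shapiro_p = shapiro.test(stats::residuals(fit))$p.value,
       anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
       tukey = TukeyHSD(fit)$g)
}
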