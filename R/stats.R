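#' Percentile-bootstrap confidence interval for a ratio of group means
#'
#' The estimate is `mean(target) / mean(reference) * 100` (percent of the
#' reference group). For each of `n_boot` resamples, both groups are
#' resampled with replacement independently and the ratio of resampled
#' means recomputed; the CI is the percentile interval at `level`. This is
#' the reporting style "163% (95% CI, 122% to 222%)".
#'
#' @param target,reference numeric vectors (>= 3 values each).
#' @param n_boot number of bootstrap resamples (default 10000, >= 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed (logged in the result; default 0).
#' @param p_value optional p-value to carry (from the matching rank test).
#' @param test_name optional test label.
#' @return an object of class `group_comparison` with fields
#'   `ratio_of_means_pct`, `ci_low_pct`, `ci_high_pct`, `n_boot`, `level`,
#'   `seed`, `p_value`, `test_name`, `degenerate` (single-value groups
#'   collapse the CI and are flagged), `ci_contains_estimate`.
#' @export
bootstrap_ratio_ci <- function(target, reference, n_boot = 10000L,
                               level = 0.95, seed = 0L, p_value = NA_real_,
                               test_name = NA_character_) {
  if (length(target) < 3L || length(reference) < 3L)
    stop("both groups need at least 3 values")
  if (mean(reference) <= 0) stop("reference mean must be positive")
  if (n_boot < 1000L) stop("n_boot must be >= 1000")
  degenerate <- length(unique(target)) == 1L &&
    length(unique(reference)) == 1L
  est <- mean(target) / mean(reference) * 100
  nt <- length(target); nr <- length(reference)
  ratios <- with_seed(seed, {
    tm <- matrix(target[sample.int(nt, nt * n_boot, replace = TRUE)],
                 n_boot, nt)
    rm_ <- matrix(reference[sample.int(nr, nr * n_boot, replace = TRUE)],
                  n_boot, nr)
    rowMeans(tm) / rowMeans(rm_) * 100
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(ratios, c(alpha, 1 - alpha), type = 7))
  structure(list(ratio_of_means_pct = est, ci_low_pct = ci[1],
                 ci_high_pct = ci[2], n_boot = as.integer(n_boot),
                 level = level, seed = seed, p_value = p_value,
                 test_name = test_name, degenerate = degenerate,
                 ci_contains_estimate = ci[1] <= est && est <= ci[2],
                 n_target = nt, n_reference = nr),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%.0f%% (%.0f%% CI, %.0f%% to %.0f%%", x$ratio_of_means_pct,
              100 * x$level, x$ci_low_pct, x$ci_high_pct))
  if (!is.na(x$p_value)) cat(sprintf("; p=%.3g", x$p_value))
  cat(")\n")
  cat(sprintf("  ratio of means, %d resamples, seed %d, n=%d vs n=%d%s\n",
              x$n_boot, x$seed, x$n_target, x$n_reference,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Routes a comparison to parametric or non-parametric tests: the
#' non-parametric route is taken iff any compared group fails Shapiro-Wilk
#' at `alpha`. Groups with fewer than 3 values (or constant values) cannot
#' be tested and force the non-parametric route with a flag.
#'
#' @param ... numeric vectors, or a single list of them.
#' @param alpha significance level (default 0.05).
#' @return list: `route` (`"parametric"` / `"nonparametric"`), `p_values`
#'   per group, `flagged` (logical per group: untestable).
#' @export
shapiro_gate <- function(..., alpha = 0.05) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1]])) groups <- groups[[1]]
  p <- numeric(length(groups)); flagged <- logical(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (length(g) < 3L || length(unique(g)) == 1L) {
      p[i] <- NA_real_; flagged[i] <- TRUE
    } else {
      ## shapiro.test caps n at 5000; subsample is not needed at this scale
      g <- if (length(g) > 5000) g[seq(1, length(g), length.out = 5000)] else g
      p[i] <- stats::shapiro.test(g)$p.value
    }
  }
  nonpar <- any(flagged) || any(p < alpha, na.rm = TRUE)
  list(route = if (nonpar) "nonparametric" else "parametric",
       p_values = p, flagged = flagged)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Rank-based omnibus test (via [stats::kruskal.test()]) followed by Dunn's
#' pairwise z statistics with the tie correction, Holm-adjusted.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2).
#' @return list: `omnibus_p`, `statistic`, `pairwise` (data frame group1,
#'   group2, z, p_raw, p_adj), `all_tied` flag (p = 1 when every value is
#'   identical).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L) {
    pairs <- t(utils::combn(names(groups), 2))
    return(list(omnibus_p = 1, statistic = 0,
                pairwise = data.frame(group1 = pairs[, 1],
                                      group2 = pairs[, 2], z = 0,
                                      p_raw = 1, p_adj = 1),
                all_tied = TRUE))
  }
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- t(utils::combn(seq_along(groups), 2))
  z <- apply(pairs, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    (rbar[i] - rbar[j]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(group1 = names(groups)[pairs[, 1]],
                   group2 = names(groups)[pairs[, 2]],
                   z = as.numeric(z), p_raw = p_raw,
                   p_adj = stats::p.adjust(p_raw, "holm"))
  list(omnibus_p = kw$p.value, statistic = unname(kw$statistic),
       pairwise = pw, all_tied = FALSE)
}

#' Holm-Sidak step-down adjustment
#'
#' Adjusted p for the i-th smallest of m raw p-values is
#' `1 - (1 - p_(i))^(m - i + 1)`, with monotonicity enforced by a running
#' maximum.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way ANOVA with Holm-Sidak post-hoc comparisons
#'
#' Standard one-way ANOVA on per-animal summary values, followed by
#' pairwise t comparisons using the pooled residual variance and
#' Holm-Sidak step-down adjustment. Groups with a single value cannot enter
#' the post-hoc stage and are flagged.
#'
#' @param groups named list of numeric vectors of per-animal values.
#' @return list: `omnibus_p`, `f_statistic`, `pairwise` (group1, group2, t,
#'   df, p_raw, p_adj), `excluded` (names of single-value groups).
#' @export
anova_holm_sidak <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(x ~ g)
  an <- summary(fit)[[1]]
  omnibus_p <- an[["Pr(>F)"]][1]
  f_stat <- an[["F value"]][1]
  mse <- an[["Mean Sq"]][2]
  df <- an[["Df"]][2]
  excluded <- names(groups)[lengths(groups) < 2L]
  ok <- setdiff(names(groups), excluded)
  pairwise <- NULL
  if (length(ok) >= 2L) {
    pairs <- t(utils::combn(ok, 2))
    n <- stats::setNames(lengths(groups), names(groups))
    mu <- stats::setNames(vapply(groups, mean, numeric(1)), names(groups))
    tt <- apply(pairs, 1, function(ab) {
      (mu[ab[1]] - mu[ab[2]]) /
        sqrt(mse * (1 / n[ab[1]] + 1 / n[ab[2]]))
    })
    p_raw <- 2 * stats::pt(-abs(tt), df)
    pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                           t = as.numeric(tt), df = df, p_raw = p_raw,
                           p_adj = holm_sidak_adjust(p_raw))
  }
  if (length(excluded))
    warning("single-animal group(s) excluded from post-hoc: ",
            paste(excluded, collapse = ", "))
  list(omnibus_p = omnibus_p, f_statistic = f_stat, pairwise = pairwise,
       excluded = excluded)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences (e.g. ipsi- vs contralateral
#' responsive areas of the same animal); zero differences are dropped, and
#' the exact distribution is used for n <= 25 without ties.
#'
#' @param ipsi,contra equal-length numeric vectors, paired by animal.
#' @param alternative `"two.sided"` (default), `"greater"` (ipsi > contra)
#'   or `"less"`.
#' @return list: `p_value`, `statistic` (V), `direction` (sign of the
#'   median difference), `n_effective` (non-zero pairs), `all_zero` flag
#'   (p = 1 when every difference is zero).
#' @export
wilcoxon_paired <- function(ipsi, contra,
                            alternative = c("two.sided", "greater",
                                            "less")) {
  alternative <- match.arg(alternative)
  if (length(ipsi) != length(contra))
    stop("paired vectors must have equal length")
  d <- ipsi - contra
  if (all(d == 0))
    return(list(p_value = 1, statistic = NA_real_, direction = 0L,
                n_effective = 0L, all_zero = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(ipsi, contra, paired = TRUE,
                                            alternative = alternative,
                                            exact = sum(d != 0) <= 25))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       direction = sign(stats::median(d[d != 0])),
       n_effective = sum(d != 0), all_zero = FALSE)
}
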