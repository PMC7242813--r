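#' One-tailed paired t test on per-animal condition means
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the per-animal differences
#' d = loaded − unloaded, df = n − 1, one-tailed p in the hypothesized
#' direction (default \code{"greater"}: load increases the measure).
#'
#' @param table a \code{\link{paired_table}} (or any data.frame with
#'   \code{unloaded}/\code{loaded} columns).
#' @param direction \code{"greater"} (loaded > unloaded) or \code{"less"}.
#' @param alpha significance threshold applied (recorded in the report).
#' @return list of class \code{"stat_report"}: test, statistic, df, p_value,
#'   one_tailed, direction, n, mean_diff, sem_diff, effect_size (pooled
#'   Cohen's d), alpha, significant.
#' @export
paired_t_one_tailed <- function(table, direction = c("greater", "less"),
                                alpha = 0.05) {
  direction <- match.arg(direction)
  d <- table$loaded - table$unloaded
  n <- length(d)
  if (n < 2) stop("need at least two animals")
  if (stats::sd(d) == 0) {
    warning("zero variance of differences; p reported as boundary value")
    p <- if (mean(d) == 0) 0.5 else 0
    tt <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
  } else {
    ht <- stats::t.test(table$loaded, table$unloaded, paired = TRUE,
                        alternative = direction)
    tt <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(test = "paired t (one-tailed)", statistic = tt, df = n - 1,
                 p_value = p, one_tailed = TRUE, direction = direction,
                 n = n, mean_diff = mean(d),
                 sem_diff = stats::sd(d) / sqrt(n),
                 effect_size = cohens_d(table), alpha = alpha,
                 significant = p < alpha),
            class = "stat_report")
}

#' Cohen's d for paired condition means
#'
#' Default (\code{"pooled"}): mean paired difference divided by the pooled SD
#' of the two sets of per-animal condition means,
#' sqrt((var(unloaded) + var(loaded)) / 2). The within-pair variants dz
#' (mean(d)/sd(d)) and d_av (denominator (sd(u)+sd(l))/2) are available but
#' non-default.
#'
#' @param table a \code{\link{paired_table}}.
#' @param method \code{"pooled"}, \code{"dz"}, or \code{"av"}.
#' @return effect size (dimensionless).
#' @export
cohens_d <- function(table, method = c("pooled", "dz", "av")) {
  method <- match.arg(method)
  d <- table$loaded - table$unloaded
  denom <- switch(method,
    pooled = sqrt((stats::var(table$unloaded) + stats::var(table$loaded)) / 2),
    dz = stats::sd(d),
    av = (stats::sd(table$unloaded) + stats::sd(table$loaded)) / 2)
  if (denom == 0) stop("zero pooled SD")
  mean(d) / denom
}

#' Shapiro-Wilk normality gate
#'
#' Run on the per-animal differences before every t test; a significant
#' deviation (p below \code{alpha}) routes the comparison to the exact
#' Wilcoxon signed-rank test instead.
#'
#' @param diffs numeric vector of differences (3 <= n <= 5000; outside that
#'   range the gate cannot be computed and is reported as passed).
#' @param alpha gate threshold (default 0.05).
#' @return list with W, p_value, alpha, normal (logical).
#' @export
shapiro_gate <- function(diffs, alpha = 0.05) {
  if (length(diffs) < 3 || length(diffs) > 5000)
    return(list(W = NA_real_, p_value = NA_real_, alpha = alpha,
                normal = TRUE, note = "sample size outside test range"))
  sw <- stats::shapiro.test(diffs)
  list(W = unname(sw$statistic), p_value = sw$p.value, alpha = alpha,
       normal = sw$p.value >= alpha)
}

#' Exact one-tailed paired Wilcoxon signed-rank test
#'
#' W is the sum of ranks (of |d|) of the positive differences. The one-tailed
#' p is computed by exact enumeration of all 2^n equally likely sign
#' assignments (feasible for the small n of animal studies; capped at
#' n = 25). Zero differences are dropped before ranking (standard signed-rank
#' convention) and ties in |d| get midranks, both with a warning; the
#' enumeration is exact in either case because it permutes the observed
#' ranks.
#'
#' @param diffs per-animal differences (loaded − unloaded).
#' @param direction \code{"greater"}: p = P(W >= observed) under the null;
#'   \code{"less"}: p = P(W <= observed).
#' @param alpha significance threshold recorded in the report.
#' @return list of class \code{"stat_report"} with statistic W, p_value, n
#'   (after dropping zeros).
#' @export
wilcoxon_signed_rank_exact <- function(diffs,
                                       direction = c("greater", "less"),
                                       alpha = 0.05) {
  direction <- match.arg(direction)
  d <- diffs[diffs != 0]
  if (length(d) < length(diffs))
    warning("dropped ", length(diffs) - length(d), " zero difference(s)")
  n <- length(d)
  if (n < 1) stop("no nonzero differences")
  if (n > 25) stop("exact enumeration capped at n = 25")
  r <- rank(abs(d))                      # midranks on ties
  if (anyDuplicated(abs(d)))
    warning("ties in |d|; midranks used with exact enumeration")
  W <- sum(r[d > 0])
  # all 2^n sign assignments: W' = sum of ranks assigned '+'
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  p <- if (direction == "greater") mean(Wnull >= W) else mean(Wnull <= W)
  structure(list(test = "paired Wilcoxon signed-rank (exact, one-tailed)",
                 statistic = W, p_value = p, one_tailed = TRUE,
                 direction = direction, n = n, mean_diff = mean(d),
                 alpha = alpha, significant = p < alpha),
            class = "stat_report")
}

#' Paired Hotelling's T-squared test
#'
#' Multivariate paired comparison of p measures across conditions:
#' T2 = n * dbar' S^{-1} dbar on the per-animal difference vectors, with
#' dbar the mean difference vector and S its sample covariance;
#' F = ((n − p)/(p(n − 1))) * T2 follows F(p, n − p) under the null.
#' With p = 1 this reduces to the square of the paired t statistic.
#'
#' @param tables list of \code{\link{paired_table}}s, one per measure, same
#'   animals in the same order.
#' @param alpha significance threshold.
#' @return list of class \code{"stat_report"} with T2, statistic (the F
#'   value), df (c(p, n − p)), p_value.
#' @export
hotelling_t2_paired <- function(tables, alpha = 0.05) {
  D <- vapply(tables, function(tb) tb$loaded - tb$unloaded,
              numeric(nrow(tables[[1]])))
  D <- as.matrix(D)
  n <- nrow(D); p <- ncol(D)
  if (n <= p) stop("need more animals than measures (n > p)")
  dbar <- colMeans(D)
  S <- stats::cov(D)
  qr_S <- qr(S)
  if (qr_S$rank < p) stop("singular difference covariance matrix")
  T2 <- n * drop(t(dbar) %*% solve(S, dbar))
  Fv <- (n - p) / (p * (n - 1)) * T2
  pv <- stats::pf(Fv, p, n - p, lower.tail = FALSE)
  structure(list(test = "paired Hotelling's T2", T2 = T2, statistic = Fv,
                 df = c(p, n - p), p_value = pv, n = n,
                 mean_diff = dbar, alpha = alpha, significant = pv < alpha),
            class = "stat_report")
}

#' Bonferroni-adjusted post hoc decisions
#'
#' After a significant group-level multivariate test, each of the k post hoc
#' univariate tests is judged at alpha / k (for the bivariate groups here,
#' 0.05/2 = 0.025). Raw p values are reported unchanged; only the
#' significance flag uses the corrected threshold.
#'
#' @param reports list of \code{stat_report}s (the post hoc tests).
#' @param alpha family-wise threshold (default 0.05).
#' @return the reports with updated \code{alpha} and \code{significant}
#'   fields, plus attribute \code{threshold}.
#' @export
posthoc_bonferroni <- function(reports, alpha = 0.05) {
  k <- length(reports)
  thr <- alpha / k
  out <- lapply(reports, function(r) {
    r$alpha <- thr
    r$significant <- r$p_value < thr
    r
  })
  attr(out, "threshold") <- thr
  out
}

#' Linear regression R-squared and p value
#'
#' Ordinary least squares of y on x (e.g. force-maintenance duration on
#' retractor burst duration), reporting the coefficient of determination and
#' the two-sided p value of the slope.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list with r_squared, p_value, slope, intercept, n.
#' @export
linregress_r2 <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients["x", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x))
}

#' Normality-gated paired comparison
#'
#' The routing used for every univariate comparison: Shapiro-Wilk on the
#' per-animal differences; if normality is not rejected, a one-tailed paired
#' t test, otherwise the exact one-tailed Wilcoxon signed-rank test.
#'
#' @param table a \code{\link{paired_table}}.
#' @param direction tail direction (\code{"greater"}: loaded > unloaded).
#' @param alpha significance threshold for the routed test.
#' @param gate_alpha Shapiro-Wilk gate threshold.
#' @return a \code{stat_report} with an extra \code{shapiro} element.
#' @export
paired_battery <- function(table, direction = "greater", alpha = 0.05,
                           gate_alpha = 0.05) {
  d <- table$loaded - table$unloaded
  gate <- shapiro_gate(d, gate_alpha)
  rep <- if (gate$normal)
    paired_t_one_tailed(table, direction, alpha)
  else
    wilcoxon_signed_rank_exact(d, direction, alpha)
  rep$shapiro <- gate
  rep
}

#' Difference-column summary of a paired table
#'
#' Mean and SEM of the per-animal differences (loaded − unloaded), and of
#' the per-animal percent changes relative to the unloaded mean; animals with
#' a zero unloaded mean are excluded from the percent summary (their percent
#' change is undefined).
#'
#' @param table a \code{\link{paired_table}}.
#' @return list with mean_diff, sem_diff, n, pct_mean, pct_sem, pct_n.
#' @export
diff_summary <- function(table) {
  d <- table$loaded - table$unloaded
  n <- length(d)
  ok <- table$unloaded != 0
  pct <- 100 * d[ok] / table$unloaded[ok]
  list(mean_diff = mean(d), sem_diff = stats::sd(d) / sqrt(n), n = n,
       pct_mean = mean(pct), pct_sem = stats::sd(pct) / sqrt(length(pct)),
       pct_n = length(pct))
}

#' Run the grouped statistical plan on a set of paired tables
#'
#' The planned battery: univariate measures get the normality-gated paired
#' comparison; bivariate groups (e.g. the protraction pair B38 + I2, the
#' retraction pair B8a/b + B3/B6/B9) get a paired Hotelling's T2 at the group
#' level, followed — only when significant — by Bonferroni-corrected one-tailed
#' post hoc t tests on each member.
#'
#' @param tables named list of \code{\link{paired_table}}s.
#' @param plan list of groups; each group is a list with \code{name},
#'   \code{measures} (names into \code{tables}) and optional
#'   \code{direction}.
#' @param alpha group-level significance threshold.
#' @return named list of group results (each: group test and, where run,
#'   post hoc reports), plus per-measure difference summaries.
#' @export
run_stats_plan <- function(tables, plan, alpha = 0.05) {
  out <- list()
  for (g in plan) {
    ms <- g$measures
    dir <- g$direction %||% "greater"
    if (length(ms) == 1) {
      res <- list(type = "univariate",
                  report = paired_battery(tables[[ms]], dir, alpha))
    } else {
      grp <- hotelling_t2_paired(tables[ms], alpha)
      post <- NULL
      if (grp$significant) {
        post <- posthoc_bonferroni(
          lapply(ms, function(m) paired_t_one_tailed(tables[[m]], dir)),
          alpha)
        names(post) <- ms
        for (m in ms)
          post[[m]]$shapiro <- shapiro_gate(
            tables[[m]]$loaded - tables[[m]]$unloaded)
      }
      res <- list(type = "multivariate", group = grp, posthoc = post)
    }
    res$measures <- ms
    res$differences <- lapply(tables[ms], diff_summary)
    out[[g$name]] <- res
  }
  out
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, p = %.4g (%s at alpha = %g)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "significant" else "n.s.", x$alpha))
  invisible(x)
}
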