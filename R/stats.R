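#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD (estimated parameters, so the test is conservative in
#' the Lilliefors sense); a sample is called normal when p >= 0.05. A
#' degenerate sample (zero SD) is non-normal by definition.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha gate level (default 0.05).
#' @return list with `verdict` ("normal"/"non_normal"), `p`, `statistic`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (length(values) < 3L) stop("need at least 3 values for the normality gate")
  if (stats::sd(values) == 0)
    return(list(verdict = "non_normal", p = 0, statistic = NA_real_))
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                        stats::sd(values)))
  list(verdict = if (kt$p.value >= alpha) "normal" else "non_normal",
       p = kt$p.value, statistic = unname(kt$statistic))
}

#' Bonferroni adjustment
#' @param p raw p-values.
#' @param m number of comparisons (default `length(p)`).
#' @return `min(1, m * p)` per element.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, m * p)

#' Significance tier of a p-value
#'
#' Conventional tiers: `ns` for p >= 0.05, `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001.
#'
#' @param p p-values.
#' @return character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Mann-Whitney U test (exact for small samples, midranks for ties)
#'
#' For combined n <= `exact_max` the two-sided p-value is computed from the
#' exact permutation distribution of the rank sum over all group-label
#' assignments (enumerated with midranks, so ties are handled exactly);
#' otherwise the normal approximation with tie-corrected variance is used.
#' Two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param exact_max combined-size limit for the exact path (default 12).
#' @return list of class `ulm_test`: `test`, `statistic` (U of sample `a`),
#'   `p`, `method` ("exact"/"normal").
#' @export
mann_whitney <- function(a, b, exact_max = 12L) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 values")
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  if (n <= exact_max) {
    sets <- utils::combn(n, na)
    ranksum <- colSums(matrix(r[sets], nrow = na))
    u_all <- ranksum - na * (na + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(test = "mann_whitney", statistic = u_obs, p = p,
                 method = method), class = "ulm_test")
}

#' @export
print.ulm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n", x$test, x$statistic,
              x$p, x$method %||% ""))
  invisible(x)
}

#' Three-group comparison with normality gating
#'
#' If every group passes the KS normality gate, a one-way ANOVA is run with
#' Bonferroni-adjusted pairwise Welch t tests; otherwise a Kruskal-Wallis H
#' test (tie-corrected) with Bonferroni-adjusted pairwise Mann-Whitney U
#' tests.
#'
#' @param samples named list of 3 numeric vectors (each n >= 2 for the
#'   omnibus; n >= 3 for the gate).
#' @return list: `test` ("anova"/"kruskal_wallis"), `statistic`, `p`,
#'   `pairwise` data frame (`group_a`, `group_b`, `p_raw`, `p_adj`, `tier`).
#' @export
compare_three_groups <- function(samples) {
  if (length(samples) != 3L) stop("exactly 3 groups required")
  if (any(vapply(samples, length, integer(1)) < 2L))
    stop("every group needs at least 2 values")
  if (is.null(names(samples))) names(samples) <- paste0("g", 1:3)
  gates <- vapply(samples, function(v) {
    if (length(v) < 3L) return("non_normal")
    normality_gate(v)$verdict
  }, character(1))
  values <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), lengths(samples)), levels = names(samples))
  pairs <- utils::combn(names(samples), 2)
  if (all(gates == "normal")) {
    fit <- stats::aov(values ~ group)
    s <- summary(fit)[[1]]
    omni <- list(test = "anova", statistic = s[["F value"]][1],
                 p = s[["Pr(>F)"]][1])
    p_raw <- apply(pairs, 2, function(pr)
      stats::t.test(samples[[pr[1]]], samples[[pr[2]]])$p.value)
  } else {
    kt <- stats::kruskal.test(values, group)
    omni <- list(test = "kruskal_wallis", statistic = unname(kt$statistic),
                 p = kt$p.value)
    p_raw <- apply(pairs, 2, function(pr)
      mann_whitney(samples[[pr[1]]], samples[[pr[2]]])$p)
  }
  p_adj <- bonferroni(p_raw, m = ncol(pairs))
  omni$pairwise <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                              p_raw = p_raw, p_adj = p_adj,
                              tier = significance_tier(p_adj),
                              stringsAsFactors = FALSE)
  omni$tier <- significance_tier(omni$p)
  omni
}

#' Correlation with normality-gated method choice and strength label
#'
#' In `auto` mode Pearson correlation is used when both variables pass the
#' KS normality gate, Spearman rank correlation otherwise. The strength
#' label follows the conventional cutoffs: |r| >= 0.700 strong,
#' 0.400 <= |r| <= 0.699 moderate, below weak.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param method "auto", "pearson" or "spearman".
#' @return list of class `ulm_correlation`: `method`, `r`, `p`, `label`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  if (method == "auto") {
    method <- if (normality_gate(x)$verdict == "normal" &&
                  normality_gate(y)$verdict == "normal") "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  r <- unname(ct$estimate)
  label <- if (abs(r) >= 0.700) "strong" else if (abs(r) >= 0.400) "moderate" else "weak"
  structure(list(method = method, r = r, p = ct$p.value, label = label),
            class = "ulm_correlation")
}

#' @export
print.ulm_correlation <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f (%s), p = %.4g\n",
              x$method, x$r, x$label, x$p))
  invisible(x)
}

#' Region-wise comparison table for a tidy metric data frame
#'
#' Runs [compare_three_groups()] per parameter across the three regions and
#' (when requested) the pairwise core-vs-invasive Mann-Whitney test, the
#' workflow used to contrast tumor core, invasive zone and normal tissue.
#'
#' @param metrics tidy data frame with columns `region`, `parameter`,
#'   `value` (one value per animal/replicate).
#' @return data frame: `parameter`, `test`, `statistic`, `p`, `tier`, and
#'   Bonferroni-adjusted pairwise columns.
#' @export
compare_regions <- function(metrics) {
  stopifnot(all(c("region", "parameter", "value") %in% names(metrics)))
  out <- list()
  for (par in unique(metrics$parameter)) {
    d <- metrics[metrics$parameter == par, ]
    groups <- split(d$value, d$region)
    if (length(groups) != 3L || any(lengths(groups) < 2L)) next
    cmp <- compare_three_groups(groups)
    row <- data.frame(parameter = par, test = cmp$test,
                      statistic = cmp$statistic, p = cmp$p, tier = cmp$tier,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cmp$pairwise))) {
      nm <- paste0("p_", cmp$pairwise$group_a[i], "_vs_", cmp$pairwise$group_b[i])
      row[[nm]] <- cmp$pairwise$p_adj[i]
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
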