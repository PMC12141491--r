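#' Normality and variance-homogeneity gate
#'
#' Implements the assumption checks that decide between the parametric and
#' non-parametric comparison branches: Shapiro-Wilk normality per group and
#' Levene's test (classic, mean-centered) for variance homogeneity. The
#' parametric branch is taken only when every normality p-value and the
#' Levene p-value all exceed `alpha`. Groups too small for Shapiro-Wilk
#' (n < 3) or with zero variance force the non-parametric branch with a note.
#'
#' @param groups Named list of numeric vectors, >= 2 groups.
#' @param alpha Gate significance level (default 0.05).
#' @return A list of class `gate_report`: `branch` ("parametric" or
#'   "nonparametric"), `shapiro_p` (named per-group p-values, NA where
#'   undefined), `levene_p`, `notes`.
#' @export
assumption_gate <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  notes <- character()
  shap <- vapply(groups, function(g) {
    if (length(g) < 3L || sd(g) == 0) NA_real_ else shapiro.test(g)$p.value
  }, numeric(1))
  small <- vapply(groups, function(g) length(g) < 3L, logical(1))
  const <- vapply(groups, function(g) sd(g) == 0, logical(1))
  if (any(small))
    notes <- c(notes, sprintf("group(s) %s too small for Shapiro-Wilk",
                              paste(names(groups)[small], collapse = ", ")))
  if (any(const))
    notes <- c(notes, sprintf("constant-valued group(s) %s",
                              paste(names(groups)[const], collapse = ", ")))
  lev <- NA_real_
  if (!any(small) && !any(const)) {
    long <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups))))
    lev <- car::leveneTest(value ~ group, data = long,
                           center = mean)[1L, "Pr(>F)"]
  }
  branch <- if (any(is.na(shap)) || is.na(lev) ||
                any(shap <= alpha) || lev <= alpha)
    "nonparametric" else "parametric"
  structure(list(branch = branch, shapiro_p = shap, levene_p = lev,
                 alpha = alpha, notes = notes),
            class = "gate_report")
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  if (any(lengths(groups) < 2L))
    stop("each group needs at least 2 values")
  groups
}

#' Gated group comparison
#'
#' The full decision tree for comparing treatment groups: the assumption
#' gate ([assumption_gate()]) picks the branch; two parametric groups get a
#' two-tailed Student's t-test (equal variances, as already vouched for by
#' the gate; set `welch = TRUE` to override), three or more get one-way
#' ANOVA with Tukey's HSD post hoc when the omnibus is significant; the
#' non-parametric branch uses Kruskal-Wallis with Dunn's post hoc (adjusted
#' p-values, default Holm) when significant and more than two groups are
#' present.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch's t instead of Student's for the two-group
#'   parametric case (default FALSE).
#' @param posthoc_adjust Multiplicity adjustment for Dunn's test (default
#'   "holm"; any method of [stats::p.adjust()]).
#' @return A list of class `group_comparison`: `branch`, `gate`
#'   (the gate report), `omnibus` (list: `test`, `statistic`, `df`,
#'   `p_value`), `significant` (omnibus p < alpha), `posthoc` (data frame or
#'   NULL), `effect` (two groups only: difference of means), `alpha`.
#' @export
gated_compare <- function(groups, alpha = 0.05, welch = FALSE,
                          posthoc_adjust = "holm") {
  groups <- check_groups(groups)
  gate <- assumption_gate(groups, alpha = alpha)
  k <- length(groups)
  long <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(names(groups), lengths(groups))))
  posthoc <- NULL
  if (gate$branch == "parametric" && k == 2L) {
    tt <- t.test(groups[[1L]], groups[[2L]], var.equal = !welch,
                 alternative = "two.sided")
    omnibus <- list(test = if (welch) "Welch t" else "Student t",
                    statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p_value = tt$p.value)
  } else if (gate$branch == "parametric") {
    fit <- aov(value ~ group, data = long)
    an <- summary(fit)[[1L]]
    omnibus <- list(test = "one-way ANOVA",
                    statistic = an[1L, "F value"],
                    df = an[["Df"]], p_value = an[1L, "Pr(>F)"])
    if (omnibus$p_value < alpha) {
      tk <- TukeyHSD(fit)$group
      posthoc <- data.frame(comparison = rownames(tk),
                            estimate = tk[, "diff"],
                            p_adjusted = tk[, "p adj"],
                            significant = tk[, "p adj"] < alpha,
                            row.names = NULL,
                            stringsAsFactors = FALSE)
    }
  } else {
    kw <- kruskal.test(value ~ group, data = long)
    omnibus <- list(test = "Kruskal-Wallis",
                    statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)
    if (omnibus$p_value < alpha && k > 2L) {
      posthoc <- dunn_test(long$value, long$group, adjust = posthoc_adjust,
                           alpha = alpha)
    }
  }
  res <- list(branch = gate$branch, gate = gate, omnibus = omnibus,
              significant = is.finite(omnibus$p_value) &&
                omnibus$p_value < alpha,
              posthoc = posthoc, alpha = alpha,
              effect = if (k == 2L) mean(groups[[1L]]) - mean(groups[[2L]])
                       else NA_real_)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s branch: %s\n", x$branch, x$omnibus$test))
  cat(sprintf("  statistic = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$omnibus$statistic, x$omnibus$p_value,
              if (x$significant) "" else "not ", x$alpha))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Dunn's rank-based post-hoc test
#'
#' All-pairs z tests on mean ranks after a significant Kruskal-Wallis
#' omnibus, with the standard tie correction; p-values are two-sided and
#' multiplicity-adjusted (default Holm).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of the same length.
#' @param adjust Adjustment method for [stats::p.adjust()] (default "holm").
#' @param alpha Significance level used for the `significant` column.
#' @return Data frame: `comparison`, `z`, `p_unadjusted`, `p_adjusted`,
#'   `significant`.
#' @export
dunn_test <- function(values, groups, adjust = "holm", alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  mean_r <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  z <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    (mean_r[[i]] - mean_r[[j]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  padj <- p.adjust(p, method = adjust)
  data.frame(comparison = paste(pairs[1L, ], pairs[2L, ], sep = "-"),
             z = z, p_unadjusted = p, p_adjusted = padj,
             significant = padj < alpha,
             stringsAsFactors = FALSE)
}

#' Empirical power of the gated comparison
#'
#' Simulates two-group (or multi-group) normal experiments with a mean shift
#' in the last group and reports the fraction declared significant by
#' [gated_compare()] --- a quick check that the pipeline can resolve effects
#' of a given size at a given replication level.
#'
#' @param effect Mean shift of the last group (same units as `sd`).
#' @param sd Within-group standard deviation.
#' @param n Replicates per group.
#' @param reps Number of simulated experiments (>= 100).
#' @param seed RNG seed.
#' @param n_groups Number of groups (default 2; the shift applies to the
#'   last).
#' @param alpha Significance level.
#' @return Empirical power (numeric scalar) with attribute `reps`.
#' @export
power_check <- function(effect, sd, n, reps = 200, seed = 1,
                        n_groups = 2, alpha = 0.05) {
  if (reps < 100) stop("reps must be >= 100")
  set.seed(seed)
  hits <- vapply(seq_len(reps), function(i) {
    g <- lapply(seq_len(n_groups), function(j) {
      rnorm(n, mean = if (j == n_groups) effect else 0, sd = sd)
    })
    names(g) <- paste0("g", seq_len(n_groups))
    gated_compare(g, alpha = alpha)$significant
  }, logical(1))
  structure(mean(hits), reps = reps)
}
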