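#' Chemotaxis index
#'
#' `(n_test - n_control) / (n_test + n_control)`: +1 is complete attraction
#' to the stimulus side, -1 complete repulsion. Antisymmetric under
#' swapping the two counts.
#'
#' @param counts A `chemotaxis_counts`, or the test-side count when
#'   `n_control` is supplied.
#' @param n_control Control-side count (when `counts` is numeric).
#' @return Index in `[-1, 1]`.
#' @export
chemotaxis_index <- function(counts, n_control = NULL) {
  if (inherits(counts, "chemotaxis_counts")) {
    n_test <- counts$n_test
    n_control <- counts$n_control
  } else {
    n_test <- counts
  }
  if (!is.numeric(n_test) || !is.numeric(n_control) ||
      n_test < 0 || n_control < 0)
    abort_invalid("counts must be non-negative numbers")
  total <- n_test + n_control
  if (total == 0)
    abort_invalid("at least one worm is required (n_test + n_control > 0)")
  (n_test - n_control) / total
}

new_test_result <- function(test_name, statistic, p_value, comparisons = NULL,
                            n = NULL) {
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         comparisons = comparisons, n = n),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_name, x$statistic,
              x$p_value))
  if (!is.null(x$comparisons)) {
    cmp <- x$comparisons
    cmp$p_raw <- signif(cmp$p_raw, 4)
    cmp$p_adj <- signif(cmp$p_adj, 4)
    print(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' Two-group comparison (Welch's t or Mann-Whitney)
#'
#' Thin typed wrapper over [stats::t.test()] (Welch, unequal variances) and
#' [stats::wilcox.test()] (exact when sample sizes permit and there are no
#' ties), two-sided.
#'
#' @param a,b Numeric vectors, at least 2 values each.
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @return A `test_result`.
#' @export
compare_two <- function(a, b, method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2)
    abort_invalid("each group needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    abort_invalid("groups must contain only finite values")
  n <- c(length(a), length(b))
  if (method == "welch_t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      abort_invalid("both groups are constant; Welch's t test is undefined")
    ht <- stats::t.test(a, b, var.equal = FALSE)
    new_test_result("welch_t", unname(ht$statistic), ht$p.value, n = n)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                              correct = TRUE))
    new_test_result("mann_whitney", unname(ht$statistic), ht$p.value, n = n)
  }
}

# Dunn's posttest after Kruskal-Wallis: pairwise z from joint rank sums
# with tie correction; Bonferroni-style adjustment over the tested pairs
# (the classic Dunn procedure).
dunn_posttest <- function(values, groups, pairs) {
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  m <- nrow(pairs)
  out <- lapply(seq_len(m), function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[g1] + 1 / n_g[g2]))
    z <- (mean_rank[g1] - mean_rank[g2]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(g1, "vs", g2), estimate = unname(z),
               statistic = unname(z), p_raw = unname(p),
               p_adj = min(1, unname(p) * m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sidak adjustment for m comparisons.
sidak_adjust <- function(p, m) {
  1 - (1 - p)^m
}

# Locale-independent factor: levels in C (radix) order so contrast
# directions and pair labels do not depend on the session's collation.
c_factor <- function(x) {
  if (is.factor(x)) return(x)
  factor(x, levels = sort(unique(as.character(x)), method = "radix"))
}

#' Multi-group comparison with posttest
#'
#' Omnibus test plus the posttest the study reports for that design:
#' * `kruskal_dunn` — Kruskal-Wallis ([stats::kruskal.test()]) with Dunn's
#'   posttest over all pairs (or vs `ref` when given), Bonferroni-style
#'   adjustment.
#' * `anova_dunnett` — one-way ANOVA ([stats::aov()]) with Dunnett's
#'   posttest vs the reference level via [multcomp::glht()].
#' * `anova2_sidak` — two-way factorial ANOVA (factors from `design`);
#'   posttest compares the two levels of `design$condition` within each
#'   level of `design$group` using the pooled residual mean square, with
#'   Sidak adjustment over those comparisons; the omnibus statistic is the
#'   interaction F.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (factor or character), same length.
#' @param method One of `"kruskal_dunn"`, `"anova_dunnett"`,
#'   `"anova2_sidak"`.
#' @param design For `anova2_sidak`: data frame with columns `group` and
#'   `condition` (two levels), one row per observation.
#' @param ref Reference level (Dunnett and optional Dunn vs-control).
#' @param posttests If `FALSE`, skip posttest computation (omnibus only;
#'   useful for large calibration runs).
#' @return A `test_result` with `comparisons` rows `(pair, estimate,
#'   statistic, p_raw, p_adj)` when posttests are computed.
#' @export
compare_multi <- function(values, groups = NULL,
                          method = c("kruskal_dunn", "anova_dunnett",
                                     "anova2_sidak"),
                          design = NULL, ref = NULL, posttests = TRUE) {
  method <- match.arg(method)
  if (method == "anova2_sidak") {
    if (is.null(design) || !all(c("group", "condition") %in% names(design)))
      abort_invalid("`design` with columns group and condition is required for anova2_sidak")
    return(anova2_sidak(values, design, posttests))
  }
  if (is.null(groups) || length(groups) != length(values))
    abort_invalid("`groups` must match `values` in length")
  groups <- c_factor(groups)
  if (nlevels(groups) < 2)
    abort_invalid("at least 2 groups are required")
  if (any(table(groups) < 2))
    abort_invalid("every group needs at least 2 observations")
  if (method == "kruskal_dunn") {
    ht <- stats::kruskal.test(values, groups)
    cmp <- NULL
    if (posttests) {
      lv <- levels(groups)
      pairs <- if (is.null(ref)) t(utils::combn(lv, 2)) else
        cbind(setdiff(lv, ref), ref)
      cmp <- dunn_posttest(values, groups, pairs)
    }
    new_test_result("kruskal_dunn", unname(ht$statistic), ht$p.value,
                    comparisons = cmp, n = as.vector(table(groups)))
  } else {
    dat <- data.frame(y = values, g = groups)
    if (!is.null(ref)) dat$g <- stats::relevel(dat$g, ref = ref)
    fit <- stats::aov(y ~ g, data = dat)
    tab <- summary(fit)[[1]]
    cmp <- NULL
    if (posttests) {
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
      sm <- summary(gl)
      cmp <- data.frame(
        pair = names(sm$test$coefficients),
        estimate = unname(sm$test$coefficients),
        statistic = unname(sm$test$tstat),
        p_raw = 2 * stats::pt(-abs(unname(sm$test$tstat)),
                              df = fit$df.residual),
        p_adj = unname(as.numeric(sm$test$pvalues)),
        stringsAsFactors = FALSE
      )
      cmp$p_adj <- pmax(cmp$p_adj, cmp$p_raw)
    }
    new_test_result("anova_dunnett", tab$`F value`[1], tab$`Pr(>F)`[1],
                    comparisons = cmp, n = as.vector(table(groups)))
  }
}

anova2_sidak <- function(values, design, posttests = TRUE) {
  g <- c_factor(design$group)
  cnd <- c_factor(design$condition)
  if (nlevels(cnd) != 2)
    abort_invalid("`design$condition` must have exactly 2 levels")
  cells <- table(g, cnd)
  if (any(cells < 2))
    abort_invalid("every group x condition cell needs at least 2 observations")
  dat <- data.frame(y = values, g = g, cnd = cnd)
  fit <- stats::aov(y ~ g * cnd, data = dat)
  tab <- summary(fit)[[1]]
  inter <- grep(":", rownames(tab))
  cmp <- NULL
  if (posttests) {
    mse <- tab$`Mean Sq`[nrow(tab)]
    dfr <- fit$df.residual
    lv <- levels(g)
    cl <- levels(cnd)
    cmp <- do.call(rbind, lapply(lv, function(l) {
      y1 <- values[g == l & cnd == cl[1]]
      y2 <- values[g == l & cnd == cl[2]]
      est <- mean(y2) - mean(y1)
      se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
      tstat <- est / se
      p <- 2 * stats::pt(-abs(tstat), dfr)
      data.frame(pair = sprintf("%s: %s vs %s", l, cl[2], cl[1]),
                 estimate = est, statistic = tstat, p_raw = p,
                 p_adj = sidak_adjust(p, length(lv)),
                 stringsAsFactors = FALSE)
    }))
  }
  new_test_result("anova2_sidak", tab$`F value`[inter],
                  tab$`Pr(>F)`[inter], comparisons = cmp,
                  n = as.vector(cells))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration (tables with probability at
#' most that of the observed table), delegated to [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A `test_result`.
#' @export
compare_categorical <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2)) ||
      any(table < 0) || any(table != round(table)))
    abort_invalid("`table` must be a 2x2 matrix of non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort_invalid("`table` has an empty margin")
  ht <- stats::fisher.test(table, alternative = "two.sided")
  new_test_result("fisher_exact", unname(ht$estimate), ht$p.value,
                  n = rowSums(table))
}
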