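# Normality-gated statistical layer for group comparisons: Shapiro-Wilk
# gate, Student's t / Mann-Whitney for two groups, one-way ANOVA + Tukey or
# Kruskal-Wallis + Dunn for several (Dunnett against a control group),
# Pearson chi-square for nominal outcomes, and ordinary least-squares
# regression with R^2.

#' Significance code for a p-value
#'
#' Thresholds 0.05, 0.01, 0.001, 0.0001. Parametric results use the
#' asterisk family (`ns`, `*`, `**`, `***`, `****`), non-parametric the
#' `x` family (`ns`, `x`, `xx`, `xxx`, `xxxx`).
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param branch `"parametric"` or `"nonparametric"`.
#' @return Character vector of codes.
#' @export
significance_code <- function(p, branch = c("parametric", "nonparametric")) {
  branch <- match.arg(branch)
  sym <- if (branch == "parametric") "*" else "x"
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    k <- sum(pi < c(0.05, 0.01, 0.001, 0.0001))
    if (k == 0) "ns" else paste(rep(sym, k), collapse = "")
  }, character(1))
}

.as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups)) stop("groups must be a list or data frame",
                             call. = FALSE)
  lapply(groups, function(g) as.numeric(g[is.finite(g)]))
}

#' Normality gate
#'
#' Applies the Shapiro-Wilk test to every group; the analysis branch is
#' parametric only if every group passes at `alpha`. A group with zero
#' variance has no defined test and is rejected as degenerate.
#'
#' @param groups A named list of numeric vectors, or a data frame with
#'   columns `group` and `value`. Every group needs `n >= 3`.
#' @param alpha Gate level (default 0.05).
#' @return A list with `branch` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro_p` (named per-group p-values).
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  gl <- .as_group_list(groups)
  if (any(vapply(gl, length, integer(1)) < 3L)) {
    stop("every group needs at least 3 observations", call. = FALSE)
  }
  if (any(vapply(gl, sd, numeric(1)) == 0)) {
    stop("degenerate group: zero variance, normality test undefined",
         call. = FALSE)
  }
  p <- vapply(gl, function(g) shapiro.test(g)$p.value, numeric(1))
  list(branch = if (all(p >= alpha)) "parametric" else "nonparametric",
       shapiro_p = p)
}

.test_result <- function(test_name, statistic, p_value, branch,
                         posthoc = NULL, extra = NULL) {
  res <- list(test_name = test_name, statistic = unname(statistic),
              p_value = unname(p_value), branch = branch,
              posthoc = posthoc,
              significance_code = significance_code(p_value, branch))
  structure(c(res, extra), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s) %s\n", x$test_name,
              x$statistic, x$p_value, x$branch, x$significance_code))
  if (!is.null(x$posthoc)) {
    cat("post-hoc (adjusted):\n")
    for (i in seq_len(nrow(x$posthoc))) {
      cat(sprintf("  %s: p = %.4g %s\n", x$posthoc$pair[i],
                  x$posthoc$p_adjusted[i],
                  significance_code(x$posthoc$p_adjusted[i], x$branch)))
    }
  }
  invisible(x)
}

#' Two-group comparison
#'
#' Unpaired two-sided Student's t-test (pooled variance; `welch = TRUE`
#' switches to the unequal-variance form) on the parametric branch,
#' Mann-Whitney (Wilcoxon rank-sum) on the non-parametric branch. If both
#' groups are constant the t-test is undefined; the comparison then falls
#' back to the rank test with a warning.
#'
#' @param a,b Numeric samples, `n >= 3` each.
#' @param branch `"parametric"` or `"nonparametric"`; typically from
#'   [normality_gate()].
#' @param welch Use the Welch t-test on the parametric branch.
#' @return A `test_result`.
#' @export
compare_two <- function(a, b, branch = c("parametric", "nonparametric"),
                        welch = FALSE) {
  branch <- match.arg(branch)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  if (branch == "parametric" && sd(a) == 0 && sd(b) == 0) {
    warning("degenerate variance: falling back to the rank test")
    branch <- "nonparametric"
  }
  if (branch == "parametric") {
    tt <- t.test(a, b, var.equal = !welch)
    .test_result(if (welch) "Welch t-test" else "Student t-test",
                 tt$statistic, tt$p.value, branch)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b))
    .test_result("Mann-Whitney", wt$statistic, wt$p.value, branch)
  }
}

# Dunn's post-test: pairwise rank-sum z statistics on the shared ranking
# with a tie correction, Bonferroni-adjusted over the comparisons made.
.dunn_posthoc <- function(gl, pairs) {
  all_vals <- unlist(gl, use.names = FALSE)
  n_tot <- length(all_vals)
  rk <- rank(all_vals)
  grp <- rep(names(gl), vapply(gl, length, integer(1)))
  mean_rank <- tapply(rk, grp, mean)
  ties <- table(all_vals)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  base_var <- n_tot * (n_tot + 1) / 12 - tie_term
  raw <- vapply(pairs, function(pr) {
    ni <- length(gl[[pr[1]]]); nj <- length(gl[[pr[2]]])
    z <- (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) /
      sqrt(base_var * (1 / ni + 1 / nj))
    2 * pnorm(-abs(z))
  }, numeric(1))
  data.frame(pair = vapply(pairs, paste, character(1), collapse = " vs "),
             p_unadjusted = raw,
             p_adjusted = pmin(raw * length(pairs), 1),
             stringsAsFactors = FALSE)
}

#' Multi-group comparison with post-test
#'
#' Parametric branch: one-way ANOVA, followed by Tukey's honestly
#' significant difference over all pairs, or Dunnett's many-to-one test
#' against a designated control. Non-parametric branch: Kruskal-Wallis,
#' followed by Dunn's rank comparisons (Bonferroni-adjusted), over all
#' pairs or restricted to control comparisons. Adjusted p-values are never
#' smaller than the corresponding unadjusted ones.
#'
#' @param groups Named list of numeric vectors or a `group`/`value` data
#'   frame; at least 3 groups.
#' @param branch `"parametric"` or `"nonparametric"`.
#' @param mode `"all_pairs"` or `"vs_control"`.
#' @param control Control group name, required for `"vs_control"`.
#' @return A `test_result` whose `posthoc` data frame has columns `pair`,
#'   `p_unadjusted` (where available) and `p_adjusted`.
#' @export
compare_many <- function(groups, branch = c("parametric", "nonparametric"),
                         mode = c("all_pairs", "vs_control"),
                         control = NULL) {
  branch <- match.arg(branch)
  mode <- match.arg(mode)
  gl <- .as_group_list(groups)
  if (length(gl) < 3L) stop("need at least 3 groups", call. = FALSE)
  if (is.null(names(gl))) names(gl) <- paste0("g", seq_along(gl))
  if (mode == "vs_control") {
    if (is.null(control) || !control %in% names(gl)) {
      stop("vs_control mode needs a control group present in the data",
           call. = FALSE)
    }
  }
  df <- data.frame(
    value = unlist(gl, use.names = FALSE),
    group = factor(rep(names(gl), vapply(gl, length, integer(1))),
                   levels = unique(c(control, names(gl)))))
  pairs <- if (mode == "all_pairs") {
    utils::combn(names(gl), 2, simplify = FALSE)
  } else {
    lapply(setdiff(names(gl), control), function(g) c(g, control))
  }

  if (branch == "parametric") {
    fit <- aov(value ~ group, data = df)
    s <- summary(fit)[[1]]
    fstat <- s$`F value`[1]; p <- s$`Pr(>F)`[1]
    if (mode == "all_pairs") {
      tk <- TukeyHSD(fit)$group
      ph <- data.frame(pair = gsub("-", " vs ", rownames(tk), fixed = TRUE),
                       p_adjusted = tk[, "p adj"], stringsAsFactors = FALSE)
      rownames(ph) <- NULL
      .test_result("one-way ANOVA + Tukey", fstat, p, branch, posthoc = ph)
    } else {
      # Dunnett's quantiles come from a randomised multivariate-t
      # integration; a fixed local seed keeps reruns bit-identical.
      gh <- withr::with_seed(
        1L, summary(multcomp::glht(fit,
                                   linfct = multcomp::mcp(group = "Dunnett"))))
      ph <- data.frame(
        pair = gsub(" - ", " vs ", names(gh$test$coefficients), fixed = TRUE),
        p_adjusted = as.numeric(gh$test$pvalues), stringsAsFactors = FALSE)
      .test_result("one-way ANOVA + Dunnett", fstat, p, branch, posthoc = ph)
    }
  } else {
    kw <- kruskal.test(gl)
    ph <- .dunn_posthoc(gl, pairs)
    .test_result("Kruskal-Wallis + Dunn", kw$statistic, kw$p.value, branch,
                 posthoc = ph)
  }
}

#' Pearson chi-square test on a contingency table
#'
#' Without Yates continuity correction by default; degrees of freedom
#' `(r - 1)(c - 1)`. All expected counts must be positive.
#'
#' @param counts Matrix of counts, 2x2 or larger.
#' @param correct Apply the continuity correction (2x2 only).
#' @return A `test_result` with extra fields `df` and `expected`.
#' @export
chi_square_counts <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  if (any(ct$expected <= 0)) stop("expected counts must be > 0",
                                  call. = FALSE)
  .test_result("chi-square", ct$statistic, ct$p.value, "parametric",
               extra = list(df = unname(ct$parameter),
                            expected = ct$expected))
}

#' Linear regression with coefficient of determination
#'
#' Ordinary least squares of `y` on `x`; `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` non-constant.
#' @return A list with `slope`, `intercept`, `r2` and `p_value` (slope
#'   t-test).
#' @export
linreg_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (sd(x) == 0) stop("x is constant: slope undefined", call. = FALSE)
  fit <- lm(y ~ x)
  # summary.lm warns on numerically perfect fits; R^2 = 1 is a valid answer
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, p_value = sm$coefficients[2, 4])
}
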