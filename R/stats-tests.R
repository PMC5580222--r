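# Statistical primitives used by the selection funnel and the downstream
# association layer.  These are thin contract wrappers around base R: the
# wrapper owns input validation, missing-value policy, degenerate-case
# behaviour and the small-sample/approximation switch, while the numerics are
# delegated to stats::*.  Every wrapper is tested against an independent
# brute-force oracle (exhaustive enumeration, explicit sums of squares, grid
# search) in the test suite.

# Total-sample-size switch point below which exact rank-test distributions
# are used (ties permitting); above, the tie-corrected normal approximation.
.exact_switch <- 25L

test_result <- function(statistic, p_value, method, ...) {
  structure(list(statistic = as.numeric(statistic),
                 p_value = min(max(as.numeric(p_value), 0), 1),
                 method = method, ...),
            class = "radsig_test")
}

#' @export
print.radsig_test <- function(x, ...) {
  cat(sprintf("<radsig_test> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences.  Pairs with a missing
#' member are dropped, as are zero differences.  With at most 12 informative
#' pairs the p-value comes from full enumeration of all sign assignments
#' (valid under ties); with fewer than 25 and no tied absolute differences,
#' from the exact signed-rank distribution; otherwise from the normal
#' approximation with continuity correction.  If every difference is zero the
#' result is degenerate (statistic 0, p = 1).
#'
#' @param a,b paired numeric vectors of equal length.
#' @return a `radsig_test` with fields `statistic` (V), `p_value`, `n` (pairs
#'   used).
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop_radsig("paired vectors differ in length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop_radsig("need at least 2 complete pairs")
  d <- a - b
  if (all(d == 0)) return(test_result(0, 1, "paired_wilcoxon", n = length(d)))
  nz <- d[d != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= 12L) {
    # full sign enumeration; handles tied |differences| exactly
    mid <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    p <- mean(abs(vs - mid) >= abs(v - mid))
    return(test_result(v, p, "paired_wilcoxon", n = n))
  }
  exact <- n < .exact_switch && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, paired = TRUE, exact = exact, correct = TRUE,
    alternative = "two.sided"))
  test_result(unname(wt$statistic), wt$p.value, "paired_wilcoxon", n = n)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for two independent groups.  Exact distribution
#' below a total of 25 observations when there are no ties; tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param a,b numeric vectors (each of length >= 2 after removing missing).
#' @return a `radsig_test` with `statistic` = U for the first group.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop_radsig("each group needs at least 2 observations")
  if (length(unique(c(a, b))) == 1L)
    return(test_result(length(a) * length(b) / 2, 1, "mann_whitney"))
  exact <- (length(a) + length(b)) < .exact_switch && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  test_result(unname(wt$statistic), wt$p.value, "mann_whitney")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k-1 degrees of
#' freedom.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 observations.
#' @return a `radsig_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_radsig("kruskal_wallis needs a list of at least 2 groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) < 2L))
    stop_radsig("every group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(test_result(0, 1, "kruskal_wallis", df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(x, g)
  test_result(unname(kt$statistic), kt$p.value, "kruskal_wallis",
              df = unname(kt$parameter))
}

#' Two-factor group-effect ANOVA
#'
#' Fits the additive linear model `value ~ group + block` and returns the F
#' test for the group main effect with type II sums of squares (i.e. the
#' group effect adjusted for the block factor).  Used by the cell-line stage
#' with group = radioresistance label and block = post-irradiation timepoint.
#' If the block factor has a single observed level it is dropped and the test
#' reduces to a one-way ANOVA.
#'
#' @param values numeric response vector.
#' @param group binary factor of interest.
#' @param block nuisance categorical factor.
#' @param interaction include a group:block interaction term (the group main
#'   effect is still the quantity tested).
#' @return a `radsig_test` with `statistic` = F.
#' @export
anova_group_effect <- function(values, group, block, interaction = FALSE) {
  keep <- is.finite(values)
  values <- values[keep]
  group <- factor(group[keep]); block <- factor(block[keep])
  if (nlevels(group) < 2L)
    return(test_result(0, 1, "anova_group"))
  if (stats::var(values) == 0)
    return(test_result(0, 1, "anova_group"))
  if (nlevels(block) < 2L) {
    fit <- stats::lm(values ~ group)
    tab <- stats::anova(fit)
    return(test_result(tab["group", "F value"], tab["group", "Pr(>F)"],
                       "anova_group"))
  }
  # Type II SS for `group`: sequential SS with group entered last.
  fml <- if (interaction) values ~ block + group + block:group else values ~ block + group
  tab <- stats::anova(stats::lm(fml))
  test_result(tab["group", "F value"], tab["group", "Pr(>F)"], "anova_group")
}

#' Pearson correlation with t-based p-value
#'
#' Pairwise-complete Pearson correlation; two-sided p from the t transform on
#' n-2 degrees of freedom.  Zero variance in either variable yields a
#' degenerate result with `r = NA` and `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return a `radsig_test` with fields `statistic` = r, `p_value`, `n`,
#'   `degenerate`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_radsig("x and y differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_radsig("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(test_result(NA_real_, 1, "pearson", n = n, degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ct$estimate), ct$p.value, "pearson", n = n,
              degenerate = FALSE)
}

#' Multiple-testing adjustment
#'
#' Step-down Holm (the default, matching the funnel's "false discovery rate"
#' label, which is a family-wise adjustment) or Benjamini-Hochberg.  Output
#' is order-aligned with the input and capped at 1.
#'
#' @param p numeric vector of p-values in \[0,1\] (`NA` allowed, propagated).
#' @param method `"holm"` or `"bh"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_radsig("p-values must lie in [0,1]")
  stats::p.adjust(p, method = c(holm = "holm", bh = "BH")[[method]])
}
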