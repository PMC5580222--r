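# Downstream association layer: survival stratification by the median score,
# score comparisons across labelled groups (molecular subtype, HPV status,
# genotype flags), and univariate Pearson correlation screens against
# feature-by-sample matrices (hallmark enrichment scores, protein panels,
# drug IC50 panels) with a cross-dataset consensus rule.

#' Median-split survival stratification
#'
#' Splits subjects at the in-cohort median score (subjects at or below the
#' median form the low group, deterministic tie rule), estimates a
#' Kaplan-Meier curve per group and compares them with the log-rank test.
#'
#' @param scores score table (named numeric vector).
#' @param surv survival table; only subjects with both a score and a record
#'   are used (>= 10 required).
#' @return object of class `radsig_split`: `split_value`, `group_sizes`,
#'   `km_low`, `km_high`, `logrank`.
#' @export
median_split_survival <- function(scores, surv) {
  surv <- survival_records(surv)
  shared <- intersect(names(scores), surv$sample_id)
  if (length(shared) < 10L)
    stop_radsig("need >= 10 subjects with both score and survival, have %d",
                length(shared))
  surv <- surv[match(shared, surv$sample_id), , drop = FALSE]
  s <- scores[shared]
  med <- stats::median(s)
  if (all(s == s[1L])) stop_radsig("all scores equal; no median split possible")
  high <- s > med
  if (!any(high) || all(high))
    stop_radsig("median split produced an empty group (heavily tied scores)")
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  structure(list(
    split_value = med,
    group_sizes = c(low = sum(!high), high = sum(high)),
    km_low = kaplan_meier(surv[!high, , drop = FALSE]),
    km_high = kaplan_meier(surv[high, , drop = FALSE]),
    logrank = logrank_test(surv, grp)),
    class = "radsig_split")
}

#' @export
print.radsig_split <- function(x, ...) {
  cat(sprintf("<radsig_split> median = %.4g, n(low/high) = %d/%d, log-rank p = %.4g\n",
              x$split_value, x$group_sizes["low"], x$group_sizes["high"],
              x$logrank$p_value))
  invisible(x)
}

#' Compare scores across labelled groups
#'
#' Two groups are compared with the Mann-Whitney test, more with
#' Kruskal-Wallis.  Singleton groups are excluded with a warning; fewer than
#' two remaining groups is an error.
#'
#' @param scores score table.
#' @param labels named character vector (sample id -> group label), or a
#'   vector aligned with `scores`.
#' @return a `radsig_test` with an added `medians` field (per-group median
#'   score) and `n_per_group`.
#' @export
compare_groups <- function(scores, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != length(scores))
      stop_radsig("unnamed labels must align with scores")
    names(labels) <- names(scores)
  }
  shared <- intersect(names(scores), names(labels))
  lab <- as.character(labels[shared])
  keep <- !is.na(lab)
  s <- scores[shared][keep]; lab <- lab[keep]
  sizes <- table(lab)
  if (any(sizes < 2L)) {
    warn_radsig("excluding singleton group(s): %s",
                paste(names(sizes)[sizes < 2L], collapse = ", "))
    ok <- lab %in% names(sizes)[sizes >= 2L]
    s <- s[ok]; lab <- lab[ok]
  }
  groups <- split(as.numeric(s), lab)
  if (length(groups) < 2L)
    stop_radsig("need at least 2 groups with >= 2 members")
  res <- if (length(groups) == 2L) mann_whitney(groups[[1L]], groups[[2L]])
         else kruskal_wallis(groups)
  res$medians <- vapply(groups, stats::median, 1)
  res$n_per_group <- vapply(groups, length, 1L)
  res
}

#' Correlation screen of a score against a feature matrix
#'
#' Pearson correlation of the score with every feature over pairwise-complete
#' shared samples.  A feature is a hit when its raw p-value is at most
#' `p_max` and its correlation clears `r_min` with the requested sign.
#' Holm-adjusted p-values are reported alongside, but the hit rule uses the
#' raw thresholds.  Features with fewer than `min_n` complete pairs or zero
#' variance are flagged and can never be hits.
#'
#' @param scores score table.
#' @param features numeric matrix, features as rows, samples as columns.
#' @param r_min minimum |r| (applied with sign per `sign`).
#' @param p_max maximum raw p.
#' @param sign `"any"`, `"positive"` or `"negative"`.
#' @param min_n minimum complete pairs per feature (default 10, never below
#'   3).
#' @return object of class `radsig_screen`: data.frame `table` (feature, r,
#'   p_value, adjusted_p, n, hit, flagged) sorted by decreasing r, plus the
#'   thresholds used.
#' @export
correlate_with_matrix <- function(scores, features, r_min = 0.2, p_max = 0.01,
                                  sign = c("any", "positive", "negative"),
                                  min_n = 10L) {
  sign <- match.arg(sign)
  if (!is.matrix(features) || !is.numeric(features))
    stop_radsig("features must be a numeric matrix (features x samples)")
  if (is.null(rownames(features)) || is.null(colnames(features)))
    stop_radsig("feature matrix requires dimnames")
  shared <- intersect(names(scores), colnames(features))
  if (length(shared) < 3L)
    stop_radsig("fewer than 3 samples shared between scores and features")
  min_n <- max(3L, as.integer(min_n))
  s <- as.numeric(scores[shared])
  f <- features[, shared, drop = FALSE]
  rows <- lapply(rownames(f), function(ft) {
    y <- f[ft, ]
    ok <- is.finite(y) & is.finite(s)
    if (sum(ok) < min_n || stats::var(y[ok]) == 0 || stats::var(s[ok]) == 0) {
      return(data.frame(feature = ft, r = NA_real_, p_value = NA_real_,
                        n = sum(ok), flagged = TRUE, stringsAsFactors = FALSE))
    }
    ct <- pearson_cor(s[ok], y[ok])
    data.frame(feature = ft, r = ct$statistic, p_value = ct$p_value,
               n = ct$n, flagged = isTRUE(ct$degenerate),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$adjusted_p <- adjust_pvalues(tab$p_value, "holm")
  sign_ok <- switch(sign,
                    any = abs(tab$r) >= r_min,
                    positive = tab$r >= r_min,
                    negative = tab$r <= -r_min)
  tab$hit <- !tab$flagged & !is.na(tab$p_value) & tab$p_value <= p_max &
    sign_ok & !is.na(sign_ok)
  tab$hit[is.na(tab$hit)] <- FALSE
  tab <- tab[order(-ifelse(is.na(tab$r), -Inf, tab$r)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab[, c("feature", "r", "p_value", "adjusted_p",
                                 "n", "hit", "flagged")],
                 r_min = r_min, p_max = p_max, sign = sign, min_n = min_n),
            class = "radsig_screen")
}

#' @export
print.radsig_screen <- function(x, ...) {
  cat(sprintf("<radsig_screen> %d features, %d hit(s) (|r| >= %g, p <= %g, sign %s)\n",
              nrow(x$table), sum(x$table$hit), x$r_min, x$p_max, x$sign))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Cross-dataset consensus of correlation screens
#'
#' Features that are hits with a consistent correlation sign in every screen.
#' All screens must share a feature namespace.
#'
#' @param screens list of `radsig_screen` objects over the same features.
#' @return data.frame (feature, mean_r, n_screens) sorted by decreasing
#'   mean r.
#' @export
multi_dataset_consensus <- function(screens) {
  if (!length(screens)) stop_radsig("no screens supplied")
  tabs <- lapply(screens, function(sc) sc$table)
  common <- Reduce(intersect, lapply(tabs, `[[`, "feature"))
  if (!length(common))
    stop_radsig("screens share no feature namespace")
  rs <- vapply(tabs, function(t) t$r[match(common, t$feature)],
               numeric(length(common)))
  hits <- vapply(tabs, function(t) t$hit[match(common, t$feature)],
                 logical(length(common)))
  rs <- matrix(rs, nrow = length(common))
  hits <- matrix(hits, nrow = length(common))
  all_hit <- rowSums(hits) == ncol(hits)
  consistent <- apply(rs, 1L, function(r) all(r > 0) || all(r < 0))
  keep <- all_hit & consistent & !apply(rs, 1L, anyNA)
  out <- data.frame(feature = common[keep],
                    mean_r = rowMeans(rs)[keep],
                    n_screens = length(screens),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_r), , drop = FALSE]
}
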