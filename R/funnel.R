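# The three-stage selection funnel: (1) paired tumour-vs-normal differential
# expression, (2) radioresistant-vs-radiosensitive cell-line two-way ANOVA
# blocked on post-irradiation timepoint, (3) per-gene multivariate Cox
# screening against disease-free survival.  The signature is the direction-
# concordant intersection of the three stages.

#' Funnel thresholds
#'
#' @param fdr_max maximum Holm-adjusted p (the funnel's "FDR") for stages 1
#'   and 2; default 0.05.
#' @param abs_fc_min minimum absolute signed fold change (linear scale,
#'   strict inequality); default 1, i.e. any difference.
#' @param cox_p_max maximum raw Wald p for the stage-3 expression term;
#'   default 0.05.
#' @return list of class `radsig_thresholds`.
#' @export
funnel_thresholds <- function(fdr_max = 0.05, abs_fc_min = 1, cox_p_max = 0.05) {
  stopifnot(fdr_max > 0, fdr_max <= 1, cox_p_max > 0, cox_p_max <= 1,
            abs_fc_min >= 1)
  structure(list(fdr_max = fdr_max, abs_fc_min = abs_fc_min,
                 cox_p_max = cox_p_max),
            class = "radsig_thresholds")
}

#' Signed linear fold change
#'
#' Ratio of two linear-scale group means, reported as `mean_a / mean_b` when
#' the first group is higher and as the negative reciprocal
#' `-mean_b / mean_a` when it is lower, so that `|fc| >= 1` always and the
#' sign encodes direction (positive = up in the first group).
#'
#' @param mean_a,mean_b positive linear-scale means (vectorized).
#' @return signed fold change(s).
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  if (any(!is.finite(mean_a)) || any(!is.finite(mean_b)) ||
      any(mean_a <= 0) || any(mean_b <= 0))
    stop_radsig("group means must be positive and finite")
  ifelse(mean_a >= mean_b, mean_a / mean_b, -mean_b / mean_a)
}

# Genes with more than `max_missing` missing are excluded from selection.
usable_genes <- function(expr, max_missing = 0.2) {
  frac <- rowMeans(is.na(expr))
  rownames(expr)[frac <= max_missing]
}

linear_mean <- function(x) mean(2^x, na.rm = TRUE)

de_frame <- function(gene, fc, p, fdr) {
  data.frame(gene = gene, fc = fc, p_value = p, fdr = fdr,
             direction = ifelse(fc > 0, "UP", "DN"),
             stringsAsFactors = FALSE)
}

apply_de_filter <- function(df, th) {
  keep <- !is.na(df$fdr) & df$fdr < th$fdr_max & abs(df$fc) > th$abs_fc_min
  out <- df[keep, , drop = FALSE]
  out[order(out$gene), , drop = FALSE]
}

#' Stage 1: paired tumour-versus-normal differential expression
#'
#' For every gene, a paired Wilcoxon signed-rank test on log2 values across
#' complete tumour/normal pairs, with the signed fold change computed from
#' linear-scale pair means.  P-values are Holm-adjusted across all tested
#' genes; genes pass with adjusted p < `fdr_max` and |FC| > `abs_fc_min`.
#'
#' @param expr genes-by-samples log2 expression matrix.
#' @param ann sample annotations with `tissue` and `pair_id`.
#' @param th a [funnel_thresholds()] object.
#' @return data.frame (gene, fc, p_value, fdr, direction) of passing genes,
#'   sorted by gene symbol, with attribute `n_tested`.
#' @export
stage1_tumor_vs_normal <- function(expr, ann, th = funnel_thresholds()) {
  assert_expression_matrix(expr)
  ann <- sample_annotation(ann)
  ann <- ann[ann$sample_id %in% colnames(expr) & !is.na(ann$pair_id), ,
             drop = FALSE]
  pairs <- intersect(ann$pair_id[ann$tissue == "tumor"],
                     ann$pair_id[ann$tissue == "normal"])
  if (length(pairs) < 3L)
    stop_radsig("need at least 3 complete tumor/normal pairs, found %d",
                length(pairs))
  t_ids <- ann$sample_id[match(paste0(pairs, ".tumor"),
                               paste0(ann$pair_id, ".", ann$tissue))]
  n_ids <- ann$sample_id[match(paste0(pairs, ".normal"),
                               paste0(ann$pair_id, ".", ann$tissue))]
  genes <- usable_genes(expr)
  tum <- expr[genes, t_ids, drop = FALSE]
  nor <- expr[genes, n_ids, drop = FALSE]
  p <- vapply(seq_along(genes), function(i)
    paired_wilcoxon(tum[i, ], nor[i, ])$p_value, 1)
  fc <- signed_fold_change(rowMeans(2^tum, na.rm = TRUE),
                           rowMeans(2^nor, na.rm = TRUE))
  res <- de_frame(genes, fc, p, adjust_pvalues(p, "holm"))
  out <- apply_de_filter(res, th)
  attr(out, "n_tested") <- length(genes)
  out
}

#' Classify a cell line as radioresistant or radiosensitive
#'
#' In `sf2` mode the surviving fraction at 2 Gy is used: below 0.2 is
#' radiosensitive, above 0.8 radioresistant, in between intermediate.  In
#' `auc` mode the clonogenic dose-survival area under the curve is
#' dichotomized at 2.0 (above = radioresistant).
#'
#' @param sf2 surviving fraction at 2 Gy, in \[0,1\] (vectorized).
#' @param auc clonogenic survival AUC, positive (vectorized).
#' @param mode which measurement drives the label.
#' @return character vector of labels.
#' @export
classify_cell_line <- function(sf2 = NULL, auc = NULL, mode = c("sf2", "auc")) {
  mode <- match.arg(mode)
  if (mode == "sf2") {
    if (is.null(sf2) || any(is.na(sf2)))
      stop_radsig("sf2 mode requires sf2 values")
    if (any(sf2 < 0 | sf2 > 1)) stop_radsig("sf2 must lie in [0,1]")
    ifelse(sf2 < 0.2, "radiosensitive",
           ifelse(sf2 > 0.8, "radioresistant", "intermediate"))
  } else {
    if (is.null(auc) || any(is.na(auc)))
      stop_radsig("auc mode requires auc values")
    if (any(auc <= 0)) stop_radsig("auc must be positive")
    ifelse(auc > 2.0, "radioresistant", "radiosensitive")
  }
}

#' Stage 2: radioresistant-versus-radiosensitive cell-line screen
#'
#' For every gene, a two-factor additive ANOVA of log2 expression on the
#' radioresistance label (group) and the post-irradiation timepoint (block),
#' pooling all timepoints for power; the reported F/p are for the group main
#' effect (type II SS).  The signed fold change is computed from linear-scale
#' group means pooled across timepoints (positive = higher in radioresistant
#' lines).  Holm adjustment across tested genes, then the `fdr_max` /
#' `abs_fc_min` filter.  With a single observed timepoint the test falls back
#' to a one-way ANOVA with a warning.
#'
#' A per-timepoint companion report (Mann-Whitney p and fold change at each
#' timepoint, for the passing genes) is attached as attribute
#' `timepoint_report`.
#'
#' @param expr genes-by-samples log2 matrix (cell-line samples).
#' @param ann annotations with `rr_label` and `timepoint`; intermediate lines
#'   are excluded.
#' @param th a [funnel_thresholds()] object.
#' @return data.frame as in [stage1_tumor_vs_normal()], direction UP =
#'   over-expressed in radioresistant lines.
#' @export
stage2_radioresistance <- function(expr, ann, th = funnel_thresholds()) {
  assert_expression_matrix(expr)
  ann <- sample_annotation(ann)
  ann <- ann[ann$sample_id %in% colnames(expr) &
               ann$rr_label %in% c("radioresistant", "radiosensitive"), ,
             drop = FALSE]
  if (!all(c("radioresistant", "radiosensitive") %in% ann$rr_label))
    stop_radsig("both radioresistant and radiosensitive lines are required")
  tp <- ann$timepoint
  if (all(is.na(tp))) tp <- rep("t0", nrow(ann))
  if (length(unique(tp[!is.na(tp)])) < 2L)
    warn_radsig("single timepoint: falling back to one-way group comparison")
  sub <- expr[, ann$sample_id, drop = FALSE]
  genes <- usable_genes(sub)
  grp <- factor(ann$rr_label, levels = c("radiosensitive", "radioresistant"))
  p <- vapply(genes, function(g)
    anova_group_effect(sub[g, ], grp, tp)$p_value, 1)
  rr <- sub[genes, grp == "radioresistant", drop = FALSE]
  rs <- sub[genes, grp == "radiosensitive", drop = FALSE]
  fc <- signed_fold_change(rowMeans(2^rr, na.rm = TRUE),
                           rowMeans(2^rs, na.rm = TRUE))
  res <- de_frame(genes, fc, p, adjust_pvalues(p, "holm"))
  out <- apply_de_filter(res, th)
  attr(out, "n_tested") <- length(genes)
  attr(out, "timepoint_report") <- stage2_timepoint_report(sub, grp, tp, out$gene)
  out
}

# Companion per-timepoint Mann-Whitney table for selected genes.
stage2_timepoint_report <- function(sub, grp, tp, genes) {
  if (!length(genes)) {
    return(data.frame(gene = character(), timepoint = character(),
                      fc = numeric(), p_value = numeric()))
  }
  tps <- sort(unique(tp[!is.na(tp)]))
  do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(tps, function(t1) {
      sel <- !is.na(tp) & tp == t1
      a <- sub[g, sel & grp == "radioresistant"]
      b <- sub[g, sel & grp == "radiosensitive"]
      data.frame(gene = g, timepoint = t1,
                 fc = signed_fold_change(mean(2^a, na.rm = TRUE),
                                         mean(2^b, na.rm = TRUE)),
                 p_value = mann_whitney(a, b)$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Stage 3: per-gene multivariate Cox screen
#'
#' For every candidate gene, a Cox proportional-hazards model of disease-free
#' survival on the gene's log2 expression (continuous, per-log2-unit; or
#' z-scored with `standardize = TRUE`) adjusted for age, nodal stage and
#' tumour stage.  Genes are retained at raw Wald p < `cox_p_max` for the
#' expression term (no multiplicity adjustment at this stage).  Degenerate or
#' non-convergent fits are reported in the `excluded` attribute with a
#' warning, never silently dropped.
#'
#' @param expr genes-by-samples log2 matrix (tumour cohort).
#' @param surv survival table (see [survival_records()]); at least 30 records
#'   and 10 events.
#' @param genes candidate gene symbols (typically stage1/stage2 survivors).
#' @param th a [funnel_thresholds()] object.
#' @param standardize z-score the expression covariate.
#' @return data.frame (gene, hr, p_value) of retained genes sorted by symbol,
#'   with attributes `n_tested`, `excluded`, and `all` (unfiltered table).
#' @export
stage3_cox_screen <- function(expr, surv, genes, th = funnel_thresholds(),
                              standardize = FALSE) {
  assert_expression_matrix(expr)
  surv <- survival_records(surv)
  surv <- surv[surv$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(surv) < 30L || sum(surv$event) < 10L)
    stop_radsig("cox screen needs >= 30 subjects and >= 10 events (have %d / %d)",
                nrow(surv), sum(surv$event))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop_radsig("candidate genes absent from expression matrix: %s",
                paste(missing, collapse = ", "))
  clin <- data.frame(age = surv$age, node_stage = surv$node_stage,
                     tumor_stage = surv$tumor_stage)
  excluded <- character()
  rows <- lapply(genes, function(g) {
    x <- expr[g, surv$sample_id]
    if (all(is.na(x)) || stats::var(x, na.rm = TRUE) == 0) {
      excluded <<- c(excluded, g)
      return(NULL)
    }
    if (standardize) x <- as.numeric(scale(x))
    fit <- tryCatch(cox_fit(surv, cbind(expr_ = x, clin)),
                    radsig_error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      excluded <<- c(excluded, g)
      return(NULL)
    }
    data.frame(gene = g, hr = unname(fit$hr["expr_"]),
               p_value = unname(fit$p_values["expr_"]),
               stringsAsFactors = FALSE)
  })
  if (length(excluded))
    warn_radsig("cox screen excluded %d gene(s) with degenerate or non-convergent fits: %s",
                length(excluded), paste(excluded, collapse = ", "))
  all_res <- do.call(rbind, rows)
  if (is.null(all_res))
    all_res <- data.frame(gene = character(), hr = numeric(), p_value = numeric())
  out <- all_res[all_res$p_value < th$cox_p_max, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  attr(out, "n_tested") <- length(genes) - length(excluded)
  attr(out, "excluded") <- excluded
  attr(out, "all") <- all_res
  out
}

#' Intersect the three funnel stages into a directional signature
#'
#' The signature is the set of genes passing all three stages.  With
#' `concordance = TRUE` (default) a gene must have the same differential-
#' expression direction in stage 1 and stage 2; membership in the UP or DN
#' side of the signature follows that shared direction.  Concordance with the
#' hazard-ratio direction is not required.  An empty intersection yields an
#' empty signature with a warning, not an error.
#'
#' @param s1,s2 stage-1/stage-2 results (data.frames with `gene`,
#'   `direction`).
#' @param s3 stage-3 result (data.frame with `gene`).
#' @param concordance require stage1/stage2 direction agreement.
#' @param name signature name.
#' @return a [signature_gene_set()] (possibly empty).
#' @export
select_signature <- function(s1, s2, s3, concordance = TRUE, name = "RadR") {
  common <- Reduce(intersect, list(s1$gene, s2$gene, s3$gene))
  if (concordance && length(common)) {
    d1 <- s1$direction[match(common, s1$gene)]
    d2 <- s2$direction[match(common, s2$gene)]
    common <- common[d1 == d2]
  }
  common <- sort(common)
  if (!length(common)) {
    warn_radsig("empty signature: no gene passed all three stages")
    return(structure(list(name = name, up = character(), dn = character()),
                     class = "radsig_signature"))
  }
  dir1 <- s1$direction[match(common, s1$gene)]
  signature_gene_set(name, up = common[dir1 == "UP"], dn = common[dir1 == "DN"])
}

#' Tabulate funnel results in the style of a signature summary table
#'
#' One row per signature gene with its stage-1 and stage-2 fold change and
#' adjusted p, and stage-3 hazard ratio and p.
#'
#' @param s1,s2,s3 stage results.
#' @param sig the selected signature.
#' @return data.frame with columns gene, direction, fc_s1, fdr_s1, fc_s2,
#'   fdr_s2, hr, p.
#' @export
funnel_table <- function(s1, s2, s3, sig) {
  genes <- c(sig$up, sig$dn)
  genes <- sort(genes)
  data.frame(
    gene = genes,
    direction = ifelse(genes %in% sig$up, "UP", "DN"),
    fc_s1 = s1$fc[match(genes, s1$gene)],
    fdr_s1 = s1$fdr[match(genes, s1$gene)],
    fc_s2 = s2$fc[match(genes, s2$gene)],
    fdr_s2 = s2$fdr[match(genes, s2$gene)],
    hr = s3$hr[match(genes, s3$gene)],
    p = s3$p_value[match(genes, s3$gene)],
    stringsAsFactors = FALSE)
}

#' Replay printed per-stage statistics through the funnel filter logic
#'
#' Takes a table in [funnel_table()] layout (for instance the packaged
#' 13-gene signature table, [radr_table1()]) and re-applies the stage filters
#' and the intersection rule, without recomputing any statistic.  Used to
#' verify that the published per-gene numbers reproduce the published
#' signature under the stated thresholds.
#'
#' @param tbl data.frame with columns gene, fc_s1, fdr_s1, fc_s2, fdr_s2, hr,
#'   p.
#' @param th a [funnel_thresholds()] object.
#' @param concordance as in [select_signature()].
#' @param name signature name.
#' @return a [signature_gene_set()].
#' @export
funnel_replay <- function(tbl, th = funnel_thresholds(), concordance = TRUE,
                          name = "RadR") {
  s1 <- apply_de_filter(de_frame(tbl$gene, tbl$fc_s1, NA_real_, tbl$fdr_s1), th)
  s2 <- apply_de_filter(de_frame(tbl$gene, tbl$fc_s2, NA_real_, tbl$fdr_s2), th)
  s3 <- tbl[!is.na(tbl$p) & tbl$p < th$cox_p_max, c("gene", "hr", "p")]
  names(s3)[3] <- "p_value"
  select_signature(s1, s2, s3, concordance = concordance, name = name)
}

#' The packaged 13-gene radioresistance signature table
#'
#' Per-gene published statistics of the 13-gene signature: tumour-vs-normal
#' fold change and Holm-adjusted p (fc_s1, fdr_s1), radioresistant-vs-
#' radiosensitive cell-line fold change and adjusted p (fc_s2, fdr_s2), and
#' the multivariate Cox hazard ratio and p for disease-free survival (hr, p).
#' Adjusted p-values published as "< 0.0001" are stored as 1e-4.
#'
#' @return data.frame, one row per gene.
#' @export
radr_table1 <- function() {
  path <- system.file("extdata", "radr_table1.tsv", package = "radsig",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' The packaged 13-gene signature as a directional gene set
#'
#' Three genes over-expressed and ten under-expressed in the radioresistant
#' state (see [radr_table1()]).
#'
#' @return a [signature_gene_set()].
#' @export
radr_signature <- function() {
  tbl <- radr_table1()
  signature_gene_set("RadR",
                     up = tbl$gene[tbl$direction == "UP"],
                     dn = tbl$gene[tbl$direction == "DN"])
}
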