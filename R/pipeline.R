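# Orchestration: the two end-to-end entry points (discovery funnel and
# validation battery) plus the simulation bundle writer.  Configuration is a
# plain named list of paths (or in-memory objects); every run writes a
# machine-readable manifest with input hashes, seed and thresholds.

read_or_pass <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

file_digest <- function(path) {
  if (is.character(path) && length(path) == 1L && file.exists(path))
    unname(tools::md5sum(path))
  else NA_character_
}

write_manifest <- function(out_dir, inputs, seed, extra = list()) {
  manifest <- c(list(
    package = "radsig",
    version = as.character(utils::packageVersion("radsig")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = lapply(inputs, function(p)
      list(path = if (is.character(p)) p else "<in-memory>",
           md5 = file_digest(p)))),
    extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

log_msg <- function(log_con, fmt, ...) {
  msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the discovery funnel end to end
#'
#' Executes the sequential funnel: stage 1 on the paired tumour/normal
#' cohort, stage 2 on the cell-line panel restricted to stage-1 survivors,
#' stage 3 on the stage-1/stage-2 intersection, then the direction-concordant
#' signature selection.  Writes (when `out_dir` is given) the signature GMT,
#' a summary-table TSV, stage-by-stage counts, a run log and a manifest.
#'
#' @param config named list with elements `paired_expr`, `paired_ann`,
#'   `cellline_expr`, `cellline_ann`, `survival_expr`, `survival_records`
#'   (each a path or an in-memory object), optional `thresholds`
#'   ([funnel_thresholds()]), `concordance`, `name`.
#' @param out_dir optional output directory.
#' @param seed seed recorded in the manifest (the funnel itself is
#'   deterministic).
#' @return list with `signature`, `table`, per-stage results and counts.
#' @export
run_discovery <- function(config, out_dir = NULL, seed = 1L) {
  th <- config$thresholds %||% funnel_thresholds()
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file(file.path(out_dir, "discovery.log"), "w")
    on.exit(close(log_con))
  }
  paired_expr <- read_or_pass(config$paired_expr, read_gct)
  paired_ann <- read_or_pass(config$paired_ann,
                             function(p) read_clinical(p, "annotation"))
  cl_expr <- read_or_pass(config$cellline_expr, read_gct)
  cl_ann <- read_or_pass(config$cellline_ann,
                         function(p) read_clinical(p, "annotation"))
  sv_expr <- read_or_pass(config$survival_expr, read_gct)
  sv_rec <- read_or_pass(config$survival_records,
                         function(p) read_clinical(p, "survival"))

  log_msg(log_con, "stage 1: paired tumor-vs-normal (%d genes)", nrow(paired_expr))
  s1 <- stage1_tumor_vs_normal(paired_expr, paired_ann, th)
  log_msg(log_con, "stage 1 passed: %d genes", nrow(s1))
  if (!nrow(s1)) stop_radsig("stage 1 selected no genes; funnel cannot proceed")

  cand1 <- intersect(s1$gene, rownames(cl_expr))
  log_msg(log_con, "stage 2: cell-line ANOVA on %d stage-1 survivors", length(cand1))
  s2 <- stage2_radioresistance(cl_expr[cand1, , drop = FALSE], cl_ann, th)
  log_msg(log_con, "stage 2 passed: %d genes", nrow(s2))
  if (!nrow(s2)) stop_radsig("stage 2 selected no genes; funnel cannot proceed")

  cand2 <- intersect(intersect(s1$gene, s2$gene), rownames(sv_expr))
  log_msg(log_con, "stage 3: Cox screen on %d candidates", length(cand2))
  s3 <- stage3_cox_screen(sv_expr, sv_rec, cand2, th)
  log_msg(log_con, "stage 3 passed: %d genes", nrow(s3))

  sig <- select_signature(s1, s2, s3,
                          concordance = config$concordance %||% TRUE,
                          name = config$name %||% "RadR")
  tbl <- funnel_table(s1, s2, s3, sig)
  counts <- c(stage1 = nrow(s1), stage2 = nrow(s2), stage3 = nrow(s3),
              signature = length(sig$up) + length(sig$dn))
  log_msg(log_con, "signature: %d up, %d dn", length(sig$up), length(sig$dn))

  if (!is.null(out_dir)) {
    if (length(sig$up) + length(sig$dn) > 0)
      write_gmt(sig, file.path(out_dir, "signature.gmt"))
    write_clinical(tbl, file.path(out_dir, "signature_table.tsv"))
    write_clinical(data.frame(stage = names(counts), n = as.integer(counts)),
                   file.path(out_dir, "stage_counts.tsv"))
    write_manifest(out_dir,
                   config[c("paired_expr", "paired_ann", "cellline_expr",
                            "cellline_ann", "survival_expr", "survival_records")],
                   seed,
                   list(thresholds = unclass(th),
                        concordance = config$concordance %||% TRUE))
  }
  list(signature = sig, table = tbl, stage1 = s1, stage2 = s2, stage3 = s3,
       counts = counts)
}

#' Run the validation battery on one or more datasets
#'
#' For each dataset entry, computes the per-sample signature score and then
#' whichever analyses its annotations support: paired tumour-vs-normal score
#' comparison, radioresistance-group comparison, median-split survival,
#' subtype / HPV / genotype group comparisons, and correlation screens
#' against hallmark ES, protein and drug-IC50 matrices.  Analyses whose
#' required annotations are absent are skipped with a logged reason.
#'
#' @param signature a [signature_gene_set()] or path to a 2-set GMT
#'   (`<name>_UP` / `<name>_DN`).
#' @param datasets named list of dataset entries; each a list with `expr`
#'   (path or matrix) and optional `ann`, `surv`, `hallmarks`, `proteins`,
#'   `ic50`.
#' @param params an [ssgsea_params()] object.
#' @param out_dir optional output directory (one TSV per analysis plus a
#'   combined summary).
#' @param screen_r_min,screen_p_max hit thresholds for the correlation
#'   screens.
#' @return list per dataset: `scores` plus one entry per executed analysis,
#'   and `summary`, a data.frame of every analysis with its headline
#'   statistic, p-value and status (run/skipped).
#' @export
run_validation <- function(signature, datasets, params = ssgsea_params(),
                           out_dir = NULL, screen_r_min = 0.2,
                           screen_p_max = 0.01) {
  if (is.character(signature)) {
    sets <- read_gmt(signature)
    up <- sets[[grep("_UP$", names(sets))[1L]]] %||% character()
    dn <- sets[[grep("_DN$", names(sets))[1L]]] %||% character()
    signature <- signature_gene_set(sub("_UP$", "", names(sets)[1L]), up, dn)
  }
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file(file.path(out_dir, "validation.log"), "w")
    on.exit(close(log_con))
  }
  summary_rows <- list()
  note <- function(dataset, analysis, status, stat = NA, p = NA, reason = "") {
    summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
      dataset = dataset, analysis = analysis, status = status,
      statistic = stat, p_value = p, reason = reason,
      stringsAsFactors = FALSE)
  }
  results <- lapply(names(datasets), function(ds_name) {
    ds <- datasets[[ds_name]]
    expr <- read_or_pass(ds$expr, read_gct)
    ann <- if (!is.null(ds$ann))
      read_or_pass(ds$ann, function(p) read_clinical(p, "annotation")) else NULL
    surv <- if (!is.null(ds$surv))
      read_or_pass(ds$surv, function(p) read_clinical(p, "survival")) else NULL
    out <- list(scores = score_signature(expr, signature, params))
    scores <- out$scores
    skip <- function(analysis, reason) {
      log_msg(log_con, "WARNING [%s] skipping %s: %s", ds_name, analysis, reason)
      note(ds_name, analysis, "skipped", reason = reason)
    }
    # paired tumour-vs-normal score comparison
    if (!is.null(ann) && "pair_id" %in% names(ann) &&
        any(!is.na(ann$pair_id))) {
      pr <- ann[!is.na(ann$pair_id) & ann$sample_id %in% names(scores), ]
      pids <- intersect(pr$pair_id[pr$tissue == "tumor"],
                        pr$pair_id[pr$tissue == "normal"])
      if (length(pids) >= 3L) {
        t_s <- scores[pr$sample_id[match(paste0(pids, ".tumor"),
                                         paste0(pr$pair_id, ".", pr$tissue))]]
        n_s <- scores[pr$sample_id[match(paste0(pids, ".normal"),
                                         paste0(pr$pair_id, ".", pr$tissue))]]
        out$paired_score <- paired_wilcoxon(t_s, n_s)
        note(ds_name, "paired_score", "run", out$paired_score$statistic,
             out$paired_score$p_value)
      } else skip("paired_score", "fewer than 3 complete pairs")
    } else skip("paired_score", "no pairing annotation")
    # radioresistance-group comparison
    if (!is.null(ann) && "rr_label" %in% names(ann) &&
        sum(!is.na(ann$rr_label)) >= 4L) {
      lab <- stats::setNames(ann$rr_label, ann$sample_id)
      lab[!lab %in% c("radioresistant", "radiosensitive")] <- NA
      res <- tryCatch(compare_groups(scores, lab),
                      radsig_error = function(e) NULL)
      if (!is.null(res)) {
        out$rr_groups <- res
        note(ds_name, "rr_groups", "run", res$statistic, res$p_value)
      } else skip("rr_groups", "fewer than 2 usable radioresistance groups")
    } else skip("rr_groups", "no radioresistance labels")
    # median-split survival
    if (!is.null(surv)) {
      res <- tryCatch(median_split_survival(scores, surv),
                      radsig_error = function(e) NULL)
      if (!is.null(res)) {
        out$survival <- res
        note(ds_name, "survival", "run", res$logrank$statistic,
             res$logrank$p_value)
      } else skip("survival", "median split not possible")
    } else skip("survival", "no survival table")
    # subtype and HPV group comparisons
    for (col in c("subtype", "hpv_status")) {
      if (!is.null(ann) && col %in% names(ann) && sum(!is.na(ann[[col]])) >= 4L) {
        lab <- stats::setNames(ann[[col]], ann$sample_id)
        res <- tryCatch(suppressWarnings(compare_groups(scores, lab)),
                        radsig_error = function(e) NULL)
        if (!is.null(res)) {
          out[[col]] <- res
          note(ds_name, col, "run", res$statistic, res$p_value)
        } else skip(col, "fewer than 2 usable groups")
      } else skip(col, sprintf("no %s labels", col))
    }
    # correlation screens
    for (panel in c("hallmarks", "proteins", "ic50")) {
      if (is.null(ds[[panel]])) { skip(panel, "panel not configured"); next }
      feat <- if (panel == "hallmarks") {
        sets <- read_or_pass(ds$hallmarks, read_gmt)
        suppressWarnings(score_collection(expr, sets, params))
      } else read_or_pass(ds[[panel]], function(p) as.matrix(
        utils::read.table(p, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)))
      scr <- correlate_with_matrix(scores, feat, r_min = screen_r_min,
                                   p_max = screen_p_max,
                                   sign = if (panel == "ic50") "positive" else "any")
      out[[panel]] <- scr
      note(ds_name, panel, "run", sum(scr$table$hit), NA)
      if (!is.null(out_dir))
        write_clinical(scr$table,
                       file.path(out_dir, sprintf("%s_%s_screen.tsv", ds_name, panel)))
    }
    if (!is.null(out_dir))
      write_scores(scores, file.path(out_dir, sprintf("%s_scores.tsv", ds_name)))
    out
  })
  names(results) <- names(datasets)
  summary <- do.call(rbind, summary_rows)
  if (!is.null(out_dir)) {
    write_clinical(summary, file.path(out_dir, "validation_summary.tsv"))
    write_manifest(out_dir, lapply(datasets, `[[`, "expr"), NA,
                   list(signature = signature$name,
                        params = unclass(params)))
  }
  results$summary <- summary
  results
}

#' Write a complete synthetic bundle to disk
#'
#' Generates the paired cohort, cell-line panel, survival cohort and feature
#' panels for one (config, seed) and writes them as GCT / CSV / GMT / TSV
#' plus a ground-truth JSON.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
simulate_bundle <- function(cfg = generator_config(), seed = 1L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paired <- generate_paired_cohort(cfg, seed)
  cells <- generate_cellline_panel(cfg, seed)
  surv <- generate_survival_cohort(cfg, seed)
  panels <- generate_feature_panels(cfg, seed)
  p <- function(...) file.path(out_dir, ...)
  write_gct(paired$expr, p("paired_expr.gct"))
  write_clinical(paired$ann, p("paired_ann.csv"))
  write_gct(cells$expr, p("cellline_expr.gct"))
  write_clinical(cells$ann, p("cellline_ann.csv"))
  write_gct(surv$expr, p("survival_expr.gct"))
  write_clinical(surv$ann, p("survival_ann.csv"))
  write_clinical(surv$surv, p("survival_records.csv"))
  write_gct(panels$expr, p("panel_expr.gct"))
  write_gmt(panels$hallmarks, p("hallmarks.gmt"))
  utils::write.table(cbind(feature = rownames(panels$ic50), panels$ic50),
                     p("ic50.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(feature = rownames(panels$proteins), panels$proteins),
                     p("proteins.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(paired = paired$truth, cellline = cells$truth,
                survival = surv$truth[c("planted_up", "planted_dn",
                                        "log_hr_per_unit")],
                panels = panels$truth[c("planted_hallmark", "planted_drugs",
                                        "planted_protein")])
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, list(), seed, list(config = unclass(cfg)))
  invisible(list.files(out_dir, full.names = TRUE))
}
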