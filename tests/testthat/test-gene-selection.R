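# The three-stage funnel: fold-change conventions, cell-line classification,
# planted-signal recovery against generator truth, intersection semantics and
# threshold monotonicity.

test_that("signed_fold_change follows the signed-ratio convention", {
  expect_equal(signed_fold_change(4, 2), 2)
  expect_equal(signed_fold_change(2, 4), -2)
  expect_equal(signed_fold_change(3, 3), 1)
  expect_equal(signed_fold_change(c(4, 2), c(2, 4)), c(2, -2))
  expect_true(all(abs(signed_fold_change(runif(50, 0.1, 10),
                                         runif(50, 0.1, 10))) >= 1))
  expect_error(signed_fold_change(-1, 2), "positive")
})

test_that("classify_cell_line applies the SF2 and AUC cutoffs", {
  expect_equal(classify_cell_line(sf2 = 0.1), "radiosensitive")
  expect_equal(classify_cell_line(sf2 = 0.85), "radioresistant")
  expect_equal(classify_cell_line(sf2 = 0.5), "intermediate")
  expect_equal(classify_cell_line(auc = c(2.5, 1.2), mode = "auc"),
               c("radioresistant", "radiosensitive"))
  expect_error(classify_cell_line(mode = "sf2"), "requires sf2")
  expect_error(classify_cell_line(sf2 = 1.3), "\\[0,1\\]")
})

test_that("stage1 returns nothing when tumor equals normal", {
  expr <- tiny_expr(20, 8)
  ann <- data.frame(sample_id = colnames(expr),
                    tissue = rep(c("tumor", "normal"), 4),
                    pair_id = rep(paste0("p", 1:4), each = 2))
  # tumor identical to its paired normal
  for (p in 1:4) expr[, 2 * p - 1] <- expr[, 2 * p]
  expect_equal(nrow(stage1_tumor_vs_normal(expr, ann)), 0)
})

test_that("stage1 recovers planted genes and is scale invariant", {
  cfg <- generator_config(n_genes = 1010, n_pairs = 40, planted_up = 10,
                          planted_dn = 0)
  co <- generate_paired_cohort(cfg, 1)
  s1 <- stage1_tumor_vs_normal(co$expr, co$ann)
  rec <- intersect(s1$gene, co$truth$planted_up)
  expect_gte(length(rec), 9)
  expect_true(all(s1$direction[s1$gene %in% rec] == "UP"))
  expect_lte(sum(!s1$gene %in% co$truth$planted_up), 5)
  # doubling all linear values = +1 on log2: selection unchanged
  s1b <- stage1_tumor_vs_normal(expression_matrix(unclass(co$expr) + 1),
                                co$ann)
  expect_equal(s1b$gene, s1$gene)
  expect_equal(s1b$direction, s1$direction)
})

test_that("stage2 recovers planted genes, respects blocking, reports timepoints", {
  cfg <- generator_config(n_genes = 400)
  cp <- generate_cellline_panel(cfg, 1)
  planted <- c(cp$truth$planted_up, cp$truth$planted_dn)
  # funnel-style candidate set: planted genes plus null and nuisance genes
  cand <- unique(c(planted, cp$truth$nuisance_genes[1:5],
                   setdiff(rownames(cp$expr), planted)[1:10]))
  s2 <- stage2_radioresistance(cp$expr[cand, ], cp$ann)
  expect_gte(length(intersect(s2$gene, planted)), 12)  # >= 90% of 13
  expect_true(all(s2$direction[s2$gene %in% cp$truth$planted_up] == "UP"))
  expect_true(all(s2$direction[s2$gene %in% cp$truth$planted_dn] == "DN"))
  # timepoint-only nuisance genes are not selected by the blocked ANOVA
  expect_length(intersect(s2$gene, cp$truth$nuisance_genes), 0)
  # companion per-timepoint report covers every selected gene at 3 timepoints
  rep_tbl <- attr(s2, "timepoint_report")
  expect_setequal(unique(rep_tbl$gene), s2$gene)
  expect_equal(sort(unique(rep_tbl$timepoint)), c("t0", "t2h", "t6h"))
  # identical groups -> empty
  expr0 <- cp$expr[cand, ]
  ann0 <- cp$ann
  ann0$rr_label <- rep(c("radioresistant", "radiosensitive"),
                       length.out = nrow(ann0))
  set.seed(1)
  expr_null <- expression_matrix(matrix(rnorm(length(cand) * nrow(ann0), 8, 1),
                                        length(cand), nrow(ann0),
                                        dimnames = list(cand, ann0$sample_id)))
  expect_equal(nrow(stage2_radioresistance(expr_null, ann0)), 0)
})

test_that("stage2 warns and falls back with a single timepoint", {
  cfg <- generator_config(n_genes = 50)
  cp <- generate_cellline_panel(cfg, 2)
  ann <- cp$ann[cp$ann$timepoint == "t0", ]
  expect_warning(stage2_radioresistance(cp$expr[, ann$sample_id], ann),
                 "single timepoint")
})

test_that("stage3 retains planted genes with correctly signed HR", {
  cfg <- generator_config(n_genes = 300)
  sc <- generate_survival_cohort(cfg, 1)
  planted <- c(sc$truth$planted_up, sc$truth$planted_dn)
  s3 <- stage3_cox_screen(sc$expr, sc$surv, planted)
  expect_gte(nrow(s3), 11)  # >= 80% of 13
  expect_true(all(s3$hr[s3$gene %in% sc$truth$planted_up] > 1))
  expect_true(all(s3$hr[s3$gene %in% sc$truth$planted_dn] < 1))
})

test_that("stage3 reports degenerate genes instead of dropping them silently", {
  cfg <- generator_config(n_genes = 60)
  sc <- generate_survival_cohort(cfg, 3)
  expr <- unclass(sc$expr)
  expr["G00030", ] <- 5  # constant gene
  expr <- expression_matrix(expr)
  expect_warning(
    s3 <- stage3_cox_screen(expr, sc$surv, c("G00001", "G00030")),
    "G00030")
  expect_equal(attr(s3, "excluded"), "G00030")
  expect_error(stage3_cox_screen(sc$expr, sc$surv[1:20, ], "G00001"),
               ">= 30 subjects")
})

test_that("select_signature implements intersection and concordance semantics", {
  s1 <- data.frame(gene = c("A", "B", "C"), direction = c("UP", "DN", "UP"))
  s2 <- data.frame(gene = c("A", "B", "D"), direction = c("UP", "UP", "DN"))
  s3 <- data.frame(gene = c("A", "B", "E"))
  sig <- select_signature(s1, s2, s3)
  expect_equal(sig$up, "A")       # B discordant, dropped
  expect_length(sig$dn, 0)
  sig2 <- select_signature(s1, s2, s3, concordance = FALSE)
  expect_setequal(c(sig2$up, sig2$dn), c("A", "B"))
  expect_equal(sig2$dn, "B")      # membership follows stage-1 direction
  expect_warning(
    empty <- select_signature(s1, data.frame(gene = "Z", direction = "UP"), s3),
    "empty signature")
  expect_length(c(empty$up, empty$dn), 0)
})

test_that("funnel is monotone in thresholds and invariant to input order", {
  cfg <- generator_config(n_genes = 150, n_pairs = 20)
  co <- generate_paired_cohort(cfg, 4)
  loose <- stage1_tumor_vs_normal(co$expr, co$ann, funnel_thresholds(0.2, 1))
  tight <- stage1_tumor_vs_normal(co$expr, co$ann, funnel_thresholds(0.01, 1.5))
  expect_true(all(tight$gene %in% loose$gene))
  # permute genes and samples: identical selection
  g_perm <- sample(nrow(co$expr)); s_perm <- sample(ncol(co$expr))
  expr_p <- expression_matrix(unclass(co$expr)[g_perm, s_perm])
  s1a <- stage1_tumor_vs_normal(co$expr, co$ann)
  s1b <- stage1_tumor_vs_normal(expr_p, co$ann[s_perm, ])
  expect_equal(s1a, s1b, ignore_attr = TRUE)
})

test_that("the packaged signature table replays to 3 up and 10 dn genes", {
  tbl <- radr_table1()
  expect_equal(nrow(tbl), 13)
  sig <- funnel_replay(tbl)
  expect_length(c(sig$up, sig$dn), 13)
  expect_length(sig$up, 3)
  expect_length(sig$dn, 10)
  expect_setequal(sig$up, c("CSTF3", "ST3GAL5", "UFD1L"))
  expect_equal(radr_signature()$dn, sort(tbl$gene[tbl$direction == "DN"]))
  # tightening the Cox threshold below the largest printed p drops genes
  sig2 <- funnel_replay(tbl, funnel_thresholds(cox_p_max = 0.03))
  expect_lt(length(c(sig2$up, sig2$dn)), 13)
})
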