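# Synthetic-cohort generators with known ground truth.  Every cohort type the
# pipeline consumes can be generated offline: a paired tumour/normal cohort
# with planted up/down genes, a radioresistant/radiosensitive cell-line panel
# measured at three post-irradiation timepoints, a survival cohort whose
# hazard depends on the planted genes, and hallmark/protein/drug feature
# panels correlated with a latent radioresistance score.  Expression is
# log-normal on the log2 scale with additive effects: all selection stages
# are rank- or ratio-based, so monotone structure is what matters.
# Determinism: identical (config, seed) give identical outputs (Mersenne-
# Twister, locally seeded).

#' Generator configuration
#'
#' Defaults mirror the designs the pipeline is meant to emulate: 40 tumour/
#' normal pairs, 32 cell lines split 18 radioresistant / 14 radiosensitive
#' measured at 3 timepoints, a 300-patient survival cohort, a signature of 3
#' planted up and 10 planted down genes, stage effects of linear fold change
#' 4 (tumour vs normal) and 2 (radioresistant vs radiosensitive), a per-gene
#' per-log2-unit log hazard ratio of 0.5, log2-scale noise sd 1, and 40%
#' censoring.
#'
#' @param n_genes total genes.
#' @param n_pairs tumour/normal pairs.
#' @param n_lines cell lines; `n_rr` of them radioresistant.
#' @param n_rr radioresistant lines.
#' @param n_patients survival-cohort size.
#' @param n_panel cell lines in the feature panels (drug/protein/hallmark);
#'   default 659, the size of the published pancancer drug-sensitivity panel.
#' @param planted_up,planted_dn planted signature sizes.
#' @param de_fc linear fold change of planted genes, tumour vs normal.
#' @param rr_fc linear fold change of planted genes, radioresistant vs
#'   radiosensitive lines.
#' @param log_hr_per_unit per-gene log hazard ratio per log2 expression unit.
#' @param noise_sd log2-scale residual sd.
#' @param censor_rate target censored fraction (independent exponential
#'   censoring).
#' @param subtype_shifts named numeric: latent-score shift per molecular
#'   subtype (applied through the planted genes).
#' @param n_planted_drugs drugs planted to correlate with the score (of 140).
#' @return list of class `radsig_genconfig`.
#' @export
generator_config <- function(n_genes = 2000L, n_pairs = 40L, n_lines = 32L,
                             n_rr = 18L, n_patients = 300L, n_panel = 659L,
                             planted_up = 3L, planted_dn = 10L,
                             de_fc = 4, rr_fc = 2, log_hr_per_unit = 0.5,
                             noise_sd = 1.0, censor_rate = 0.4,
                             subtype_shifts = c(atypical = -1, basal = 0,
                                                classical = 0, mesenchymal = 1),
                             n_planted_drugs = 4L) {
  cfg <- list(n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
              n_lines = as.integer(n_lines), n_rr = as.integer(n_rr),
              n_patients = as.integer(n_patients), n_panel = as.integer(n_panel),
              planted_up = as.integer(planted_up),
              planted_dn = as.integer(planted_dn),
              de_fc = de_fc, rr_fc = rr_fc, log_hr_per_unit = log_hr_per_unit,
              noise_sd = noise_sd, censor_rate = censor_rate,
              subtype_shifts = subtype_shifts,
              n_planted_drugs = as.integer(n_planted_drugs))
  bad <- character()
  if (cfg$planted_up + cfg$planted_dn > cfg$n_genes)
    bad <- c(bad, "planted_up + planted_dn exceeds n_genes")
  pos <- c("n_genes", "n_pairs", "n_lines", "n_rr", "n_patients", "n_panel")
  for (f in pos) if (cfg[[f]] <= 0L) bad <- c(bad, sprintf("%s must be positive", f))
  if (cfg$n_rr >= cfg$n_lines) bad <- c(bad, "n_rr must be below n_lines")
  if (cfg$de_fc < 1 || cfg$rr_fc < 1) bad <- c(bad, "fold changes must be >= 1")
  if (cfg$noise_sd <= 0) bad <- c(bad, "noise_sd must be positive")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    bad <- c(bad, "censor_rate must lie in [0,1)")
  if (!all(names(cfg$subtype_shifts) %in% .subtype_levels) ||
      is.null(names(cfg$subtype_shifts)))
    bad <- c(bad, "subtype_shifts must be named by molecular subtype")
  if (cfg$n_planted_drugs < 0L || cfg$n_planted_drugs > 140L)
    bad <- c(bad, "n_planted_drugs must lie in [0, 140]")
  if (length(bad))
    stop_radsig("invalid generator config: %s", paste(bad, collapse = "; "))
  structure(cfg, class = "radsig_genconfig")
}

gene_ids <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))

planted_genes <- function(cfg) {
  ids <- gene_ids(cfg)
  list(up = ids[seq_len(cfg$planted_up)],
       dn = ids[cfg$planted_up + seq_len(cfg$planted_dn)])
}

# 20 "hallmark program" genes driven by the latent score in the feature
# panels; positioned right after the planted signature block.
program_genes <- function(cfg) {
  ids <- gene_ids(cfg)
  n_sig <- cfg$planted_up + cfg$planted_dn
  n_prog <- min(20L, cfg$n_genes - n_sig)
  ids[n_sig + seq_len(n_prog)]
}

base_matrix <- function(cfg, sample_ids) {
  means <- stats::rnorm(cfg$n_genes, 8, 2)
  m <- means + matrix(stats::rnorm(cfg$n_genes * length(sample_ids),
                                   0, cfg$noise_sd),
                      cfg$n_genes, length(sample_ids))
  dimnames(m) <- list(gene_ids(cfg), sample_ids)
  m
}

#' Generate a paired tumour/normal cohort
#'
#' Baseline log2 expression is Normal(8, 2) per gene with per-sample noise sd
#' `noise_sd`; planted up (down) genes are shifted by +log2(de_fc)
#' (-log2(de_fc)) in the tumour member of each pair.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed; identical (cfg, seed) give identical output.
#' @return list with `expr` ([expression_matrix()]), `ann`
#'   ([sample_annotation()] with pairing) and `truth` (planted gene lists and
#'   effect sizes).
#' @export
generate_paired_cohort <- function(cfg = generator_config(), seed = 1L) {
  with_seed(derive_seed(seed, 11L), {
    pid <- sprintf("P%03d", seq_len(cfg$n_pairs))
    ids <- c(paste0(pid, "T"), paste0(pid, "N"))
    m <- base_matrix(cfg, ids)
    pl <- planted_genes(cfg)
    shift <- log2(cfg$de_fc)
    tum <- seq_len(cfg$n_pairs)
    m[pl$up, tum] <- m[pl$up, tum] + shift
    m[pl$dn, tum] <- m[pl$dn, tum] - shift
    ann <- sample_annotation(data.frame(
      sample_id = ids,
      tissue = rep(c("tumor", "normal"), each = cfg$n_pairs),
      pair_id = c(pid, pid), stringsAsFactors = FALSE))
    list(expr = expression_matrix(m), ann = ann,
         truth = list(planted_up = pl$up, planted_dn = pl$dn,
                      de_log2fc = shift))
  })
}

#' Generate a radioresistant/radiosensitive cell-line panel
#'
#' `n_lines` lines (first `n_rr` radioresistant), each measured at timepoints
#' t0, t2h and t6h.  Planted genes are shifted by +/- log2(rr_fc) in
#' radioresistant lines at every timepoint.  A random 10% of the remaining
#' genes receive a nuisance timepoint main effect (so a test that fails to
#' block on timepoint would select them).  SF2 values are drawn so that the
#' labels honour the SF2 < 0.2 / > 0.8 classification rule, and clonogenic
#' AUC values so that the 2.0 cutoff agrees.
#'
#' @inheritParams generate_paired_cohort
#' @return list with `expr`, `ann` (rr_label, timepoint, sf2, auc, line_id)
#'   and `truth` (planted and nuisance gene lists).
#' @export
generate_cellline_panel <- function(cfg = generator_config(), seed = 1L) {
  with_seed(derive_seed(seed, 23L), {
    lines <- sprintf("CL%02d", seq_len(cfg$n_lines))
    rr <- rep(c("radioresistant", "radiosensitive"),
              c(cfg$n_rr, cfg$n_lines - cfg$n_rr))
    tps <- .tp_levels
    ids <- as.vector(outer(lines, tps, paste, sep = "_"))
    m <- base_matrix(cfg, ids)
    pl <- planted_genes(cfg)
    shift <- log2(cfg$rr_fc)
    rr_cols <- rep(rr, times = length(tps)) == "radioresistant"
    m[pl$up, rr_cols] <- m[pl$up, rr_cols] + shift
    m[pl$dn, rr_cols] <- m[pl$dn, rr_cols] - shift
    pool <- setdiff(gene_ids(cfg), c(pl$up, pl$dn))
    nuis <- sample(pool, round(0.1 * length(pool)))
    if (length(nuis)) {
      eff <- matrix(stats::rnorm(length(nuis) * 2L, 0, 0.7), ncol = 2L)
      tp_of <- rep(tps, each = cfg$n_lines)
      m[nuis, tp_of == "t2h"] <- m[nuis, tp_of == "t2h"] + eff[, 1L]
      m[nuis, tp_of == "t6h"] <- m[nuis, tp_of == "t6h"] + eff[, 2L]
    }
    sf2 <- ifelse(rr == "radioresistant", stats::runif(cfg$n_lines, 0.82, 0.95),
                  stats::runif(cfg$n_lines, 0.05, 0.18))
    auc <- ifelse(rr == "radioresistant", stats::runif(cfg$n_lines, 2.1, 3.5),
                  stats::runif(cfg$n_lines, 0.8, 1.9))
    ann <- sample_annotation(data.frame(
      sample_id = ids, tissue = "cell_line",
      rr_label = rep(rr, times = length(tps)),
      timepoint = rep(tps, each = cfg$n_lines),
      sf2 = rep(sf2, times = length(tps)),
      auc = rep(auc, times = length(tps)),
      line_id = rep(lines, times = length(tps)),
      stringsAsFactors = FALSE))
    list(expr = expression_matrix(m), ann = ann,
         truth = list(planted_up = pl$up, planted_dn = pl$dn,
                      rr_log2fc = shift, nuisance_genes = nuis))
  })
}

#' Generate a survival cohort with expression-linked hazard
#'
#' Tumour-like expression with the planted genes as in the paired cohort.
#' Each planted gene carries a per-log2-unit log hazard ratio of
#' `log_hr_per_unit` (positive for up genes, negative for dn genes); event
#' times are exponential with hazard proportional to
#' exp(sum of per-gene effects + small age/node/tumour-stage effects), with
#' independent exponential censoring calibrated to `censor_rate`.  Molecular
#' subtype labels are drawn uniformly and `subtype_shifts` are applied
#' through the planted genes (default: atypical lowest, mesenchymal
#' highest), so they shift both the latent score and the hazard.
#'
#' @inheritParams generate_paired_cohort
#' @return list with `expr`, `surv` ([survival_records()]), `ann` (subtype,
#'   HPV status) and `truth` (planted genes, per-gene log hazard ratios, and
#'   the per-sample latent score mean(up) - mean(dn)).
#' @export
generate_survival_cohort <- function(cfg = generator_config(), seed = 1L) {
  with_seed(derive_seed(seed, 37L), {
    ids <- sprintf("PT%04d", seq_len(cfg$n_patients))
    m <- base_matrix(cfg, ids)
    pl <- planted_genes(cfg)
    shift <- log2(cfg$de_fc)
    m[pl$up, ] <- m[pl$up, ] + shift
    m[pl$dn, ] <- m[pl$dn, ] - shift
    subtypes <- names(cfg$subtype_shifts)
    st <- sample(subtypes, cfg$n_patients, replace = TRUE)
    delta <- cfg$subtype_shifts[st]
    m[pl$up, ] <- m[pl$up, ] + rep(delta / 2, each = length(pl$up))
    m[pl$dn, ] <- m[pl$dn, ] - rep(delta / 2, each = length(pl$dn))
    up_block <- m[pl$up, , drop = FALSE]
    dn_block <- m[pl$dn, , drop = FALSE]
    latent <- colMeans(up_block) - colMeans(dn_block)
    centered <- function(b) b - rowMeans(b)
    lp_gene <- cfg$log_hr_per_unit *
      (colSums(centered(up_block)) - colSums(centered(dn_block)))
    age <- round(stats::rnorm(cfg$n_patients, 62, 10))
    node <- stats::rbinom(cfg$n_patients, 1L, 0.5)
    tum <- stats::rbinom(cfg$n_patients, 1L, 0.5)
    lp <- lp_gene + 0.01 * (age - 62) + 0.2 * node + 0.2 * tum
    lambda0 <- log(2) / 30  # baseline median DFS ~ 30 months
    t_event <- stats::rexp(cfg$n_patients, rate = lambda0 * exp(lp))
    if (cfg$censor_rate > 0) {
      lambda_c <- lambda0 * cfg$censor_rate / (1 - cfg$censor_rate)
      t_cens <- stats::rexp(cfg$n_patients, rate = lambda_c)
    } else t_cens <- rep(Inf, cfg$n_patients)
    surv <- survival_records(data.frame(
      sample_id = ids,
      time = pmax(pmin(t_event, t_cens), 0.01),
      event = as.integer(t_event <= t_cens),
      age = age, node_stage = node, tumor_stage = tum,
      stringsAsFactors = FALSE))
    ann <- sample_annotation(data.frame(
      sample_id = ids, tissue = "tumor", subtype = st,
      hpv_status = "negative", stringsAsFactors = FALSE))
    list(expr = expression_matrix(m), surv = surv, ann = ann,
         truth = list(planted_up = pl$up, planted_dn = pl$dn,
                      log_hr_per_unit = cfg$log_hr_per_unit,
                      latent_score = stats::setNames(latent, ids),
                      subtype = stats::setNames(st, ids)))
  })
}

# Hallmark set membership must be identical across dataset seeds (a shared
# namespace for the consensus rule), so it is derived from the config alone
# with a fixed internal seed.
hallmark_collection <- function(cfg) {
  ids <- gene_ids(cfg)
  prog <- program_genes(cfg)
  pool <- setdiff(ids, c(unlist(planted_genes(cfg)), prog))
  sets <- vector("list", 48L)
  names(sets) <- sprintf("HALLMARK_SYN%02d", 1:48)
  extra <- with_seed(990001L, sample(pool, min(5L, length(pool))))
  sets[[1L]] <- c(prog, extra)
  for (k in 2:48) {
    sets[[k]] <- with_seed(990000L + k,
                           sample(pool, min(25L, length(pool))))
  }
  gene_set_collection(sets)
}

#' Generate hallmark/protein/drug feature panels
#'
#' A panel of `n_panel` cell lines with a latent radioresistance score u ~
#' Normal(0, 1): planted signature genes load on u with slope +/- 1 (log2
#' units), so the enrichment score of the planted signature tracks u; a
#' 20-gene "program" block loads on u with slope 0.8 and forms the planted
#' hallmark set (first of 48 synthetic hallmark sets; the other 47 are fixed
#' random sets, identical across seeds).  Of 140 drugs, `n_planted_drugs`
#' have IC50 correlated with u (true r = 0.5, higher score = higher IC50 =
#' less sensitive... the positive-correlation structure of the published
#' four-drug result); the rest are null.  One of 30 protein features tracks
#' mean planted-up-gene expression.
#'
#' @inheritParams generate_paired_cohort
#' @return list with `expr`, `hallmarks` ([gene_set_collection()]), `ic50`
#'   (drugs x lines), `proteins` (features x lines), `ann` and `truth`
#'   (planted hallmark/drug/protein names and the latent u).
#' @export
generate_feature_panels <- function(cfg = generator_config(), seed = 1L) {
  with_seed(derive_seed(seed, 53L), {
    n <- cfg$n_panel
    ids <- sprintf("LINE%03d", seq_len(n))
    u <- stats::rnorm(n)
    m <- base_matrix(cfg, ids)
    pl <- planted_genes(cfg)
    prog <- program_genes(cfg)
    m[pl$up, ] <- m[pl$up, ] + rep(u, each = length(pl$up))
    m[pl$dn, ] <- m[pl$dn, ] - rep(u, each = length(pl$dn))
    m[prog, ] <- m[prog, ] + rep(0.8 * u, each = length(prog))
    hallmarks <- hallmark_collection(cfg)
    drugs <- sprintf("D%03d", seq_len(140L))
    ic50 <- matrix(stats::rnorm(140L * n), 140L, n,
                   dimnames = list(drugs, ids))
    if (cfg$n_planted_drugs > 0L) {
      for (k in seq_len(cfg$n_planted_drugs)) {
        ic50[k, ] <- 0.5 * u + sqrt(1 - 0.25) * stats::rnorm(n)
      }
    }
    prot <- matrix(stats::rnorm(30L * n), 30L, n,
                   dimnames = list(sprintf("PR%02d", 1:30), ids))
    prot[1L, ] <- colMeans(m[pl$up, , drop = FALSE]) + stats::rnorm(n, 0, 0.5)
    ann <- sample_annotation(data.frame(
      sample_id = ids, tissue = "cell_line", stringsAsFactors = FALSE))
    list(expr = expression_matrix(m), hallmarks = hallmarks, ic50 = ic50,
         proteins = prot, ann = ann,
         truth = list(planted_up = pl$up, planted_dn = pl$dn,
                      planted_hallmark = names(hallmarks)[1L],
                      planted_drugs = if (cfg$n_planted_drugs > 0L)
                        drugs[seq_len(cfg$n_planted_drugs)] else character(),
                      planted_protein = "PR01",
                      latent = stats::setNames(u, ids)))
  })
}

#' Null generator configuration
#'
#' The default configuration with every planted effect removed: fold changes
#' 1, zero hazard effect, no subtype shifts, no planted drugs.  Used for
#' calibration tests.
#'
#' @param ... overrides passed on to [generator_config()].
#' @return a [generator_config()].
#' @export
null_config <- function(...) {
  generator_config(de_fc = 1, rr_fc = 1, log_hr_per_unit = 0,
                   subtype_shifts = c(atypical = 0, basal = 0,
                                      classical = 0, mesenchymal = 0),
                   n_planted_drugs = 0L, ...)
}
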