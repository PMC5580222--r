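# Single-sample gene-set enrichment (ssGSEA).  For one sample, genes are
# ranked by expression; walking the genes from the highest rank down, the
# enrichment score accumulates the difference between the rank^alpha-weighted
# empirical distribution of the in-set genes and the unweighted empirical
# distribution of the out-of-set genes.  The score depends on within-sample
# ranks only, which makes it robust to monotone platform effects.

#' Scoring parameters for single-sample enrichment
#'
#' @param alpha rank-weight exponent (>= 0).  0 gives unweighted
#'   Kolmogorov-Smirnov-style running sums; the conventional default is 0.75.
#' @param normalize divide each score row by its range across samples.
#' @param mode `"directional"` scores a signature as ES(up) - ES(dn);
#'   `"combined"` scores the union as a single set.
#' @return list of class `radsig_ssgsea_params`.
#' @export
ssgsea_params <- function(alpha = 0.75, normalize = FALSE,
                          mode = c("directional", "combined")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop_radsig("alpha must be a single non-negative number")
  structure(list(alpha = alpha, normalize = isTRUE(normalize), mode = mode),
            class = "radsig_ssgsea_params")
}

#' Rank genes within one sample
#'
#' Ranks 1..N with the largest expression receiving rank N; ties get the
#' average rank.  Missing values are excluded (their names are dropped).
#'
#' @param sample_values named numeric vector of per-gene expression for one
#'   sample (>= 2 non-missing values).
#' @return named rank vector.
#' @export
rank_genes <- function(sample_values) {
  if (is.null(names(sample_values)))
    stop_radsig("sample values must be named by gene")
  v <- sample_values[is.finite(sample_values)]
  if (length(v) < 2L) stop_radsig("need at least 2 non-missing gene values")
  rank(v, ties.method = "average")
}

# Core running-sum ES on a precomputed rank vector.  Traversal is by
# decreasing rank with ties broken by gene symbol, making the walk
# deterministic.  `ord` may be precomputed once per sample and reused across
# sets.
es_from_ranks <- function(r, in_set, alpha, ord = NULL) {
  if (is.null(ord)) ord <- order(-r, names(r), method = "radix")
  inb <- in_set[ord]
  w <- ifelse(inb, r[ord]^alpha, 0)
  sw <- sum(w)
  p_in <- cumsum(w) / sw
  p_out <- cumsum(!inb) / sum(!inb)
  sum(p_in - p_out)
}

#' Single-sample enrichment score for one gene set
#'
#' Positive when the set's genes concentrate at the top of the sample's
#' expression ranking, negative when at the bottom.
#'
#' @param sample_values named per-gene expression vector for one sample.
#' @param gene_set character vector of gene symbols; must intersect the
#'   expressed genes and must not cover all of them (the out-of-set
#'   complement is the reference).
#' @param params an [ssgsea_params()] object.
#' @return a single finite enrichment score.
#' @export
ssgsea_es <- function(sample_values, gene_set, params = ssgsea_params()) {
  r <- rank_genes(sample_values)
  in_set <- names(r) %in% gene_set
  if (!any(in_set))
    stop_radsig("no gene of the set is expressed; missing: %s",
                paste(utils::head(setdiff(gene_set, names(r)), 10), collapse = ", "))
  if (all(in_set))
    stop_radsig("gene set covers every expressed gene; the complement is empty")
  es_from_ranks(r, in_set, params$alpha)
}

#' Score a directional signature across samples
#'
#' Computes one radioresistance-style score per sample.  In directional mode
#' (default) the score is ES(up genes) - ES(dn genes), so coordinate
#' over-expression of the up genes and under-expression of the dn genes both
#' push the score up; combined mode scores the pooled set.  Signature genes
#' absent from the matrix trigger a warning below full overlap and an error
#' below 50% overlap.
#'
#' @param expr genes-by-samples log2 expression matrix.
#' @param sig a [signature_gene_set()].
#' @param params an [ssgsea_params()] object.
#' @return a score table (named numeric vector, one score per sample).
#' @export
score_signature <- function(expr, sig, params = ssgsea_params()) {
  assert_expression_matrix(expr)
  genes <- rownames(expr)
  all_sig <- c(sig$up, sig$dn)
  present <- all_sig %in% genes
  if (mean(present) < 0.5)
    stop_radsig("only %d/%d signature genes present; missing: %s",
                sum(present), length(all_sig),
                paste(all_sig[!present], collapse = ", "))
  if (!all(present))
    warn_radsig("%d/%d signature genes absent from the matrix: %s",
                sum(!present), length(all_sig),
                paste(all_sig[!present], collapse = ", "))
  up <- intersect(sig$up, genes); dn <- intersect(sig$dn, genes)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank_genes(expr[, j])
    if (params$mode == "combined") {
      es_from_ranks(r, names(r) %in% c(up, dn), params$alpha)
    } else {
      e_up <- if (length(up)) es_from_ranks(r, names(r) %in% up, params$alpha) else 0
      e_dn <- if (length(dn)) es_from_ranks(r, names(r) %in% dn, params$alpha) else 0
      e_up - e_dn
    }
  }, 1)
  if (params$normalize && length(scores) > 1L) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  score_table(scores, colnames(expr))
}

#' Enrichment-score matrix for a gene-set collection
#'
#' One ES per set and sample; sets with no gene in the matrix are skipped
#' with a warning.  Each sample is ranked once and reused across sets.
#'
#' @param expr genes-by-samples log2 expression matrix.
#' @param sets a [gene_set_collection()].
#' @param params an [ssgsea_params()] object.
#' @return numeric matrix, sets as rows, samples as columns.
#' @export
score_collection <- function(expr, sets, params = ssgsea_params()) {
  assert_expression_matrix(expr)
  if (!length(sets)) stop_radsig("empty gene-set collection")
  genes <- rownames(expr)
  overlap <- vapply(sets, function(s) sum(s %in% genes), 1L)
  if (any(overlap == 0L))
    warn_radsig("skipping %d gene set(s) with no expressed gene: %s",
                sum(overlap == 0L),
                paste(names(sets)[overlap == 0L], collapse = ", "))
  keep <- names(sets)[overlap > 0L & overlap < length(genes)]
  out <- matrix(NA_real_, length(keep), ncol(expr),
                dimnames = list(keep, colnames(expr)))
  memb <- lapply(sets[keep], function(s) genes %in% s)
  for (j in seq_len(ncol(expr))) {
    v <- expr[, j]
    fin <- is.finite(v)
    r <- rank(v[fin], ties.method = "average")
    ord <- order(-r, names(r), method = "radix")
    for (k in seq_along(keep)) {
      out[k, j] <- es_from_ranks(r, memb[[k]][fin], params$alpha, ord)
    }
  }
  if (params$normalize && ncol(out) > 1L) {
    rng <- apply(out, 1L, function(x) diff(range(x)))
    out <- sweep(out, 1L, ifelse(rng > 0, rng, 1), "/")
  }
  out
}
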