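#' Construct a validated expression matrix
#'
#' The substrate of every pipeline stage: a numeric genes-by-samples matrix of
#' log2-scale expression.  Row names are gene symbols, column names sample
#' identifiers; both must be unique and non-empty.  Missing values are
#' permitted (they are dropped pairwise by downstream statistics) but
#' non-finite values are not.
#'
#' @param values numeric matrix, genes as rows, samples as columns.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @return a numeric matrix of class `c("radsig_expr", "matrix")`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_radsig("expression values must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_radsig("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop_radsig("dimnames do not match matrix dimensions (%d x %d)",
                nrow(values), ncol(values))
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop_radsig("expression matrix must have at least one gene and one sample")
  if (anyDuplicated(gene_ids))
    stop_radsig("duplicate gene identifiers: %s",
                paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_radsig("duplicate sample identifiers: %s",
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- is.infinite(values) | is.nan(values)
  if (any(bad))
    stop_radsig("expression matrix contains %d non-finite values", sum(bad))
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("radsig_expr", class(matrix()))
  values
}

is_expression_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

assert_expression_matrix <- function(x) {
  if (!is_expression_matrix(x))
    stop_radsig("expected a genes-by-samples numeric matrix with dimnames")
  invisible(x)
}

.tissue_levels  <- c("tumor", "normal", "cell_line")
.rr_levels      <- c("radioresistant", "radiosensitive", "intermediate")
.tp_levels      <- c("t0", "t2h", "t6h")
.subtype_levels <- c("atypical", "basal", "classical", "mesenchymal")

#' Validate a sample-annotation table
#'
#' Required columns: `sample_id`, `tissue` (tumor / normal / cell_line).
#' Recognized optional columns: `pair_id` (links the tumor and normal sample
#' of one patient), `rr_label`, `sf2`, `auc`, `timepoint`, `subtype`,
#' `hpv_status`; any further columns are carried through untouched.
#' When `pair_id` values are present, each must be shared by exactly one
#' tumor and one normal sample.
#'
#' @param df data.frame of per-sample labels.
#' @return the validated data.frame (character columns, `NA` for absent
#'   optional fields).
#' @export
sample_annotation <- function(df) {
  if (!is.data.frame(df)) stop_radsig("annotations must be a data.frame")
  req <- c("sample_id", "tissue")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_radsig("annotation table missing required column(s): %s",
                paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_radsig("duplicate sample_id in annotations: %s",
                df$sample_id[duplicated(df$sample_id)][1])
  chk_enum <- function(col, levels) {
    if (!col %in% names(df)) return()
    v <- as.character(df[[col]])
    bad <- !is.na(v) & v != "" & !(v %in% levels)
    if (any(bad))
      stop_radsig("invalid %s value '%s' for sample %s (allowed: %s)",
                  col, v[bad][1], df$sample_id[bad][1],
                  paste(levels, collapse = ", "))
    df[[col]] <<- ifelse(v == "", NA_character_, v)
  }
  chk_enum("tissue", .tissue_levels)
  chk_enum("rr_label", .rr_levels)
  chk_enum("timepoint", .tp_levels)
  chk_enum("subtype", .subtype_levels)
  chk_enum("hpv_status", c("positive", "negative"))
  if (any(is.na(df$tissue)))
    stop_radsig("tissue missing for sample %s", df$sample_id[is.na(df$tissue)][1])
  if ("sf2" %in% names(df)) {
    sf2 <- suppressWarnings(as.numeric(df$sf2))
    bad <- !is.na(sf2) & (sf2 < 0 | sf2 > 1)
    if (any(bad))
      stop_radsig("sf2 outside [0,1] for sample %s", df$sample_id[bad][1])
    df$sf2 <- sf2
  }
  if ("auc" %in% names(df)) {
    auc <- suppressWarnings(as.numeric(df$auc))
    bad <- !is.na(auc) & auc <= 0
    if (any(bad))
      stop_radsig("auc must be positive for sample %s", df$sample_id[bad][1])
    df$auc <- auc
  }
  if ("pair_id" %in% names(df)) {
    df$pair_id <- as.character(df$pair_id)
    df$pair_id[df$pair_id == ""] <- NA_character_
    validate_pairing(df)
  }
  df
}

validate_pairing <- function(ann) {
  paired <- ann[!is.na(ann$pair_id), , drop = FALSE]
  for (pid in unique(paired$pair_id)) {
    grp <- paired[paired$pair_id == pid, , drop = FALSE]
    n_t <- sum(grp$tissue == "tumor")
    n_n <- sum(grp$tissue == "normal")
    if (n_t != 1L || n_n != 1L)
      stop_radsig(
        "pair_id '%s' must link exactly one tumor and one normal sample (found %d tumor, %d normal)",
        pid, n_t, n_n)
  }
  invisible(ann)
}

#' Validate a survival table
#'
#' Required columns: `sample_id`, `time` (months, strictly positive), `event`
#' (1 = recurrence/death, 0 = censored), `age` (years), `node_stage`
#' (0 = pN0-N1, 1 = pN2-N3) and `tumor_stage` (0 = pT1-T2, 1 = pT3-T4).
#'
#' @param df data.frame of time-to-event records.
#' @return the validated data.frame with numeric columns.
#' @export
survival_records <- function(df) {
  if (!is.data.frame(df)) stop_radsig("survival records must be a data.frame")
  req <- c("sample_id", "time", "event", "age", "node_stage", "tumor_stage")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_radsig("survival table missing required column(s): %s",
                paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_radsig("duplicate sample_id in survival table: %s",
                df$sample_id[duplicated(df$sample_id)][1])
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !is.na(df[[col]])
    if (any(bad))
      stop_radsig("unparseable %s value '%s' for sample %s",
                  col, as.character(df[[col]][bad][1]), df$sample_id[bad][1])
    v
  }
  df$time <- num("time"); df$event <- num("event"); df$age <- num("age")
  df$node_stage <- num("node_stage"); df$tumor_stage <- num("tumor_stage")
  for (col in req[-1]) {
    if (any(is.na(df[[col]])))
      stop_radsig("missing %s for sample %s", col, df$sample_id[is.na(df[[col]])][1])
  }
  if (any(df$time <= 0))
    stop_radsig("time must be strictly positive (sample %s)",
                df$sample_id[df$time <= 0][1])
  for (col in c("event", "node_stage", "tumor_stage")) {
    if (!all(df[[col]] %in% c(0, 1)))
      stop_radsig("%s must be 0/1 (sample %s)", col,
                  df$sample_id[!df[[col]] %in% c(0, 1)][1])
  }
  df
}

#' Construct a directional signature gene set
#'
#' A named pair of disjoint gene sets: `up` genes expected to be coordinately
#' over-expressed in the radioresistant state and `dn` genes under-expressed.
#'
#' @param name signature name.
#' @param up,dn character vectors of gene symbols; disjoint, jointly non-empty.
#' @return an object of class `radsig_signature`.
#' @export
signature_gene_set <- function(name, up = character(), dn = character()) {
  up <- unique(as.character(up)); dn <- unique(as.character(dn))
  if (length(intersect(up, dn)))
    stop_radsig("up and dn gene sets overlap: %s",
                paste(intersect(up, dn), collapse = ", "))
  if (length(up) + length(dn) == 0L)
    stop_radsig("signature must contain at least one gene")
  structure(list(name = as.character(name), up = sort(up), dn = sort(dn)),
            class = "radsig_signature")
}

#' @export
print.radsig_signature <- function(x, ...) {
  cat(sprintf("<radsig_signature> %s: %d up, %d dn\n",
              x$name, length(x$up), length(x$dn)))
  if (length(x$up)) cat("  up:", paste(x$up, collapse = " "), "\n")
  if (length(x$dn)) cat("  dn:", paste(x$dn, collapse = " "), "\n")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set name -> gene symbols).
#'   Names must be unique and every set non-empty.
#' @return named list of class `radsig_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop_radsig("gene-set collection must be a fully named list")
  if (anyDuplicated(names(sets)))
    stop_radsig("duplicate gene-set name: %s",
                names(sets)[duplicated(names(sets))][1])
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty))
    stop_radsig("empty gene set: %s", names(sets)[empty][1])
  structure(sets, class = "radsig_collection")
}

#' Construct a per-sample score table
#'
#' @param scores numeric vector of finite scores.
#' @param sample_ids identifiers, unique, same length as `scores`.
#' @return named numeric vector (names = sample ids).
#' @export
score_table <- function(scores, sample_ids = names(scores)) {
  if (is.null(sample_ids))
    stop_radsig("score table requires sample identifiers")
  sample_ids <- as.character(sample_ids)
  if (length(scores) != length(sample_ids))
    stop_radsig("scores and sample_ids differ in length")
  if (anyDuplicated(sample_ids))
    stop_radsig("duplicate sample id in score table: %s",
                sample_ids[duplicated(sample_ids)][1])
  scores <- as.numeric(scores)
  if (any(!is.finite(scores)))
    stop_radsig("non-finite score for sample %s",
                sample_ids[!is.finite(scores)][1])
  names(scores) <- sample_ids
  scores
}
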