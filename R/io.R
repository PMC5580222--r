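# Readers/writers for the external formats the pipeline touches: GCT 1.2 for
# expression, GMT for gene sets, headered CSV/TSV for clinical tables and
# scores.  All readers validate eagerly and report the file and line or sample
# implicated; nothing is silently coerced.

#' Read a GCT 1.2 expression file
#'
#' Expression is assumed to be on log2 scale; pass `linear = TRUE` to apply
#' `log2(x + 1)` on load.  Duplicate gene symbols are collapsed to the row
#' with the largest mean expression (deterministic, ties broken by first
#' occurrence).
#'
#' @param path path to a GCT 1.2 file.
#' @param linear logical; input is linear-scale and should be log2(x+1)
#'   transformed.
#' @return an [expression_matrix()].
#' @export
read_gct <- function(path, linear = FALSE) {
  if (!file.exists(path)) stop_radsig("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop_radsig("%s: truncated GCT (need version, dimension and header lines)", path)
  if (!grepl("^#1\\.2\\s*$", lines[1L]))
    stop_radsig("%s: line 1 must be the GCT version tag '#1.2', got '%s'",
                path, lines[1L])
  dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop_radsig("%s: line 2 must give '<n_genes>\\t<n_samples>', got '%s'",
                path, lines[2L])
  nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
  hdr <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != nc + 2L || tolower(hdr[1L]) != "name")
    stop_radsig("%s: line 3 must be 'Name\\tDescription\\t<%d sample ids>', found %d fields",
                path, nc, length(hdr))
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != nr)
    stop_radsig("%s: header declares %d data rows but file contains %d",
                path, nr, length(body))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nc + 2L))
    stop_radsig("%s: line %d has %d fields, expected %d",
                path, which(nf != nc + 2L)[1L] + 3L, nf[nf != nc + 2L][1L], nc + 2L)
  genes <- vapply(fields, `[[`, "", 1L)
  vals <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(fields, `[`, -(1:2)), use.names = FALSE))),
    nrow = nr, ncol = nc, byrow = TRUE)
  raw <- unlist(lapply(fields, `[`, -(1:2)), use.names = FALSE)
  bad <- is.na(vals) & !(raw %in% c("", "NA", "na", "NaN"))
  if (any(bad))
    stop_radsig("%s: unparseable numeric value '%s' (gene %s)",
                path, raw[bad][1L], genes[ceiling(which(bad)[1L] / nc)])
  rownames(vals) <- make.unique(genes)
  colnames(vals) <- hdr[-(1:2)]
  if (anyDuplicated(genes)) vals <- collapse_duplicate_genes(vals, genes)
  if (linear) {
    if (any(vals < 0, na.rm = TRUE))
      stop_radsig("%s: negative values are incompatible with linear=TRUE", path)
    vals <- log2(vals + 1)
  }
  expression_matrix(vals)
}

# Keep, for each duplicated symbol, the row with maximal mean expression.
collapse_duplicate_genes <- function(vals, genes) {
  means <- rowMeans(vals, na.rm = TRUE)
  ord <- order(genes, -means)
  keep <- ord[!duplicated(genes[ord])]
  keep <- sort(keep)  # preserve original file order
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out
}

#' Write a GCT 1.2 expression file
#'
#' Values are written with 6 significant digits so that write-read round
#' trips are stable.
#'
#' @param expr genes-by-samples matrix.
#' @param path output path.
#' @export
write_gct <- function(expr, path) {
  assert_expression_matrix(expr)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t"),
               paste(c("Name", "Description", colnames(expr)), collapse = "\t")),
             con)
  txt <- format(signif(unclass(expr), 6), trim = TRUE, scientific = FALSE)
  rows <- apply(cbind(rownames(expr), "na", txt), 1L, paste, collapse = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path tab-separated GMT file (set name, description, genes...).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_radsig("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_radsig("%s: empty GMT file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop_radsig("%s: line %d has fewer than 3 fields (name, description, genes...)",
                path, which(short)[1L])
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets)
}

#' Write a GMT gene-set file
#'
#' @param sets a [gene_set_collection()] or named list; a
#'   [signature_gene_set()] is written as two sets `<name>_UP`, `<name>_DN`.
#' @param path output path.
#' @param description description field, recycled.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "radsig_signature")) {
    out <- list()
    if (length(sets$up)) out[[paste0(sets$name, "_UP")]] <- sets$up
    if (length(sets$dn)) out[[paste0(sets$name, "_DN")]] <- sets$dn
    sets <- out
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table (sample annotations or survival records)
#'
#' Delimiter is inferred from the extension (`.csv` -> comma, otherwise tab).
#'
#' @param path headered CSV/TSV file.
#' @param schema `"annotation"` for per-sample labels or `"survival"` for
#'   time-to-event records.
#' @return validated data.frame (see [sample_annotation()],
#'   [survival_records()]).
#' @export
read_clinical <- function(path, schema = c("annotation", "survival")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_radsig("no such file: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  tryCatch(
    switch(schema, annotation = sample_annotation(df), survival = survival_records(df)),
    radsig_error = function(e) stop_radsig("%s: %s", path, conditionMessage(e)))
}

#' Write a clinical or score table
#' @param df data.frame (or named score vector for `write_scores`).
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @export
write_clinical <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
write_scores <- function(df, path) {
  if (!is.data.frame(df))
    df <- data.frame(sample_id = names(df), score = as.numeric(df))
  write_clinical(df, path)
}

#' Read a per-sample score table (TSV with columns sample_id, score)
#' @param path input path.
#' @return named numeric vector (a score table).
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "score") %in% names(df)))
    stop_radsig("%s: score table needs columns sample_id, score", path)
  score_table(df$score, df$sample_id)
}
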