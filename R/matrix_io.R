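# Reading, validation and alignment of the three input tables, and the
# ranked per-direction output files.
#
# File dialect: tab-separated, UTF-8. Matrix files carry sample ids in the
# first row and gene ids in the first column. The annotation file has two
# columns (sample id, class) where class is TUMOR or NORMAL,
# case-insensitive, with or without a header line.

read_matrix_table <- function(path, missing_token = NA_character_) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  na_str <- if (is.na(missing_token)) character(0) else missing_token
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = na_str,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2) {
    stop("matrix file needs a gene id column plus at least one sample: ",
         path, call. = FALSE)
  }
  gene_ids <- as.character(dt[[1]])
  sample_ids <- colnames(dt)[-1]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  for (k in seq_along(sample_ids)) {
    col <- dt[[k + 1]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop("non-numeric value ", dQuote(col[bad[1]]), " at gene ",
             gene_ids[bad[1]], ", sample ", sample_ids[k], " in ", path,
             call. = FALSE)
      }
      col <- num
    }
    m[, k] <- as.numeric(col)
  }
  m
}

#' Read a gene-by-sample expression matrix
#'
#' Parses a tab-separated table whose first row holds sample ids and first
#' column gene ids. Values are log2 expression intensities. Cells equal to
#' `missing_token` become `NA` and are excluded from all downstream group
#' statistics.
#'
#' @param path Path to the tab-separated file.
#' @param missing_token Text token marking a missing value (default `"NA"`).
#' @return A numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  read_matrix_table(path, missing_token = missing_token)
}

#' Read a gene-by-sample copy-number status matrix
#'
#' Same dialect as [read_expression_matrix()]. Cells must be discrete
#' GISTIC/RAE-style codes in -2, -1, 0, +1, +2 (multi-copy amplification
#' = +2, homozygous deletion = -2).
#'
#' @param path Path to the tab-separated file.
#' @return An integer matrix of copy-number codes with gene/sample dimnames.
#' @export
read_cna_matrix <- function(path) {
  m <- read_matrix_table(path, missing_token = NA_character_)
  bad <- which(!(m %in% c(-2L, -1L, 0L, 1L, 2L)) | m != round(m))
  if (length(bad)) {
    k <- bad[1]
    g <- rownames(m)[(k - 1) %% nrow(m) + 1]
    s <- colnames(m)[(k - 1) %/% nrow(m) + 1]
    stop("copy-number code out of range {-2..2} at gene ", g, ", sample ",
         s, ": ", m[k], call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Read a sample annotation table
#'
#' Two tab-separated columns: sample id and class (`TUMOR` or `NORMAL`,
#' case-insensitive). A header line is detected and skipped if its second
#' field is not a valid class.
#'
#' @param path Path to the tab-separated file.
#' @return A named character vector mapping sample id to `"TUMOR"` or
#'   `"NORMAL"`.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (ncol(dt) < 2) {
    stop("annotation file needs two columns (sample, class): ", path,
         call. = FALSE)
  }
  ids <- as.character(dt[[1]])
  cls <- toupper(trimws(as.character(dt[[2]])))
  if (length(cls) && !cls[1] %in% c("TUMOR", "NORMAL")) {
    ids <- ids[-1]
    cls <- cls[-1]
  }
  bad <- which(!cls %in% c("TUMOR", "NORMAL"))
  if (length(bad)) {
    stop("invalid sample class ", dQuote(cls[bad[1]]), " for sample ",
         ids[bad[1]], " (expected TUMOR or NORMAL)", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample id(s) in annotation: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!any(cls == "TUMOR")) {
    stop("annotation contains no TUMOR samples", call. = FALSE)
  }
  setNames(cls, ids)
}

#' Align expression, copy-number and annotation into one dataset
#'
#' Restricts the three inputs to their shared genes and shared annotated
#' samples (order preserved from the expression matrix). Counts of dropped
#' genes/samples are reported as warnings; empty intersections are errors.
#'
#' @param expr Numeric expression matrix (genes x samples).
#' @param cna Integer copy-number status matrix (genes x samples).
#' @param annot Named character vector from [read_sample_annotation()].
#' @return A `cis_dataset` object: list with elements `expression`, `cna`
#'   (aligned matrices) and `annotation` (named vector for the retained
#'   samples).
#' @export
align_dataset <- function(expr, cna, annot) {
  genes <- intersect(rownames(expr), rownames(cna))
  samples <- Reduce(intersect,
                    list(colnames(expr), colnames(cna), names(annot)))
  if (length(genes) == 0) {
    stop("no genes shared between expression and copy-number matrices",
         call. = FALSE)
  }
  if (length(samples) == 0) {
    stop("no samples shared between expression, copy-number and annotation",
         call. = FALSE)
  }
  drop_msg <- function(what, n_in, keep) {
    n_drop <- n_in - length(keep)
    if (n_drop > 0) {
      warning(sprintf("dropped %d %s not shared by all inputs",
                      n_drop, what), call. = FALSE)
    }
  }
  drop_msg("expression samples", ncol(expr), samples)
  drop_msg("copy-number samples", ncol(cna), samples)
  drop_msg("annotated samples", length(annot), samples)
  drop_msg("expression genes", nrow(expr), genes)
  drop_msg("copy-number genes", nrow(cna), genes)
  out <- list(expression = expr[genes, samples, drop = FALSE],
              cna = cna[genes, samples, drop = FALSE],
              annotation = annot[samples])
  class(out) <- "cis_dataset"
  out
}

#' @export
print.cis_dataset <- function(x, ...) {
  cat(sprintf("cis_dataset: %d genes x %d samples (%d tumors, %d normals)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$annotation == "TUMOR"), sum(x$annotation == "NORMAL")))
  invisible(x)
}

format_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

#' Write a ranked result table
#'
#' Writes the per-gene results of one alteration-set analysis as a
#' tab-separated file with columns gene, n_altered, eis_normal, eis_tumor,
#' z_normal, z_tumor, z_comb, p_value, corrected_p. Rows are expected to be
#' ranked already: decreasing combined Z for amplifications, increasing
#' (most negative first) for deletions.
#'
#' @param results Data frame from [cis_analyze()].
#' @param direction `"AMP"` or `"DEL"` (recorded for validation only).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_results <- function(results, direction = c("AMP", "DEL"), path) {
  direction <- match.arg(direction)
  cols <- c("gene", "n_altered", "eis_normal", "eis_tumor", "z_normal",
            "z_tumor", "z_comb", "p_value", "corrected_p")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols)) {
    stop("results table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  lines <- paste(cols, collapse = "\t")
  if (nrow(results)) {
    body <- cbind(results$gene, as.character(results$n_altered),
                  format_full(results$eis_normal),
                  format_full(results$eis_tumor),
                  format_full(results$z_normal),
                  format_full(results$z_tumor),
                  format_full(results$z_comb),
                  format_full(results$p_value),
                  format_full(results$corrected_p))
    lines <- c(lines, apply(body, 1, paste, collapse = "\t"))
  }
  writeLines(lines, con = con)
  invisible(path)
}

#' Write a numeric or integer matrix in the package's TSV dialect
#'
#' First row sample ids, first column gene ids. Numeric values are written
#' with enough digits to round-trip bit-identically through
#' [read_expression_matrix()].
#'
#' @param m Matrix with dimnames.
#' @param path Output file path.
#' @param digits17 Write full-precision floats (default TRUE); integers are
#'   written as-is.
#' @return Invisibly, the path written.
#' @export
write_matrix_tsv <- function(m, path, digits17 = TRUE) {
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  if (is.integer(m) || !digits17) {
    body <- apply(m, 1, function(r) paste(r, collapse = "\t"))
  } else {
    fm <- matrix(format_full(m), nrow = nrow(m))
    body <- apply(fm, 1, function(r) paste(r, collapse = "\t"))
  }
  writeLines(c(header, paste(rownames(m), body, sep = "\t")), con = con)
  invisible(path)
}
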