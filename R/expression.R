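#' Construct an expression profile
#'
#' An expression profile holds the (log2-normalized, non-negative)
#' expression values of one sample as a named numeric vector. It is the
#' elementary input of all divergence computations: the value of gene j
#' feeds the mass-action interaction probability of every gene that has
#' j as a network neighbor.
#'
#' @param values named numeric vector, gene symbols as names; all values
#'   must be finite and non-negative, names unique.
#' @param sample_id sample label carried through to result tables.
#' @return an `expression_profile`: the named numeric vector with a
#'   `sample_id` attribute.
#' @export
expression_profile <- function(values, sample_id = "sample") {
  if (!is.numeric(values) || is.null(names(values)))
    stop("`values` must be a named numeric vector")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite (no NA/Inf)")
  if (any(values < 0)) {
    bad <- names(values)[which(values < 0)[1L]]
    stop(sprintf("negative expression value for gene '%s' in sample '%s'",
                 bad, sample_id))
  }
  if (anyDuplicated(names(values)))
    stop("duplicate gene symbols in profile")
  structure(values, sample_id = as.character(sample_id),
            class = c("expression_profile", "numeric"))
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile '%s': %d genes\n",
              attr(x, "sample_id"), length(x)))
  utils::str(unclass(x)[seq_len(min(6L, length(x)))])
  invisible(x)
}

#' Sample label of an expression profile
#' @param x an `expression_profile`.
#' @return the sample id string.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Read a gene-by-sample expression table
#'
#' Reads a TSV whose first column holds gene symbols and whose header
#' row holds sample ids, validates that every value is numeric, finite
#' and non-negative, and optionally applies a log2(x+1) transform for
#' raw counts/TPM. All downstream probabilities are ratios of expression
#' values, so negative inputs are rejected outright.
#'
#' Duplicate gene rows (common after probe-to-symbol mapping) are
#' collapsed, by per-sample maximum by default, with a message.
#'
#' @param path path to the TSV file.
#' @param transform `"none"` (values already log2-normalized) or
#'   `"log2p1"` (apply log2(x+1)).
#' @param collapse how duplicate gene rows are merged: `"max"` or
#'   `"mean"`.
#' @return a numeric genes x samples matrix with unique rownames
#'   (genes) and colnames (samples).
#' @export
load_expression <- function(path, transform = c("none", "log2p1"),
                            collapse = c("max", "mean")) {
  transform <- match.arg(transform)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop(sprintf("expression file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop(sprintf("expression table %s needs a gene column plus >=1 sample", path))
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample ids in %s", path))
  mat <- matrix(NA_real_, nrow(raw), length(samples),
                dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1L]]))
    if (length(bad))
      stop(sprintf(
        "non-numeric value '%s' in %s, line %d (sample '%s')",
        raw[[j + 1L]][bad[1L]], path, bad[1L] + 1L, samples[j]))
    mat[, j] <- v
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf(
      "negative expression value (%g) for gene '%s', sample '%s' in %s",
      mat[neg[1L, 1L], neg[1L, 2L]], genes[neg[1L, 1L]],
      samples[neg[1L, 2L]], path))
  }
  if (transform == "log2p1") mat <- log2(mat + 1)
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    message(sprintf("collapsing %d duplicate gene row(s) by %s", ndup, collapse))
    f <- factor(genes, levels = unique(genes))
    agg <- if (collapse == "max") {
      do.call(rbind, lapply(split(seq_len(nrow(mat)), f), function(i)
        apply(mat[i, , drop = FALSE], 2L, max)))
    } else {
      do.call(rbind, lapply(split(seq_len(nrow(mat)), f), function(i)
        colMeans(mat[i, , drop = FALSE])))
    }
    mat <- agg
    rownames(mat) <- levels(f)
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Write an expression matrix back to TSV
#'
#' Inverse of [load_expression()]; values are printed at full double
#' precision so a load/write/load cycle round-trips exactly.
#'
#' @param mat genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @param gene_col header name for the gene column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, gene_col = "gene") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(gene_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one sample as an expression profile
#'
#' @param mat genes x samples matrix.
#' @param sample sample id (column name) or index.
#' @return an [expression_profile()].
#' @export
profile_from_matrix <- function(mat, sample) {
  if (is.character(sample) && !sample %in% colnames(mat))
    stop(sprintf("unknown sample id '%s'", sample))
  v <- mat[, sample]
  id <- if (is.character(sample)) sample else colnames(mat)[sample]
  expression_profile(stats::setNames(as.numeric(v), rownames(mat)), id)
}

#' Average samples into a reference profile
#'
#' Builds the normal-reference state used in tITH from several normal
#' samples: the per-gene arithmetic mean of the (log2-scale) values.
#' A mean in linear space, log2(mean(2^v)), is available behind
#' `scale = "linear"` for users who prefer averaging un-logged
#' abundances.
#'
#' @param mat genes x samples matrix.
#' @param sample_ids columns to average (character ids or indices);
#'   defaults to all samples.
#' @param label sample id given to the resulting profile.
#' @param scale `"log2"` (mean of the stored values) or `"linear"`.
#' @return an [expression_profile()].
#' @export
aggregate_reference <- function(mat, sample_ids = colnames(mat),
                                label = "reference",
                                scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (length(sample_ids) < 1L) stop("need at least one sample to aggregate")
  if (is.character(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(mat))
    if (length(missing))
      stop(sprintf("unknown sample id(s): %s", paste(missing, collapse = ", ")))
  }
  sub <- mat[, sample_ids, drop = FALSE]
  v <- if (scale == "log2") rowMeans(sub) else log2(rowMeans(2^sub))
  expression_profile(stats::setNames(as.numeric(v), rownames(mat)), label)
}
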