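#' Maximally ambiguous reference state
#'
#' The reference state A assigns the same expression value to every
#' gene, so each gene's mass-action neighbor distribution is uniform
#' over its neighbors: the network carries no directional information
#' at all. A tumor whose bulk profile approaches this state is read as
#' maximally heterogeneous. Any positive constant induces the same
#' distributions (mass-action probabilities are scale-free); 1.0 is
#' used.
#'
#' @param net an [interaction_network()].
#' @param genes gene universe; the profile covers `genes` intersected
#'   with the network nodes.
#' @param value the constant (default 1.0; any c > 0 is equivalent).
#' @return an [expression_profile()] with sample id `"stateA"`.
#' @export
ambiguous_reference <- function(net, genes, value = 1.0) {
  g <- intersect(net$nodes, genes)
  if (length(g) == 0L)
    stop("no overlap between the gene universe and the network")
  expression_profile(stats::setNames(rep(value, length(g)), g), "stateA")
}

# Shared per-gene table behind tith() and pathway_tith(): jsd_nt and
# jsd_ta per gene on the common universe (network + both profiles).
# The averaging set for BOTH distances is the set of genes defined for
# NT (positive neighbor sums in normal and tumor); state A is always
# defined there, so NT and TA average over identical gene sets and
# their ratio compares like with like.
.tith_gene_table <- function(normal, tumor, net, base = 2) {
  universe <- intersect(names(normal), names(tumor))
  engine <- .njsd_engine(net, universe)
  vn <- as.numeric(normal[engine$universe])
  vt <- as.numeric(tumor[engine$universe])
  va <- rep(1.0, length(engine$universe))
  nt <- .jsd_per_gene(engine, vn, vt, base)
  ta <- .jsd_per_gene(engine, vt, va, base)
  data.frame(gene = nt$gene, jsd_nt = nt$jsd, jsd_ta = ta$jsd,
             defined = nt$defined & ta$defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Ratio with degenerate-case flag.
.tith_from_means <- function(sample_id, nt, ta, n_used) {
  degenerate <- (nt + ta) <= 0
  structure(list(sample_id = sample_id, nt = nt, ta = ta,
                 tith = if (degenerate) 0 else nt / (nt + ta),
                 degenerate = degenerate, n_genes_used = n_used),
            class = "tith_result")
}

#' Transcriptome-based intratumor heterogeneity score
#'
#' Computes NT = nJSD(normal, tumor), TA = nJSD(tumor, state A) on the
#' shared gene universe, and the score tITH = NT / (NT + TA) in
#' [0, 1]. A tumor indistinguishable from the normal reference scores
#' 0; a tumor whose network state is maximally ambiguous (all neighbor
#' distributions uniform) scores 1. Both distances average over the
#' identical gene set, so the ratio never mixes incomparable scales.
#'
#' @param normal reference [expression_profile()] (e.g. from
#'   [aggregate_reference()]).
#' @param tumor tumor [expression_profile()].
#' @param net an [interaction_network()].
#' @param base logarithm base; the ratio is base-invariant.
#' @return a `tith_result`: list with `sample_id`, `nt`, `ta`, `tith`,
#'   `degenerate` and `n_genes_used`. When NT + TA = 0 (tumor equals
#'   both references) `tith` is 0 with `degenerate = TRUE`.
#' @export
tith <- function(normal, tumor, net, base = 2) {
  tab <- .tith_gene_table(normal, tumor, net, base)
  used <- tab$defined
  if (!any(used))
    stop("no usable gene for tITH (all neighbor sums zero)")
  .tith_from_means(attr(tumor, "sample_id") %||% "tumor",
                   mean(tab$jsd_nt[used]), mean(tab$jsd_ta[used]),
                   sum(used))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tith_result <- function(x, ...) {
  cat(sprintf("tITH['%s'] = %.4f (NT = %.6g, TA = %.6g, %d genes%s)\n",
              x$sample_id, x$tith, x$nt, x$ta, x$n_genes_used,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' tITH for a cohort of tumors against pooled normals
#'
#' Aggregates all normal samples into a single reference profile (mean
#' log2 expression per gene) and scores every tumor column against it.
#'
#' @param normals genes x samples matrix of normal samples.
#' @param tumors genes x samples matrix of tumor samples.
#' @param net an [interaction_network()].
#' @param base logarithm base.
#' @param reference_scale passed to [aggregate_reference()].
#' @return a data.frame with one row per tumor: `sample`, `nt`, `ta`,
#'   `tith`, `n_genes_used`, `degenerate`, in the tumors' column order.
#' @export
tith_cohort <- function(normals, tumors, net, base = 2,
                        reference_scale = c("log2", "linear")) {
  if (ncol(normals) < 1L) stop("need at least one normal sample")
  if (ncol(tumors) < 1L) stop("need at least one tumor sample")
  ref <- aggregate_reference(normals, scale = match.arg(reference_scale))
  rows <- lapply(colnames(tumors), function(s) {
    r <- tith(ref, profile_from_matrix(tumors, s), net, base)
    data.frame(sample = s, nt = r$nt, ta = r$ta, tith = r$tith,
               n_genes_used = r$n_genes_used, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a tITH result table to TSV
#'
#' @param results data.frame from [tith_cohort()].
#' @param path output path; columns `sample`, `NT`, `TA`, `tITH`,
#'   `n_genes_used`.
#' @return `path`, invisibly.
#' @export
write_tith <- function(results, path) {
  out <- data.frame(sample = results$sample, NT = results$nt,
                    TA = results$ta, tITH = results$tith,
                    n_genes_used = results$n_genes_used)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
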