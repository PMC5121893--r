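#' Read a GMT gene-set collection
#'
#' Standard GMT: one gene set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a set are deduplicated; duplicate set names are an error.
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection`: named list of character vectors
#'   with a `source` attribute.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("GMT file %s is empty", path))
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d in %s has %d field(s); need name, description, >=1 gene",
                   i, path, length(f)))
    nm[i] <- f[1L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nm))
    stop(sprintf("duplicate gene-set name '%s' in %s", nm[duplicated(nm)][1L], path))
  names(sets) <- nm
  structure(sets, source = path, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Pathway-level tITH for one gene set
#'
#' Per-gene JSDs are computed exactly as in [tith()] — each gene's
#' neighborhood is taken from the full network — but the NT and TA
#' averages run only over usable genes belonging to the gene set. The
#' count-weighted mean of per-set NT values over a partition of the
#' usable genes therefore reconstructs the global NT exactly. An
#' alternative mode restricts neighborhoods to the pathway-induced
#' subgraph.
#'
#' @param normal,tumor [expression_profile()]s.
#' @param net an [interaction_network()].
#' @param gene_set character vector of gene symbols.
#' @param pathway label carried into the result.
#' @param base logarithm base.
#' @param neighborhoods `"full"` (default: full-network neighborhoods)
#'   or `"subgraph"` (pathway-induced subgraph).
#' @return a one-row data.frame: `sample`, `pathway`, `nt`, `ta`,
#'   `tith`, `n_genes_used`, `degenerate`. If no usable gene falls in
#'   the set, a row with `NA` scores and `n_genes_used = 0` is
#'   returned with a warning.
#' @export
pathway_tith <- function(normal, tumor, net, gene_set, pathway = "set",
                         base = 2, neighborhoods = c("full", "subgraph")) {
  neighborhoods <- match.arg(neighborhoods)
  if (neighborhoods == "subgraph")
    net <- suppressMessages(restrict_to_genes(net, gene_set))
  sample <- attr(tumor, "sample_id") %||% "tumor"
  if (length(net$nodes) == 0L || !any(gene_set %in% net$nodes)) {
    warning(sprintf("pathway '%s' shares no gene with the usable network", pathway))
    return(data.frame(sample = sample, pathway = pathway, nt = NA_real_,
                      ta = NA_real_, tith = NA_real_, n_genes_used = 0L,
                      degenerate = NA, stringsAsFactors = FALSE))
  }
  tab <- .tith_gene_table(normal, tumor, net, base)
  .pathway_row_from_table(tab, gene_set, sample, pathway)
}

# Average the per-gene table over a gene set; shared with the screen.
.pathway_row_from_table <- function(tab, gene_set, sample, pathway) {
  sel <- tab$defined & tab$gene %in% gene_set
  if (!any(sel)) {
    warning(sprintf("pathway '%s' has no usable gene", pathway))
    return(data.frame(sample = sample, pathway = pathway, nt = NA_real_,
                      ta = NA_real_, tith = NA_real_, n_genes_used = 0L,
                      degenerate = NA, stringsAsFactors = FALSE))
  }
  r <- .tith_from_means(sample, mean(tab$jsd_nt[sel]), mean(tab$jsd_ta[sel]),
                        sum(sel))
  data.frame(sample = sample, pathway = pathway, nt = r$nt, ta = r$ta,
             tith = r$tith, n_genes_used = r$n_genes_used,
             degenerate = r$degenerate, stringsAsFactors = FALSE)
}

#' Pathway-tITH across a whole collection
#'
#' One [pathway_tith()] row per gene set, reusing a single per-gene
#' divergence table for the sample, so a 300-pathway collection costs
#' barely more than one global tITH.
#'
#' @inheritParams pathway_tith
#' @param collection a `gene_set_collection` from [load_gmt()] or a
#'   named list of character vectors.
#' @return data.frame with one row per pathway.
#' @export
pathway_tith_all <- function(normal, tumor, net, collection, base = 2) {
  sample <- attr(tumor, "sample_id") %||% "tumor"
  tab <- .tith_gene_table(normal, tumor, net, base)
  rows <- lapply(names(collection), function(p)
    .pathway_row_from_table(tab, collection[[p]], sample, p))
  do.call(rbind, rows)
}

#' Screen pathways for association with an external covariate
#'
#' Computes pathway-tITH for every tumor sample and every gene set,
#' then tests each pathway's scores against a per-sample covariate
#' (e.g. a genome-based subclone count) with a two-sided Pearson
#' correlation test. Rows are sorted by decreasing |r|.
#'
#' @param normals,tumors genes x samples matrices.
#' @param net an [interaction_network()].
#' @param collection named list of gene sets.
#' @param covariate named numeric vector, names matching tumor sample
#'   ids; samples without a value are dropped.
#' @param base logarithm base.
#' @param adjust also report Benjamini-Hochberg q-values (`"BH"`) or
#'   raw p-values only (`"none"`, default).
#' @return data.frame `pathway`, `r`, `p` (and `q` when adjusted),
#'   plus `n` samples used; pathways with constant scores get `NA`
#'   and a `constant` flag.
#' @export
pathway_screen <- function(normals, tumors, net, collection, covariate,
                           base = 2, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  samples <- intersect(colnames(tumors), names(covariate))
  if (length(samples) < 3L)
    stop("need >= 3 tumor samples with covariate values")
  ref <- aggregate_reference(normals)
  score <- sapply(samples, function(s) {
    tab <- .tith_gene_table(ref, profile_from_matrix(tumors, s), net, base)
    vapply(collection, function(gs) {
      sel <- tab$defined & tab$gene %in% gs
      if (!any(sel)) return(NA_real_)
      nt <- mean(tab$jsd_nt[sel]); ta <- mean(tab$jsd_ta[sel])
      if (nt + ta <= 0) 0 else nt / (nt + ta)
    }, numeric(1L))
  })
  score <- matrix(score, nrow = length(collection),
                  dimnames = list(names(collection), samples))
  cov <- covariate[samples]
  rows <- lapply(rownames(score), function(p) {
    v <- score[p, ]
    ok <- !is.na(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(cov[ok]) == 0)
      return(data.frame(pathway = p, r = NA_real_, p = NA_real_,
                        n = sum(ok), constant = TRUE,
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(v[ok], cov[ok], method = "pearson")
    data.frame(pathway = p, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), constant = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(-abs(out$r), na.last = TRUE), , drop = FALSE]
}
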