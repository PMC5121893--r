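#' Mass-action neighbor distribution of a gene
#'
#' Under the mass-action assumption, the probability that gene i
#' interacts with neighbor j is proportional to the expression of j:
#' p_ij = e_j / sum over k in J_i of e_k, where J_i is i's neighbor set
#' restricted to genes measured in the profile. If every measured
#' neighbor has zero expression the distribution is undefined and the
#' gene is flagged rather than imputed.
#'
#' @param profile an [expression_profile()] (or named numeric vector).
#' @param net an [interaction_network()].
#' @param gene gene symbol; must be a network node with at least one
#'   neighbor present in the profile.
#' @return a `neighbor_distribution`: list with `gene`, `neighbors`
#'   (sorted), `probs` (aligned to neighbors; `NA` when undefined) and
#'   `defined`.
#' @export
neighbor_distribution <- function(profile, net, gene) {
  nb <- net_neighbors(net, gene)
  nb <- nb[nb %in% names(profile)]
  if (length(nb) == 0L)
    stop(sprintf("gene '%s' has no neighbor measured in the profile", gene))
  e <- as.numeric(profile[nb])
  s <- sum(e)
  if (s > 0) {
    probs <- e / s
    defined <- TRUE
  } else {
    probs <- rep(NA_real_, length(e))
    defined <- FALSE
  }
  structure(list(gene = gene, neighbors = nb, probs = probs,
                 defined = defined),
            class = "neighbor_distribution")
}

#' @export
print.neighbor_distribution <- function(x, ...) {
  cat(sprintf("neighbor_distribution for '%s' (%d neighbors, %s)\n",
              x$gene, length(x$neighbors),
              if (x$defined) "defined" else "undefined"))
  invisible(x)
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' D(P || Q) = sum_l P_l * log(P_l / Q_l), with the convention
#' 0 * log(0/x) = 0. Base-2 logarithms by default, so the value is in
#' bits and the derived Jensen-Shannon divergence is bounded by 1.
#'
#' @param p,q numeric probability vectors of equal length, each summing
#'   to 1; `q` must be positive wherever `p` is.
#' @param base logarithm base.
#' @return non-negative divergence.
#' @export
kld <- function(p, q, base = 2) {
  if (length(p) != length(q))
    stop("p and q must have equal length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("p and q must each sum to 1")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (any(p > 0 & q == 0))
    stop("infinite divergence: q is zero where p has support")
  pos <- p > 0
  max(0, sum(p[pos] * (log(p[pos] / q[pos]) / log(base))))
}

#' Jensen-Shannon divergence between two neighbor distributions
#'
#' JSD(P, Q) = KLD(P || M)/2 + KLD(Q || M)/2 with mixture M = (P+Q)/2.
#' Symmetric in its arguments and, with base-2 logarithms, bounded in
#' [0, 1]. If exactly one side is undefined (zero neighbor-expression
#' sum) the result is flagged undefined rather than guessed.
#'
#' @param p,q `neighbor_distribution`s for the same gene over the same
#'   neighbor ordering.
#' @param base logarithm base.
#' @return a `gene_divergence`: list with `gene`, `jsd` and `defined`.
#' @export
gene_jsd <- function(p, q, base = 2) {
  if (!identical(p$gene, q$gene))
    stop(sprintf("distributions are for different genes ('%s' vs '%s')",
                 p$gene, q$gene))
  if (!identical(p$neighbors, q$neighbors))
    stop(sprintf("neighbor lists for '%s' are not aligned", p$gene))
  if (!p$defined || !q$defined)
    return(structure(list(gene = p$gene, jsd = NA_real_, defined = FALSE),
                     class = "gene_divergence"))
  m <- (p$probs + q$probs) / 2
  jsd <- (kld(p$probs, m, base) + kld(q$probs, m, base)) / 2
  structure(list(gene = p$gene, jsd = jsd, defined = TRUE),
            class = "gene_divergence")
}

#' @export
print.gene_divergence <- function(x, ...) {
  cat(sprintf("gene_divergence '%s': jsd = %s\n", x$gene,
              if (x$defined) format(x$jsd) else "undefined"))
  invisible(x)
}

# Precomputed index structure for vectorized per-gene JSD over a fixed
# gene universe. `genes` index both the averaging set and the neighbor
# positions; profiles passed to .jsd_per_gene must be aligned to
# `universe`.
.njsd_engine <- function(net, universe) {
  universe <- sort(intersect(net$nodes, universe))
  if (length(universe) == 0L)
    stop("no network gene is present in both expression profiles")
  adj <- lapply(net$adj[universe], function(nb) nb[nb %in% universe])
  len <- lengths(adj)
  genes <- universe[len > 0L]
  if (length(genes) == 0L)
    stop("no network gene has a measured neighbor in both profiles")
  adj <- adj[genes]
  nbr <- unlist(adj, use.names = FALSE)
  grp <- rep.int(seq_along(genes), lengths(adj))
  list(universe = universe, genes = genes,
       nbr_pos = match(nbr, universe), grp = grp,
       n_grp = length(genes))
}

# Per-gene JSD between two profiles aligned to engine$universe.
# Returns data.frame(gene, jsd, defined). Degenerate genes (zero
# neighbor-expression sum in either state) get defined = FALSE.
.jsd_per_gene <- function(engine, vx, vy, base = 2) {
  ex <- vx[engine$nbr_pos]
  ey <- vy[engine$nbr_pos]
  grp <- engine$grp
  sx <- rowsum(ex, grp, reorder = FALSE)[, 1L]
  sy <- rowsum(ey, grp, reorder = FALSE)[, 1L]
  defined <- sx > 0 & sy > 0
  p <- ex / sx[grp]
  q <- ey / sy[grp]
  m <- (p + q) / 2
  tp <- p * (log(p / m) / log(base))
  tp[!is.finite(tp) | p == 0] <- 0
  tq <- q * (log(q / m) / log(base))
  tq[!is.finite(tq) | q == 0] <- 0
  jsd <- (rowsum(tp, grp, reorder = FALSE)[, 1L] +
          rowsum(tq, grp, reorder = FALSE)[, 1L]) / 2
  jsd <- pmin(pmax(jsd, 0), log(2) / log(base))
  jsd[!defined] <- NA_real_
  data.frame(gene = engine$genes, jsd = jsd, defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Network Jensen-Shannon divergence between two expression states
#'
#' The nJSD between profiles X and Y on a protein-interaction network
#' is the mean, over usable network genes, of the per-gene JSD between
#' the mass-action neighbor distributions of each gene in the two
#' states. Usable genes are those in the network with at least one
#' neighbor measured in both profiles and a positive
#' neighbor-expression sum in both states; skipped genes are counted,
#' never silently imputed.
#'
#' @param x,y [expression_profile()]s (or named numeric vectors).
#' @param net an [interaction_network()].
#' @param base logarithm base; 2 (default) bounds each per-gene JSD in
#'   [0, 1]. The tITH ratio is invariant to this choice.
#' @return an `njsd_result`: list with `value` (the mean JSD),
#'   `per_gene` (data.frame gene/jsd/defined), `n_genes_used`,
#'   `n_genes_skipped`.
#' @export
njsd <- function(x, y, net, base = 2) {
  universe <- intersect(names(x), names(y))
  engine <- .njsd_engine(net, universe)
  tab <- .jsd_per_gene(engine,
                       as.numeric(x[engine$universe]),
                       as.numeric(y[engine$universe]), base)
  used <- tab$defined
  if (!any(used))
    stop("no gene yields a defined divergence (all neighbor sums zero)")
  structure(list(value = mean(tab$jsd[used]), per_gene = tab,
                 n_genes_used = sum(used), n_genes_skipped = sum(!used)),
            class = "njsd_result")
}

#' @export
print.njsd_result <- function(x, ...) {
  cat(sprintf("nJSD = %.6g over %d genes (%d skipped)\n",
              x$value, x$n_genes_used, x$n_genes_skipped))
  invisible(x)
}

#' Write a per-gene JSD table to TSV
#'
#' @param result an `njsd_result` from [njsd()].
#' @param path output path; columns `gene`, `jsd`, `defined`.
#' @return `path`, invisibly.
#' @export
write_jsd_table <- function(result, path) {
  utils::write.table(result$per_gene, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
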