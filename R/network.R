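#' Construct a protein-interaction network
#'
#' An undirected simple graph over gene symbols. Self-loops are dropped
#' (a gene's own expression never enters its neighbor distribution) and
#' duplicate/reversed edges are merged. Neighbor lists are stored
#' lexicographically sorted so every downstream summation order is
#' deterministic.
#'
#' @param from,to character vectors of equal length giving edge
#'   endpoints.
#' @return an `interaction_network`: list with `nodes` (sorted character
#'   vector), `adj` (named list of sorted neighbor vectors) and
#'   `n_edges`.
#' @export
interaction_network <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- as.character(from); to <- as.character(to)
  self <- from == to
  if (any(self))
    message(sprintf("dropped %d self-loop(s)", sum(self)))
  from <- from[!self]; to <- to[!self]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  nodes <- sort(unique(c(a, b)))
  adj <- split(c(b, a), factor(c(a, b), levels = nodes))
  adj <- lapply(adj, function(x) sort(unique(x)))
  structure(list(nodes = nodes, adj = adj, n_edges = length(a)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d genes, %d edges\n",
              length(x$nodes), x$n_edges))
  invisible(x)
}

#' Neighbor genes of a gene
#' @param net an [interaction_network()].
#' @param gene gene symbol.
#' @return sorted character vector of neighbors.
#' @export
net_neighbors <- function(net, gene) {
  if (!gene %in% net$nodes)
    stop(sprintf("gene '%s' is not in the network", gene))
  net$adj[[gene]]
}

#' Read a protein-interaction edge list
#'
#' Parses a 2-3 column TSV (geneA, geneB, optional confidence score),
#' e.g. an export from STRING, BioPlex or HINT, into an undirected
#' simple graph. A score column can be used to filter edges at load
#' time; the divergence math itself always treats edges as unweighted.
#'
#' @param path path to the edge-list TSV.
#' @param score_column 1-based column index of a numeric confidence
#'   score, or `NULL` for no filtering.
#' @param min_score minimum score to retain an edge; must be given
#'   together with `score_column`.
#' @param header does the file carry a header line? No autodetection:
#'   state it explicitly.
#' @return an [interaction_network()].
#' @export
load_network <- function(path, score_column = NULL, min_score = NULL,
                         header = FALSE) {
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines < 1L + as.integer(header))
    stop(sprintf("network file %s contains no edges", path))
  raw <- utils::read.delim(path, header = header, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop(sprintf("edge list %s needs at least 2 columns (geneA, geneB)", path))
  if (xor(is.null(score_column), is.null(min_score)))
    stop("score_column and min_score must be given together")
  if (!is.null(score_column)) {
    if (score_column > ncol(raw))
      stop(sprintf("score_column %d exceeds %d columns in %s",
                   score_column, ncol(raw), path))
    score <- suppressWarnings(as.numeric(raw[[score_column]]))
    if (anyNA(score))
      stop(sprintf("non-numeric score in column %d of %s, line %d",
                   score_column, path,
                   which(is.na(score))[1L] + as.integer(header)))
    keep <- score >= min_score
    message(sprintf("score filter >= %g kept %d of %d edges",
                    min_score, sum(keep), length(keep)))
    raw <- raw[keep, , drop = FALSE]
  }
  if (nrow(raw) == 0L)
    stop(sprintf("no edges left in %s after score filtering", path))
  net <- interaction_network(raw[[1L]], raw[[2L]])
  if (net$n_edges == 0L)
    stop(sprintf("network from %s is empty after cleaning", path))
  net
}

#' Restrict a network to a gene universe
#'
#' Induced subgraph on the intersection of the network's nodes with
#' `genes`; nodes left without any neighbor are removed. Used to align
#' the network with the measured gene universe before computing
#' divergences.
#'
#' @param net an [interaction_network()].
#' @param genes character vector of gene symbols to keep.
#' @return an [interaction_network()]; a message reports dropped nodes.
#' @export
restrict_to_genes <- function(net, genes) {
  keep <- intersect(net$nodes, genes)
  adj <- lapply(net$adj[keep], function(nb) nb[nb %in% keep])
  adj <- adj[lengths(adj) > 0L]
  nodes <- sort(names(adj))
  dropped <- length(net$nodes) - length(nodes)
  if (dropped > 0L)
    message(sprintf("restriction dropped %d of %d network genes",
                    dropped, length(net$nodes)))
  if (length(nodes) == 0L) {
    warning("restriction left an empty network")
    return(structure(list(nodes = character(), adj = list(), n_edges = 0L),
                     class = "interaction_network"))
  }
  structure(list(nodes = nodes, adj = adj[nodes],
                 n_edges = sum(lengths(adj)) %/% 2L),
            class = "interaction_network")
}
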