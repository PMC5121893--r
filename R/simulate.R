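#' Configuration for a synthetic clone cohort
#'
#' The generator emulates the ingredients of a clone-mixing study: a
#' connected random protein-interaction network, a baseline (normal)
#' expression state, and a panel of clone profiles that diverge from
#' the baseline by independent per-gene perturbations on the log2
#' scale. Defaults give a 200-gene scale-free network (mean degree
#' about 6) and clone divergence comparable to the spread between
#' unrelated cancer cell lines.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_clones number of clone profiles (>= 1).
#' @param network_model `"barabasi_albert"` (scale-free, default) or
#'   `"erdos_renyi"`.
#' @param network_param edges per new node (BA) or edge probability
#'   (ER).
#' @param clone_divergence s.d. of the per-gene log2 perturbation added
#'   to the baseline for each clone.
#' @param baseline_logmean,baseline_logsd mean and s.d. of the baseline
#'   log2 expression values (normal draws clipped at 0).
#' @param seed RNG seed; all outputs are reproducible from it.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_genes = 200, n_clones = 128,
                                    network_model = c("barabasi_albert",
                                                      "erdos_renyi"),
                                    network_param = 3,
                                    clone_divergence = 1.0,
                                    baseline_logmean = 3,
                                    baseline_logsd = 2,
                                    seed = 1L) {
  network_model <- match.arg(network_model)
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (clone_divergence < 0) stop("clone_divergence must be >= 0")
  if (baseline_logsd < 0) stop("baseline_logsd must be >= 0")
  if (network_param <= 0) stop("network_param must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 n_clones = as.integer(n_clones),
                 network_model = network_model,
                 network_param = network_param,
                 clone_divergence = clone_divergence,
                 baseline_logmean = baseline_logmean,
                 baseline_logsd = baseline_logsd,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Generate a synthetic clone cohort
#'
#' Draws the baseline log2 expression of each gene from
#' N(baseline_logmean, baseline_logsd) clipped at 0, then each clone as
#' baseline plus independent N(0, clone_divergence) per gene, clipped
#' at 0. The network is a random graph over the gene symbols; if the
#' model leaves it disconnected only the largest connected component is
#' kept as the network (expression is still generated for every gene).
#'
#' @param cfg a [synthetic_cohort_config()].
#' @return list with `net` (an [interaction_network()]), `clones`
#'   (genes x clones matrix, columns `clone001`...) and `baseline`
#'   (an [expression_profile()]).
#' @export
generate_synthetic_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  g <- if (cfg$network_model == "barabasi_albert") {
    igraph::sample_pa(cfg$n_genes, m = cfg$network_param, directed = FALSE)
  } else {
    igraph::sample_gnp(cfg$n_genes, cfg$network_param)
  }
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  el <- igraph::as_edgelist(g, names = FALSE)
  kept_genes <- genes[keep]
  net <- interaction_network(kept_genes[el[, 1L]], kept_genes[el[, 2L]])
  baseline <- pmax(0, stats::rnorm(cfg$n_genes, cfg$baseline_logmean,
                                   cfg$baseline_logsd))
  clones <- baseline +
    matrix(stats::rnorm(cfg$n_genes * cfg$n_clones, 0, cfg$clone_divergence),
           cfg$n_genes, cfg$n_clones)
  clones <- pmax(clones, 0)
  dimnames(clones) <- list(genes, sprintf("clone%03d", seq_len(cfg$n_clones)))
  list(net = net,
       clones = clones,
       baseline = expression_profile(stats::setNames(baseline, genes),
                                     "baseline"))
}

#' Average k randomly chosen profiles into a bulk mixture
#'
#' Emulates bulk sequencing of a heterogeneous tumor: k columns are
#' sampled without replacement and averaged per gene. The default
#' averages the stored log2-scale values; `scale = "linear"` averages
#' un-logged abundances (2^v) instead, since physical RNA pools mix
#' linearly.
#'
#' @param mat genes x samples matrix (e.g. `clones` from
#'   [generate_synthetic_cohort()]).
#' @param k number of profiles to mix; must not exceed `ncol(mat)`.
#' @param scale `"log2"` (default) or `"linear"`.
#' @param label sample id of the mixture.
#' @return an [expression_profile()]. Uses the current RNG state; seed
#'   upstream for reproducibility.
#' @export
mix_profiles <- function(mat, k, scale = c("log2", "linear"),
                         label = sprintf("mix_k%d", k)) {
  scale <- match.arg(scale)
  if (k < 1L || k > ncol(mat))
    stop(sprintf("k = %d must be between 1 and %d profiles", k, ncol(mat)))
  idx <- sample.int(ncol(mat), k)
  sub <- mat[, idx, drop = FALSE]
  v <- if (scale == "log2") rowMeans(sub) else log2(rowMeans(2^sub))
  expression_profile(stats::setNames(as.numeric(v), rownames(mat)), label)
}

#' Configuration for the clone-mixing experiment
#'
#' @param mixture_sizes numbers of clones per mixture (the study design
#'   doubles from 2 to 512 out of a 675-profile pool).
#' @param replicates mixtures drawn per size.
#' @param seed RNG seed.
#' @return a `mixing_config` list.
#' @export
mixing_config <- function(mixture_sizes = c(2, 4, 8, 16, 32, 64, 128, 256, 512),
                          replicates = 1000, seed = 1L) {
  if (any(mixture_sizes < 1)) stop("mixture sizes must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(mixture_sizes = as.integer(mixture_sizes),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "mixing_config")
}

#' In-silico clone-mixing experiment
#'
#' For each mixture size k, repeatedly averages k randomly chosen
#' clone profiles into a bulk mixture and measures its nJSD distance
#' to the maximally ambiguous state A. Averaging over more, mutually
#' divergent clones washes out each clone's directional signal, so the
#' distance to state A shrinks as k grows — the signature by which a
#' bulk profile betrays a heterogeneous cell population.
#'
#' @param mat genes x samples matrix of clone profiles.
#' @param net an [interaction_network()].
#' @param cfg a [mixing_config()]; every `mixture_sizes` entry must be
#'   <= `ncol(mat)`.
#' @param scale mixing scale, see [mix_profiles()].
#' @return list with `table` (data.frame `k`, `replicate`,
#'   `distance_to_A`) and `summary` (per-k `mean` and `sd`).
#' @export
mixing_experiment <- function(mat, net, cfg, scale = c("log2", "linear")) {
  stopifnot(inherits(cfg, "mixing_config"))
  scale <- match.arg(scale)
  if (any(cfg$mixture_sizes > ncol(mat)))
    stop(sprintf("mixture size %d exceeds the %d available profiles",
                 max(cfg$mixture_sizes), ncol(mat)))
  set.seed(cfg$seed)
  engine <- .njsd_engine(net, rownames(mat))
  va <- rep(1.0, length(engine$universe))
  dist_to_A <- function(profile) {
    tab <- .jsd_per_gene(engine, as.numeric(profile[engine$universe]), va)
    mean(tab$jsd[tab$defined])
  }
  rows <- lapply(cfg$mixture_sizes, function(k) {
    d <- vapply(seq_len(cfg$replicates), function(r)
      dist_to_A(mix_profiles(mat, k, scale)), numeric(1L))
    data.frame(k = k, replicate = seq_len(cfg$replicates),
               distance_to_A = d)
  })
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$k), function(d)
    data.frame(k = d$k[1L], mean = mean(d$distance_to_A),
               sd = stats::sd(d$distance_to_A))))
  summ <- summ[order(summ$k), , drop = FALSE]
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}

#' Is a bulk profile closer to state A than its single cells?
#'
#' Computes the nJSD distance to state A for each single-cell profile
#' and for the bulk profile, then scores the bulk as
#' z = (d_bulk - mean(d_cells)) / sd(d_cells) (sample s.d.) with a
#' one-sided p-value from the lower normal tail. A significantly
#' negative z says the bulk's network state is more ambiguous than any
#' typical constituent cell — the expected footprint of a mixed
#' population.
#'
#' @param cells genes x cells matrix (>= 3 cells).
#' @param bulk bulk [expression_profile()].
#' @param net an [interaction_network()].
#' @return list with `z`, `p`, `d_bulk`, `d_cells` (named vector) and
#'   `defined` (FALSE with `NA` z when the cells' distances have zero
#'   variance).
#' @export
bulk_vs_cells_zscore <- function(cells, bulk, net) {
  if (ncol(cells) < 3L) stop("need >= 3 single-cell profiles")
  universe <- intersect(rownames(cells), names(bulk))
  engine <- .njsd_engine(net, universe)
  va <- rep(1.0, length(engine$universe))
  dist_to_A <- function(v) {
    tab <- .jsd_per_gene(engine, v, va)
    mean(tab$jsd[tab$defined])
  }
  d_cells <- vapply(seq_len(ncol(cells)), function(j)
    dist_to_A(as.numeric(cells[engine$universe, j])), numeric(1L))
  names(d_cells) <- colnames(cells)
  d_bulk <- dist_to_A(as.numeric(bulk[engine$universe]))
  s <- stats::sd(d_cells)
  if (s == 0) {
    warning("single-cell distances have zero variance; z undefined")
    return(list(z = NA_real_, p = NA_real_, d_bulk = d_bulk,
                d_cells = d_cells, defined = FALSE))
  }
  z <- (d_bulk - mean(d_cells)) / s
  list(z = z, p = stats::pnorm(z), d_bulk = d_bulk, d_cells = d_cells,
       defined = TRUE)
}

#' Write a synthetic cohort and mixing experiment to a directory
#'
#' Materializes a [generate_synthetic_cohort()] draw as plain-text
#' files (expression TSV of clones + baseline, edge-list TSV, a small
#' GMT of random gene sets) and runs [mixing_experiment()], writing
#' its table. Used by the `simulate` CLI subcommand.
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param mix_cfg a [mixing_config()] (sizes capped at `n_clones`).
#' @param out_dir output directory, created if needed.
#' @param n_gene_sets,genes_per_set shape of the random GMT.
#' @return invisible list of written paths.
#' @export
write_synthetic_cohort <- function(cfg, mix_cfg, out_dir,
                                   n_gene_sets = 5, genes_per_set = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_synthetic_cohort(cfg)
  expr <- cbind(cohort$clones, baseline = as.numeric(cohort$baseline))
  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    network = file.path(out_dir, "network.tsv"),
    gmt = file.path(out_dir, "gene_sets.gmt"),
    mixing = file.path(out_dir, "mixing.tsv"))
  write_expression(expr, paths$expression)
  edges <- do.call(rbind, lapply(cohort$net$nodes, function(g) {
    nb <- cohort$net$adj[[g]]
    nb <- nb[nb > g]
    if (length(nb)) data.frame(a = g, b = nb) else NULL
  }))
  utils::write.table(edges, paths$network, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  genes <- rownames(cohort$clones)
  gmt <- vapply(seq_len(n_gene_sets), function(i)
    paste(c(sprintf("set%02d", i), "synthetic random gene set",
            sample(genes, min(genes_per_set, length(genes)))),
          collapse = "\t"), character(1L))
  writeLines(gmt, paths$gmt)
  mix_cfg$mixture_sizes <- mix_cfg$mixture_sizes[
    mix_cfg$mixture_sizes <= ncol(cohort$clones)]
  mix <- mixing_experiment(cohort$clones, cohort$net, mix_cfg)
  utils::write.table(mix$table, paths$mixing, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
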