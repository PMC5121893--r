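# Shared fixtures and the independent loop oracle.

# 3-node star: center A with leaves B, C. The center's expression only
# matters for the leaves' (degree-1) distributions and must be > 0.
star_net <- function() interaction_network(c("A", "A"), c("B", "C"))
star_normal <- function() expression_profile(c(A = 1, B = 2, C = 2), "N")
star_tumor <- function() expression_profile(c(A = 1, B = 1, C = 3), "T")

# Random undirected simple graph over n named genes with ~m edges,
# possibly disconnected; at least one edge.
random_net <- function(n, m = 2L * n) {
  genes <- sprintf("G%02d", seq_len(n))
  a <- sample(genes, m, replace = TRUE)
  b <- sample(genes, m, replace = TRUE)
  keep <- a != b
  if (!any(keep)) return(interaction_network(genes[1L], genes[2L]))
  suppressMessages(interaction_network(a[keep], b[keep]))
}

random_profile <- function(genes, id = "x", zero_frac = 0) {
  v <- stats::runif(length(genes), 0.1, 10)
  if (zero_frac > 0)
    v[stats::runif(length(v)) < zero_frac] <- 0
  expression_profile(stats::setNames(v, genes), id)
}

# ---- independent oracle: literal per-gene loop transcription of the
# mass-action distribution, KLD, JSD and their network average. Kept
# deliberately naive and separate from the package's vectorized path.

oracle_kld <- function(p, q, base = 2) {
  s <- 0
  for (l in seq_along(p))
    if (p[l] > 0) s <- s + p[l] * log(p[l] / q[l], base = base)
  s
}

oracle_njsd <- function(x, y, net, base = 2) {
  universe <- sort(intersect(net$nodes, intersect(names(x), names(y))))
  jsds <- numeric(0)
  skipped <- 0L
  for (g in universe) {
    nb <- net$adj[[g]]
    nb <- nb[nb %in% universe]
    if (length(nb) == 0L) next
    ex <- as.numeric(x[nb])
    ey <- as.numeric(y[nb])
    if (sum(ex) == 0 || sum(ey) == 0) {
      skipped <- skipped + 1L
      next
    }
    p <- ex / sum(ex)
    q <- ey / sum(ey)
    m <- (p + q) / 2
    jsds <- c(jsds, oracle_kld(p, m, base) / 2 + oracle_kld(q, m, base) / 2)
  }
  list(value = if (length(jsds)) mean(jsds) else NA_real_,
       n_used = length(jsds), n_skipped = skipped)
}

oracle_tith <- function(normal, tumor, net, base = 2) {
  universe <- sort(intersect(net$nodes,
                             intersect(names(normal), names(tumor))))
  a <- expression_profile(stats::setNames(rep(1, length(universe)), universe),
                          "A")
  jn <- jt <- numeric(0)
  for (g in universe) {
    nb <- net$adj[[g]]
    nb <- nb[nb %in% universe]
    if (length(nb) == 0L) next
    en <- as.numeric(normal[nb]); et <- as.numeric(tumor[nb])
    ea <- as.numeric(a[nb])
    if (sum(en) == 0 || sum(et) == 0) next
    pn <- en / sum(en); pt <- et / sum(et); pa <- ea / sum(ea)
    m1 <- (pn + pt) / 2
    m2 <- (pt + pa) / 2
    jn <- c(jn, oracle_kld(pn, m1, base) / 2 + oracle_kld(pt, m1, base) / 2)
    jt <- c(jt, oracle_kld(pt, m2, base) / 2 + oracle_kld(pa, m2, base) / 2)
  }
  nt <- mean(jn); ta <- mean(jt)
  list(nt = nt, ta = ta,
       tith = if (nt + ta > 0) nt / (nt + ta) else 0)
}

# Small expression TSV on disk; returns the path.
write_expr_fixture <- function(mat, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  write_expression(mat, path)
  path
}
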