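test_that("mass-action neighbor distributions follow expression ratios", {
  net <- star_net()
  # equal expression -> uniform
  d <- neighbor_distribution(star_normal(), net, "A")
  expect_equal(d$neighbors, c("B", "C"))
  expect_equal(d$probs, c(0.5, 0.5))
  # e_B = 1, e_C = 3 -> (0.25, 0.75)
  d <- neighbor_distribution(star_tumor(), net, "A")
  expect_equal(d$probs, c(0.25, 0.75))
  # all-zero neighborhood is flagged undefined, not imputed
  zero <- expression_profile(c(A = 1, B = 0, C = 0), "z")
  d <- neighbor_distribution(zero, net, "A")
  expect_false(d$defined)
  expect_true(all(is.na(d$probs)))
  # absent gene errors
  expect_error(neighbor_distribution(star_normal(), net, "Z"),
               "not in the network")
  # neighbors missing from the profile are dropped
  partial <- expression_profile(c(A = 1, B = 4), "p")
  d <- neighbor_distribution(partial, net, "A")
  expect_equal(d$neighbors, "B")
  expect_equal(d$probs, 1)
})

test_that("kld matches hand-computed values and rejects bad input", {
  expect_equal(kld(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kld(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(kld(c(0.25, 0.75), c(0.375, 0.625)), 0.051035, tolerance = 1e-5)
  expect_error(kld(c(1, 0), c(0, 1)), "infinite divergence")
  expect_error(kld(c(0.5, 0.5), c(0.3, 0.3)), "sum to 1")
  expect_error(kld(c(1), c(0.5, 0.5)), "equal length")
})

test_that("gene_jsd is symmetric, bounded, and guards alignment", {
  net <- star_net()
  p <- neighbor_distribution(star_normal(), net, "A")
  q <- neighbor_distribution(star_tumor(), net, "A")
  j <- gene_jsd(p, q)
  expect_equal(j$jsd, 0.048795, tolerance = 1e-5)
  expect_equal(gene_jsd(q, p)$jsd, j$jsd)
  # identical distributions
  expect_equal(gene_jsd(p, p)$jsd, 0)
  # disjoint support reaches the base-2 maximum of 1
  pd <- structure(list(gene = "A", neighbors = c("B", "C"),
                       probs = c(1, 0), defined = TRUE),
                  class = "neighbor_distribution")
  qd <- structure(list(gene = "A", neighbors = c("B", "C"),
                       probs = c(0, 1), defined = TRUE),
                  class = "neighbor_distribution")
  expect_equal(gene_jsd(pd, qd)$jsd, 1)
  # one undefined side flags the result
  zero <- expression_profile(c(A = 1, B = 0, C = 0), "z")
  u <- neighbor_distribution(zero, net, "A")
  expect_false(gene_jsd(p, u)$defined)
  # mismatched neighbors error
  q2 <- q; q2$neighbors <- c("B", "D")
  expect_error(gene_jsd(p, q2), "not aligned")
  q3 <- q; q3$gene <- "B"
  expect_error(gene_jsd(p, q3), "different genes")
})

test_that("njsd equals the worked star example and basic identities", {
  net <- star_net()
  r <- njsd(star_normal(), star_tumor(), net)
  # leaves are degree-1: point-mass distributions, jsd 0
  expect_equal(r$per_gene$jsd[r$per_gene$gene %in% c("B", "C")], c(0, 0))
  expect_equal(r$value, mean(c(0.048795, 0, 0)), tolerance = 1e-5)
  expect_equal(r$n_genes_used, 3L)

  # identity and two-gene path
  expect_equal(njsd(star_normal(), star_normal(), net)$value, 0)
  path2 <- interaction_network("A", "B")
  x <- expression_profile(c(A = 1, B = 2), "x")
  y <- expression_profile(c(A = 3, B = 1), "y")
  r2 <- njsd(x, y, path2)
  # both genes are degree-1 -> both divergences equal (here 0)
  expect_equal(r2$per_gene$jsd[1], r2$per_gene$jsd[2])

  # zero-usable-genes error
  z1 <- expression_profile(c(A = 0, B = 0, C = 0), "z")
  expect_error(njsd(z1, z1, net), "no gene yields a defined divergence")
})

test_that("njsd properties hold over fuzzed networks and profiles", {
  set.seed(7)
  for (i in 1:40) {
    net <- random_net(sample(5:15, 1))
    x <- random_profile(net$nodes, "x", zero_frac = 0.1)
    y <- random_profile(net$nodes, "y", zero_frac = 0.1)
    rxy <- tryCatch(njsd(x, y, net), error = function(e) NULL)
    if (is.null(rxy)) next
    ryx <- njsd(y, x, net)
    # bounds and symmetry
    ok <- rxy$per_gene$defined
    expect_true(all(rxy$per_gene$jsd[ok] >= 0 & rxy$per_gene$jsd[ok] <= 1))
    expect_identical(rxy$value, ryx$value)
    # identity of indiscernibles
    expect_equal(njsd(x, x, net)$value, 0)
    # scaling invariance
    xs <- expression_profile(unclass(x) * 7.3, "xs")
    expect_equal(njsd(xs, y, net)$value, rxy$value, tolerance = 1e-12)
    # oracle agreement on the same instance
    o <- oracle_njsd(x, y, net)
    expect_equal(rxy$value, o$value, tolerance = 1e-12)
    expect_equal(rxy$n_genes_used, o$n_used)
    expect_equal(rxy$n_genes_skipped, o$n_skipped)
  }
})

test_that("per-gene JSD tables write to TSV", {
  dir <- withr::local_tempdir()
  r <- njsd(star_normal(), star_tumor(), star_net())
  path <- write_jsd_table(r, file.path(dir, "jsd.tsv"))
  back <- read.delim(path)
  expect_equal(back$gene, c("A", "B", "C"))
  expect_equal(back$jsd, r$per_gene$jsd, tolerance = 1e-12)
})
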