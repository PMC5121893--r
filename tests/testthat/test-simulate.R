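test_that("synthetic cohorts are reproducible and respect divergence", {
  cfg <- synthetic_cohort_config(n_genes = 60, n_clones = 10,
                                 clone_divergence = 0, seed = 9)
  a <- generate_synthetic_cohort(cfg)
  b <- generate_synthetic_cohort(cfg)
  # same seed -> bit-identical
  expect_identical(a$clones, b$clones)
  expect_identical(a$net$adj, b$net$adj)
  # zero divergence -> every clone equals the baseline
  expect_equal(max(abs(a$clones - as.numeric(a$baseline))), 0)
  # network connected (single component) by construction
  expect_true(all(rownames(a$clones) %in% names(a$baseline)))
  expect_gte(length(a$net$nodes), 2L)
  expect_error(synthetic_cohort_config(n_genes = 5), "n_genes")
  expect_error(synthetic_cohort_config(clone_divergence = -1), "divergence")
})

test_that("larger clone divergence yields larger nJSD to baseline", {
  mean_d <- function(div, seed) {
    cfg <- synthetic_cohort_config(n_genes = 80, n_clones = 50,
                                   clone_divergence = div, seed = seed)
    co <- generate_synthetic_cohort(cfg)
    vapply(seq_len(ncol(co$clones)), function(j)
      njsd(co$baseline, profile_from_matrix(co$clones, j), co$net)$value,
      numeric(1))
  }
  d1 <- mean_d(0.3, 21)
  d2 <- mean_d(1.5, 21)
  expect_lt(wilcox.test(d1, d2, alternative = "less")$p.value, 0.01)
})

test_that("mix_profiles averages sampled columns", {
  mat <- cbind(c1 = c(B = 1, C = 3), c2 = c(B = 3, C = 1))
  set.seed(1)
  m <- mix_profiles(mat, 2)
  expect_equal(unname(m[c("B", "C")]), c(2, 2))
  # k = 1 returns one original column
  m1 <- mix_profiles(mat, 1)
  expect_true(any(sapply(1:2, function(j)
    isTRUE(all.equal(unname(m1[rownames(mat)]), unname(mat[, j]))))))
  # k = all columns is the global mean regardless of draw
  expect_equal(as.numeric(mix_profiles(mat, 2)), unname(rowMeans(mat)))
  expect_error(mix_profiles(mat, 3), "between 1 and 2")
  # linear-scale mixing averages 2^v
  mlin <- mix_profiles(mat, 2, scale = "linear")
  expect_equal(unname(mlin["B"]), log2((2^1 + 2^3) / 2))
})

test_that("mixing_experiment is seeded and flat for identical clones", {
  cfg <- synthetic_cohort_config(n_genes = 60, n_clones = 16,
                                 clone_divergence = 0, seed = 2)
  co <- generate_synthetic_cohort(cfg)
  mc <- mixing_config(mixture_sizes = c(1, 4, 16), replicates = 3, seed = 5)
  r <- mixing_experiment(co$clones, co$net, mc)
  # mixing identical profiles is a no-op for the distance
  expect_equal(diff(range(r$table$distance_to_A)), 0, tolerance = 1e-12)
  expect_equal(nrow(r$table), 9L)
  # determinism
  r2 <- mixing_experiment(co$clones, co$net, mc)
  expect_identical(r$table, r2$table)
  expect_error(mixing_experiment(co$clones, co$net,
                                 mixing_config(mixture_sizes = 32,
                                               replicates = 1)),
               "exceeds")
})

test_that("distance to state A shrinks as divergent clones are mixed", {
  cfg <- synthetic_cohort_config(n_genes = 100, n_clones = 32,
                                 clone_divergence = 1, seed = 13)
  co <- generate_synthetic_cohort(cfg)
  mc <- mixing_config(mixture_sizes = c(1, 4, 32), replicates = 30, seed = 13)
  r <- mixing_experiment(co$clones, co$net, mc)
  expect_true(all(diff(r$summary$mean) <= 0))
  expect_lt(r$summary$mean[3], r$summary$mean[1])
})

test_that("bulk_vs_cells_zscore flags mixtures and behaves under the null", {
  cfg <- synthetic_cohort_config(n_genes = 100, n_clones = 50,
                                 clone_divergence = 1, seed = 31)
  co <- generate_synthetic_cohort(cfg)
  bulk <- expression_profile(
    stats::setNames(rowMeans(co$clones), rownames(co$clones)), "bulk")
  r <- bulk_vs_cells_zscore(co$clones, bulk, co$net)
  expect_true(r$defined)
  expect_lt(r$z, 0)
  expect_lt(r$p, 0.05)
  # null: bulk is just another i.i.d. clone -> |z| small typically
  cfg2 <- synthetic_cohort_config(n_genes = 100, n_clones = 51,
                                  clone_divergence = 1, seed = 32)
  co2 <- generate_synthetic_cohort(cfg2)
  rn <- bulk_vs_cells_zscore(co2$clones[, 1:50],
                             profile_from_matrix(co2$clones, 51), co2$net)
  expect_lt(abs(rn$z), 4)
  # zero variance across cells is flagged
  flat <- generate_synthetic_cohort(
    synthetic_cohort_config(n_genes = 60, n_clones = 4,
                            clone_divergence = 0, seed = 1))
  expect_warning(
    rz <- bulk_vs_cells_zscore(flat$clones, flat$baseline, flat$net),
    "zero variance")
  expect_false(rz$defined)
  expect_error(bulk_vs_cells_zscore(flat$clones[, 1:2], flat$baseline,
                                    flat$net),
               ">= 3")
})

test_that("write_synthetic_cohort materializes a readable fixture set", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_cohort_config(n_genes = 40, n_clones = 8, seed = 4)
  mc <- mixing_config(mixture_sizes = c(1, 2, 8), replicates = 2, seed = 4)
  paths <- write_synthetic_cohort(cfg, mc, dir)
  expect_true(all(file.exists(unlist(paths))))
  mat <- load_expression(paths$expression)
  expect_equal(ncol(mat), 9L)  # clones + baseline
  net <- load_network(paths$network)
  expect_gte(net$n_edges, 1L)
  col <- load_gmt(paths$gmt)
  expect_gte(length(col), 1L)
  mix <- read.delim(paths$mixing)
  expect_named(mix, c("k", "replicate", "distance_to_A"))
})
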