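test_that("identical seeds give bit-identical datasets", {
  s1 <- simulate_expression(small_synthetic(seed = 7))
  s2 <- simulate_expression(small_synthetic(seed = 7))
  expect_identical(s1$raw, s2$raw)
  expect_identical(s1$expr$signal, s2$expr$signal)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_expression(small_synthetic(seed = 8))
  expect_false(identical(s1$raw, s3$raw))
})

test_that("zero diffusion and no effects give identical tissues", {
  spec <- null_spec(small_synthetic(seed = 3, tau2 = 0, replicate_sd = 0))
  sim <- simulate_expression(spec)
  expect_equal(sim$expr$signal, sim$expr$signal[, 1] %o%
                 rep(1, ncol(sim$expr$signal)), ignore_attr = TRUE)
  pr <- prank_transform(sim$expr)
  e <- gene_divergence(pr, sim$expr$tissue_ids[1], sim$expr$tissue_ids[2])
  expect_true(all(e == 0))
  le <- log_expression(sim$expr)
  expect_equal(module_distance(le, sim$modules[[1]],
                               sim$expr$tissue_ids[1],
                               sim$expr$tissue_ids[3]), 0)
})

test_that("null_spec strips planted effects and truth labels", {
  spec <- small_synthetic(seed = 2)
  nspec <- null_spec(spec)
  expect_identical(nspec$n_conserved, 0L)
  expect_identical(nspec$n_divergent, 0L)
  expect_identical(nspec$n_correlated, 0L)
  sim <- simulate_expression(nspec)
  expect_true(all(sim$truth$role == "null"))
})

test_that("leaf correlation decays with tree distance", {
  sim <- simulate_expression(null_spec(synthetic_spec(
    n_genes = 1500L, n_modules = 10L, module_size = 20L,
    n_conserved = 0L, n_divergent = 0L, seed = 5)))
  S <- log_expression(sim$expr)
  tree <- sim$spec$fate_map$tree
  dists <- ape::cophenetic.phylo(tree)
  prs <- t(utils::combn(colnames(S), 2))
  d <- apply(prs, 1, function(p) dists[p[1], p[2]])
  r <- apply(prs, 1, function(p) cor(S[, p[1]], S[, p[2]]))
  # average correlation within distance bands decreases monotonically
  bands <- split(r, cut(d, breaks = c(0, 3, 6, 9, Inf)))
  means <- vapply(bands, mean, 0)
  expect_true(all(diff(means) < 0))
})

test_that("planted conserved modules shrink within-clade distances", {
  sim <- simulate_expression(small_synthetic(seed = 9))
  le <- log_expression(sim$expr)
  prs <- node_pairs(sim$spec$fate_map, sim$spec$target_node)
  D <- all_pair_distances(le, sim$modules, prs)
  Dm <- tapply(D$D, D$module_id, mean)
  cons <- sim$truth$module_id[sim$truth$role == "conserved"]
  nul <- sim$truth$module_id[sim$truth$role == "null"]
  expect_lt(max(Dm[cons]), min(Dm[nul]))
})

test_that("planted correlated modules exceed the r_mean threshold", {
  sim <- simulate_expression(small_synthetic(seed = 10))
  le <- log_expression(sim$expr)
  prs <- node_pairs(sim$spec$fate_map, "Zygote")
  corr <- sim$truth$module_id[sim$truth$role == "correlated"]
  r_mean <- vapply(corr, function(m) {
    mean(apply(prs, 1, function(p)
      module_correlation(le, sim$modules[[m]], p[1], p[2])))
  }, 0)
  expect_true(all(r_mean > 0.9))
})

test_that("synthetic dataset round-trips through the standard formats", {
  dir <- withr::local_tempdir()
  sim <- simulate_expression(small_synthetic(seed = 12))
  paths <- write_synthetic_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  rm_df <- read.delim(paths[["replicate_map"]])
  rmap <- stats::setNames(rm_df$tissue, rm_df$raw_column)
  back <- read_expression_table(paths[["expression"]], replicate_map = rmap)
  expect_equal(back$signal, sim$expr$signal)
  sets <- suppressMessages(read_gene_sets(paths[["gene_sets"]],
                                          universe = back$gene_ids))
  expect_identical(names(sets), names(sim$modules))
  map <- read_fatemap(paths[["fate_map"]], paths[["fate_map_meta"]])
  expect_setequal(map$leaves, sim$spec$fate_map$leaves)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_genes = 10L, module_size = 20L),
               "module_size exceeds")
  expect_error(synthetic_spec(n_genes = 100L, n_modules = 10L,
                              module_size = 20L), "layout exceeds")
  expect_error(small_synthetic(target_node = "NoSuchNode"), "unknown target")
  expect_error(small_synthetic(conserved_factor = 0), "conserved_factor")
})
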