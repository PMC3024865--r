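log2_fixture <- function() {
  set.seed(31)
  mat <- matrix(2^rnorm(200 * 4, 6, 2), 200, 4,
                dimnames = list(sprintf("g%03d", 1:200),
                                c("t1", "t2", "t3", "t4")))
  expression_matrix(mat)
}

test_that("module distance is the size-normalized squared log2 difference", {
  le <- matrix(c(5, 4, 6, 7), 2, 2,
               dimnames = list(c("gA", "gB"), c("t1", "t2")))
  # log2 differences 1 and 3 -> D = (1 + 9)/2 = 5
  expect_equal(module_distance(le, c("gA", "gB"), "t1", "t2"), 5)
  expect_equal(module_distance(le, c("gA", "gB"), "t2", "t1"), 5)
  expect_equal(module_distance(le, c("gA", "gB"), "t1", "t1"), 0)
  expect_equal(module_distance(le, c("gA", "gB"), "t1", "t2",
                               method = "euclidean"), sqrt(5))
  expect_error(module_distance(le, c("gA", "gZ"), "t1", "t2"), "gZ")
})

test_that("module distance is invariant to common rescaling of raw signals", {
  em <- log2_fixture()
  genes <- rownames(em$signal)[1:12]
  d1 <- module_distance(log_expression(em), genes, "t1", "t2")
  doubled <- expression_matrix(em$signal * 2)
  d2 <- module_distance(log_expression(doubled), genes, "t1", "t2")
  expect_equal(d1, d2)
})

test_that("distance null fit recovers moments and flags degenerate pools", {
  msg <- capture.output(null <- fit_distance_null(c(1, 2, 3)),
                        type = "message")
  expect_equal(null$mu, 2)
  expect_equal(null$sigma, 1)
  expect_match(paste(msg, collapse = " "), "skewness")
  set.seed(8)
  pool <- rnorm(1e4, 5, 2)
  null2 <- suppressMessages(fit_distance_null(pool))
  se_mu <- 2 / sqrt(1e4)
  expect_lt(abs(null2$mu - 5), 3 * se_mu)
  expect_lt(abs(null2$sigma - 2), 3 * 2 / sqrt(2 * 1e4))
  expect_error(fit_distance_null(rep(1, 50)), "zero variance")
})

test_that("distance p-value is the lower-tail normal probability", {
  null <- suppressMessages(fit_distance_null(c(rnorm(100, 10, 2), 10, 12)))
  null$mu <- 10; null$sigma <- 2
  expect_equal(distance_pvalue(10, null), 0.5)
  expect_equal(distance_pvalue(10 - 1.96 * 2, null), pnorm(-1.96))
  expect_lt(distance_pvalue(0, null), 1e-6)
  # monotone increasing in D
  d <- seq(0, 20, length.out = 50)
  expect_true(all(diff(distance_pvalue(d, null)) > 0))
})

test_that("integrated distance p shrinks the null variance by the group size", {
  null <- structure(list(mu = 10, sigma = 2, n = 1000, skewness = 0,
                         kurtosis_excess = 0), class = "DistanceNull")
  # single pair reduces to the pairwise p-value
  expect_equal(integrated_distance_pvalue(7.3, null), distance_pvalue(7.3, null))
  # N = 4, D_sub = mu - sigma/2 -> z = -1
  expect_equal(integrated_distance_pvalue(rep(10 - 1, 4), null), pnorm(-1))
  expect_equal(integrated_distance_pvalue(rep(10, 7), null), 0.5)
  # decreasing in N below mu
  p_n <- vapply(1:6, function(N) integrated_distance_pvalue(rep(9, N), null), 0)
  expect_true(all(diff(p_n) < 0))
  expect_error(integrated_distance_pvalue(numeric(0), null), "no distance")
})

test_that("module KS agrees with the exhaustive-enumeration oracle", {
  set.seed(12)
  for (n in 2:5) {
    x <- round(runif(n), 6)
    y <- round(runif(n) + 0.1, 6)
    pr <- rbind(matrix(c(x, y), n, 2), matrix(runif(2 * 5), 5, 2))
    rownames(pr) <- paste0("g", seq_len(nrow(pr)))
    colnames(pr) <- c("a", "b")
    p_pkg <- module_ks(pr, paste0("g", 1:n), "a", "b")
    expect_equal(p_pkg, ks_oracle(x, y), tolerance = 1e-10)
  }
  # complete separation of 3 vs 3: p = 2 / C(6,3) = 0.1 exactly
  pr <- cbind(a = c(0.1, 0.2, 0.3), b = c(0.7, 0.8, 0.9))
  rownames(pr) <- paste0("g", 1:3)
  expect_equal(module_ks(pr, paste0("g", 1:3), "a", "b"), 0.1)
  # identical samples: p = 1
  pr2 <- cbind(a = c(0.2, 0.5, 0.8), b = c(0.2, 0.5, 0.8))
  rownames(pr2) <- paste0("g", 1:3)
  expect_equal(module_ks(pr2, paste0("g", 1:3), "a", "b"), 1)
})

test_that("module KS p-values are calibrated under the null", {
  set.seed(77)
  reps <- 1500
  ps <- vapply(seq_len(reps), function(i) {
    pr <- matrix(runif(40), 20, 2,
                 dimnames = list(paste0("g", 1:20), c("a", "b")))
    module_ks(pr, paste0("g", 1:20), "a", "b")
  }, 0)
  # discrete exact p-values are stochastically >= uniform; check type-I level
  expect_lt(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("Stouffer integration of KS p-values follows the closed form", {
  expect_equal(integrate_ks(c(0.5, 0.5))$z_sub, 0)
  expect_equal(integrate_ks(c(0.5, 0.5))$p, 0.5)
  z2 <- integrate_ks(c(0.05, 0.05))
  expect_equal(z2$z_sub, 2 * qnorm(0.05) / sqrt(2))
  expect_equal(z2$p, pnorm(2 * qnorm(0.05) / sqrt(2)))
  # n = 1 is the identity
  expect_equal(integrate_ks(0.123)$p, 0.123)
  expect_warning(out <- integrate_ks(c(0, 0.5)), "clamped")
  expect_true(is.finite(out$z_sub))
  expect_error(integrate_ks(numeric(0)), "no p-values")
})

test_that("module correlation matches hand-computed Pearson r", {
  mat <- cbind(t1 = c(1, 2, 3), t2 = c(1, 2, 4), t3 = c(3, 2, 1),
               t4 = c(5, 5, 5))
  rownames(mat) <- c("gA", "gB", "gC")
  genes <- c("gA", "gB", "gC")
  expect_equal(module_correlation(mat, genes, "t1", "t1"), 1)
  expect_equal(module_correlation(mat, genes, "t1", "t3"), -1)
  expect_equal(module_correlation(mat, genes, "t1", "t2"), 9 / sqrt(84))
  expect_warning(r <- module_correlation(mat, genes, "t1", "t4"),
                 "constant profile")
  expect_true(is.na(r))
  # invariant to per-tissue affine rescaling
  mat2 <- mat; mat2[, "t2"] <- 3 * mat2[, "t2"] + 7
  expect_equal(module_correlation(mat2, genes, "t1", "t2"), 9 / sqrt(84))
})

test_that("node summary flags follow the thresholds and reduce for one pair", {
  em <- log2_fixture()
  le <- log_expression(em)
  pr <- prank_transform(em)
  mods <- gene_set_collection(list(M1 = sprintf("g%03d", 1:10),
                                   M2 = sprintf("g%03d", 11:20)),
                              rownames(le))
  null <- suppressMessages(
    fit_distance_null(all_pair_distances(le, mods)))
  prs <- rbind(c("t1", "t2"))
  st <- module_pair_stats(le, pr, mods, pairs = prs)
  sm <- summarize_node(st, null)
  expect_identical(nrow(sm), 2L)
  # one pair: integrated quantities equal the pairwise ones
  expect_equal(sm$D_sub, st$D)
  expect_equal(sm$p_distance, distance_pvalue(st$D, null))
  expect_equal(sm$p_ks, st$p_ks)
  expect_equal(sm$r_mean, st$r)
  expect_identical(sm$conserved, sm$p_distance < 0.05)
  expect_identical(sm$correlated, sm$r_mean > 0.9)
  expect_true(all(sm$p_distance_bh >= sm$p_distance))
  # missing pair stats are a hard error
  st_broken <- module_pair_stats(le, pr, mods,
                                 pairs = rbind(c("t1", "t2"), c("t1", "t3")))
  expect_error(summarize_node(st_broken[-1, ], null), "missing pair")
})

test_that("a module identical across tissues is conserved and correlated, not differential", {
  set.seed(55)
  mat <- matrix(2^rnorm(100 * 3, 6, 2), 100, 3,
                dimnames = list(sprintf("g%03d", 1:100), c("t1", "t2", "t3")))
  # module genes: identical values in every tissue
  mat[1:10, 2] <- mat[1:10, 1]
  mat[1:10, 3] <- mat[1:10, 1]
  em <- expression_matrix(mat)
  le <- log_expression(em); pr <- prank_transform(em)
  mods <- gene_set_collection(split(sprintf("g%03d", 1:100),
                                    rep(1:10, each = 10)), rownames(mat))
  null <- suppressMessages(fit_distance_null(all_pair_distances(le, mods)))
  st <- module_pair_stats(le, pr, mods)
  # identical samples give KS p = 1, which the quantile transform must clamp
  expect_warning(sm <- summarize_node(st, null), "clamped")
  row <- sm[sm$module_id == "1", ]
  expect_true(row$conserved)
  expect_false(row$differential)
  expect_true(row$correlated)
  expect_equal(row$r_mean, 1)
})
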