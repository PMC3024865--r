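make_pr <- function(...) {
  cols <- list(...)
  mat <- do.call(cbind, cols)
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  mat
}

test_that("p-rank transform gives tie-averaged fractional ranks", {
  mat <- matrix(c(10, 20, 30, 40,
                  10, 10, 30, 40,
                  7, 7, 7, 7), 4, 3,
                dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  pr <- prank_transform(mat)
  expect_equal(unname(pr[, "a"]), c(0.25, 0.5, 0.75, 1))
  expect_equal(unname(pr[, "b"]), c(0.375, 0.375, 0.75, 1))
  # full tie: all ranks (n+1)/(2n)
  expect_equal(unname(pr[, "c"]), rep(5 / 8, 4))
})

test_that("p-rank transform is invariant to strictly monotone transforms", {
  set.seed(5)
  x <- matrix(rexp(300), 100, 3,
              dimnames = list(paste0("g", 1:100), c("a", "b", "c")))
  expect_equal(prank_transform(x), prank_transform(log1p(x)))
  expect_equal(prank_transform(x), prank_transform(x^3 + 2))
})

test_that("gene divergence is the absolute p-rank difference, symmetric and bounded", {
  pr <- make_pr(a = c(0.25, 0.5, 0.75, 1), b = c(1, 0.75, 0.5, 0.25))
  e <- gene_divergence(pr, "a", "b")
  expect_equal(unname(e), c(0.75, 0.25, 0.25, 0.75))
  expect_equal(e, gene_divergence(pr, "b", "a"))
  expect_equal(unname(gene_divergence(pr, "a", "a")), rep(0, 4))
  # attained bound (n-1)/n for a gene lowest in one tissue, highest in the other
  expect_equal(max(e), (4 - 1) / 4)
  expect_error(gene_divergence(pr, "a", "zz"), "unknown tissue")
})

test_that("divergence bound holds on random data", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:200, 1)
    mat <- matrix(rexp(2 * n), n, 2, dimnames = list(paste0("g", 1:n),
                                                     c("a", "b")))
    pr <- prank_transform(mat)
    e <- gene_divergence(pr, "a", "b")
    expect_true(all(pr > 0 & pr <= 1))
    expect_true(all(e >= 0 & e <= (n - 1) / n))
  }
})

test_that("conserved genes are the lowest-q fraction with threshold ties included", {
  # 10 distinct values, q = 0.05 -> ceiling(0.5) = 1 smallest
  e <- stats::setNames(seq(0, 0.9, by = 0.1), paste0("g", 1:10))
  expect_identical(conserved_genes(e, 0.05), "g1")
  # 100 distinct values -> exactly the 5 smallest
  set.seed(3)
  e100 <- stats::setNames(sample(seq_len(100)) / 101, paste0("g", 1:100))
  expect_identical(sort(conserved_genes(e100, 0.05)),
                   sort(names(sort(e100))[1:5]))
  # full tie at the threshold: everything returned
  e_tie <- stats::setNames(rep(0.2, 7), paste0("g", 1:7))
  expect_length(conserved_genes(e_tie, 0.05), 7L)
})

test_that("ubiquitous conservation intersects per-pair conserved sets", {
  set.seed(17)
  n <- 100
  base <- rexp(n)
  mat <- cbind(a = base,
               b = base[c(2:n, 1)],
               c = base[c(3:n, 1:2)])
  rownames(mat) <- paste0("g", 1:n)
  pr <- prank_transform(mat)
  # plant one gene with equal p-rank in all three tissues
  pr["g1", ] <- 0.42
  res <- ubiquitous_conserved(pr, c("a", "b", "c"), q = 0.1)
  expect_true("g1" %in% res)
  manual <- Reduce(intersect, list(
    conserved_genes(gene_divergence(pr, "a", "b"), 0.1),
    conserved_genes(gene_divergence(pr, "a", "c"), 0.1),
    conserved_genes(gene_divergence(pr, "b", "c"), 0.1)))
  expect_setequal(res, manual)
  # two tissues reduce to the single-pair conserved set
  expect_setequal(ubiquitous_conserved(pr, c("a", "b"), q = 0.1),
                  conserved_genes(gene_divergence(pr, "a", "b"), 0.1))
  expect_error(ubiquitous_conserved(pr, "a"), "at least 2")
})

test_that("top-expression mode returns genes highly ranked in every tissue", {
  pr <- make_pr(a = (1:20) / 20, b = c((1:19) / 20, 1))
  res <- ubiquitous_conserved(pr, c("a", "b"), q = 0.1, mode = "top_expression")
  # the p-rank >= 1 - q boundary is inclusive: g18 sits exactly at 0.9
  expect_setequal(res, c("g18", "g19", "g20"))
})

test_that("stratified divergence reflects lineage distance on tree-structured data", {
  sim <- simulate_expression(null_spec(small_synthetic(seed = 42)))
  pr <- prank_transform(sim$expr)
  res <- divergence_by_pair_class(pr, sim$spec$fate_map)
  m <- stats::setNames(res$summary$mean_E, res$summary$class)
  expect_lt(m["inner"], m["mid"])
  expect_lt(m["mid"], m["outer"])
  expect_lt(res$tests$t_p[res$tests$comparison == "inner_vs_outer"], 0.05)
  expect_identical(sum(res$summary$n_pairs), as.integer(choose(24L, 2L)))
})

test_that("degenerate identical tissues give zero means and unavailable tests", {
  mat <- matrix(rep(rexp(50), 4), 50, 4,
                dimnames = list(paste0("g", 1:50), c("t1", "t2", "t3", "t4")))
  res <- divergence_by_pair_class(prank_transform(mat), toy_fatemap())
  # the toy map has no mid pairs: that class is reported as unavailable
  expect_identical(res$summary$n_pairs, c(2L, 0L, 4L))
  expect_equal(res$summary$mean_E[c(1, 3)], c(0, 0))
  expect_true(is.na(res$summary$mean_E[2]))
  expect_true(all(is.na(res$tests$t_p)))
})
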