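test_that("spearman distance has the rank-based properties", {
  x <- rbind(inc = 1:6, dec = 6:1, noisy = c(2, 1, 4, 3, 6, 5))
  colnames(x) <- paste0("s", 1:6)
  d <- spearman_distance_matrix(x)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["inc", "dec"], 2)              # rho = -1
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(d, t(d))
  # strictly increasing transform leaves distances unchanged
  x2 <- x; x2["noisy", ] <- exp(x2["noisy", ])
  expect_equal(spearman_distance_matrix(x2), d)
  # constant genes excluded with warning
  x3 <- rbind(x, flat = rep(1, 6))
  expect_warning(d3 <- spearman_distance_matrix(x3), "constant")
  expect_false("flat" %in% rownames(d3))
  expect_error(spearman_distance_matrix(x[, 1:2]), "3 samples")
})

test_that("UPGMA reproduces the hand-worked merge sequence", {
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- average_linkage_tree(d)
  expect_equal(tr$height, c(0.1, 0.9))
  expect_equal(tr$leafsets[[1]], c("A", "B"))
  expect_equal(tr$leafsets[[2]], c("A", "B", "C"))
  # identical profiles merge at height zero
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 1, 2))
  colnames(x) <- paste0("s", 1:4)
  tr2 <- average_linkage_tree(spearman_distance_matrix(x))
  expect_equal(tr2$height[1], 0)
  expect_error(average_linkage_tree(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("UPGMA matches the from-scratch oracle on random instances", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(3:5, 1)
    # coarse grid values provoke ties, exercising the tie-break
    m <- matrix(sample(seq(0.1, 1, by = 0.1), n * n, replace = TRUE), n, n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    rownames(d) <- colnames(d) <- sample(LETTERS, n)
    tr <- average_linkage_tree(d)
    orc <- upgma_oracle(d)
    expect_equal(tr$height, orc$heights, tolerance = 1e-12)
    expect_equal(tr$leafsets, orc$leafsets)
    # merge heights non-decreasing (monotone linkage)
    expect_true(all(diff(tr$height) >= -1e-12))
    # heights agree with stats::hclust average linkage
    expect_equal(sort(tr$height),
                 sort(stats::hclust(stats::as.dist(d), "average")$height),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap support separates planted modules from noise", {
  ex <- module_expression(n_per_module = 6, n_background = 4, seed = 2)
  truth <- attr(ex, "truth")
  sup <- bootstrap_support(ex, nboot = 200, seed = 31)
  expect_true(all(sup$bp >= 0 & sup$bp <= 1))
  mods <- split(truth$gene[truth$role == "module"],
                truth$module[truth$role == "module"])
  sets <- lapply(strsplit(sup$leafset, ";"), sort)
  for (m in mods) {
    i <- which(vapply(sets, identical, TRUE, y = sort(m)))
    expect_length(i, 1L)
    expect_gte(sup$bp[i], 0.95)
  }
  # bit-for-bit reproducible under a fixed seed
  sup2 <- bootstrap_support(ex, nboot = 200, seed = 31)
  expect_identical(sup$bp, sup2$bp)
  expect_error(bootstrap_support(ex, nboot = 0), "nboot")
})

test_that("independent genes give weak support for random-sized clusters", {
  set.seed(5)
  x <- matrix(rnorm(12 * 20), 12, 20,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:20)))
  sup <- bootstrap_support(x, nboot = 150, seed = 6)
  inner <- sup[sup$size < 12, ]  # root excluded: trivially BP = 1
  expect_lt(mean(inner$bp), 0.3)
})

test_that("AU support: planted modules high, degenerate nodes flagged", {
  ex <- module_expression(n_per_module = 6, n_background = 2,
                          n_samples = 20, seed = 3)
  truth <- attr(ex, "truth")
  sup <- au_pvalues(ex, nboot_per_scale = 100, seed = 13)
  expect_true(all(sup$au >= 0 & sup$au <= 1))
  # root: BP = 1 at every scale -> AU = 1, degenerate, SE 0
  root <- which(sup$size == length(attr(sup, "tree")$labels))
  expect_true(sup$degenerate[root])
  expect_equal(sup$au[root], 1)
  expect_equal(sup$se_au[root], 0)
  mods <- split(truth$gene[truth$role == "module"],
                truth$module[truth$role == "module"])
  sets <- lapply(strsplit(sup$leafset, ";"), sort)
  for (m in mods) {
    i <- which(vapply(sets, identical, TRUE, y = sort(m)))
    expect_gte(sup$au[i], 0.95)
  }
  expect_error(au_pvalues(ex, scale_factors = 1), "2 scale factors")
})

test_that("significant_clusters keeps only maximal passing nodes", {
  # hand-built 6-leaf support table: nested passing nodes
  sup <- data.frame(
    node = 1:5, size = c(2, 3, 2, 5, 6),
    bp = 1, au = c(0.97, 0.99, 0.50, 0.96, 1.0),
    leafset = c("a;b", "a;b;c", "d;e", "a;b;c;d;e", "a;b;c;d;e;f"))
  # root passes and absorbs everything under the literal contract
  all_in <- significant_clusters(sup, alpha = 0.95)
  expect_equal(all_in$leafset, "a;b;c;d;e;f")
  # with the root screened out, the maximal passing non-root nodes remain:
  # node 4 absorbs nodes 1 and 2; node 3 fails alpha
  out <- significant_clusters(sup, alpha = 0.95, include_root = FALSE)
  expect_equal(out$leafset, "a;b;c;d;e")
  # alpha = 0: the root cluster
  expect_equal(significant_clusters(sup, alpha = 0)$leafset, "a;b;c;d;e;f")
  # nothing passes
  expect_equal(nrow(significant_clusters(sup, alpha = 1.01)), 0L)
})

test_that("newick export writes a parseable tree with node labels", {
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- average_linkage_tree(d)
  nw <- write_newick(tr, node_labels = c("n1", "n2"))
  expect_match(nw, "^\\(.*\\)n2:0;$")
  expect_match(nw, "\\(B:0.1,A:0.1\\)n1")
  hc <- as.hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, tr$height)
})
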