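mk_counts <- function(m) {
  count_matrix(matrix(as.integer(m), nrow(m), ncol(m),
                      dimnames = list(paste0("g", seq_len(nrow(m))),
                                      paste0("s", seq_len(ncol(m))))))
}

test_that("library-size CPM columns sum to one million and scale-invariance holds", {
  cm <- mk_counts(cbind(c(1, 3, 6), c(10, 30, 60)))
  cpm <- compute_cpm(cm)
  expect_equal(unname(cpm$values[, 1]), c(1e5, 3e5, 6e5))
  expect_equal(unname(colSums(cpm$values)), rep(1e6, 2), tolerance = 1e-9)
  # doubling every count of a sample leaves its CPM column unchanged
  cm2 <- mk_counts(cbind(c(2, 6, 12), c(10, 30, 60)))
  expect_equal(compute_cpm(cm2)$values, cpm$values)
  expect_error(compute_cpm(mk_counts(cbind(c(0, 0), c(1, 2)))),
               "all-zero sample.*s1")
})

test_that("TMM factors are 1 for identical or purely scaled samples and match edgeR", {
  x <- matrix(rpois(400, 50), 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  same <- mk_counts(cbind(x[, 1], x[, 1]))
  expect_equal(unname(compute_cpm(same, "tmm")$scaling_factors), c(1, 1))
  scaled <- mk_counts(cbind(x[, 1], x[, 1] * 3L))
  expect_equal(unname(compute_cpm(scaled, "tmm")$scaling_factors), c(1, 1),
               tolerance = 1e-8)
  # independent oracle on noisy data
  set.seed(41)
  y <- matrix(rnbinom(3000 * 6, mu = 60, size = 5), 3000, 6,
              dimnames = list(paste0("g", 1:3000), paste0("s", 1:6)))
  y[, 2] <- y[, 2] * 2L
  ours <- secrepath:::tmm_factors(y)
  ref <- edgeR::calcNormFactors(edgeR::DGEList(y))$samples$norm.factors
  expect_equal(unname(ours), ref, tolerance = 1e-3)
})

test_that("filter_expressed applies the two-sample detection rule", {
  vals <- rbind(kept = c(2, 0, 0, 3), removed = c(5, 0, 0, 0))
  colnames(vals) <- paste0("s", 1:4)
  ex <- expression_matrix(vals, scale = "cpm")
  out <- filter_expressed(ex)
  expect_equal(rownames(out$values), "kept")
  expect_equal(attr(out, "filter_report")$n_removed, 1L)
  # idempotent and monotone in min_cpm
  expect_equal(filter_expressed(out)$values, out$values)
  kept_at <- vapply(c(1, 2, 3, 6), function(cut) {
    nrow(filter_expressed(ex, min_cpm = cut, min_samples = 1)$values)
  }, numeric(1))
  expect_true(all(diff(kept_at) <= 0))
  expect_error(filter_expressed(ex, min_samples = 9), "exceeds")
  empty <- expression_matrix(vals[0, , drop = FALSE], scale = "cpm")
  expect_equal(nrow(filter_expressed(empty)$values), 0L)
})

test_that("BH adjustment matches the step-up oracle", {
  # worked example: all four share the minimum of p * n / rank
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  grid <- seq(0.01, 1, by = 0.01)
  for (rep in 1:60) {
    n <- sample(1:6, 1)
    p <- sample(grid, n, replace = TRUE)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-9)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("DE flags follow the fold-change / p / FDR thresholds", {
  raw <- data.frame(
    gene = c("up", "down", "subfold", "ns", "na"),
    log2FC = c(2.5, -2.2, -1.0, 0.2, NA),
    p = c(0.001, 0.002, 0.003, 0.9, NA))
  dge <- adjust_and_flag_de(raw)
  expect_equal(dge$status,
               c("up", "down", "de_below_fold", "not_significant",
                 "not_expressed"))
  expect_equal(dge$FDR[1:3], bh_oracle(raw$p[1:4])[1:3], tolerance = 1e-12)
  expect_error(adjust_and_flag_de(data.frame(gene = "g", log2FC = 1, p = 2)),
               "outside")
})

test_that("doubling time is ln2 over mu and inverts", {
  expect_equal(doubling_time(log(2)), 1.0)
  mus <- c(0.0353, 0.0231, 0.01)
  expect_equal(log(2) / doubling_time(mus), mus)
  expect_error(doubling_time(0), "> 0")
  expect_error(doubling_time(-1), "> 0")
})

test_that("growth-rate fit recovers exact and noisy exponential growth", {
  t <- seq(0, 35, by = 5)
  rec <- growth_record(t, 1e5 * exp(0.03 * t))
  expect_equal(fit_growth_rate(rec), 0.03, tolerance = 1e-10)
  expect_equal(fit_growth_rate(growth_record(t, rep(2e5, length(t)))), 0)
  set.seed(33)
  recn <- growth_record(t, 1e5 * exp(0.025 * t) * exp(rnorm(8, 0, 0.05)))
  expect_lt(abs(fit_growth_rate(recn) - 0.025), 0.003)
  expect_error(fit_growth_rate(growth_record(c(0, 1), c(0, 0))), "2 points")
  expect_error(growth_record(c(2, 1), c(1, 1)), "strictly increasing")
})

test_that("specific productivity is titer change over integrated cell density", {
  rec <- growth_record(c(0, 5, 10), rep(1e6, 3), titer = c(0, 5, 10))
  expect_equal(specific_productivity(rec), 1.0)  # hand trapezoid
  flat <- growth_record(c(0, 10), c(1e6, 1e6), titer = c(4, 4))
  expect_equal(specific_productivity(flat), 0)
  dec <- growth_record(c(0, 10), c(1e6, 1e6), titer = c(10, 5))
  expect_warning(qp <- specific_productivity(dec), "negative")
  expect_lt(qp, 0)
  expect_error(specific_productivity(growth_record(0, 1e6, titer = 1)),
               "strictly increasing|2 timepoints")
})
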