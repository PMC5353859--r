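test_that("modular expression plants the requested correlation structure", {
  spec0 <- synthetic_spec(n_genes = 30, n_samples = 16,
                          module_sizes = c(10, 10), noise_sd = 0,
                          regulators = NULL, seed = 1)
  ex0 <- generate_modular_expression(spec0)
  truth <- attr(ex0, "truth")
  m1 <- ex0$values[truth$gene[truth$module %in% 1], ]
  # noiseless module: all pairwise Spearman correlations are 1
  expect_true(all(abs(cor(t(m1), method = "spearman") - 1) < 1e-12))

  # same seed twice: identical matrices
  spec <- synthetic_spec(n_genes = 100, n_samples = 20,
                         module_sizes = c(20, 20), noise_sd = 0.3, seed = 9)
  expect_identical(generate_modular_expression(spec)$values,
                   generate_modular_expression(spec)$values)

  # within-module minus between-module mean correlation exceeds 0.5
  ex <- generate_modular_expression(spec)
  tr <- attr(ex, "truth")
  g1 <- tr$gene[tr$role == "module" & tr$module == 1]
  g2 <- tr$gene[tr$role == "module" & tr$module == 2]
  rho <- cor(t(ex$values[c(g1, g2), ]), method = "spearman")
  within <- mean(rho[g1, g1][upper.tri(rho[g1, g1])])
  between <- mean(rho[g1, g2])
  expect_gt(within - between, 0.5)
  expect_error(synthetic_spec(n_genes = 10, module_sizes = c(9, 9), seed = 1),
               "exceed")
  expect_error(synthetic_spec(seed = NULL), "seed")
})

test_that("negative-binomial counts have the requested moments", {
  spec <- synthetic_spec(n_genes = 500, n_samples = 20, module_sizes = c(20),
                         regulators = NULL, nb_dispersion = 0, seed = 4)
  cm <- generate_counts(spec)
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == round(cm$counts)))
  # dispersion 0 (Poisson limit): Pearson residual variance near 1 over
  # the 10 000 cells of the matrix, conditioning on the per-cell means
  mu <- attr(cm, "expected_mean")
  keep <- mu > 1
  expect_equal(mean((cm$counts[keep] - mu[keep])^2 / mu[keep]), 1,
               tolerance = 0.1)
  # column sums track the drawn library sizes
  expect_equal(unname(colSums(cm$counts)),
               attr(cm, "expected_libsize"), tolerance = 0.05)
  # doubling the library-size range doubles expected column sums
  spec2 <- synthetic_spec(n_genes = 500, n_samples = 20, module_sizes = c(20),
                          regulators = NULL, nb_dispersion = 0,
                          libsize_range = 2 * spec$libsize_range, seed = 4)
  cm2 <- generate_counts(spec2)
  expect_equal(sum(cm2$counts) / sum(cm$counts), 2, tolerance = 0.02)
})

test_that("planted phenotypes realise their target correlations", {
  spec <- synthetic_spec(n_genes = 50, n_samples = 40, module_sizes = c(10),
                         regulators = NULL, seed = 6)
  ex <- generate_modular_expression(spec)
  bg <- attr(ex, "truth")$gene[attr(ex, "truth")$role == "background"]
  # exact target 1 with zero residual noise: phenotype monotone in the gene
  ph1 <- generate_phenotype(ex, data.frame(gene = bg[1], rho = 1), seed = 6)
  expect_equal(cor(ph1, ex$values[bg[1], ], method = "spearman"), 1)
  # target 0.8 at 40 samples: realised within a tolerant band across seeds
  rhos <- vapply(1:20, function(s) {
    ph <- generate_phenotype(ex, data.frame(gene = bg[2], rho = 0.8),
                             seed = 100 + s)
    cor(ph, ex$values[bg[2], ], method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.6 & rhos < 0.95))
  # no plants: correlations centred near zero
  ph0 <- generate_phenotype(ex, NULL, seed = 6)
  co <- suppressWarnings(cor(t(ex$values[bg, ]), ph0, method = "spearman"))
  expect_lt(abs(mean(co)), 0.15)
  # infeasible joint targets error out
  expect_error(
    generate_phenotype(ex, data.frame(gene = bg[3:4], rho = c(0.95, 0.95)),
                       seed = 1),
    "infeasible")
})

test_that("toy recon delivers the requested structure and tier mix", {
  toy <- generate_toy_recon(n_components = 20, n_complexes = 2, n_groups = 3,
                            seed = 10)
  expect_equal(nrow(toy$catalogue), 20L)
  cx <- unique(unlist(lapply(toy$catalogue$complexes,
                             secrepath:::split_multi)))
  fg <- unique(unlist(lapply(toy$catalogue$functional_groups,
                             secrepath:::split_multi)))
  expect_length(cx, 2L)
  expect_length(fg, 3L)
  # same seed reproduces the fixture exactly
  toy2 <- generate_toy_recon(n_components = 20, n_complexes = 2, n_groups = 3,
                             seed = 10)
  expect_identical(as.data.frame(toy$catalogue), as.data.frame(toy2$catalogue))
  expect_identical(as.data.frame(toy$hits), as.data.frame(toy2$hits))
  # tier mix close to expectation over 100 references
  big <- generate_toy_recon(n_components = 100, seed = 11,
                            tier_mix = c(high = 0.7, moderate = 0.2,
                                         unmapped = 0.1))
  tt <- table(factor(big$truth$tier, c("high", "moderate", "unmapped")))
  expect_true(all(abs(tt - c(70, 20, 10)) <= 15))
  # truth table matches what the assignment rules recover
  asg <- assign_homologs(big$hits)
  expect_equal(asg$tier[match(big$truth$reference_id, asg$reference_id)],
               big$truth$tier)
})
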