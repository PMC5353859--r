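toy_dge <- function() {
  structure(data.frame(
    gene = c("Sec61a1", "Sec61b", "Hspa5", "Psma1", "Psma2", "Ghost"),
    log2FC = c(3, 0, -1.2, -0.8, -0.9, 5),
    p = c(0.001, 0.5, 0.01, 0.01, 0.02, 0.001),
    FDR = c(0.01, 0.6, 0.03, 0.03, 0.04, 0.01),
    status = "x", stringsAsFactors = FALSE),
    class = c("dge_table", "data.frame"))
}

test_that("node annotation maps fold change to colour and FDR to border", {
  net <- build_network(toy_catalogue(), toy_interactions())
  ann <- annotate_network(net, toy_dge())$annotations
  a <- function(id, col) ann[ann$node == id, col]
  expect_equal(a("Sec61a1", "border"), "thick")
  expect_match(a("Sec61a1", "colour"), "^#FF")             # red side
  expect_equal(a("Sec61b", "colour"), "#FFFFFF")           # log2FC = 0
  expect_match(a("Hspa5", "colour"), "FF$")                # blue side
  # no DE row: neutral colour, thin border; group nodes carry no colour
  expect_equal(a("Sec61g", "colour"), "#bfbfbf")
  expect_equal(a("Sec61g", "border"), "thin")
  expect_true(is.na(a("SEC61", "log2FC")))
  expect_setequal(attr(annotate_network(net, toy_dge()), "unmapped_genes"),
                  "ghost")
  # colour saturates at |log2FC| = 4
  expect_equal(fold_change_colour(c(4, 9)), c("#FF0000", "#FF0000"))
})

test_that("fisher_p_greater matches enumeration and fisher.test", {
  set.seed(23)
  for (rep in 1:100) {
    N <- sample(8:60, 1)
    a <- sample(0:min(10, N - 3), 1)
    b <- sample(0:(N - a - 2), 1)
    c <- sample(0:(N - a - b - 1), 1)
    d <- N - a - b - c
    p_impl <- secrepath:::fisher_p_greater(a, b, c, d)
    expect_equal(p_impl, fisher_oracle(a, b, c, d), tolerance = 1e-10)
    p_ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                alternative = "greater")$p.value
    expect_equal(p_impl, p_ref, tolerance = 1e-10)
  }
})

test_that("complex enrichment builds the right 2x2 tables", {
  # 10-member complex all down, 10% of the 200-gene background down
  cat <- complex_catalogue(200, c(10, 20))
  net <- build_network(cat)
  down <- c(cat$id[1:10], cat$id[31:40])
  dge <- data.frame(gene = cat$id,
                    log2FC = ifelse(cat$id %in% down, -1, 0.5),
                    p = ifelse(cat$id %in% down, 1e-4, 0.5),
                    FDR = ifelse(cat$id %in% down, 1e-3, 0.6))
  enr <- complex_enrichment(net, cat, dge, kind = "complex",
                            direction = "down")
  r1 <- enr[enr$group == "CPX01", ]
  expect_equal(c(r1$a, r1$b, r1$c, r1$d), c(10, 0, 10, 180))
  expect_lt(r1$p, 0.05)
  expect_equal(r1$neg_log10_p, -log10(r1$p))
  # CPX02 spans ids 11-30, none down
  r2 <- enr[enr$group == "CPX02", ]
  expect_equal(r2$a, 0)
  expect_equal(r2$odds_ratio, 0)
  # a group regulated at exactly the background rate: OR = 1, p >= 0.5
  expect_gte(secrepath:::fisher_p_greater(2, 18, 18, 162), 0.5)
  # q is BH over the tested groups
  expect_equal(enr$q, bh_oracle(enr$p), tolerance = 1e-12)
  # direction matters: nothing is up-regulated significantly
  up <- complex_enrichment(net, cat, dge, kind = "complex", direction = "up")
  expect_true(all(up$a == 0))
  # neg_log10_p strictly decreasing in p
  expect_equal(order(enr$neg_log10_p), order(enr$p, decreasing = TRUE))
})

test_that("member criterion and subsystem grouping are honoured", {
  cat <- complex_catalogue(60, c(8))
  net <- build_network(cat)
  # sub-threshold FDR: fdr_sign finds nothing, sign_only still counts signs
  dge <- data.frame(gene = cat$id, log2FC = -0.5, p = 0.5, FDR = 0.9)
  e1 <- complex_enrichment(net, cat, dge, "complex", "down", "fdr_sign")
  expect_equal(e1$a, 0)
  e2 <- complex_enrichment(net, cat, dge, "complex", "down", "sign_only")
  expect_equal(e2$a, 8)
  es <- complex_enrichment(net, cat, dge, "subsystem", "down", "sign_only")
  expect_equal(es$group, "other")
  expect_equal(es$a + es$b, 60)
})

test_that("style_and_export writes round-trippable tables", {
  net <- annotate_network(build_network(toy_catalogue(), toy_interactions()),
                          toy_dge())
  cat <- toy_catalogue()
  enr <- complex_enrichment(net, cat, toy_dge(), "complex", "down",
                            fdr_cut = 0.05)
  dir <- tempfile()
  paths <- style_and_export(net, enr, dir, cat = cat)
  expect_true(all(file.exists(paths)))
  at <- read.delim(paths[["node_attributes"]])
  expect_equal(nrow(at), nrow(net$nodes))
  m <- match(net$annotations$node, at$id)
  expect_equal(at$colour[m], net$annotations$colour)
  expect_equal(at$log2FC[m], net$annotations$log2FC)
  etab <- read.delim(paths[["enrichment"]])
  expect_equal(nrow(etab), nrow(enr))
  # empty enrichment still writes a header-only TSV
  p2 <- style_and_export(net, NULL, tempfile())
  expect_equal(nrow(read.delim(p2[["enrichment"]])), 0L)
  expect_error(style_and_export(build_network(toy_catalogue()), NULL,
                                tempfile()), "annotate_network")
})
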