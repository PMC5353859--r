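test_that("catalogue loading parses, validates and reports", {
  path <- write_lines_tmp(c(
    "id\tsubsystems\tcomplexes\tevidence",
    "A1\ttranslocation\tCPX\tverified",
    "B2\tERAD;UPR\t\ttentative",
    "C3\tERAD\tCPX\tverified",
    "D4\tprotein_folding\t\tverified",
    "E5\t\t\tverified"))
  expect_message(cat <- load_catalogue(path), "5 components")
  expect_s3_class(cat, "secrepath_catalogue")
  expect_equal(nrow(cat), 5L)
  expect_equal(cat$evidence[2], "tentative")

  dup <- write_lines_tmp(c("id\tsubsystems", "A1\tERAD", "a1\tUPR"))
  expect_error(suppressMessages(load_catalogue(dup)), "duplicate.*A1|a1")

  bad <- write_lines_tmp(c("id\tsubsystems", "A1\tgolgi_glyco"))
  expect_error(suppressMessages(load_catalogue(bad)),
               "unknown subsystem.*golgi_glyco.*row 1")
  expect_silent(validate_catalogue(
    catalogue(data.frame(id = "A1", subsystems = "golgi_glyco"),
              allow_extra_labels = TRUE)))
})

test_that("subsystem counts respect multi-membership", {
  cat <- catalogue(data.frame(
    id = c("a", "b", "c"),
    subsystems = c("ERAD", "ERAD;UPR", "UPR")))
  counts <- subsystem_counts(cat)
  expect_equal(counts[["ERAD"]], 2L)
  expect_equal(counts[["UPR"]], 2L)
  expect_equal(counts[["translocation"]], 0L)
  # multi-membership inflates the sum, never deflates
  expect_gte(sum(counts), sum(nzchar(cat$subsystems)))
})

test_that("build_network materialises complexes, groups and memberships", {
  cat <- toy_catalogue()
  net <- build_network(cat)
  expect_setequal(net$nodes$id[net$nodes$kind == "complex"],
                  c("SEC61", "PSMA"))
  expect_setequal(net$nodes$id[net$nodes$kind == "functional_group"],
                  c("sec61_pore", "chaperones"))
  # 3 SEC61 + 2 PSMA complex memberships, 3 + 1 functional-group memberships
  expect_equal(sum(net$edges$interaction_class == "membership"), 9L)
  # a component in 2 groups gets 2 membership edges
  cat2 <- catalogue(data.frame(id = "x", functional_groups = "f1;f2"))
  net2 <- build_network(cat2)
  expect_equal(sum(net2$edges$interaction_class == "membership"), 2L)

  expect_error(build_network(cat, interactions("Sec61a1", "NotAGene")),
               "unknown node.*NotAGene")
})

test_that("drop_isolated matches a brute-force degree scan", {
  set.seed(11)
  for (rep in 1:5) {
    toy <- generate_toy_recon(n_components = 15, n_complexes = 1,
                              n_groups = 1, interaction_density = 0.05,
                              seed = 100 + rep)
    full <- build_network(toy$catalogue, toy$interactions)
    dropped <- build_network(toy$catalogue, toy$interactions,
                             drop_isolated = TRUE)
    deg <- table(factor(c(full$edges$source, full$edges$target),
                        levels = full$nodes$id))
    expected <- sum(deg[full$nodes$id[full$nodes$kind == "component"]] > 0)
    expect_equal(sum(dropped$nodes$kind == "component"), expected)
  }
})

test_that("extract_subnetwork induces label unions and leaves input intact", {
  cat <- toy_catalogue()
  net <- build_network(cat, toy_interactions())
  n_before <- nrow(net$nodes)
  sub <- extract_subnetwork(net, cat, "PSMA")
  expect_setequal(sub$nodes$id, c("Psma1", "Psma2", "PSMA"))
  expect_equal(nrow(net$nodes), n_before)

  expect_equal(nrow(extract_subnetwork(net, cat, character(0))$nodes), 0L)
  expect_equal(nrow(extract_subnetwork(net, cat, "no_such_label")$nodes), 0L)

  # two-selector result equals the union of single-selector node sets
  s1 <- extract_subnetwork(net, cat, "translocation")$nodes$id
  s2 <- extract_subnetwork(net, cat, "UPR")$nodes$id
  s12 <- extract_subnetwork(net, cat, c("translocation", "UPR"))$nodes$id
  expect_setequal(s12, union(s1, s2))
})

test_that("export / import round trip preserves structure", {
  cat <- toy_catalogue()
  net <- build_network(cat, toy_interactions())
  dir <- tempfile()
  paths <- export_network(net, dir, cat = cat)
  expect_true(all(file.exists(paths)))
  back <- import_sif(paths[["sif"]], paths[["node_attributes"]])
  expect_equal(nrow(back$nodes), nrow(net$nodes))
  expect_equal(nrow(back$edges), nrow(net$edges))
  expect_setequal(back$nodes$id, net$nodes$id)
  # edge multiset preserved
  key <- function(e) sort(paste(e$source, e$interaction_class, e$target))
  expect_equal(key(back$edges), key(net$edges))
  # annotated export carries the annotation columns
  ann <- data.frame(node = net$nodes$id, log2FC = 1, FDR = 0.01,
                    colour = "#ff0000", border = "thick")
  paths2 <- export_network(net, tempfile(), annotations = ann)
  tab <- read.delim(paths2[["node_attributes"]])
  expect_true(all(c("log2FC", "FDR", "colour", "border") %in% names(tab)))
  expect_equal(nrow(tab), nrow(net$nodes))
  # empty network exports syntactically valid empty files
  empty <- extract_subnetwork(net, cat, character(0))
  p3 <- export_network(empty, tempfile())
  expect_identical(readLines(p3[["sif"]]), character(0))
})

test_that("catalogue write / load round trip preserves content", {
  for (seed in c(3, 4)) {
    toy <- generate_toy_recon(n_components = 12, seed = seed)
    p <- tempfile(fileext = ".tsv")
    write_catalogue(toy$catalogue, p)
    back <- suppressMessages(load_catalogue(p))
    expect_equal(nrow(back), nrow(toy$catalogue))
    expect_equal(back$subsystems, toy$catalogue$subsystems)
    expect_equal(back$core, toy$catalogue$core)
  }
})

test_that("network stats count node kinds and connected components", {
  cat <- toy_catalogue()
  st <- network_stats(build_network(cat, toy_interactions()))
  expect_equal(st$n_component_nodes, 7L)
  expect_equal(st$n_complex_nodes, 2L)
  expect_equal(st$n_functional_group_nodes, 2L)
  # SEC61+pore+Hspa5+Xbp1 chain joins via interactions; PSMA block separate
  expect_equal(st$n_connected_components, 2L)
})
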