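#' Read a pipeline configuration file
#'
#' Flat key-value format, one `section.key = value` per line; `#` starts a
#' comment. Sections are the pipeline stages (`network`, `transfer`,
#' `expression`, `clustering`, `regulators`, `phenotype`, `overlay`) plus the
#' top-level keys `seed` and `out_dir`. Every threshold of the analysis
#' methods is surfaced with its conventional default.
#'
#' @param path path to the config file.
#' @return Nested list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    if (identical(val, "true")) val <- TRUE
    if (identical(val, "false")) val <- FALSE
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      cfg[[parts]] <- val
    } else {
      cfg[[parts[1]]][[paste(parts[-1], collapse = ".")]] <- val
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @keywords internal
pipeline_defaults <- function() {
  list(
    transfer = list(high_pident = 80, mod_pident = 60, mod_bitscore = 50,
                    mod_evalue = 1e-5),
    expression = list(normalization = "libsize", min_cpm = 1, min_samples = 2,
                      fc_cut = 2, p_cut = 0.05, fdr_cut = 0.05),
    clustering = list(nboot = 1000, alpha = 0.95, multiscale = FALSE),
    regulators = list(top = 10),
    overlay = list(kind = "complex", direction = "down",
                   member_criterion = "fdr_sign", fdr_cut = 0.05))
}

#' @keywords internal
cfg_get <- function(cfg, stage, key) {
  cfg[[stage]][[key]] %||% pipeline_defaults()[[stage]][[key]]
}

# Which inputs each stage requires (paths in its config section).
#' @keywords internal
stage_requirements <- function() {
  list(network = c("catalogue"),
       transfer = c("catalogue", "hits"),
       expression = c("counts"),
       clustering = c("genes"),          # plus an expression source
       regulators = c("seed_genes"),     # plus an expression source
       phenotype = c("phenotypes"),      # plus an expression source
       overlay = c("catalogue", "dge"))
}

#' Run the configured analysis pipeline
#'
#' Orchestrates catalogue loading / network build, homology transfer,
#' expression normalisation and filtering, cluster support, regulator
#' screening, phenotype correlation and the differential-expression network
#' overlay as one seeded, logged run. All enabled stages are validated
#' before any computation (pre-flight: a missing input aborts the run with
#' no partial outputs), results are written as plain-text tables under the
#' output directory, and a run log records thresholds and per-stage counts.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return Invisibly, a list of in-memory stage results; files are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$seed)) stop("config must set 'seed'", call. = FALSE)
  out_dir <- config$out_dir %||% stop("config must set 'out_dir'",
                                      call. = FALSE)
  stages <- names(stage_requirements())
  enabled <- vapply(stages, function(s) isTRUE(config[[s]][["enabled"]]),
                    logical(1))
  # expression-consuming stages can share the expression stage's output
  for (s in c("clustering", "regulators", "phenotype")) {
    if (enabled[[s]] && is.null(config[[s]][["expr"]]) &&
        !enabled[["expression"]]) {
      stop("pre-flight: stage '", s, "' needs an 'expr' input or the ",
           "expression stage enabled", call. = FALSE)
    }
  }
  for (s in stages[enabled]) {
    for (req in stage_requirements()[[s]]) {
      p <- config[[s]][[req]]
      if (is.null(p)) {
        stop("pre-flight: stage '", s, "' is enabled but lacks input '",
             req, "'", call. = FALSE)
      }
      if (!file.exists(p)) {
        stop("pre-flight: stage '", s, "' input '", req,
             "' does not exist: ", p, call. = FALSE)
      }
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("secrepath pipeline run, seed=%d", config$seed),
                 sprintf("R %s, secrepath %s", getRversion(),
                         as.character(utils::packageVersion("secrepath"))))
  res <- list()

  if (enabled[["network"]]) {
    cat <- load_catalogue(config$network$catalogue)
    ia <- if (!is.null(config$network$interactions))
      load_interactions(config$network$interactions) else NULL
    net <- build_network(cat, ia,
                         drop_isolated = isTRUE(config$network$drop_isolated))
    export_network(net, file.path(out_dir, "network"), cat = cat)
    st <- network_stats(net)
    log_lines <- c(log_lines, sprintf(
      "network: %d components, %d complexes, %d groups, %d edges, %d connected components",
      st$n_component_nodes + st$n_isoprotein_nodes, st$n_complex_nodes,
      st$n_functional_group_nodes, st$n_edges, st$n_connected_components))
    res$network <- net
    res$catalogue <- cat
  }

  if (enabled[["transfer"]]) {
    ref <- res$catalogue %||% load_catalogue(config$transfer$catalogue)
    hits <- parse_hits(config$transfer$hits)
    thr <- homology_thresholds(
      high_pident = cfg_get(config, "transfer", "high_pident"),
      mod_pident = cfg_get(config, "transfer", "mod_pident"),
      mod_bitscore = cfg_get(config, "transfer", "mod_bitscore"),
      mod_evalue = cfg_get(config, "transfer", "mod_evalue"))
    asg <- assign_homologs(hits, thr)
    tgt <- transfer_catalogue(ref, asg,
                              species = config$transfer$species %||% "target")
    write_tsv(as.data.frame(asg), file.path(out_dir, "homology_assignments.tsv"))
    write_catalogue(tgt, file.path(out_dir, "target_catalogue.tsv"))
    rep <- attr(tgt, "transfer_report")
    log_lines <- c(log_lines, sprintf(
      "transfer: %d mapped, %d unmapped, %d many-to-one targets",
      rep$n_mapped, length(rep$unmapped), length(rep$many_to_one)))
    res$transfer <- tgt
  }

  expr <- NULL
  if (enabled[["expression"]]) {
    cts <- read_tsv_strict(config$expression$counts)
    mat <- as.matrix(cts[, -1, drop = FALSE])
    rownames(mat) <- cts[[1]]
    cm <- count_matrix(mat)
    cpm <- compute_cpm(cm, normalization = cfg_get(config, "expression",
                                                   "normalization"))
    expr <- filter_expressed(cpm,
                             min_cpm = cfg_get(config, "expression", "min_cpm"),
                             min_samples = cfg_get(config, "expression",
                                                   "min_samples"))
    fr <- attr(expr, "filter_report")
    write_tsv(data.frame(gene = rownames(expr$values), expr$values,
                         check.names = FALSE),
              file.path(out_dir, "expression_cpm_filtered.tsv"))
    log_lines <- c(log_lines, sprintf(
      "expression: %d genes kept, %d removed (CPM>=%g in >=%d samples)",
      fr$n_kept, fr$n_removed, fr$min_cpm, fr$min_samples))
    res$expression <- expr
  }

  load_expr <- function(stage) {
    p <- config[[stage]][["expr"]]
    if (!is.null(p)) {
      tab <- read_tsv_strict(p)
      mat <- as.matrix(tab[, -1, drop = FALSE])
      rownames(mat) <- tab[[1]]
      expression_matrix(mat, scale = "cpm", normalization = "libsize")
    } else expr
  }

  if (enabled[["clustering"]]) {
    ex <- load_expr("clustering")
    genes <- readLines(config$clustering$genes)
    genes <- intersect(genes, rownames(ex$values))
    x <- log2(ex$values[genes, , drop = FALSE] + 1)
    seed <- derive_seed(config$seed, 11L)
    if (isTRUE(cfg_get(config, "clustering", "multiscale"))) {
      sup <- au_pvalues(x, nboot_per_scale = cfg_get(config, "clustering",
                                                     "nboot"),
                        seed = seed)
    } else {
      sup <- bootstrap_support(x, nboot = cfg_get(config, "clustering",
                                                  "nboot"), seed = seed)
    }
    tree <- attr(sup, "tree")
    lab <- if (!is.null(sup$au)) sprintf("au=%.3f|bp=%.3f", sup$au, sup$bp)
           else sprintf("bp=%.3f", sup$bp)
    write_newick(tree, node_labels = lab, path = file.path(out_dir, "tree.nwk"))
    write_tsv(sup, file.path(out_dir, "cluster_support.tsv"))
    sig <- significant_clusters(sup, alpha = cfg_get(config, "clustering",
                                                     "alpha"),
                                include_root = FALSE)
    write_tsv(sig, file.path(out_dir, "significant_clusters.tsv"))
    log_lines <- c(log_lines, sprintf(
      "clustering: %d genes, %d nodes, %d significant clusters (alpha=%g)",
      length(genes), nrow(sup), nrow(sig),
      cfg_get(config, "clustering", "alpha")))
    res$clustering <- sup
  }

  if (enabled[["regulators"]]) {
    ex <- load_expr("regulators")
    seeds <- readLines(config$regulators$seed_genes)
    sc <- summed_correlation_scores(log2(ex$values + 1), seeds)
    cand <- rank_regulator_candidates(sc, k = cfg_get(config, "regulators",
                                                      "top"))
    write_tsv(sc, file.path(out_dir, "regulator_scores.tsv"))
    write_tsv(rbind(cbind(direction = "positive", cand$positive),
                    cbind(direction = "negative", cand$negative)),
              file.path(out_dir, "regulator_candidates.tsv"))
    log_lines <- c(log_lines, sprintf(
      "regulators: %d genes scored against %d seed genes",
      nrow(sc), sc$n_seed[1]))
    res$regulators <- sc
  }

  if (enabled[["phenotype"]]) {
    ex <- load_expr("phenotype")
    ph <- read_tsv_strict(config$phenotype$phenotypes)
    tabs <- list()
    for (col in setdiff(names(ph), "sample")) {
      v <- stats::setNames(ph[[col]], ph$sample)
      co <- correlate_to_phenotype(ex, v, phenotype_name = col)
      tabs[[col]] <- classify_targets(co)
    }
    allc <- do.call(rbind, tabs)
    write_tsv(allc, file.path(out_dir, "phenotype_correlations.tsv"))
    if (length(tabs) >= 2) {
      write_tsv(phenotype_scatter(tabs[[1]], tabs[[2]]),
                file.path(out_dir, "phenotype_scatter.tsv"))
    }
    log_lines <- c(log_lines, sprintf(
      "phenotype: %d correlations, %d flagged (Spearman two-SD rule)",
      nrow(allc), sum(allc$significant_spearman)))
    res$phenotype <- tabs
  }

  if (enabled[["overlay"]]) {
    cat2 <- res$catalogue %||% load_catalogue(config$overlay$catalogue)
    ia2 <- if (!is.null(config$overlay$interactions))
      load_interactions(config$overlay$interactions) else NULL
    net2 <- res$network %||% build_network(cat2, ia2)
    dge_raw <- read_tsv_strict(config$overlay$dge)
    dge <- adjust_and_flag_de(dge_raw,
                              fc_cut = cfg_get(config, "expression", "fc_cut"),
                              p_cut = cfg_get(config, "expression", "p_cut"),
                              fdr_cut = cfg_get(config, "expression",
                                                "fdr_cut"))
    ann <- annotate_network(net2, dge,
                            fdr_cut = cfg_get(config, "overlay", "fdr_cut"))
    enr <- complex_enrichment(
      net2, cat2, dge,
      kind = cfg_get(config, "overlay", "kind"),
      direction = cfg_get(config, "overlay", "direction"),
      member_criterion = cfg_get(config, "overlay", "member_criterion"),
      fdr_cut = cfg_get(config, "overlay", "fdr_cut"))
    style_and_export(ann, enr, file.path(out_dir, "overlay"), cat = cat2)
    write_tsv(as.data.frame(dge), file.path(out_dir, "dge_flagged.tsv"))
    log_lines <- c(log_lines, sprintf(
      "overlay: %d nodes annotated, %d groups tested, %d with p<0.05",
      nrow(ann$annotations), nrow(enr), sum(enr$p < 0.05)))
    res$overlay <- list(network = ann, enrichment = enr)
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  echo <- unlist(lapply(names(config), function(s) {
    v <- config[[s]]
    if (is.list(v)) sprintf("%s.%s = %s", s, names(v), vapply(v, format, ""))
    else sprintf("%s = %s", s, format(v))
  }))
  writeLines(echo, file.path(out_dir, "config_echo.txt"))
  invisible(res)
}
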