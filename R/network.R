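#' Construct an interaction table
#'
#' Interactions are reported links between catalogue nodes: DNA-DNA,
#' protein-DNA or protein-protein links from the literature, plus the
#' `membership` edges that connect components to protein-complex or
#' functional-group nodes (normally materialised by [build_network()], not
#' supplied by the user).
#'
#' @param source,target node ids.
#' @param interaction_class one of `protein_protein`, `protein_DNA`,
#'   `DNA_DNA`, `membership` (recycled).
#' @param directed logical (recycled).
#' @param provenance free-text provenance (recycled).
#' @return data.frame of class `secrepath_interactions`.
#' @export
interactions <- function(source, target,
                         interaction_class = "protein_protein",
                         directed = FALSE, provenance = "") {
  n <- length(source)
  if (length(target) != n) stop("source/target length mismatch", call. = FALSE)
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   interaction_class = rep_len(as.character(interaction_class), n),
                   directed = rep_len(as.logical(directed), n),
                   provenance = rep_len(as.character(provenance), n),
                   stringsAsFactors = FALSE)
  bad <- !df$interaction_class %in% interaction_classes()
  if (any(bad)) {
    stop("invalid interaction_class: ",
         paste(unique(df$interaction_class[bad]), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("secrepath_interactions", "data.frame")
  df
}

#' @keywords internal
interaction_classes <- function() {
  c("protein_protein", "protein_DNA", "DNA_DNA", "membership")
}

#' Load an interaction table from a TSV file
#'
#' Expected columns: `source`, `target`, and optionally `interaction_class`,
#' `directed`, `provenance`.
#'
#' @param path path to the interaction TSV.
#' @return A `secrepath_interactions` data.frame.
#' @export
load_interactions <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("source", "target")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("interaction file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  interactions(df$source, df$target,
               interaction_class = df$interaction_class %||% "protein_protein",
               directed = df$directed %||% FALSE,
               provenance = df$provenance %||% "")
}

#' Build the heterogeneous reconstruction network
#'
#' Materialises the graph representation of a catalogue: one node per
#' component (or isoprotein), one node per protein complex and per functional
#' group mentioned in the catalogue, a `membership` edge for every
#' component-to-complex/group assignment, plus the literature interaction
#' edges. Components with no edge at all can be dropped (`drop_isolated`),
#' mirroring a network representation that leaves out components with no
#' described interactions.
#'
#' @param cat a `secrepath_catalogue`.
#' @param interactions optional `secrepath_interactions` (or data.frame with
#'   the same columns); endpoints are resolved case-insensitively against
#'   component ids and declared complex / functional-group labels.
#' @param drop_isolated drop component-kind nodes of degree zero.
#' @return An object of class `recon_network`: list with `nodes`
#'   (data.frame id, kind), `edges` (interaction table) and `provenance`.
#' @export
build_network <- function(cat, interactions = NULL, drop_isolated = FALSE) {
  validate_catalogue(cat)
  mem <- catalogue_memberships(cat)
  nodes <- data.frame(id = cat$id, kind = cat$kind, stringsAsFactors = FALSE)
  for (gk in c("complex", "functional_group")) {
    labs <- unique(mem$group[mem$group_kind == gk])
    if (length(labs)) {
      nodes <- rbind(nodes, data.frame(id = labs, kind = gk,
                                       stringsAsFactors = FALSE))
    }
  }
  if (anyDuplicated(canon_id(nodes$id))) {
    dup <- nodes$id[duplicated(canon_id(nodes$id))]
    stop("node id collision between components and complex/group labels: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  mem_edges <- if (nrow(mem)) {
    secrepath::interactions(mem$component, mem$group,
                            interaction_class = "membership",
                            directed = FALSE, provenance = "catalogue")
  } else {
    secrepath::interactions(character(0), character(0))
  }
  edges <- mem_edges
  if (!is.null(interactions) && nrow(interactions)) {
    ia <- interactions
    lookup <- stats::setNames(nodes$id, canon_id(nodes$id))
    for (col in c("source", "target")) {
      hit <- lookup[canon_id(ia[[col]])]
      bad <- which(is.na(hit))
      if (length(bad)) {
        stop("interaction edge(s) ", paste(bad, collapse = ", "),
             " reference unknown node(s): ",
             paste(unique(ia[[col]][bad]), collapse = ", "), call. = FALSE)
      }
      ia[[col]] <- unname(hit)
    }
    edges <- rbind(edges, ia)
  }
  net <- structure(list(nodes = nodes, edges = edges,
                        provenance = attr(cat, "source") %||% "catalogue"),
                   class = "recon_network")
  if (isTRUE(drop_isolated)) {
    deg <- node_degrees(net)
    keep <- net$nodes$kind %in% c("complex", "functional_group") | deg > 0
    net$nodes <- net$nodes[keep, , drop = FALSE]
    rownames(net$nodes) <- NULL
    # complex/group nodes that lost all members become isolated too; prune
    deg2 <- node_degrees(net)
    keep2 <- !(net$nodes$kind %in% c("complex", "functional_group") & deg2 == 0)
    net$nodes <- net$nodes[keep2, , drop = FALSE]
    rownames(net$nodes) <- NULL
  }
  validate_network(net)
}

#' @keywords internal
node_degrees <- function(net) {
  tab <- table(factor(canon_id(c(net$edges$source, net$edges$target)),
                      levels = canon_id(net$nodes$id)))
  as.integer(tab)
}

#' Validate a reconstruction network
#'
#' @param net a `recon_network`.
#' @return The network, invisibly, or an error.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "recon_network"))
  if (anyDuplicated(canon_id(net$nodes$id))) {
    stop("duplicate node ids in network", call. = FALSE)
  }
  bad_kind <- !net$nodes$kind %in% c("component", "complex",
                                     "functional_group", "isoprotein")
  if (any(bad_kind)) {
    stop("invalid node kind(s): ",
         paste(unique(net$nodes$kind[bad_kind]), collapse = ", "),
         call. = FALSE)
  }
  known <- canon_id(net$nodes$id)
  for (col in c("source", "target")) {
    bad <- which(!canon_id(net$edges[[col]]) %in% known)
    if (length(bad)) {
      stop("edge(s) ", paste(bad, collapse = ", "),
           " reference unknown node(s): ",
           paste(unique(net$edges[[col]][bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  memb <- net$edges$interaction_class == "membership"
  if (any(memb)) {
    kind_of <- stats::setNames(net$nodes$kind, known)
    tk <- kind_of[canon_id(net$edges$target[memb])]
    sk <- kind_of[canon_id(net$edges$source[memb])]
    ok <- sk %in% c("component", "isoprotein") &
      tk %in% c("complex", "functional_group")
    if (any(!ok)) {
      stop("membership edge(s) must connect a component to a complex or ",
           "functional-group node (violations: ",
           paste(which(memb)[!ok], collapse = ", "), ")", call. = FALSE)
    }
  }
  invisible(net)
}

#' @export
print.recon_network <- function(x, ...) {
  k <- table(factor(x$nodes$kind, levels = c("component", "isoprotein",
                                             "complex", "functional_group")))
  cat("recon network: ", nrow(x$nodes), " nodes (",
      paste(names(k), as.integer(k), sep = "=", collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a reconstruction network to an igraph object
#'
#' @param net a `recon_network`.
#' @return An undirected `igraph` graph with `kind` vertex attribute and
#'   `interaction_class` edge attribute.
#' @export
as_igraph <- function(net) {
  validate_network(net)
  igraph::graph_from_data_frame(
    d = net$edges[, c("source", "target", "interaction_class", "directed",
                      "provenance")],
    directed = FALSE,
    vertices = net$nodes)
}

#' Summary statistics of a reconstruction network
#'
#' @param net a `recon_network`.
#' @return List with node counts by kind, edge count, and the number of
#'   connected components of the graph.
#' @export
network_stats <- function(net) {
  validate_network(net)
  g <- as_igraph(net)
  kinds <- table(factor(net$nodes$kind,
                        levels = c("component", "isoprotein", "complex",
                                   "functional_group")))
  list(n_nodes = nrow(net$nodes),
       n_component_nodes = as.integer(kinds[["component"]]),
       n_isoprotein_nodes = as.integer(kinds[["isoprotein"]]),
       n_complex_nodes = as.integer(kinds[["complex"]]),
       n_functional_group_nodes = as.integer(kinds[["functional_group"]]),
       n_edges = nrow(net$edges),
       n_connected_components = igraph::count_components(g))
}

#' Extract the subnetwork matching subsystem / group / complex labels
#'
#' Induces the subgraph on components annotated with any selector label (as a
#' subsystem, functional group or complex, matched against the catalogue) plus
#' the complex / functional-group nodes named by the selector or attached to a
#' selected component. The original network is not modified.
#'
#' @param net a `recon_network`.
#' @param cat the catalogue the network was built from (source of subsystem
#'   annotations).
#' @param selector character vector of labels; empty selector yields an empty
#'   network.
#' @return A `recon_network`.
#' @export
extract_subnetwork <- function(net, cat, selector) {
  validate_network(net)
  validate_catalogue(cat)
  selector <- unique(as.character(selector))
  if (!length(selector)) {
    return(structure(list(nodes = net$nodes[0, ], edges = net$edges[0, ],
                          provenance = net$provenance),
                     class = "recon_network"))
  }
  sel <- canon_id(selector)
  matches <- vapply(seq_len(nrow(cat)), function(i) {
    labs <- canon_id(c(split_multi(cat$subsystems[i]),
                       split_multi(cat$functional_groups[i]),
                       split_multi(cat$complexes[i])))
    any(sel %in% labs)
  }, logical(1))
  comp_ids <- canon_id(cat$id[matches])
  keep_nodes <- canon_id(net$nodes$id) %in% comp_ids |
    (net$nodes$kind %in% c("complex", "functional_group") &
       canon_id(net$nodes$id) %in% sel)
  # group/complex nodes attached to a selected component stay in
  memb <- net$edges$interaction_class == "membership" &
    canon_id(net$edges$source) %in% comp_ids
  keep_nodes <- keep_nodes | canon_id(net$nodes$id) %in%
    canon_id(net$edges$target[memb])
  nodes <- net$nodes[keep_nodes, , drop = FALSE]
  ids <- canon_id(nodes$id)
  edges <- net$edges[canon_id(net$edges$source) %in% ids &
                       canon_id(net$edges$target) %in% ids, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  validate_network(structure(list(nodes = nodes, edges = edges,
                                  provenance = net$provenance),
                             class = "recon_network"))
}

#' Export a network for Cytoscape-style visualisation
#'
#' Writes three files to `out_dir`: `network.sif` (one line per edge:
#' source, interaction class, target; isolated nodes as single-column lines),
#' `node_attributes.tsv` (one row per node: kind, subsystems and any extra
#' annotation columns) and `network.graphml`.
#'
#' @param net a `recon_network`.
#' @param out_dir output directory (created if needed).
#' @param cat optional catalogue used to attach subsystem annotations.
#' @param annotations optional data.frame with a `node` or `id` column plus
#'   arbitrary annotation columns, joined case-insensitively.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_network <- function(net, out_dir, cat = NULL, annotations = NULL) {
  validate_network(net)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  sif <- file.path(out_dir, "network.sif")
  attr_path <- file.path(out_dir, "node_attributes.tsv")
  gml <- file.path(out_dir, "network.graphml")
  edge_lines <- sprintf("%s\t%s\t%s", net$edges$source,
                        net$edges$interaction_class, net$edges$target)
  deg <- node_degrees(net)
  iso_lines <- net$nodes$id[deg == 0]
  writeLines(c(edge_lines, iso_lines), sif)
  node_tab <- net$nodes
  if (!is.null(cat)) {
    m <- match(canon_id(node_tab$id), canon_id(cat$id))
    node_tab$subsystems <- ifelse(is.na(m), "", cat$subsystems[m])
    node_tab$functional_groups <- ifelse(is.na(m), "", cat$functional_groups[m])
    node_tab$complexes <- ifelse(is.na(m), "", cat$complexes[m])
  }
  if (!is.null(annotations)) {
    idcol <- intersect(c("node", "id"), names(annotations))[1]
    if (is.na(idcol)) stop("annotations need a 'node' or 'id' column",
                           call. = FALSE)
    m <- match(canon_id(node_tab$id), canon_id(annotations[[idcol]]))
    for (col in setdiff(names(annotations), idcol)) {
      node_tab[[col]] <- annotations[[col]][m]
    }
  }
  write_tsv(node_tab, attr_path)
  igraph::write_graph(as_igraph(net), gml, format = "graphml")
  invisible(c(sif = sif, node_attributes = attr_path, graphml = gml))
}

#' Import a network from a SIF file (plus optional node attributes)
#'
#' Round-trip counterpart of [export_network()]: reconstructs node and edge
#' sets from the 3-column SIF lines (single-column lines are isolated nodes).
#' Node kinds are taken from the attribute table when given, else default to
#' `component`.
#'
#' @param sif_path path to a `.sif` file.
#' @param attributes_path optional path to the node-attribute TSV.
#' @return A `recon_network`.
#' @export
import_sif <- function(sif_path, attributes_path = NULL) {
  lines <- readLines(sif_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(!n_fields %in% c(1L, 3L))) {
    stop("malformed SIF line(s): ",
         paste(which(!n_fields %in% c(1L, 3L)), collapse = ", "),
         call. = FALSE)
  }
  edge_part <- parts[n_fields == 3L]
  edges <- if (length(edge_part)) {
    interactions(vapply(edge_part, `[[`, "", 1L),
                 vapply(edge_part, `[[`, "", 3L),
                 interaction_class = vapply(edge_part, `[[`, "", 2L),
                 provenance = "sif")
  } else {
    interactions(character(0), character(0))
  }
  iso <- vapply(parts[n_fields == 1L], `[[`, "", 1L)
  ids <- unique(c(edges$source, edges$target, iso))
  nodes <- data.frame(id = ids, kind = "component", stringsAsFactors = FALSE)
  if (!is.null(attributes_path)) {
    at <- read_tsv_strict(attributes_path)
    m <- match(canon_id(nodes$id), canon_id(at$id))
    nodes$kind <- ifelse(is.na(m), "component", at$kind[m])
  }
  validate_network(structure(list(nodes = nodes, edges = edges,
                                  provenance = sif_path),
                             class = "recon_network"))
}
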