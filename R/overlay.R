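#' Fold-change colour on a blue-white-red gradient
#'
#' Maps log2 fold change to a continuous signed gradient: white at 0, fully
#' saturated red at `+saturate` and blue at `-saturate` (no hard fold-change
#' cut-off - minor coordinated shifts are informative; the conventional
#' +/- 2 fold-change marks are reference ticks, not clipping points).
#' Missing values map to a neutral grey.
#'
#' @param log2fc numeric vector.
#' @param saturate absolute log2FC at which the colour saturates.
#' @return Character vector of hex colours.
#' @export
fold_change_colour <- function(log2fc, saturate = 4) {
  v <- pmax(pmin(log2fc / saturate, 1), -1)
  out <- rep("#bfbfbf", length(log2fc))
  ok <- !is.na(v)
  up <- ok & v >= 0
  dn <- ok & v < 0
  out[up] <- grDevices::rgb(1, 1 - v[up], 1 - v[up])
  out[dn] <- grDevices::rgb(1 + v[dn], 1 + v[dn], 1)
  out
}

#' Annotate network nodes with differential expression
#'
#' Attaches per-node log2 fold change, FDR, a gradient colour and a border
#' style to the component nodes of a reconstruction network. Gene ids are
#' matched case-insensitively; genes absent from the DE table stay neutral;
#' complex and functional-group nodes never carry expression colour. The
#' border is `thick` exactly when `FDR < fdr_cut`.
#'
#' @param net a `recon_network`.
#' @param dge a `dge_table` (or data.frame with `gene`, `log2FC`, `FDR`).
#' @param fdr_cut FDR threshold for the thick border.
#' @param saturate colour saturation point, see [fold_change_colour()].
#' @return The network with an `annotations` element (data.frame: `node`,
#'   `kind`, `log2FC`, `FDR`, `colour`, `border`); DE genes that match no
#'   node are recorded in the `"unmapped_genes"` attribute.
#' @export
annotate_network <- function(net, dge, fdr_cut = 0.05, saturate = 4) {
  validate_network(net)
  m <- match(canon_id(net$nodes$id), canon_id(dge$gene))
  is_comp <- net$nodes$kind %in% c("component", "isoprotein")
  log2fc <- ifelse(is_comp, dge$log2FC[m], NA_real_)
  fdr <- ifelse(is_comp, dge$FDR[m], NA_real_)
  ann <- data.frame(
    node = net$nodes$id,
    kind = net$nodes$kind,
    log2FC = log2fc,
    FDR = fdr,
    colour = fold_change_colour(log2fc, saturate),
    border = ifelse(!is.na(fdr) & fdr < fdr_cut, "thick", "thin"),
    stringsAsFactors = FALSE)
  out <- net
  out$annotations <- ann
  attr(out, "unmapped_genes") <-
    setdiff(canon_id(dge$gene), canon_id(net$nodes$id[is_comp]))
  out
}

# One-sided (enrichment) Fisher exact p for a 2x2 table: upper tail of the
# hypergeometric distribution, computed directly from log binomial
# coefficients. a = regulated members, b = unregulated members,
# c = regulated non-members, d = unregulated non-members.
#' @keywords internal
fisher_p_greater <- function(a, b, c, d) {
  K <- a + b        # group size
  n <- a + c        # regulated genes
  N <- a + b + c + d
  kmax <- min(K, n)
  k <- a:kmax
  logp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  min(sum(exp(logp)), 1)
}

#' Complex-level Fisher enrichment of coordinated regulation
#'
#' Scores every protein complex, functional group or subsystem of the
#' network for enrichment of genes regulated in a given direction, against
#' the background of all component nodes with a DE record. The default
#' member criterion is `sign(log2FC)` matching the direction AND
#' `FDR < 0.05`, with no fold-change magnitude constraint: a complex whose
#' subunits all shift below the 2-fold cut is exactly the signal this test
#' exists to catch. The p-value is the one-sided Fisher exact
#' (hypergeometric upper-tail) probability; `-log10(p)` is reported and
#' Benjamini-Hochberg adjustment is applied across the groups tested.
#'
#' @param net a `recon_network`.
#' @param cat the catalogue (source of subsystem labels when
#'   `kind = "subsystem"`).
#' @param dge a `dge_table` (or data.frame with `gene`, `log2FC`, `FDR`).
#' @param kind grouping to score: `"complex"`, `"functional_group"` or
#'   `"subsystem"`.
#' @param direction `"up"` or `"down"`.
#' @param member_criterion `"fdr_sign"` (default: significant by FDR and
#'   signed accordingly) or `"sign_only"` (direction of change only).
#' @param fdr_cut FDR threshold used by the `fdr_sign` criterion.
#' @param min_members minimum scored members for a group to be tested.
#' @return data.frame of class `enrichment_result`: `group`, `kind`,
#'   `direction`, counts `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `neg_log10_p`, `q`. Groups skipped (too few scored members) are listed
#'   in the `"skipped"` attribute.
#' @export
complex_enrichment <- function(net, cat, dge,
                               kind = c("complex", "functional_group",
                                        "subsystem"),
                               direction = c("down", "up"),
                               member_criterion = c("fdr_sign", "sign_only"),
                               fdr_cut = 0.05, min_members = 2) {
  validate_network(net)
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  member_criterion <- match.arg(member_criterion)
  comp <- net$nodes$id[net$nodes$kind %in% c("component", "isoprotein")]
  m <- match(canon_id(comp), canon_id(dge$gene))
  scored <- !is.na(m) & !is.na(dge$log2FC[m])
  background <- comp[scored]
  if (!length(background)) stop("empty background: no component of the ",
                                "network has a DE record", call. = FALSE)
  fc <- dge$log2FC[m][scored]
  fdr <- dge$FDR[m][scored]
  sgn <- if (direction == "up") fc > 0 else fc < 0
  regulated <- switch(member_criterion,
                      fdr_sign = sgn & !is.na(fdr) & fdr < fdr_cut,
                      sign_only = sgn)
  groups <- group_members(net, cat, kind)
  skipped <- character(0)
  rows <- lapply(names(groups), function(g) {
    memb <- canon_id(background) %in% canon_id(groups[[g]])
    if (sum(memb) < min_members) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    a <- sum(memb & regulated)
    b <- sum(memb & !regulated)
    cc <- sum(!memb & regulated)
    dd <- sum(!memb & !regulated)
    p <- fisher_p_greater(a, b, cc, dd)
    or <- if (b == 0 || cc == 0) Inf else (a * dd) / (b * cc)
    if (a == 0) or <- 0
    data.frame(group = g, kind = kind, direction = direction,
               a = a, b = b, c = cc, d = dd, odds_ratio = or,
               p = p, neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    group = character(0), kind = character(0), direction = character(0),
    a = integer(0), b = integer(0), c = integer(0), d = integer(0),
    odds_ratio = numeric(0), p = numeric(0), neg_log10_p = numeric(0),
    stringsAsFactors = FALSE))))
  out$q <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

# Member component ids per group of the requested kind.
#' @keywords internal
group_members <- function(net, cat, kind) {
  if (kind == "subsystem") {
    vocab <- attr(cat, "vocabulary") %||% subsystem_vocabulary()
    labs <- lapply(cat$subsystems, split_multi)
    out <- lapply(vocab, function(s) {
      cat$id[vapply(labs, function(l) s %in% l, logical(1))]
    })
    names(out) <- vocab
    out[lengths(out) > 0]
  } else {
    memb <- net$edges[net$edges$interaction_class == "membership", ,
                      drop = FALSE]
    kind_of <- stats::setNames(net$nodes$kind, canon_id(net$nodes$id))
    memb <- memb[kind_of[canon_id(memb$target)] == kind, , drop = FALSE]
    split(memb$source, memb$target)
  }
}

#' Export the styled network and enrichment tables
#'
#' Writes the SIF / GraphML / node-attribute exports of [export_network()]
#' with the expression annotation (log2FC, FDR, colour, border) attached,
#' plus `enrichment.tsv` with the 2x2 counts, odds ratio, p, `-log10(p)` and
#' BH q per group. All files are plain text and round-trip loadable.
#'
#' @param net an annotated `recon_network` from [annotate_network()].
#' @param enrichment an `enrichment_result` (or several, rbind-ed), or
#'   `NULL`.
#' @param out_dir output directory.
#' @param cat optional catalogue for subsystem columns.
#' @return Named vector of written paths, invisibly.
#' @export
style_and_export <- function(net, enrichment = NULL, out_dir, cat = NULL) {
  if (is.null(net$annotations)) {
    stop("network has no annotations; call annotate_network() first",
         call. = FALSE)
  }
  paths <- export_network(net, out_dir, cat = cat,
                          annotations = net$annotations)
  enr_path <- file.path(out_dir, "enrichment.tsv")
  enr <- if (is.null(enrichment) || !nrow(enrichment)) {
    data.frame(group = character(0), kind = character(0),
               direction = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), odds_ratio = numeric(0),
               p = numeric(0), neg_log10_p = numeric(0), q = numeric(0))
  } else {
    as.data.frame(enrichment)
  }
  write_tsv(enr, enr_path)
  invisible(c(paths, enrichment = enr_path))
}
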