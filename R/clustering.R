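#' Spearman correlation distance matrix
#'
#' Distance `d = 1 - rho` (Spearman rank correlation with average ranks for
#' ties), symmetric with zero diagonal and values in `[0, 2]`. Genes with a
#' constant profile have no defined rank correlation and are excluded with a
#' warning.
#'
#' @param expr an `expression_matrix` (or plain genes x samples matrix).
#' @param genes optional subset of gene ids.
#' @return Symmetric numeric matrix with gene dimnames.
#' @export
spearman_distance_matrix <- function(expr, genes = NULL) {
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss)) {
      stop("gene(s) not in expression matrix: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    x <- x[genes, , drop = FALSE]
  }
  if (ncol(x) < 3) stop("need at least 3 samples", call. = FALSE)
  const <- apply(x, 1, function(v) max(v) == min(v))
  if (any(const)) {
    warning("excluding ", sum(const), " constant gene(s): ",
            paste(utils::head(rownames(x)[const], 5), collapse = ", "))
    x <- x[!const, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 usable genes", call. = FALSE)
  rho <- stats::cor(t(x), method = "spearman")
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' arithmetic mean of all cross-pair distances. Tie-breaking is
#' deterministic: labels are sorted lexicographically, each cluster is
#' indexed by its lowest member, and among equidistant pairs the lowest
#' `(i, j)` index pair merges first. Average linkage is monotone, so merge
#' heights are non-decreasing.
#'
#' @param d symmetric distance matrix with labels as dimnames.
#' @return Object of class `cluster_tree`: list with `labels` (sorted),
#'   hclust-style `merge` and `height`, and `leafsets` (per internal node,
#'   the sorted leaf labels it spans).
#' @export
average_linkage_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n <- length(labels)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  o <- order(labels)
  d <- d[o, o, drop = FALSE]
  labels <- labels[o]

  D <- d
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  code <- -seq_len(n)              # hclust coding: negative leaf index
  members <- as.list(seq_len(n))   # integer leaf sets per active slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  leafsets <- vector("list", n - 1L)

  mask <- matrix(Inf, n, n)
  mask[upper.tri(mask)] <- 0

  for (step in seq_len(n - 1L)) {
    W <- D + mask
    W[!active, ] <- Inf
    W[, !active] <- Inf
    m <- min(W)
    # values equal in exact arithmetic can differ in the last float bit
    # (incremental vs direct averaging); treat near-equal as tied so the
    # documented deterministic tie-break governs
    cand <- which(W <= m + 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    merge[step, ] <- sort_codes(code[i], code[j])
    height[step] <- m
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    leafsets[[step]] <- labels[members[[i]]]
    # Lance-Williams update for average linkage
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(others)) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- step
  }
  structure(list(labels = labels, merge = merge, height = height,
                 leafsets = leafsets),
            class = "cluster_tree")
}

# hclust convention: singletons (negative) before clusters, else ascending.
#' @keywords internal
sort_codes <- function(a, b) {
  if (a < b) c(a, b) else c(b, a)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster tree: ", length(x$labels), " leaves, ",
      nrow(x$merge), " merges (average linkage)\n", sep = "")
  invisible(x)
}

#' Convert a cluster tree to an hclust object
#'
#' @param x a `cluster_tree`.
#' @param ... unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.cluster_tree <- function(x, ...) {
  ord <- integer(0)
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(x$merge[code, 1L]), expand(x$merge[code, 2L]))
  }
  ord <- expand(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "spearman"),
            class = "hclust")
}

#' Newick serialisation of a cluster tree
#'
#' @param tree a `cluster_tree`.
#' @param node_labels optional character vector (one per internal node, in
#'   merge order) written as internal node labels, e.g. `"au=0.98|bp=0.95"`.
#' @param path optional output file.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, node_labels = NULL, path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  h <- function(code) if (code < 0) 0 else tree$height[code]
  render <- function(code, parent_h) {
    len <- max(parent_h - h(code), 0)
    if (code < 0) {
      sprintf("%s:%.6g", gsub("[,:;()\\s]", "_", tree$labels[-code]), len)
    } else {
      lab <- if (is.null(node_labels)) "" else node_labels[code]
      sprintf("(%s,%s)%s:%.6g",
              render(tree$merge[code, 1L], tree$height[code]),
              render(tree$merge[code, 2L], tree$height[code]),
              lab, len)
    }
  }
  root <- nrow(tree$merge)
  nw <- paste0(render(root, tree$height[root]), ";")
  if (!is.null(path)) {
    writeLines(nw, path)
    return(invisible(nw))
  }
  nw
}

#' @keywords internal
leafset_key <- function(idx) paste(idx, collapse = ",")

# One bootstrap pass: resample m columns with replacement, rebuild the tree,
# return the integer-leafset keys of its internal nodes. Gene order (hence
# leaf indexing) is fixed by the caller.
#' @keywords internal
boot_tree_keys <- function(x, m) {
  cols <- sample.int(ncol(x), m, replace = TRUE)
  xb <- x[, cols, drop = FALSE]
  rho <- suppressWarnings(stats::cor(t(xb), method = "spearman"))
  rho[is.na(rho)] <- 0  # gene constant in the resample: no signal
  d <- 1 - rho
  diag(d) <- 0
  tr <- average_linkage_tree(d)
  pos <- match(tr$labels, rownames(x))
  vapply(tr$leafsets, function(ls) leafset_key(sort(pos[match(ls, tr$labels)])),
         character(1))
}

#' Bootstrap probabilities of the clusters of a tree
#'
#' Resamples SAMPLES (columns) with replacement `nboot` times, recomputes the
#' Spearman distance and average-linkage tree, and scores each internal node
#' of the observed tree by the fraction of replicate trees containing an
#' internal node with the identical leaf set.
#'
#' @param expr `expression_matrix` or genes x samples matrix.
#' @param genes optional gene subset.
#' @param nboot number of bootstrap replicates (>= 1).
#' @param seed RNG seed for reproducibility.
#' @param resample_size number of columns drawn per replicate (default: all).
#' @return data.frame with one row per internal node of the observed tree:
#'   `node`, `size`, `bp`, `leafset` (";"-joined labels). The observed
#'   `cluster_tree` is attached as attribute `"tree"`.
#' @export
bootstrap_support <- function(expr, genes = NULL, nboot = 1000, seed = NULL,
                              resample_size = NULL) {
  if (nboot < 1) stop("nboot must be >= 1", call. = FALSE)
  d <- spearman_distance_matrix(expr, genes)
  tree <- average_linkage_tree(d)
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  x <- x[tree$labels, , drop = FALSE]
  m <- resample_size %||% ncol(x)
  if (m < 3) stop("resample size must be >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs_keys <- vapply(tree$leafsets, function(ls) {
    leafset_key(sort(match(ls, rownames(x))))
  }, character(1))
  counts <- stats::setNames(integer(length(obs_keys)), obs_keys)
  for (b in seq_len(nboot)) {
    keys <- boot_tree_keys(x, m)
    hit <- keys[keys %in% obs_keys]
    counts[hit] <- counts[hit] + 1L
  }
  out <- data.frame(node = seq_along(obs_keys),
                    size = lengths(tree$leafsets),
                    bp = as.numeric(counts) / nboot,
                    leafset = vapply(tree$leafsets, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  out
}

#' Approximately unbiased (AU) cluster support by multiscale bootstrap
#'
#' Runs the bootstrap of [bootstrap_support()] at several resample sizes
#' `round(r * n_samples)` for scale factors `r`, then for each internal node
#' fits the scaling law `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` by
#' weighted least squares (weights from the binomial variance of the
#' estimated quantile) and reports `AU = 1 - pnorm(v - c)` with a standard
#' error from the fit covariance: the `sqrt(r)` coefficient carries the
#' signed-distance signal (bootstrap support of a real cluster grows with
#' the resample fraction `r`), the `1/sqrt(r)` coefficient the boundary
#' curvature correction. Nodes whose BP is 0 or 1 at every scale are
#' degenerate: they get `AU = BP` with `SE = 0` and `degenerate = TRUE`; the
#' same fallback applies when fewer than 2 scales have BP strictly inside
#' (0, 1).
#'
#' @inheritParams bootstrap_support
#' @param scale_factors resample-fraction grid (conventional default
#'   0.5-1.4 in steps of 0.1).
#' @param nboot_per_scale bootstrap replicates per scale.
#' @return data.frame with per-node `node`, `size`, `bp` (at the scale
#'   closest to 1), `au`, `se_au`, `degenerate`, `leafset`; the observed
#'   `cluster_tree` is attribute `"tree"` and the per-scale BP matrix is
#'   attribute `"bp_by_scale"`.
#' @export
au_pvalues <- function(expr, genes = NULL,
                       scale_factors = seq(0.5, 1.4, by = 0.1),
                       nboot_per_scale = 1000, seed = NULL) {
  if (length(scale_factors) < 2) {
    stop("need at least 2 scale factors", call. = FALSE)
  }
  if (nboot_per_scale < 1) stop("nboot_per_scale must be >= 1", call. = FALSE)
  d <- spearman_distance_matrix(expr, genes)
  tree <- average_linkage_tree(d)
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  x <- x[tree$labels, , drop = FALSE]
  ns <- ncol(x)
  sizes <- pmax(3L, as.integer(round(scale_factors * ns)))
  r_eff <- sizes / ns  # actual scales achieved after rounding
  if (!is.null(seed)) set.seed(seed)
  obs_keys <- vapply(tree$leafsets, function(ls) {
    leafset_key(sort(match(ls, rownames(x))))
  }, character(1))
  bp_mat <- matrix(0, length(obs_keys), length(sizes),
                   dimnames = list(NULL, sprintf("r=%.3f", r_eff)))
  for (s in seq_along(sizes)) {
    counts <- stats::setNames(integer(length(obs_keys)), obs_keys)
    for (b in seq_len(nboot_per_scale)) {
      keys <- boot_tree_keys(x, sizes[s])
      hit <- keys[keys %in% obs_keys]
      counts[hit] <- counts[hit] + 1L
    }
    bp_mat[, s] <- as.numeric(counts) / nboot_per_scale
  }
  near1 <- which.min(abs(r_eff - 1))
  fits <- lapply(seq_along(obs_keys), function(i) {
    msfit_au(bp_mat[i, ], r_eff, nboot_per_scale, bp_mat[i, near1])
  })
  out <- data.frame(node = seq_along(obs_keys),
                    size = lengths(tree$leafsets),
                    bp = bp_mat[, near1],
                    au = vapply(fits, `[[`, 0, "au"),
                    se_au = vapply(fits, `[[`, 0, "se"),
                    degenerate = vapply(fits, `[[`, TRUE, "degenerate"),
                    leafset = vapply(tree$leafsets, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "bp_by_scale") <- bp_mat
  out
}

# Weighted least-squares fit of the multiscale scaling law for one node.
#' @keywords internal
msfit_au <- function(bp, r, nboot, bp_ref) {
  use <- bp > 0 & bp < 1
  if (sum(use) < 2) {
    return(list(au = bp_ref, se = 0, degenerate = TRUE))
  }
  bpv <- bp[use]; rv <- r[use]
  z <- stats::qnorm(1 - bpv)
  # var(z_hat) by the delta method on the binomial BP estimate
  v <- bpv * (1 - bpv) / (nboot * stats::dnorm(z)^2)
  X <- cbind(sqrt(rv), 1 / sqrt(rv))
  XtWX <- crossprod(X, X / v)
  coef <- solve(XtWX, crossprod(X, z / v))
  cvr <- solve(XtWX)
  cc <- coef[1L]; dd <- coef[2L]
  # z_au contrast: +1 on the sqrt(r) (signal) coefficient, -1 on the
  # 1/sqrt(r) (curvature) coefficient, matching the multiscale bootstrap of
  # the reference implementation
  zau <- cc - dd
  var_zau <- cvr[1, 1] + cvr[2, 2] - 2 * cvr[1, 2]
  au <- 1 - stats::pnorm(zau)
  se <- stats::dnorm(zau) * sqrt(max(var_zau, 0))
  list(au = au, se = se, degenerate = FALSE)
}

#' Extract maximal significant clusters
#'
#' Returns the maximal (non-nested) internal nodes whose AU support reaches
#' `alpha`: a passing node nested inside a passing ancestor is absorbed by
#' the ancestor. The root node spans all leaves and its bootstrap support is
#' tautologically 1, so with `include_root = TRUE` (the default contract) it
#' absorbs every other cluster whenever it passes; set `include_root = FALSE`
#' to screen it out for practical cluster extraction.
#'
#' @param support data.frame from [au_pvalues()] (or [bootstrap_support()],
#'   in which case `bp` is used as the support value).
#' @param alpha support threshold (default 0.95).
#' @param include_root whether the root node competes.
#' @return data.frame of maximal passing clusters: `node`, `size`, support
#'   columns, `leafset`.
#' @export
significant_clusters <- function(support, alpha = 0.95, include_root = TRUE) {
  val <- support$au %||% support$bp
  tree <- attr(support, "tree")
  cand <- which(val >= alpha)
  if (!include_root && length(cand)) {
    cand <- setdiff(cand, nrow(support))
  }
  if (!length(cand)) return(support[0, , drop = FALSE])
  sets <- strsplit(support$leafset[cand], ";", fixed = TRUE)
  ord <- order(-lengths(sets))
  keep <- logical(length(cand))
  kept_sets <- list()
  for (i in ord) {
    nested <- any(vapply(kept_sets, function(ks) all(sets[[i]] %in% ks),
                         logical(1)))
    if (!nested) {
      keep[i] <- TRUE
      kept_sets[[length(kept_sets) + 1L]] <- sets[[i]]
    }
  }
  out <- support[cand[keep], , drop = FALSE]
  out[order(-out$size), , drop = FALSE]
}
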