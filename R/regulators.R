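#' Summed Spearman correlation of every gene to a seed cluster
#'
#' Ranks candidate regulators of a functional cluster: for every gene `g` in
#' the expression matrix, `sum_rho` is the sum over seed genes `s` of the
#' Spearman correlation `rho(g, s)` and `sum_rho_sq` the sum of squared
#' correlations. Seed members are scored too (including their
#' self-correlation of 1) and flagged rather than silently dropped, so the
#' seed's internal coherence is inspectable. Constant genes get missing
#' scores.
#'
#' @param expr `expression_matrix` (or genes x samples matrix) covering the
#'   whole transcriptome.
#' @param seed_genes non-empty character vector of seed gene ids, all present
#'   in `expr`.
#' @return data.frame of class `regulator_scores`: `gene`, `sum_rho`,
#'   `sum_rho_sq`, `n_seed`, `is_seed`, `rank_pos` (1 = most positively
#'   correlated), `rank_neg` (1 = most negatively correlated); ties broken by
#'   gene id.
#' @export
summed_correlation_scores <- function(expr, seed_genes) {
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (!length(seed_genes)) stop("empty seed set", call. = FALSE)
  miss <- setdiff(seed_genes, rownames(x))
  if (length(miss)) {
    stop("seed gene(s) not in expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  if (ncol(x) < 4) stop("need at least 4 samples", call. = FALSE)
  seed_genes <- unique(seed_genes)
  rho <- suppressWarnings(
    stats::cor(t(x), t(x[seed_genes, , drop = FALSE]), method = "spearman"))
  sum_rho <- rowSums(rho)
  sum_rho_sq <- rowSums(rho^2)
  out <- data.frame(gene = rownames(x),
                    sum_rho = sum_rho,
                    sum_rho_sq = sum_rho_sq,
                    n_seed = length(seed_genes),
                    is_seed = rownames(x) %in% seed_genes,
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$sum_rho)
  out$rank_pos <- NA_integer_
  out$rank_neg <- NA_integer_
  out$rank_pos[ok] <- order(order(-out$sum_rho[ok], out$gene[ok]))
  out$rank_neg[ok] <- order(order(out$sum_rho[ok], out$gene[ok]))
  rownames(out) <- NULL
  class(out) <- c("regulator_scores", "data.frame")
  out
}

#' Top regulator candidates by summed correlation
#'
#' @param scores a `regulator_scores` table.
#' @param k number of candidates per direction (all genes if larger than the
#'   available count).
#' @param exclude_seed drop seed members from the candidate lists.
#' @param negative_by ranking statistic for the anti-correlated list:
#'   `"sum_rho"` (most negative summed correlation) or `"sum_rho_sq"`
#'   (largest summed squared correlation among genes with negative
#'   `sum_rho`).
#' @return List with data.frames `positive` and `negative`, each at most `k`
#'   rows in rank order.
#' @export
rank_regulator_candidates <- function(scores, k = 10, exclude_seed = TRUE,
                                      negative_by = c("sum_rho", "sum_rho_sq")) {
  stopifnot(inherits(scores, "regulator_scores"))
  negative_by <- match.arg(negative_by)
  pool <- scores[!is.na(scores$sum_rho), , drop = FALSE]
  if (exclude_seed) pool <- pool[!pool$is_seed, , drop = FALSE]
  pos <- pool[order(-pool$sum_rho, pool$gene), , drop = FALSE]
  neg <- if (negative_by == "sum_rho") {
    pool[order(pool$sum_rho, pool$gene), , drop = FALSE]
  } else {
    anti <- pool[pool$sum_rho < 0, , drop = FALSE]
    anti[order(-anti$sum_rho_sq, anti$gene), , drop = FALSE]
  }
  list(positive = utils::head(pos, k), negative = utils::head(neg, k))
}
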