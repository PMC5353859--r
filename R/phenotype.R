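#' Correlate gene expression with a phenotype
#'
#' Computes, per gene, both the Spearman rank correlation (monotonic
#' relationships) and the Pearson correlation (linear relationships) between
#' the gene's expression profile and a per-sample phenotype such as specific
#' growth rate or specific productivity. Samples are aligned by name;
#' constant genes or a constant phenotype yield missing values with a
#' warning.
#'
#' @param expr `expression_matrix` (or genes x samples matrix), typically
#'   restricted to network genes.
#' @param phenotype named numeric vector (names = sample ids) or unnamed
#'   vector of length `ncol(expr)` in column order; `NA`s are dropped.
#' @param phenotype_name label stored in the output.
#' @return data.frame of class `phenotype_correlations`: `gene`,
#'   `phenotype`, `rho_spearman`, `r_pearson`.
#' @export
correlate_to_phenotype <- function(expr, phenotype,
                                   phenotype_name = "phenotype") {
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (!is.null(names(phenotype))) {
    miss <- setdiff(colnames(x), names(phenotype))
    if (length(miss)) {
      stop("phenotype missing for sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    phenotype <- phenotype[colnames(x)]
  } else if (length(phenotype) != ncol(x)) {
    stop("unnamed phenotype vector must match the sample count",
         call. = FALSE)
  }
  use <- !is.na(phenotype)
  if (sum(use) < 4) {
    stop("need at least 4 samples with non-missing phenotype", call. = FALSE)
  }
  x <- x[, use, drop = FALSE]
  ph <- phenotype[use]
  if (max(ph) == min(ph)) {
    warning("constant phenotype: all correlations missing")
    rho <- r <- rep(NA_real_, nrow(x))
  } else {
    rho <- suppressWarnings(drop(stats::cor(t(x), ph, method = "spearman")))
    r <- suppressWarnings(drop(stats::cor(t(x), ph, method = "pearson")))
    n_const <- sum(is.na(rho))
    if (n_const) {
      warning(n_const, " constant gene(s) have missing correlations")
    }
  }
  out <- data.frame(gene = rownames(x), phenotype = phenotype_name,
                    rho_spearman = rho, r_pearson = r,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phenotype_correlations", "data.frame")
  out
}

#' Adaptive two-standard-deviation significance threshold
#'
#' Data-driven cut-offs for "significantly correlated": the mean and sample
#' standard deviation (n-1 denominator) of all non-missing per-gene
#' correlation values define the band `mean +/- 2 * sd`, clipped to
#' `[-1, 1]`; genes outside the band are called significant. Computed
#' separately per statistic and per phenotype - the realised numeric value is
#' data-set specific, not a constant.
#'
#' @param correlations numeric vector of per-gene correlation values for one
#'   statistic (missing values excluded).
#' @return List with `mean`, `sd`, `lower`, `upper`.
#' @export
adaptive_threshold <- function(correlations) {
  v <- correlations[!is.na(correlations)]
  if (length(v) < 2) {
    stop("need at least 2 non-missing correlations", call. = FALSE)
  }
  m <- mean(v)
  s <- stats::sd(v)
  list(mean = m, sd = s,
       lower = max(m - 2 * s, -1),
       upper = min(m + 2 * s, 1))
}

#' Flag phenotype-correlated genes against adaptive thresholds
#'
#' Applies the two-SD rule per statistic (Spearman and Pearson) to a
#' correlation table and attaches an optional known-target annotation
#' (category in `{folding_UPR, apoptosis, generic}` or any user labels) for
#' scatter-plot export.
#'
#' @param corrs a `phenotype_correlations` table (one phenotype).
#' @param thresholds optional list with elements `spearman` and `pearson`,
#'   each as returned by [adaptive_threshold()]; computed from `corrs` when
#'   `NULL`.
#' @param known_targets optional data.frame with columns `gene`, `category`.
#' @return The input table with added columns `significant_spearman`,
#'   `significant_pearson`, `category`; threshold records are kept in the
#'   `"thresholds"` attribute.
#' @export
classify_targets <- function(corrs, thresholds = NULL, known_targets = NULL) {
  stopifnot(inherits(corrs, "phenotype_correlations"))
  if (is.null(thresholds)) {
    thresholds <- list(spearman = adaptive_threshold(corrs$rho_spearman),
                       pearson = adaptive_threshold(corrs$r_pearson))
  }
  out <- corrs
  out$significant_spearman <- !is.na(out$rho_spearman) &
    (out$rho_spearman < thresholds$spearman$lower |
       out$rho_spearman > thresholds$spearman$upper)
  out$significant_pearson <- !is.na(out$r_pearson) &
    (out$r_pearson < thresholds$pearson$lower |
       out$r_pearson > thresholds$pearson$upper)
  out$category <- ""
  if (!is.null(known_targets)) {
    m <- match(canon_id(out$gene), canon_id(known_targets$gene))
    out$category <- ifelse(is.na(m), "", as.character(known_targets$category[m]))
  }
  attr(out, "thresholds") <- thresholds
  out
}

#' Scatter-ready table of correlations against two phenotypes
#'
#' Joins two classified correlation tables (e.g. growth rate and specific
#' productivity) by gene into one wide table for the classic
#' rho-growth versus rho-productivity scatter.
#'
#' @param corrs_x,corrs_y classified tables from [classify_targets()] for the
#'   x and y phenotypes.
#' @return data.frame with per-gene `rho_<phenotype>` columns, significance
#'   flags and the known-target category.
#' @export
phenotype_scatter <- function(corrs_x, corrs_y) {
  px <- corrs_x$phenotype[1]
  py <- corrs_y$phenotype[1]
  m <- match(canon_id(corrs_x$gene), canon_id(corrs_y$gene))
  out <- data.frame(gene = corrs_x$gene, stringsAsFactors = FALSE)
  out[[paste0("rho_", px)]] <- corrs_x$rho_spearman
  out[[paste0("rho_", py)]] <- corrs_y$rho_spearman[m]
  out[[paste0("significant_", px)]] <- corrs_x$significant_spearman %||%
    rep(NA, nrow(corrs_x))
  out[[paste0("significant_", py)]] <-
    (corrs_y$significant_spearman %||% rep(NA, nrow(corrs_y)))[m]
  out$category <- corrs_x$category %||% ""
  out
}
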