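#' Construct a count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = unique sample ids).
#' @param samples optional data.frame of per-sample metadata with a `sample`
#'   column matching `colnames(counts)`; typical columns: `cell_line`,
#'   `phase` (`exponential` / `stationary`), `treatment`, `product`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(counts), stringsAsFactors = FALSE)
  } else {
    if (!"sample" %in% names(samples)) {
      stop("sample metadata needs a 'sample' column", call. = FALSE)
    }
    if (!setequal(samples$sample, colnames(counts))) {
      stop("sample metadata does not match count matrix columns",
           call. = FALSE)
    }
    samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' Construct an expression matrix
#'
#' @param values numeric genes x samples matrix.
#' @param scale `"cpm"` or `"log2cpm"`.
#' @param normalization `"libsize"` or `"tmm"`.
#' @param scaling_factors per-sample scaling factors used (for provenance).
#' @param samples per-sample metadata data.frame.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, scale = c("cpm", "log2cpm"),
                              normalization = c("libsize", "tmm"),
                              scaling_factors = NULL, samples = NULL) {
  values <- as.matrix(values)
  scale <- match.arg(scale)
  normalization <- match.arg(normalization)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("expression values must have gene rownames and sample colnames",
         call. = FALSE)
  }
  if (is.null(colnames(values))) colnames(values) <- character(0)
  structure(list(values = values, scale = scale,
                 normalization = normalization,
                 scaling_factors = scaling_factors %||%
                   stats::setNames(rep(1, ncol(values)), colnames(values)),
                 samples = samples %||%
                   data.frame(sample = colnames(values),
                              stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (scale=", x$scale, ", normalization=", x$normalization,
      ")\n", sep = "")
  invisible(x)
}

#' Counts-per-million normalisation (library size or TMM)
#'
#' With `normalization = "libsize"`, `cpm[g,s] = counts[g,s] / libsize[s] *
#' 1e6`, so every non-empty column sums to one million. With
#' `normalization = "tmm"` the trimmed mean of M-values procedure is applied
#' first: the reference sample is the one whose upper-quartile count fraction
#' is closest to the mean upper quartile; per sample, log-ratios M and
#' average log-abundances A versus the reference are computed over genes
#' positive in both, the most extreme 30% of M and 5% of A are trimmed, and
#' the factor is the (inverse-variance weighted) mean M on the double-trimmed
#' set. Factors are normalised to geometric mean 1 and CPM uses effective
#' library sizes `libsize * factor`.
#'
#' @param x a `count_matrix`.
#' @param normalization `"libsize"` or `"tmm"`.
#' @param log if `TRUE`, return `log2(cpm + 1)`.
#' @return An `expression_matrix`.
#' @export
compute_cpm <- function(x, normalization = c("libsize", "tmm"), log = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  normalization <- match.arg(normalization)
  counts <- x$counts
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "),
         call. = FALSE)
  }
  factors <- if (normalization == "tmm") tmm_factors(counts) else
    stats::setNames(rep(1, ncol(counts)), colnames(counts))
  eff <- libsize * factors
  vals <- sweep(counts, 2, eff, "/") * 1e6
  scale <- "cpm"
  if (isTRUE(log)) {
    vals <- log2(vals + 1)
    scale <- "log2cpm"
  }
  expression_matrix(vals, scale = scale, normalization = normalization,
                    scaling_factors = factors, samples = x$samples)
}

# Weighted trimmed mean of M-values scaling factors.
#' @keywords internal
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  libsize <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)), function(s) {
    stats::quantile(counts[, s] / libsize[s], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    tmm_pair_factor(counts[, s], counts[, ref], libsize[s], libsize[ref],
                    trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  stats::setNames(f, colnames(counts))
}

#' @keywords internal
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  p_obs <- obs[keep] / n_obs
  p_ref <- ref[keep] / n_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  # delta-method asymptotic variance of M, used as inverse weights
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- stats::quantile(m, trim_m, names = FALSE)
  hi_m <- stats::quantile(m, 1 - trim_m, names = FALSE)
  lo_a <- stats::quantile(a, trim_a, names = FALSE)
  hi_a <- stats::quantile(a, 1 - trim_a, names = FALSE)
  use <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(use)) return(1)
  2^(sum(m[use] / w[use]) / sum(1 / w[use]))
}

#' Filter to expressed genes
#'
#' Keeps genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples (the conventional reading of "detected CPM in at least two
#' samples").
#'
#' @param expr an `expression_matrix` on the CPM scale.
#' @param min_cpm detection threshold in CPM units.
#' @param min_samples minimum number of samples reaching `min_cpm`.
#' @return The filtered `expression_matrix`; the kept / removed gene counts
#'   are stored in the `"filter_report"` attribute.
#' @export
filter_expressed <- function(expr, min_cpm = 1, min_samples = 2) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$scale != "cpm") {
    stop("filter_expressed expects scale = 'cpm' (got ", expr$scale, ")",
         call. = FALSE)
  }
  if (min_samples > ncol(expr$values)) {
    stop("min_samples (", min_samples, ") exceeds sample count (",
         ncol(expr$values), ")", call. = FALSE)
  }
  keep <- rowSums(expr$values >= min_cpm) >= min_samples
  out <- expr
  out$values <- expr$values[keep, , drop = FALSE]
  attr(out, "filter_report") <- list(n_kept = sum(keep),
                                     n_removed = sum(!keep),
                                     min_cpm = min_cpm,
                                     min_samples = min_samples)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * n / j` for the
#' order statistics, capped at 1, mapped back to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values outside [0,1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (!n) return(q)
  o <- order(p[ok])
  ranked <- p[ok][o] * n / seq_len(n)
  ranked <- rev(cummin(rev(ranked)))  # step-up monotonisation
  q[ok][o] <- pmin(ranked, 1)
  q
}

#' Adjust raw DE p-values and flag differential expression
#'
#' Applies Benjamini-Hochberg adjustment to per-gene p-values and classifies
#' each gene against the fold-change and significance thresholds:
#' `up` / `down` for genes passing `FDR < fdr_cut`, `p < p_cut` and
#' `|log2FC| >= fc_cut` in the corresponding direction; `de_below_fold` for
#' genes significant by FDR but below the fold cut (coordinated sub-fold
#' shifts matter at the complex level); `not_significant` otherwise;
#' `not_expressed` for genes with missing statistics.
#'
#' @param raw data.frame with columns `gene`, `log2FC`, `p` (and optionally a
#'   precomputed `FDR`, which is recomputed unless `recompute_fdr = FALSE`).
#' @param fc_cut absolute log2 fold-change threshold.
#' @param p_cut raw p-value threshold.
#' @param fdr_cut FDR threshold.
#' @param recompute_fdr recompute FDR from `p` by [bh_adjust()].
#' @return data.frame of class `dge_table` with columns `gene`, `log2FC`,
#'   `p`, `FDR`, `status`.
#' @export
adjust_and_flag_de <- function(raw, fc_cut = 2.0, p_cut = 0.05,
                               fdr_cut = 0.05, recompute_fdr = TRUE) {
  need <- c("gene", "log2FC", "p")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(raw$p < 0 | raw$p > 1, na.rm = TRUE)) {
    stop("p-values outside [0,1]", call. = FALSE)
  }
  fdr <- if (recompute_fdr || is.null(raw$FDR)) bh_adjust(raw$p) else raw$FDR
  status <- rep("not_significant", nrow(raw))
  na <- is.na(raw$p) | is.na(raw$log2FC)
  status[na] <- "not_expressed"
  sig <- !na & fdr < fdr_cut
  status[sig & raw$p < p_cut & raw$log2FC >= fc_cut] <- "up"
  status[sig & raw$p < p_cut & raw$log2FC <= -fc_cut] <- "down"
  status[sig & abs(raw$log2FC) < fc_cut] <- "de_below_fold"
  out <- data.frame(gene = as.character(raw$gene), log2FC = raw$log2FC,
                    p = raw$p, FDR = fdr, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("dge_table", "data.frame")
  out
}

#' Doubling time from specific growth rate
#'
#' `t_d = ln(2) / mu` (hours, for `mu` in 1/h).
#'
#' @param mu specific growth rate, strictly positive.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("mu must be finite and > 0", call. = FALSE)
  }
  log(2) / mu
}

#' Construct a culture growth record
#'
#' @param time sampling times (h), strictly increasing.
#' @param viable_density viable cell densities (cells/mL), non-negative.
#' @param titer optional product titers (mg/L).
#' @return data.frame of class `growth_record`.
#' @export
growth_record <- function(time, viable_density, titer = NULL) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (any(viable_density < 0)) {
    stop("viable densities must be >= 0", call. = FALSE)
  }
  out <- data.frame(time = time, viable_density = viable_density,
                    titer = if (is.null(titer)) NA_real_ else titer)
  class(out) <- c("growth_record", "data.frame")
  out
}

#' Fit the specific growth rate over a time window
#'
#' Least-squares slope of `ln(viable density)` versus time over the points in
#' the window with positive density.
#'
#' @param record a `growth_record`.
#' @param window numeric length-2 time interval (defaults to the full record).
#' @return Specific growth rate `mu` in 1/h.
#' @export
fit_growth_rate <- function(record, window = range(record$time)) {
  stopifnot(inherits(record, "growth_record"))
  use <- record$time >= window[1] & record$time <= window[2] &
    record$viable_density > 0
  if (sum(use) < 2) {
    stop("need at least 2 points with positive density in the window",
         call. = FALSE)
  }
  fit <- stats::lm(log(viable_density) ~ time, data = record[use, ])
  unname(stats::coef(fit)[["time"]])
}

#' Cell-specific productivity
#'
#' `q_P = dP / integral(X dt)`: total titer change divided by the trapezoidal
#' integral of viable cell density over time, converted to pg per cell per
#' hour (titer in mg/L, density in cells/mL, time in h). A decreasing titer
#' yields a negative rate with a warning.
#'
#' @param record a `growth_record` with titers.
#' @return Specific productivity in pg/cell/h.
#' @export
specific_productivity <- function(record) {
  stopifnot(inherits(record, "growth_record"))
  use <- !is.na(record$titer)
  if (sum(use) < 2) {
    stop("need at least 2 timepoints with titer", call. = FALSE)
  }
  r <- record[use, ]
  dP <- r$titer[nrow(r)] - r$titer[1]          # mg/L
  dt <- diff(r$time)                           # h
  xmid <- (r$viable_density[-1] + r$viable_density[-nrow(r)]) / 2
  ivcd <- sum(xmid * dt)                       # cells*h/mL
  if (ivcd <= 0) stop("non-positive integral of viable cell density",
                      call. = FALSE)
  qp <- dP * 1e6 / ivcd                        # mg/L -> pg/mL
  if (qp < 0) warning("titer decreased over the record: negative q_P")
  qp
}
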