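#' Specification of a synthetic expression data set
#'
#' Describes the stated world the generators emulate: a Gaussian
#' latent-factor model with planted co-regulated modules (standing in for
#' protein complexes / functional groups), planted regulator genes whose
#' profiles follow (or mirror) a module's latent factor, negative-binomial
#' count sampling, and phenotype vectors planted to correlate with chosen
#' genes. All randomness is controlled by the mandatory seed.
#'
#' @param n_genes total genes.
#' @param n_samples samples (columns).
#' @param module_sizes integer vector, one entry per planted module; must sum
#'   to at most `n_genes`.
#' @param loading_range range of per-gene loadings on the module factor.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   module genes (signal sd is 1).
#' @param regulators data.frame with columns `module` (integer) and `type`
#'   (`"correlated"` / `"anti"`); each plants one regulator gene.
#' @param regulator_noise_sd noise sd of regulator profiles (small: a
#'   regulator tracks its module's latent factor closely).
#' @param nb_dispersion common negative-binomial dispersion for
#'   [generate_counts()] (0 = Poisson).
#' @param libsize_range per-sample library-size range.
#' @param phenotype_plants data.frame with columns `gene`, `rho` (target
#'   Spearman correlation of the phenotype with that gene).
#' @param seed RNG seed (mandatory).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000, n_samples = 24,
                           module_sizes = rep(25, 4),
                           loading_range = c(0.8, 1.2),
                           noise_sd = 0.3,
                           regulators = data.frame(
                             module = c(1, 1, 1, 1, 1, 1),
                             type = c(rep("correlated", 5), "anti")),
                           regulator_noise_sd = 0.1,
                           nb_dispersion = 0.1,
                           libsize_range = c(1e6, 2e6),
                           phenotype_plants = NULL,
                           seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (sum(module_sizes) + nrow(regulators %||% data.frame()) > n_genes) {
    stop("module sizes plus regulators exceed n_genes", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(regulators) && nrow(regulators) &&
      any(!regulators$type %in% c("correlated", "anti"))) {
    stop("regulator type must be 'correlated' or 'anti'", call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 module_sizes = as.integer(module_sizes),
                 loading_range = loading_range, noise_sd = noise_sd,
                 regulators = regulators,
                 regulator_noise_sd = regulator_noise_sd,
                 nb_dispersion = nb_dispersion,
                 libsize_range = libsize_range,
                 phenotype_plants = phenotype_plants,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a modular expression matrix with planted structure
#'
#' Module gene `g` of module `m` gets `x[g, s] = a_g * f_m[s] + eps`,
#' `eps ~ N(0, noise_sd)`, with the latent factor `f_m ~ N(0, 1)` per sample
#' and loadings `a_g` uniform in `loading_range`. Background genes are
#' independent `N(0, 1)` noise. Planted regulators follow `+f_m` (type
#' `correlated`) or `-f_m` (type `anti`) plus small noise.
#'
#' @param spec a `synthetic_spec`.
#' @return An `expression_matrix` (scale `log2cpm`, abstract log-expression
#'   units) with a `"truth"` attribute: data.frame `gene`, `role`
#'   (`module` / `regulator` / `background`), `module`, `regulator_type`.
#' @export
generate_modular_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, 1L))
  ng <- spec$n_genes; ns <- spec$n_samples
  nm <- length(spec$module_sizes)
  genes <- sprintf("G%05d", seq_len(ng))
  x <- matrix(stats::rnorm(ng * ns), ng, ns,
              dimnames = list(genes, sprintf("S%02d", seq_len(ns))))
  truth <- data.frame(gene = genes, role = "background",
                      module = NA_integer_, regulator_type = NA_character_,
                      stringsAsFactors = FALSE)
  factors <- matrix(stats::rnorm(nm * ns), nm, ns)
  idx <- 0L
  for (m in seq_len(nm)) {
    sz <- spec$module_sizes[m]
    rows <- idx + seq_len(sz)
    a <- stats::runif(sz, spec$loading_range[1], spec$loading_range[2])
    x[rows, ] <- a %o% factors[m, ] +
      matrix(stats::rnorm(sz * ns, sd = spec$noise_sd), sz, ns)
    truth$role[rows] <- "module"
    truth$module[rows] <- m
    idx <- idx + sz
  }
  regs <- spec$regulators
  if (!is.null(regs) && nrow(regs)) {
    for (i in seq_len(nrow(regs))) {
      idx <- idx + 1L
      sgn <- if (regs$type[i] == "anti") -1 else 1
      x[idx, ] <- sgn * factors[regs$module[i], ] +
        stats::rnorm(ns, sd = spec$regulator_noise_sd)
      truth$role[idx] <- "regulator"
      truth$module[idx] <- regs$module[i]
      truth$regulator_type[idx] <- regs$type[i]
    }
  }
  out <- expression_matrix(x, scale = "log2cpm", normalization = "libsize")
  attr(out, "truth") <- truth
  out
}

#' Generate a negative-binomial count matrix
#'
#' Gene-wise mean expression is taken from the modular expression profile
#' (exponentiated around a per-gene baseline), scaled per sample to a library
#' size drawn from `libsize_range`, and counts are sampled with the common
#' dispersion `nb_dispersion` (`variance = mu + dispersion * mu^2`;
#' dispersion 0 gives Poisson).
#'
#' @param spec a `synthetic_spec`.
#' @return A `count_matrix`; the expression truth table, the per-cell mean
#'   matrix and the expected column sums are attached as attributes
#'   `"truth"`, `"expected_mean"` and `"expected_libsize"`.
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  expr <- generate_modular_expression(spec)
  set.seed(derive_seed(spec$seed, 2L))
  ng <- spec$n_genes; ns <- spec$n_samples
  baseline <- stats::runif(ng, 3, 10)            # log2 abundance scale
  rel <- 2^(baseline + expr$values)              # relative abundance
  prop <- sweep(rel, 2, colSums(rel), "/")
  libsize <- stats::runif(ns, spec$libsize_range[1], spec$libsize_range[2])
  mu <- sweep(prop, 2, libsize, "*")
  counts <- if (spec$nb_dispersion > 0) {
    matrix(stats::rnbinom(ng * ns, mu = mu, size = 1 / spec$nb_dispersion),
           ng, ns)
  } else {
    matrix(stats::rpois(ng * ns, lambda = mu), ng, ns)
  }
  dimnames(counts) <- dimnames(expr$values)
  out <- count_matrix(counts,
                      samples = data.frame(sample = colnames(counts),
                                           stringsAsFactors = FALSE))
  attr(out, "truth") <- attr(expr, "truth")
  attr(out, "expected_mean") <- mu
  attr(out, "expected_libsize") <- libsize
  out
}

#' Generate a phenotype vector planted to correlate with chosen genes
#'
#' The phenotype is a weighted combination of the standardised planted gene
#' profiles plus Gaussian noise. Weights solve `S w = rho` (with `S` the
#' correlation matrix of the plant profiles) and the noise variance is
#' `1 - rho' S^{-1} rho`, so each plant's population correlation with the
#' phenotype equals its target; incompatible targets (noise variance < 0)
#' raise an error.
#'
#' @param expr an `expression_matrix`.
#' @param plants data.frame with columns `gene`, `rho` (targets in
#'   `(-1, 1]`); `NULL` or empty plants give pure-noise phenotypes.
#' @param seed RNG seed.
#' @return Named numeric phenotype vector (one value per sample) with the
#'   plant table as `"truth"` attribute.
#' @export
generate_phenotype <- function(expr, plants = NULL, seed) {
  x <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  set.seed(derive_seed(seed, 3L))
  ns <- ncol(x)
  if (is.null(plants) || !nrow(plants)) {
    ph <- stats::rnorm(ns)
    names(ph) <- colnames(x)
    attr(ph, "truth") <- data.frame(gene = character(0), rho = numeric(0))
    return(ph)
  }
  miss <- setdiff(plants$gene, rownames(x))
  if (length(miss)) {
    stop("planted gene(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Z <- t(scale(t(x[plants$gene, , drop = FALSE])))  # standardised profiles
  S <- stats::cor(t(Z))
  rho <- plants$rho
  w <- solve(S, rho)
  tau2 <- 1 - sum(rho * w)
  if (tau2 < -1e-8) {
    stop("infeasible phenotype targets: rho' S^{-1} rho > 1", call. = FALSE)
  }
  tau2 <- max(tau2, 0)
  ph <- drop(t(Z) %*% w) + stats::rnorm(ns, sd = sqrt(tau2))
  ph <- as.numeric(ph)
  names(ph) <- colnames(x)
  attr(ph, "truth") <- plants
  ph
}

#' Generate a toy reconstruction: catalogue, interactions and hit table
#'
#' Builds a small but structurally complete fixture: a catalogue of
#' `n_components` components with random subsystem labels, `n_complexes`
#' protein complexes and `n_groups` functional groups with random
#' memberships, a random protein-protein interaction list of the requested
#' density, and an alignment hit table whose per-component tiers follow
#' `tier_mix` (high / moderate / unmapped), including partial and pseudogene
#' flags.
#'
#' @param n_components,n_complexes,n_groups structure sizes.
#' @param interaction_density probability that an (ordered) component pair is
#'   connected.
#' @param tier_mix length-3 probabilities for high / moderate / unmapped.
#' @param p_partial probability that a mapped subject is flagged partial.
#' @param seed RNG seed.
#' @param species species label of the catalogue.
#' @return List with `catalogue` (a `secrepath_catalogue`), `interactions`
#'   (a `secrepath_interactions`), `hits` (a `homology_hits`), and `truth`
#'   (data.frame `reference_id`, `tier`).
#' @export
generate_toy_recon <- function(n_components = 20, n_complexes = 2,
                               n_groups = 3, interaction_density = 0.1,
                               tier_mix = c(high = 0.7, moderate = 0.2,
                                            unmapped = 0.1),
                               p_partial = 0.1, seed, species = "reference") {
  set.seed(derive_seed(seed, 4L))
  ids <- sprintf("SEC%03d", seq_len(n_components))
  vocab <- subsystem_vocabulary()
  subsystems <- vapply(seq_len(n_components), function(i) {
    join_multi(sort(sample(vocab, sample(1:2, 1))))
  }, character(1))
  cx_names <- if (n_complexes > 0) sprintf("CPLX%02d", seq_len(n_complexes))
              else character(0)
  fg_names <- if (n_groups > 0) sprintf("FG%02d", seq_len(n_groups))
              else character(0)
  complexes <- rep("", n_components)
  if (n_complexes > 0) {
    assign_cx <- sample(c(cx_names, ""), n_components, replace = TRUE,
                        prob = c(rep(0.3 / n_complexes, n_complexes), 0.7))
    # guarantee every complex has at least 3 members
    for (k in seq_len(n_complexes)) {
      if (sum(assign_cx == cx_names[k]) < 3) {
        free <- which(assign_cx == "")
        take <- utils::head(free, 3 - sum(assign_cx == cx_names[k]))
        assign_cx[take] <- cx_names[k]
      }
    }
    complexes <- assign_cx
  }
  groups <- rep("", n_components)
  if (n_groups > 0) {
    groups <- vapply(seq_len(n_components), function(i) {
      k <- min(sample(0:2, 1, prob = c(0.4, 0.4, 0.2)), n_groups)
      if (k == 0) "" else join_multi(sort(sample(fg_names, k)))
    }, character(1))
    for (k in seq_len(n_groups)) {          # every group non-empty
      if (!any(grepl(fg_names[k], groups, fixed = TRUE))) {
        i <- sample(n_components, 1)
        groups[i] <- join_multi(c(split_multi(groups[i]), fg_names[k]))
      }
    }
  }
  cat_df <- data.frame(id = ids, species = species, subsystems = subsystems,
                       functional_groups = groups, complexes = complexes,
                       evidence = sample(c("verified", "tentative"),
                                         n_components, replace = TRUE,
                                         prob = c(0.9, 0.1)),
                       core = stats::runif(n_components) < 0.35,
                       stringsAsFactors = FALSE)
  cat <- catalogue(cat_df)
  pairs <- utils::combn(ids, 2)
  take <- stats::runif(ncol(pairs)) < interaction_density
  ia <- interactions(pairs[1, take], pairs[2, take],
                     interaction_class = sample(
                       c("protein_protein", "protein_DNA", "DNA_DNA"),
                       sum(take), replace = TRUE, prob = c(0.8, 0.15, 0.05)),
                     provenance = "synthetic")
  tiers <- sample(names(tier_mix), n_components, replace = TRUE,
                  prob = tier_mix)
  hit_rows <- lapply(seq_len(n_components), function(i) {
    subject <- paste0("TGT", sub("SEC", "", ids[i]))
    partial <- stats::runif(1) < p_partial
    row <- switch(
      tiers[i],
      high = c(stats::runif(1, 81, 99.5), stats::runif(1, 100, 800),
               10^stats::runif(1, -120, -20)),
      moderate = c(stats::runif(1, 60.5, 79.5), stats::runif(1, 51, 400),
                   10^stats::runif(1, -40, -6)),
      unmapped = if (stats::runif(1) < 0.5) {
        c(stats::runif(1, 20, 59.5), stats::runif(1, 20, 45),
          10^stats::runif(1, -4, 1))
      } else {
        # pseudogene subject with otherwise strong alignment
        c(stats::runif(1, 81, 99), stats::runif(1, 100, 500),
          10^stats::runif(1, -100, -20))
      })
    pseudo <- tiers[i] == "unmapped" && row[1] > 80
    len <- as.integer(round(stats::runif(1, 150, 900)))
    sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t1\t%d\t1\t%d\t%.3g\t%.1f\t%s\t%s",
            ids[i], subject, row[1], len, as.integer(round(len * 0.2)), 2L,
            len, len, row[3], row[2],
            tolower(partial && tiers[i] != "unmapped"), tolower(pseudo))
  })
  hit_path <- tempfile(fileext = ".tsv")
  writeLines(unlist(hit_rows), hit_path)
  hits <- parse_hits(hit_path)
  unlink(hit_path)
  list(catalogue = cat, interactions = ia, hits = hits,
       truth = data.frame(reference_id = ids, tier = tiers,
                          stringsAsFactors = FALSE))
}
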