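#' Parse an alignment hit table (12-column tabular format)
#'
#' Reads the standard tabular output of pairwise protein aligners
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), with optional extra columns 13–14 carrying
#' `partial` and `pseudogene` flags for the subject (default `FALSE`).
#'
#' @param path path to the hit table (tab-separated, no header).
#' @return data.frame of class `homology_hits` with columns `query_id`,
#'   `subject_id`, `pident`, `aln_length`, `mismatch`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`, `subject_partial`,
#'   `subject_pseudogene`.
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 12L)
  if (length(bad)) {
    stop("malformed hit line(s) (fewer than 12 columns): line ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  get <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, name) {
    v <- suppressWarnings(as.numeric(get(i)))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric ", name, " at line ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    v
  }
  flag <- function(i) {
    if (all(nf >= i)) parse_flag(get(i), paste0("column ", i))
    else vapply(parts, function(p) {
      if (length(p) >= i) parse_flag(p[[i]], paste0("column ", i)) else FALSE
    }, logical(1))
  }
  hits <- data.frame(
    query_id = get(1), subject_id = get(2),
    pident = num(3, "pident"), aln_length = num(4, "length"),
    mismatch = num(5, "mismatch"), gapopen = num(6, "gapopen"),
    qstart = num(7, "qstart"), qend = num(8, "qend"),
    sstart = num(9, "sstart"), send = num(10, "send"),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    subject_partial = if (any(nf >= 13L)) flag(13L) else FALSE,
    subject_pseudogene = if (any(nf >= 14L)) flag(14L) else FALSE,
    stringsAsFactors = FALSE)
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop("pident outside [0,100] at line ",
         paste(which(hits$pident < 0 | hits$pident > 100), collapse = ", "),
         call. = FALSE)
  }
  if (any(hits$evalue < 0)) {
    stop("negative e-value at line ",
         paste(which(hits$evalue < 0), collapse = ", "), call. = FALSE)
  }
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

#' @keywords internal
empty_hits <- function() {
  structure(data.frame(query_id = character(0), subject_id = character(0),
                       pident = numeric(0), aln_length = numeric(0),
                       mismatch = numeric(0), gapopen = numeric(0),
                       qstart = numeric(0), qend = numeric(0),
                       sstart = numeric(0), send = numeric(0),
                       evalue = numeric(0), bitscore = numeric(0),
                       subject_partial = logical(0),
                       subject_pseudogene = logical(0),
                       stringsAsFactors = FALSE),
            class = c("homology_hits", "data.frame"))
}

#' Default thresholds for tiered homolog acceptance
#'
#' Two acceptance tiers: a high-confidence tier for best hits with identity
#' above `high_pident` percent, and a moderate tier for best hits with
#' identity above `mod_pident` percent, bitscore above `mod_bitscore` and a
#' significant e-value (`mod_evalue` at most). Best hit per query is the one
#' with the lowest e-value (ties: higher bitscore, then higher identity, then
#' lexicographic subject id).
#'
#' @param high_pident,mod_pident,mod_bitscore,mod_evalue numeric thresholds.
#' @return Named list of thresholds.
#' @export
homology_thresholds <- function(high_pident = 80, mod_pident = 60,
                                mod_bitscore = 50, mod_evalue = 1e-5) {
  list(high_pident = high_pident, mod_pident = mod_pident,
       mod_bitscore = mod_bitscore, mod_evalue = mod_evalue)
}

#' Assign target homologs to reference components
#'
#' Produces exactly one assignment per reference id present in the hit table.
#' The best hit (lowest e-value, deterministic tie-breaking) is examined: a
#' pseudogene subject is never assigned; otherwise the tier rules of
#' [homology_thresholds()] apply and failing both tiers leaves the reference
#' unmapped. The subject's `partial` flag is propagated.
#'
#' @param hits a `homology_hits` table.
#' @param thresholds list from [homology_thresholds()].
#' @return data.frame of class `homology_assignments` with columns
#'   `reference_id`, `target_id` (`NA` when unmapped), `tier`
#'   (`high` / `moderate` / `unmapped`), `reason`, `partial`, plus best-hit
#'   statistics `pident`, `evalue`, `bitscore`.
#' @export
assign_homologs <- function(hits, thresholds = homology_thresholds()) {
  stopifnot(is.data.frame(hits))
  queries <- unique(hits$query_id)
  rows <- lapply(queries, function(q) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    o <- order(h$evalue, -h$bitscore, -h$pident, h$subject_id)
    best <- h[o[1L], , drop = FALSE]
    if (best$subject_pseudogene) {
      return(data.frame(reference_id = q, target_id = NA_character_,
                        tier = "unmapped", reason = "pseudogene",
                        partial = FALSE, pident = best$pident,
                        evalue = best$evalue, bitscore = best$bitscore,
                        stringsAsFactors = FALSE))
    }
    if (best$pident > thresholds$high_pident) {
      tier <- "high"; reason <- sprintf("identity %.1f%% > %g%%",
                                        best$pident, thresholds$high_pident)
    } else if (best$pident > thresholds$mod_pident &&
               best$bitscore > thresholds$mod_bitscore &&
               best$evalue <= thresholds$mod_evalue) {
      tier <- "moderate"
      reason <- sprintf(
        "identity %.1f%% > %g%%, bitscore %.1f > %g, e-value %.2g <= %g",
        best$pident, thresholds$mod_pident, best$bitscore,
        thresholds$mod_bitscore, best$evalue, thresholds$mod_evalue)
    } else {
      tier <- "unmapped"; reason <- "below acceptance thresholds"
    }
    data.frame(reference_id = q,
               target_id = if (tier == "unmapped") NA_character_ else best$subject_id,
               tier = tier, reason = reason,
               partial = if (tier == "unmapped") FALSE else best$subject_partial,
               pident = best$pident, evalue = best$evalue,
               bitscore = best$bitscore, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    reference_id = character(0), target_id = character(0), tier = character(0),
    reason = character(0), partial = logical(0), pident = numeric(0),
    evalue = numeric(0), bitscore = numeric(0), stringsAsFactors = FALSE))))
  class(out) <- c("homology_assignments", "data.frame")
  out
}

#' Transfer a reference catalogue to a target species
#'
#' Builds a target-species catalogue with one component per mapped
#' assignment: subsystem, functional-group and complex memberships, evidence
#' and core flags are copied from the reference component; `homolog_of`
#' records the reference id and the `partial` flag is the union of the
#' reference's and the subject's partial annotation.
#'
#' @param ref_cat reference `secrepath_catalogue`.
#' @param assignments `homology_assignments` whose `reference_id`s must all
#'   exist in `ref_cat`.
#' @param species species label for the target catalogue.
#' @return A `secrepath_catalogue` with a `transfer_report` attribute: list
#'   with `n_mapped`, `unmapped` (reference ids), and `many_to_one`
#'   (target ids serving several reference components).
#' @export
transfer_catalogue <- function(ref_cat, assignments, species = "target") {
  validate_catalogue(ref_cat)
  m <- match(canon_id(assignments$reference_id), canon_id(ref_cat$id))
  if (anyNA(m)) {
    stop("assignment(s) reference unknown component id(s): ",
         paste(unique(assignments$reference_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  mapped <- assignments[assignments$tier != "unmapped", , drop = FALSE]
  ref_rows <- ref_cat[match(canon_id(mapped$reference_id), canon_id(ref_cat$id)), ,
                      drop = FALSE]
  tgt <- data.frame(
    id = mapped$target_id,
    species = rep(species, nrow(mapped)),
    kind = ref_rows$kind,
    subsystems = ref_rows$subsystems,
    functional_groups = ref_rows$functional_groups,
    complexes = ref_rows$complexes,
    evidence = ref_rows$evidence,
    core = ref_rows$core,
    partial = ref_rows$partial | mapped$partial,
    homolog_of = ref_rows$id,
    notes = ref_rows$notes,
    stringsAsFactors = FALSE)
  # one target gene may serve several reference components; keep the first
  # occurrence as the catalogue row and report the duplicates
  dup_key <- canon_id(tgt$id)
  many <- unique(tgt$id[duplicated(dup_key)])
  tgt_unique <- tgt[!duplicated(dup_key), , drop = FALSE]
  out <- catalogue(tgt_unique,
                   vocabulary = attr(ref_cat, "vocabulary"),
                   allow_extra_labels = attr(ref_cat, "allow_extra_labels"))
  attr(out, "transfer_report") <- list(
    n_mapped = nrow(mapped),
    unmapped = assignments$reference_id[assignments$tier == "unmapped"],
    many_to_one = many)
  out
}
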