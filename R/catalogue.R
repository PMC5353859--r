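#' Controlled vocabulary of secretory-pathway subsystems
#'
#' The interconnected sub-pathways of protein secretion used to annotate
#' catalogue components: translocation into the ER, protein folding, protein
#' transport, the unfolded protein response (UPR), ER-associated degradation
#' (ERAD), plus the branch subsystems autophagy, apoptosis and ER stress.
#' Components may belong to several subsystems.
#'
#' @return Character vector of valid subsystem labels.
#' @export
subsystem_vocabulary <- function() {
  c("translocation", "protein_folding", "protein_transport", "UPR", "ERAD",
    "autophagy", "apoptosis", "ER_stress", "other")
}

#' @keywords internal
catalogue_columns <- function() {
  c("id", "species", "kind", "subsystems", "functional_groups", "complexes",
    "evidence", "core", "partial", "homolog_of", "notes")
}

#' Construct a secretory-pathway component catalogue
#'
#' A catalogue is the typed list of secretory components: one row per
#' component, with subsystem / functional-group / protein-complex memberships
#' (";"-separated multi-value cells), an evidence flag (`verified` components
#' are literature supported; `tentative` ones are only tentatively associated
#' with the machinery), a `core` flag for members of the core secretory
#' machinery, and a `partial` flag for partially annotated entries.
#'
#' @param components data.frame with at least an `id` column; missing optional
#'   columns are filled with defaults (`species = "unknown"`,
#'   `kind = "component"`, `evidence = "verified"`, logical flags `FALSE`).
#' @param vocabulary controlled vocabulary for subsystem labels.
#' @param allow_extra_labels if `TRUE`, subsystem labels outside the
#'   vocabulary are tolerated (fail-fast errors otherwise).
#' @return An object of class `secrepath_catalogue` (a validated data.frame).
#' @export
catalogue <- function(components,
                      vocabulary = subsystem_vocabulary(),
                      allow_extra_labels = FALSE) {
  stopifnot(is.data.frame(components))
  if (!"id" %in% names(components)) {
    stop("catalogue requires an 'id' column", call. = FALSE)
  }
  df <- data.frame(id = trimws(as.character(components$id)),
                   stringsAsFactors = FALSE)
  defaults <- list(species = "unknown", kind = "component", subsystems = "",
                   functional_groups = "", complexes = "",
                   evidence = "verified", core = FALSE, partial = FALSE,
                   homolog_of = "", notes = "")
  for (col in names(defaults)) {
    if (col %in% names(components)) {
      val <- components[[col]]
      if (is.logical(defaults[[col]])) {
        val <- parse_flag(val, col)
      } else {
        val <- as.character(val)
        val[is.na(val)] <- ""
      }
      df[[col]] <- val
    } else {
      df[[col]] <- rep(defaults[[col]], nrow(df))
    }
  }
  df <- df[, catalogue_columns()]
  out <- structure(df, class = c("secrepath_catalogue", "data.frame"),
                   vocabulary = vocabulary,
                   allow_extra_labels = isTRUE(allow_extra_labels))
  validate_catalogue(out)
}

#' @keywords internal
parse_flag <- function(x, col) {
  if (is.logical(x)) {
    x[is.na(x)] <- FALSE
    return(x)
  }
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("true", "t", "1", "yes", "y")
  bad <- !v %in% c("true", "t", "1", "yes", "y", "false", "f", "0", "no", "n", "", "na")
  if (any(bad)) {
    stop("column '", col, "': unparseable logical value(s): ",
         paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Validate a catalogue
#'
#' Checks the catalogue invariants: non-empty unique ids (compared
#' case-insensitively), subsystem labels within the controlled vocabulary,
#' and `evidence` in `{verified, tentative}`.
#'
#' @param cat a `secrepath_catalogue`.
#' @return The catalogue, invisibly returned unchanged, or an error.
#' @export
validate_catalogue <- function(cat) {
  stopifnot(inherits(cat, "secrepath_catalogue"))
  if (nrow(cat) > 0 && any(!nzchar(cat$id))) {
    stop("catalogue contains empty component id(s) at row(s): ",
         paste(which(!nzchar(cat$id)), collapse = ", "), call. = FALSE)
  }
  key <- canon_id(cat$id)
  if (anyDuplicated(key)) {
    dup <- unique(cat$id[duplicated(key)])
    stop("duplicate component id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_ev <- !cat$evidence %in% c("verified", "tentative")
  if (any(bad_ev)) {
    stop("invalid evidence value(s): ",
         paste(unique(cat$evidence[bad_ev]), collapse = ", "),
         " (allowed: verified, tentative)", call. = FALSE)
  }
  bad_kind <- !cat$kind %in% c("component", "isoprotein")
  if (any(bad_kind)) {
    stop("invalid kind value(s): ",
         paste(unique(cat$kind[bad_kind]), collapse = ", "),
         " (allowed: component, isoprotein)", call. = FALSE)
  }
  if (!isTRUE(attr(cat, "allow_extra_labels"))) {
    vocab <- attr(cat, "vocabulary") %||% subsystem_vocabulary()
    for (i in seq_len(nrow(cat))) {
      labs <- split_multi(cat$subsystems[i])
      unknown <- setdiff(labs, vocab)
      if (length(unknown)) {
        stop("unknown subsystem label(s) '",
             paste(unknown, collapse = "', '"), "' for component '",
             cat$id[i], "' (row ", i, ")", call. = FALSE)
      }
    }
  }
  invisible(cat)
}

#' Load a component catalogue from a tab-separated file
#'
#' The catalogue dialect is UTF-8 tab-separated text with a header row, one
#' component per row, and ";"-separated multi-value cells for `subsystems`,
#' `functional_groups` and `complexes`.
#'
#' @param path path to the catalogue TSV.
#' @inheritParams catalogue
#' @param species if non-`NULL`, overrides / fills the species column.
#' @return A `secrepath_catalogue`. The number of parsed rows is reported via
#'   `message()` and stored in the `"n_rows"` attribute.
#' @export
load_catalogue <- function(path, vocabulary = subsystem_vocabulary(),
                           allow_extra_labels = FALSE, species = NULL) {
  df <- read_tsv_strict(path)
  if (!"id" %in% names(df)) {
    stop("catalogue file ", path, " has no 'id' column in its header",
         call. = FALSE)
  }
  if (!is.null(species)) df$species <- species
  out <- catalogue(df, vocabulary = vocabulary,
                   allow_extra_labels = allow_extra_labels)
  attr(out, "n_rows") <- nrow(df)
  message("loaded catalogue: ", nrow(out), " components from ", path)
  out
}

#' Write a catalogue to a tab-separated file
#'
#' @param cat a `secrepath_catalogue`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  validate_catalogue(cat)
  write_tsv(as.data.frame(cat), path)
}

#' Count components per subsystem
#'
#' A component belonging to several subsystems is counted once in each, so the
#' sum over subsystems can exceed the number of components.
#'
#' @param cat a `secrepath_catalogue`.
#' @param vocabulary labels to report (zero counts included); defaults to the
#'   catalogue's vocabulary.
#' @return Named integer vector, one entry per subsystem label.
#' @export
subsystem_counts <- function(cat, vocabulary = NULL) {
  validate_catalogue(cat)
  vocab <- vocabulary %||% attr(cat, "vocabulary") %||% subsystem_vocabulary()
  labs <- unlist(lapply(cat$subsystems, split_multi), use.names = FALSE)
  counts <- table(factor(labs, levels = union(vocab, unique(labs))))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' @export
print.secrepath_catalogue <- function(x, ...) {
  cat("secrepath catalogue: ", nrow(x), " components (",
      sum(x$evidence == "tentative"), " tentative, ",
      sum(x$core), " core, ", sum(x$partial), " partial)\n", sep = "")
  invisible(x)
}

# Memberships of a catalogue as a long table (component id, kind of grouping,
# group label); used when materialising membership edges.
#' @keywords internal
catalogue_memberships <- function(cat) {
  rows <- lapply(seq_len(nrow(cat)), function(i) {
    cx <- split_multi(cat$complexes[i])
    fg <- split_multi(cat$functional_groups[i])
    data.frame(
      component = rep(cat$id[i], length(cx) + length(fg)),
      group_kind = c(rep("complex", length(cx)),
                     rep("functional_group", length(fg))),
      group = c(cx, fg),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(component = character(0),
                                         group_kind = character(0),
                                         group = character(0)))))
}
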