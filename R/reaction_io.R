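#' Recognised reaction-identifier namespaces
#'
#' Reaction identifiers are namespace-qualified strings of the form
#' `"PREFIX:localid"`. Prefixes `KEGG`, `META` (MetaCyc), `MNX` (MetaNetX) and
#' `SEED` (ModelSEED) are recognised; anything else, including unprefixed IDs,
#' is classed as `OTHER`.
#'
#' @format Character vector of recognised prefixes.
#' @export
REACTION_NAMESPACES <- c("KEGG", "META", "MNX", "SEED")

#' Parse the namespace prefix of a reaction identifier
#'
#' @param id Character vector of reaction identifiers.
#' @return Character vector of namespaces (`"KEGG"`, `"META"`, `"MNX"`,
#'   `"SEED"` or `"OTHER"`).
#' @examples
#' reaction_namespace(c("KEGG:R00001", "META:RXN-123", "rxn_custom"))
#' @export
reaction_namespace <- function(id) {
  pre <- sub(":.*$", "", id)
  pre[pre == id] <- "OTHER"        # no ":" present
  pre[!pre %in% REACTION_NAMESPACES] <- "OTHER"
  pre
}

#' Read per-species reaction records
#'
#' Reads a tab-separated reaction table (columns `species`, `reaction_id`,
#' `source_db`, optional `gene_association`) or extracts reaction identifiers
#' from an SBML Level 3 document. SBML reading keeps reaction IDs (and, when
#' present, identifiers.org cross-references in annotations) only; compartments
#' and stoichiometry are discarded because downstream analysis treats a draft
#' model purely as a reaction-ID set.
#'
#' @param path Path to the input file.
#' @param dialect `"tsv"` or `"sbml"`.
#' @param species Species label to use for SBML input; defaults to the SBML
#'   model id (or file name if absent).
#' @return A data frame of reaction records with columns `species`,
#'   `reaction_id`, `source_db`, `gene_association`.
#' @export
load_reaction_table <- function(path, dialect = c("tsv", "sbml"), species = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             quote = "", comment.char = "")
    if (nrow(tab) == 0L) stop("empty reaction table: ", path, call. = FALSE)
    for (col in c("species", "reaction_id", "source_db")) {
      if (!col %in% names(tab)) {
        stop(sprintf("format error: missing mandatory column '%s' in %s",
                     col, path), call. = FALSE)
      }
    }
    if (!"gene_association" %in% names(tab)) tab$gene_association <- NA_character_
    if (any(!nzchar(tab$reaction_id))) {
      stop("format error: empty reaction_id value(s)", call. = FALSE)
    }
    tab <- tab[, c("species", "reaction_id", "source_db", "gene_association")]
    rownames(tab) <- NULL
    return(tab)
  }
  # SBML: pull reaction ids; strip the conventional "R_" SBML prefix
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("unparseable SBML: ", conditionMessage(e), call. = FALSE)
  })
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx) == 0L) {
    stop("unparseable SBML: no <reaction> elements found in ", path,
         call. = FALSE)
  }
  ids <- xml2::xml_attr(rx, "id")
  if (anyNA(ids)) {
    stop("unparseable SBML: <reaction> element without an 'id' attribute",
         call. = FALSE)
  }
  ids <- sub("^R_", "", ids)
  if (is.null(species)) {
    model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
    species <- xml2::xml_attr(model, "id")
    if (is.na(species) || !nzchar(species)) {
      species <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  data.frame(species = species,
             reaction_id = ids,
             source_db = reaction_namespace(ids),
             gene_association = NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a reaction cross-reference table
#'
#' Two-column TSV `(source_id, unified_id)` mapping namespace-qualified
#' reaction IDs onto a unified namespace (typically MetaNetX). The mapping
#' must be many-to-one and terminal: a `unified_id` may only appear as a
#' `source_id` if it maps to itself (identity rows are allowed), so applying
#' the mapping twice changes nothing.
#'
#' @param path Path to the TSV file.
#' @return A named character vector (`names` = source IDs, values = unified
#'   IDs) of class `xref_table`.
#' @export
read_xref <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  for (col in c("source_id", "unified_id")) {
    if (!col %in% names(tab)) {
      stop(sprintf("format error: missing mandatory column '%s' in %s",
                   col, path), call. = FALSE)
    }
  }
  as_xref(stats::setNames(tab$unified_id, tab$source_id))
}

#' Construct a cross-reference table from a named vector
#'
#' @param x Named character vector, names = source IDs, values = unified IDs.
#' @return The validated mapping, class `xref_table`.
#' @export
as_xref <- function(x) {
  if (length(x) == 0L) {
    return(structure(character(0), class = "xref_table"))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("cross-reference entries must be named by source_id", call. = FALSE)
  }
  dup <- names(x)[duplicated(names(x))]
  if (length(dup)) {
    # many-to-one is fine; one-to-many is not
    for (d in unique(dup)) {
      if (length(unique(x[names(x) == d])) > 1L) {
        stop("source_id '", d, "' maps to more than one unified_id",
             call. = FALSE)
      }
    }
    x <- x[!duplicated(names(x))]
  }
  nonid <- x[names(x) != unname(x)]
  bad <- unname(nonid)[unname(nonid) %in% names(nonid)]
  if (length(bad)) {
    stop("cross-reference is not terminal: unified_id(s) ",
         paste(unique(bad), collapse = ", "),
         " appear again as source_id with a different target", call. = FALSE)
  }
  structure(x, class = "xref_table")
}

#' Standardize reaction identifiers for one species
#'
#' Replaces each reaction ID by its unified ID from the cross-reference table
#' when a mapping exists; unmapped IDs are retained verbatim (they are not
#' errors). The result is deduplicated into a set, so two source IDs that
#' collapse onto one unified reaction are merged silently; the original ->
#' unified pairs are kept as a provenance log. The operation is idempotent.
#'
#' @param records Data frame of reaction records for a single species (as from
#'   [load_reaction_table()]), or a character vector of reaction IDs together
#'   with `species`.
#' @param xref Cross-reference table from [read_xref()] / [as_xref()] (may be
#'   empty).
#' @param species Species label, required when `records` is a character vector.
#' @return A `draft_model`: list with `species`, `reactions` (sorted character
#'   set) and `log` (data frame `original`, `unified`).
#' @export
standardize_ids <- function(records, xref = as_xref(character(0)), species = NULL) {
  if (is.data.frame(records)) {
    sp <- unique(records$species)
    if (length(sp) != 1L) {
      stop("records must all share one species label (got ",
           length(sp), ")", call. = FALSE)
    }
    ids <- records$reaction_id
    species <- sp
  } else {
    ids <- as.character(records)
    if (is.null(species)) stop("`species` is required", call. = FALSE)
  }
  if (!inherits(xref, "xref_table")) xref <- as_xref(xref)
  hit <- ids %in% names(xref)
  unified <- ids
  unified[hit] <- unname(xref[ids[hit]])
  structure(
    list(species = species,
         reactions = sort(unique(unified)),
         log = data.frame(original = ids, unified = unified,
                          stringsAsFactors = FALSE)),
    class = "draft_model")
}

#' Standardize a multi-species reaction table into draft models
#'
#' @param records Data frame of reaction records across species.
#' @param xref Cross-reference table.
#' @return Named list of `draft_model` objects, sorted by species label.
#' @export
build_draft_models <- function(records, xref = as_xref(character(0))) {
  sp <- sort(unique(records$species))
  models <- lapply(sp, function(s) {
    standardize_ids(records[records$species == s, , drop = FALSE], xref)
  })
  names(models) <- sp
  models
}

#' @export
print.draft_model <- function(x, ...) {
  cat("Draft model:", x$species, "-", length(x$reactions), "reactions\n")
  invisible(x)
}

#' Assemble the species x reaction occurrence matrix
#'
#' Columns are the union of all reaction sets, in lexicographic order; rows are
#' species in lexicographic order, so the result is invariant to the input
#' order of the models.
#'
#' @param models Named list of `draft_model` objects, or a named list of
#'   character reaction-ID vectors.
#' @return Binary integer matrix (species x reactions).
#' @export
assemble_occurrence <- function(models) {
  if (length(models) == 0L) stop("need at least one model", call. = FALSE)
  sets <- lapply(models, function(m) {
    if (inherits(m, "draft_model")) m$reactions else unique(as.character(m))
  })
  labs <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    if (inherits(m, "draft_model")) m$species else names(models)[i] %||% NA_character_
  }, character(1))
  if (anyNA(labs) || any(!nzchar(labs))) {
    stop("every model must carry a species label", call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate species label: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(labs)
  sets <- sets[ord]
  labs <- labs[ord]
  items <- sort(unique(unlist(sets, use.names = FALSE)))
  occ <- matrix(0L, nrow = length(labs), ncol = length(items),
                dimnames = list(labs, items))
  for (i in seq_along(sets)) occ[i, match(sets[[i]], items)] <- 1L
  occ
}
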