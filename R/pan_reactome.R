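#' Build the pan-reactome from an occurrence matrix
#'
#' The pan-reactome is the union of reactions over all species, with a
#' per-reaction occurrence count (number of species containing it). Reactions
#' present in every species form the strict core; the rest are accessory.
#'
#' @param occ Binary species x reaction occurrence matrix.
#' @return A `pan_reactome` object: list with `reactions` (character, sorted),
#'   `occurrence` (named integer counts), `n_species`, `strict_core` and
#'   `accessory` (character vectors).
#' @export
build_pan_reactome <- function(occ) {
  validate_occurrence(occ)
  counts <- colSums(occ)
  keep <- counts >= 1
  if (!any(keep)) stop("empty pan-reactome: occurrence matrix is all zero",
                       call. = FALSE)
  counts <- as.integer(counts[keep])
  rxn <- colnames(occ)[keep]
  ord <- order(rxn)
  rxn <- rxn[ord]
  counts <- stats::setNames(counts[ord], rxn)
  n <- nrow(occ)
  structure(
    list(reactions = rxn,
         occurrence = counts,
         n_species = n,
         strict_core = rxn[counts == n],
         accessory = rxn[counts < n]),
    class = "pan_reactome")
}

#' @export
print.pan_reactome <- function(x, ...) {
  cat("Pan-reactome over", x$n_species, "species:",
      length(x$reactions), "reactions\n")
  cat("  strict core:", length(x$strict_core),
      " accessory:", length(x$accessory), "\n")
  invisible(x)
}

#' Classify pan-reactome reactions by occurrence
#'
#' Reactions are split into three occurrence categories using two species
#' counts: `NEAR_CORE` when occurrence is strictly above `high`, `RARE` when
#' strictly below `low`, and `INTERMEDIATE` for occurrence in `[low, high]`.
#' The defaults correspond to the 24/316-species thresholds used for a
#' 343-species collection, rescaled proportionally (fractions 24/343 and
#' 316/343) when the matrix holds a different number of species.
#'
#' @param pan A `pan_reactome` object.
#' @param low,high Integer species counts, `1 <= low <= high <= n_species`.
#'   Defaults scale 24 and 316 by `n_species/343`.
#' @return List with `category` (named factor: NEAR_CORE/INTERMEDIATE/RARE),
#'   `counts` and `fractions` per category, and the `low`/`high` thresholds
#'   used.
#' @export
classify_occurrence <- function(pan, low = NULL, high = NULL) {
  stopifnot(inherits(pan, "pan_reactome"))
  n <- pan$n_species
  if (is.null(low)) low <- max(1L, as.integer(round(n * 24 / 343)))
  if (is.null(high)) high <- min(n, as.integer(round(n * 316 / 343)))
  if (low > high) stop("parameter error: low > high", call. = FALSE)
  if (low < 1L || high > n) {
    stop("parameter error: thresholds must lie in [1, n_species]", call. = FALSE)
  }
  occ <- pan$occurrence
  lab <- ifelse(occ > high, "NEAR_CORE", ifelse(occ < low, "RARE", "INTERMEDIATE"))
  category <- factor(lab, levels = c("NEAR_CORE", "INTERMEDIATE", "RARE"))
  names(category) <- names(occ)
  counts <- table(category)
  fractions <- as.numeric(counts) / length(occ)
  names(fractions) <- names(counts)
  list(category = category,
       counts = stats::setNames(as.integer(counts), names(counts)),
       fractions = fractions,
       low = low, high = high)
}

#' Summarize the pan-reactome by subsystem
#'
#' Counts core and accessory reactions (strict-core partition) per subsystem.
#' Reactions without a subsystem assignment are pooled under `"unassigned"`;
#' a reaction mapped to several subsystems counts once in each, so subsystem
#' reaction counts may sum to more than the pan-reactome size.
#'
#' @param pan A `pan_reactome` object.
#' @param subsys_map Data frame with columns `reaction_id` and `subsystem`
#'   (one row per assignment; a reaction may appear in several rows), or a
#'   named list mapping reaction IDs to character vectors of subsystems. May
#'   be partial or empty.
#' @return Data frame (one row per subsystem) with `subsystem`, `n_reactions`,
#'   `n_core`, `n_accessory`, `core_ratio`, `accessory_ratio`; the per-subsystem
#'   occurrence counts are attached as the `"occurrence"` attribute (named list
#'   of integer vectors).
#' @export
subsystem_summary <- function(pan, subsys_map = NULL) {
  stopifnot(inherits(pan, "pan_reactome"))
  if (is.null(subsys_map)) {
    map <- data.frame(reaction_id = character(0), subsystem = character(0))
  } else if (is.data.frame(subsys_map)) {
    stopifnot(all(c("reaction_id", "subsystem") %in% names(subsys_map)))
    map <- subsys_map[, c("reaction_id", "subsystem")]
  } else {
    map <- data.frame(
      reaction_id = rep(names(subsys_map), lengths(subsys_map)),
      subsystem = unlist(subsys_map, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  map <- unique(map[map$reaction_id %in% pan$reactions, , drop = FALSE])
  unmapped <- setdiff(pan$reactions, map$reaction_id)
  if (length(unmapped)) {
    map <- rbind(map, data.frame(reaction_id = unmapped,
                                 subsystem = "unassigned",
                                 stringsAsFactors = FALSE))
  }
  is_core <- map$reaction_id %in% pan$strict_core
  subs <- sort(unique(map$subsystem))
  out <- do.call(rbind, lapply(subs, function(s) {
    sel <- map$subsystem == s
    n_core <- sum(is_core[sel])
    n_all <- sum(sel)
    data.frame(subsystem = s,
               n_reactions = n_all,
               n_core = n_core,
               n_accessory = n_all - n_core,
               core_ratio = n_core / n_all,
               accessory_ratio = (n_all - n_core) / n_all,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  occ_by_sub <- lapply(subs, function(s) {
    unname(pan$occurrence[map$reaction_id[map$subsystem == s]])
  })
  names(occ_by_sub) <- subs
  attr(out, "occurrence") <- occ_by_sub
  out
}
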