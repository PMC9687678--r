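#' Jaccard similarity of two item sets
#'
#' `|a n b| / |a u b|`. Duplicated elements are ignored (set semantics). Both
#' sets empty is an error: the similarity is undefined and the caller decides
#' how to treat the pair.
#'
#' @param a,b Vectors interpreted as sets.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' jaccard(c("A", "B", "C"), c("B", "C", "D"))   # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    stop("undefined similarity: both sets are empty", call. = FALSE)
  }
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity matrix over species
#'
#' Computes the Jaccard similarity for every unordered species pair. The same
#' formula serves three analysis layers: `"model"` (reaction sets from draft
#' metabolic models), `"genotype"` (ortholog-family sets) and `"trait"`
#' (growth-substrate sets); the layer is carried as metadata only. Species
#' with an empty item set get `NA` against every species (including
#' themselves) and are reported in the `"empty_species"` attribute.
#'
#' @param x Named list of item-set vectors (one per species), or a binary
#'   species x item occurrence matrix.
#' @param layer One of `"model"`, `"genotype"`, `"trait"`.
#' @return Symmetric numeric matrix with unit diagonal (where defined), layer
#'   recorded in the `"layer"` attribute.
#' @export
similarity_matrix <- function(x, layer = c("model", "genotype", "trait")) {
  layer <- match.arg(layer)
  if (!is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop("`x` must be a named list with unique species names", call. = FALSE)
    }
    if (length(x) < 2L) stop("need at least 2 species", call. = FALSE)
    items <- sort(unique(unlist(lapply(x, unique), use.names = FALSE)))
    occ <- matrix(0L, length(x), max(length(items), 1L),
                  dimnames = list(names(x),
                                  if (length(items)) items else "..empty.."))
    for (i in seq_along(x)) occ[i, match(unique(x[[i]]), items)] <- 1L
  } else {
    validate_occurrence(x)
    if (nrow(x) < 2L) stop("need at least 2 species", call. = FALSE)
    occ <- x
  }
  storage.mode(occ) <- "double"
  inter <- occ %*% t(occ)
  sz <- rowSums(occ)
  un <- outer(sz, sz, "+") - inter
  S <- ifelse(un > 0, inter / un, NA_real_)
  empty <- sz == 0
  S[empty, ] <- NA_real_
  S[, empty] <- NA_real_
  idx <- which(!empty)
  S[cbind(idx, idx)] <- 1
  dimnames(S) <- list(rownames(occ), rownames(occ))
  attr(S, "layer") <- layer
  attr(S, "empty_species") <- rownames(occ)[empty]
  S
}

#' Trait similarity from a ternary growth matrix
#'
#' For each species pair the comparison is restricted to substrates scored in
#' both species (pairwise-complete). Within that restriction the Jaccard
#' similarity of the two growth-positive substrate sets is taken, so shared
#' inability to grow does not inflate similarity. The pair is `NA` when the
#' restriction is empty or when neither species grows on any shared-scored
#' substrate (undefined Jaccard).
#'
#' @param traits Species x substrate matrix with values `1` (growth), `0`
#'   (no growth) and `NA` (missing).
#' @return Symmetric similarity matrix with `"layer"` attribute `"trait"`.
#' @export
trait_similarity <- function(traits) {
  validate_occurrence(traits, allow_missing = TRUE, arg = "traits")
  if (ncol(traits) < 1L) stop("need at least one substrate", call. = FALSE)
  n <- nrow(traits)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(traits), rownames(traits)))
  for (i in seq_len(n)) {
    ti <- traits[i, ]
    for (j in i:n) {
      tj <- traits[j, ]
      ok <- !is.na(ti) & !is.na(tj)
      if (!any(ok)) next
      gi <- ok & ti == 1
      gj <- ok & tj == 1
      u <- sum(gi | gj)
      if (u == 0L) next
      S[i, j] <- S[j, i] <- sum(gi & gj) / u
    }
  }
  attr(S, "layer") <- "trait"
  S
}

#' Recode a raw growth-trait table
#'
#' Upstream physiology tables score growth as growth / no-growth / variable.
#' The default recodes variable calls to missing (conservative: capability is
#' not asserted); set `variable_as_growth = TRUE` to count them as growth.
#'
#' @param raw Character (or factor) species x substrate matrix with values in
#'   `{"1", "0", "v", NA}` (case-insensitive `"v"`).
#' @param variable_as_growth Recode `"v"` as growth instead of missing.
#' @return Numeric species x substrate matrix with values `1`, `0`, `NA`.
#' @export
recode_traits <- function(raw, variable_as_growth = FALSE) {
  stopifnot(is.matrix(raw))
  v <- tolower(trimws(as.character(raw)))
  out <- rep(NA_real_, length(v))
  out[v == "1"] <- 1
  out[v == "0"] <- 0
  out[v == "v"] <- if (variable_as_growth) 1 else NA_real_
  bad <- !v %in% c("1", "0", "v", NA) & !is.na(v) & nzchar(v)
  if (any(bad)) {
    stop("unrecognised trait value(s): ",
         paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  }
  matrix(out, nrow(raw), ncol(raw), dimnames = dimnames(raw))
}
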