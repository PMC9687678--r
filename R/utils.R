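# internal validators shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# An occurrence matrix is species x items, dimnames mandatory and unique,
# values in {0, 1} (traits additionally allow NA for MISSING).
validate_occurrence <- function(occ, allow_missing = FALSE, arg = "occ") {
  if (!is.matrix(occ)) {
    stop(sprintf("`%s` must be a matrix (species x items)", arg), call. = FALSE)
  }
  if (is.null(rownames(occ)) || is.null(colnames(occ))) {
    stop(sprintf("`%s` must have species row names and item column names", arg),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(occ))) {
    stop(sprintf("duplicate species labels in `%s`", arg), call. = FALSE)
  }
  if (anyDuplicated(colnames(occ))) {
    stop(sprintf("duplicate item labels in `%s`", arg), call. = FALSE)
  }
  v <- occ[!is.na(occ)]
  if (!allow_missing && anyNA(occ)) {
    stop(sprintf("`%s` must not contain missing values", arg), call. = FALSE)
  }
  if (length(v) && !all(v %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (values 0/1)", arg), call. = FALSE)
  }
  invisible(occ)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("expected a `phylo` tree", call. = FALSE)
  }
  if (length(tree$tip.label) < 2L) {
    stop("tree must have at least 2 leaves", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    stop("every edge must carry a branch length", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("missing branch length on ", sum(is.na(tree$edge.length)), " edge(s)",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  invisible(tree)
}
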