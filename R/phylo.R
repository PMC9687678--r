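#' Parse a newick species tree
#'
#' Reads a newick string (or a file containing one) into an `ape` `phylo`
#' object and validates it for downstream distance computation: at least two
#' leaves, unique leaf labels, and a non-negative branch length on every edge
#' (missing lengths are rejected). Polytomies are accepted; a root edge, if
#' present, is ignored by the distance computation since it lies on no
#' leaf-to-leaf path.
#'
#' @param x Newick text, or the path of a file holding one tree.
#' @return A validated `phylo` tree.
#' @export
parse_newick <- function(x) {
  is_path <- length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x)
  tr <- tryCatch(
    suppressWarnings(
      if (is_path) ape::read.tree(x) else ape::read.tree(text = x)
    ),
    error = function(e) NULL)
  if (is.null(tr)) stop("newick parse error in: ", substr(paste(x, collapse = ""), 1, 80),
                        call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr)
  tr
}

#' Cophenetic (patristic) distances between all leaf pairs
#'
#' The distance between two leaves is the sum of branch lengths along the
#' unique path connecting them. Computed by a single post-order traversal:
#' leaf depths (root-to-leaf path lengths) are accumulated, and at each
#' internal node every pair of leaves drawn from two different child subtrees
#' gets `d(i, j) = depth(i) + depth(j) - 2 * depth(node)`.
#'
#' @param tree A `phylo` tree with branch lengths (see [parse_newick()]).
#' @return Symmetric numeric matrix over leaf labels, zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  E <- po$edge
  L <- po$edge.length
  nn <- n + po$Nnode
  depth <- numeric(nn)
  for (e in rev(seq_len(nrow(E)))) {      # parents before children
    depth[E[e, 2L]] <- depth[E[e, 1L]] + L[e]
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  leafset <- vector("list", nn)
  for (i in seq_len(n)) leafset[[i]] <- i
  for (e in seq_len(nrow(E))) {           # children complete before parents
    p <- E[e, 1L]
    s <- leafset[[E[e, 2L]]]
    u <- leafset[[p]]
    if (is.null(u)) {
      leafset[[p]] <- s
    } else {
      d <- outer(depth[u], depth[s], "+") - 2 * depth[p]
      D[u, s] <- d
      D[s, u] <- t(d)
      leafset[[p]] <- c(u, s)
    }
  }
  D
}
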