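# Independent oracles used across test files. These deliberately use
# different algorithms (or different libraries) from the implementation.

# Jaccard by explicit membership counting over a fixed universe.
brute_jaccard <- function(a, b, universe) {
  inter <- 0L
  uni <- 0L
  for (u in universe) {
    ina <- u %in% a
    inb <- u %in% b
    if (ina && inb) inter <- inter + 1L
    if (ina || inb) uni <- uni + 1L
  }
  inter / uni
}

# Leaf-pair distances by explicit root-path enumeration and LCA lookup.
lca_path_distances <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- n + 1L
  path_up <- function(i) {
    nodes <- i
    dists <- 0
    while (nodes[length(nodes)] != root) {
      nxt <- parent[nodes[length(nodes)]]
      dists <- c(dists, dists[length(dists)] + elen[nodes[length(nodes)]])
      nodes <- c(nodes, nxt)
    }
    stats::setNames(dists, nodes)
  }
  paths <- lapply(seq_len(n), path_up)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pi_ <- paths[[i]]
      pj <- paths[[j]]
      shared <- intersect(names(pi_), names(pj))
      lca <- shared[which.min(pi_[shared])]
      D[i, j] <- pi_[lca] + pj[lca]
    }
  }
  D
}

# Expected pan/core counts at sample size N by enumeration of all species
# subsets of that size.
subset_rarefaction_oracle <- function(occ, N) {
  combos <- utils::combn(nrow(occ), N)
  pan <- apply(combos, 2, function(ix) sum(colSums(occ[ix, , drop = FALSE]) > 0))
  core <- apply(combos, 2, function(ix) sum(colSums(occ[ix, , drop = FALSE]) == N))
  list(mean_pan = mean(pan), mean_core = mean(core))
}

# Exact two-sided rank-sum p for tie-free samples via the Wilcoxon
# distribution shipped with R (independent of the package's enumeration).
pwilcox_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(stats::pwilcox(U, nx, ny),
                 1 - stats::pwilcox(U - 1, nx, ny)))
}

# Random item sets over a fixed universe.
random_set <- function(universe, max_size = length(universe)) {
  k <- sample(0:max_size, 1)
  if (k == 0) character(0) else sample(universe, k)
}

# Occurrence matrix where column j has a prescribed occurrence count.
occ_with_counts <- function(counts, n_species) {
  m <- matrix(0L, n_species, length(counts),
              dimnames = list(sprintf("s%03d", seq_len(n_species)),
                              sprintf("r%02d", seq_along(counts))))
  for (j in seq_along(counts)) m[seq_len(counts[j]), j] <- 1L
  m
}
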