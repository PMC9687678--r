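#' Align similarity/distance layers on common species pairs
#'
#' Restricts every matrix to the species present in all of them, extracts the
#' upper triangle (unordered pairs, `i < j` in label order) and drops any pair
#' missing (`NA`) in at least one layer. The number of dropped pairs is kept
#' as an attribute.
#'
#' @param matrices Named list of square symmetric matrices (similarity or
#'   distance) with species dimnames.
#' @return Data frame with `species_a`, `species_b` and one value column per
#'   layer; attributes `n_dropped` (pairs removed for missingness) and
#'   `common_species`.
#' @export
align_layers <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    stop("`matrices` must be a named list", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) < 2L) {
    stop("fewer than 2 species shared across layers", call. = FALSE)
  }
  common <- sort(common)
  ut <- which(upper.tri(diag(length(common))), arr.ind = TRUE)
  out <- data.frame(species_a = common[ut[, 1L]],
                    species_b = common[ut[, 2L]],
                    stringsAsFactors = FALSE)
  for (nm in names(matrices)) {
    M <- matrices[[nm]][common, common]
    out[[nm]] <- M[ut]
  }
  keep <- stats::complete.cases(out)
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  attr(out, "common_species") <- common
  out
}

#' Pearson correlation with a t-test p-value
#'
#' Sample Pearson correlation; the two-sided p-value comes from the usual
#' t transform with `n - 2` degrees of freedom (via [stats::cor.test()]).
#' Because the inputs here are typically pairwise similarity values, the pairs
#' are not independent; `n_pairs` is reported so readers can judge, and a
#' Mantel-style permutation test is available separately if desired.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Computes the Mann-Whitney `U` statistic for `x` (rank sum of `x` minus its
#' minimum) using midranks for ties. The two-sided p-value is exact -- obtained
#' by enumerating all `choose(nx + ny, nx)` allocations of the pooled ranks --
#' whenever that count is at most `1e5`; enumeration with midranks handles
#' ties exactly. Larger samples use the normal approximation with the tie
#' correction and a continuity correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return List with `statistic` (U for `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n_comb <- choose(nx + ny, nx)
  if (n_comb <= 1e5) {
    idx <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= U + eps), mean(u_all >= U - eps)))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    nt <- table(r)
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    z <- U - mu
    z <- z - sign(z) * 0.5                     # continuity correction
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = U, p = p, method = method)
}

#' Within- versus between-clade similarity comparison
#'
#' For every clade with at least two analysed members, collects similarity
#' values over pairs with both species in the clade (within) and pairs with
#' exactly one species in the clade (between), and compares the two sets by
#' the two-tailed Wilcoxon rank-sum test. Clades with fewer than two members,
#' or with an empty within/between set after `NA` removal, are reported with a
#' diagnostic note and no test.
#'
#' @param S Symmetric similarity matrix over species.
#' @param clades Named character vector mapping species to clade labels.
#' @return Data frame, one row per clade: `clade`, `n_members`, `n_within`,
#'   `n_between`, `median_within`, `median_between`, `statistic`, `p`, `note`.
#' @export
clade_similarity_comparison <- function(S, clades) {
  stopifnot(is.matrix(S), !is.null(rownames(S)))
  if (is.null(names(clades))) stop("`clades` must be named by species", call. = FALSE)
  sp <- intersect(rownames(S), names(clades))
  if (length(sp) < 2L) stop("fewer than 2 species with clade assignments",
                            call. = FALSE)
  sp <- sort(sp)
  M <- S[sp, sp]
  cl <- clades[sp]
  ut <- which(upper.tri(M), arr.ind = TRUE)
  vals <- M[ut]
  ca <- cl[ut[, 1L]]
  cb <- cl[ut[, 2L]]
  res <- lapply(sort(unique(cl)), function(g) {
    members <- sum(cl == g)
    row <- data.frame(clade = g, n_members = members,
                      n_within = NA_integer_, n_between = NA_integer_,
                      median_within = NA_real_, median_between = NA_real_,
                      statistic = NA_real_, p = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    if (members < 2L) {
      row$note <- "skipped: fewer than 2 members"
      return(row)
    }
    w <- vals[ca == g & cb == g]
    b <- vals[xor(ca == g, cb == g)]
    w <- w[!is.na(w)]
    b <- b[!is.na(b)]
    row$n_within <- length(w)
    row$n_between <- length(b)
    row$median_within <- if (length(w)) stats::median(w) else NA_real_
    row$median_between <- if (length(b)) stats::median(b) else NA_real_
    if (length(w) == 0L || length(b) == 0L) {
      row$note <- "skipped: empty within or between set"
      return(row)
    }
    wt <- wilcoxon_rank_sum(w, b)
    row$statistic <- wt$statistic
    row$p <- wt$p
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-clade correlation between two similarity layers
#'
#' Pearson correlation of the two layers over within-clade species pairs only.
#' Clades with fewer than 3 usable pairs (after dropping pairs missing in
#' either layer), or with zero variance in a layer, are reported as `NA` with
#' the reason.
#'
#' @param model_S,trait_S Symmetric similarity matrices over species.
#' @param clades Named character vector mapping species to clade labels.
#' @param min_pairs Minimum usable pair count (default 3).
#' @return Data frame: `clade`, `r`, `p`, `n_pairs`, `note`.
#' @export
per_clade_correlation <- function(model_S, trait_S, clades, min_pairs = 3L) {
  if (is.null(names(clades))) stop("`clades` must be named by species", call. = FALSE)
  sp <- Reduce(intersect, list(rownames(model_S), rownames(trait_S), names(clades)))
  if (length(sp) < 2L) stop("fewer than 2 species shared across inputs",
                            call. = FALSE)
  sp <- sort(sp)
  cl <- clades[sp]
  res <- lapply(sort(unique(cl)), function(g) {
    row <- data.frame(clade = g, r = NA_real_, p = NA_real_,
                      n_pairs = 0L, note = "", stringsAsFactors = FALSE)
    memb <- sp[cl == g]
    if (length(memb) < 2L) {
      row$note <- "skipped: fewer than 2 members"
      return(row)
    }
    pv <- align_layers(list(model = model_S[memb, memb, drop = FALSE],
                            trait = trait_S[memb, memb, drop = FALSE]))
    row$n_pairs <- nrow(pv)
    if (nrow(pv) < min_pairs) {
      row$note <- "too few pairs"
      return(row)
    }
    if (stats::sd(pv$model) == 0 || stats::sd(pv$trait) == 0) {
      row$note <- "zero variance"
      return(row)
    }
    pc <- pearson_cor(pv$model, pv$trait)
    row$r <- pc$r
    row$p <- pc$p
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Confusion counts and accuracy of a reconstructed reaction set
#'
#' Compares a predicted reaction set against a reference within a fixed
#' reaction universe: `TP = |pred n ref|`, `FP = |pred \\ ref|`,
#' `FN = |ref \\ pred|`, `TN = |universe \\ (pred u ref)|`, and
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param predicted,reference Reaction-ID vectors, both subsets of `universe`.
#' @param universe Non-empty reaction-ID vector defining the comparison space.
#' @return List with `TP`, `TN`, `FP`, `FN`, `accuracy`.
#' @export
evaluate_reconstruction <- function(predicted, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty reaction universe", call. = FALSE)
  predicted <- unique(predicted)
  reference <- unique(reference)
  if (!all(predicted %in% universe)) {
    stop("predicted set is not a subset of the universe", call. = FALSE)
  }
  if (!all(reference %in% universe)) {
    stop("reference set is not a subset of the universe", call. = FALSE)
  }
  tp <- length(intersect(predicted, reference))
  fp <- length(setdiff(predicted, reference))
  fn <- length(setdiff(reference, predicted))
  tn <- length(universe) - tp - fp - fn
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       accuracy = (tp + tn) / length(universe))
}

#' Mantel-style permutation p-value for two pairwise-value layers
#'
#' Diagnostic companion to [pearson_cor()] for pairwise similarity/distance
#' data: permutes species labels of the second matrix and recomputes the
#' correlation of the aligned upper triangles.
#'
#' @param A,B Square symmetric matrices over the same species.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `r` (observed), `p` (permutation, two-sided), `n_perm`.
#' @export
mantel_permutation <- function(A, B, n_perm = 999L, seed = 1L) {
  common <- sort(intersect(rownames(A), rownames(B)))
  if (length(common) < 3L) stop("need at least 3 common species", call. = FALSE)
  A <- A[common, common]
  B <- B[common, common]
  ut <- upper.tri(A)
  ok <- !is.na(A[ut]) & !is.na(B[ut])
  r_obs <- stats::cor(A[ut][ok], B[ut][ok])
  set.seed(seed)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    pm <- sample(length(common))
    Bp <- B[pm, pm]
    okp <- !is.na(A[ut]) & !is.na(Bp[ut])
    rp <- stats::cor(A[ut][okp], Bp[ut][okp])
    if (abs(rp) >= abs(r_obs)) cnt <- cnt + 1L
  }
  list(r = r_obs, p = (cnt + 1) / (n_perm + 1), n_perm = n_perm)
}
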