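sym_matrix <- function(labels, values) {
  n <- length(labels)
  M <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  M[upper.tri(M)] <- values
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  M
}

test_that("layer alignment extracts common upper-triangle pairs and logs drops", {
  A <- sym_matrix(c("a", "b", "c"), c(0.1, 0.2, 0.3))
  B <- sym_matrix(c("a", "b", "c"), c(0.5, 0.6, 0.7))
  pv <- align_layers(list(x = A, y = B))
  expect_equal(nrow(pv), 3L)
  expect_equal(attr(pv, "n_dropped"), 0L)
  expect_equal(pv$x[pv$species_a == "a" & pv$species_b == "b"], 0.1)

  B2 <- B
  B2["a", "c"] <- B2["c", "a"] <- NA
  pv2 <- align_layers(list(x = A, y = B2))
  expect_equal(nrow(pv2), 2L)
  expect_equal(attr(pv2, "n_dropped"), 1L)

  C <- sym_matrix(c("q", "r"), 0.4)
  expect_error(align_layers(list(x = A, y = C)), "fewer than 2")
  # extra species are restricted to the common set
  D <- sym_matrix(c("a", "b", "c", "d"), runif(6))
  pv3 <- align_layers(list(x = A, y = D))
  expect_equal(attr(pv3, "common_species"), c("a", "b", "c"))
})

test_that("pearson correlation matches hand computation and the t transform", {
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_cor(1:5, -(1:5))$r, -1)
  res <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$p, stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))$p.value)
  expect_error(pearson_cor(rep(1, 4), 1:4), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")

  set.seed(8)
  x <- rnorm(20)
  y <- rnorm(20)
  expect_equal(pearson_cor(x, y)$r, pearson_cor(y, x)$r)
  expect_equal(pearson_cor(2 * x + 3, y)$r, pearson_cor(x, y)$r)
  expect_equal(pearson_cor(-x, y)$r, -pearson_cor(x, y)$r)
})

test_that("rank-sum worked examples and symmetry identities hold", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p, 1 / 3)
  expect_equal(w$method, "exact")
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 1, 9), c(5, 1, 9))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum p agrees with the R Wilcoxon distribution (no ties)", {
  set.seed(15)
  for (rep in 1:50) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    v <- sample(1:100, nx + ny)   # distinct values
    x <- v[seq_len(nx)]
    y <- v[-seq_len(nx)]
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p, pwilcox_oracle(x, y), tolerance = 1e-12)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum uses the tie-corrected normal approximation", {
  set.seed(16)
  x <- round(rnorm(60), 1)   # rounding induces ties
  y <- round(rnorm(60, 0.4), 1)
  mine <- wilcoxon_rank_sum(x, y)
  expect_equal(mine$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$statistic, unname(ref$statistic))
})

test_that("within/between clade comparison builds the right pair sets", {
  labels <- c("a1", "a2", "b1", "b2")
  M <- matrix(0.1, 4, 4, dimnames = list(labels, labels))
  M[1, 2] <- M[2, 1] <- 0.9
  M[3, 4] <- M[4, 3] <- 0.9
  diag(M) <- 1
  clades <- stats::setNames(c("A", "A", "B", "B"), labels)
  res <- clade_similarity_comparison(M, clades)
  expect_equal(res$n_within, c(1L, 1L))
  expect_equal(res$n_between, c(4L, 4L))
  expect_equal(res$median_within, c(0.9, 0.9))
  expect_equal(res$median_between, c(0.1, 0.1))
  # the rank-sum statistic sits at its extreme: all within > all between
  expect_equal(res$statistic, res$n_within * res$n_between)

  one <- clade_similarity_comparison(M, stats::setNames(rep("A", 4), labels))
  expect_match(one$note, "empty within or between")
  expect_true(is.na(one$p))

  singleton <- clade_similarity_comparison(
    M, stats::setNames(c("A", "A", "A", "B"), labels))
  expect_match(singleton$note[singleton$clade == "B"], "fewer than 2")
})

test_that("per-clade correlations reduce to pearson on within-clade pairs", {
  set.seed(23)
  labels <- sprintf("s%d", 1:6)
  vals <- runif(15)
  M <- sym_matrix(labels, vals)
  Tm <- sym_matrix(labels, 0.2 + 0.5 * vals)   # deterministic function
  clades <- stats::setNames(rep("A", 6), labels)
  res <- per_clade_correlation(M, Tm, clades)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$n_pairs, 15L)

  pv <- align_layers(list(model = M, trait = Tm))
  expect_equal(res$p, pearson_cor(pv$model, pv$trait)$p)

  flat <- sym_matrix(labels, rep(0.5, 15))
  res2 <- per_clade_correlation(M, flat, clades)
  expect_true(is.na(res2$r))
  expect_equal(res2$note, "zero variance")

  tiny <- stats::setNames(c("A", "A", rep("B", 4)), labels)
  res3 <- per_clade_correlation(M, Tm, tiny)
  expect_equal(res3$note[res3$clade == "A"], "too few pairs")
})

test_that("reconstruction accuracy follows the confusion identities", {
  uni <- sprintf("r%02d", 1:20)
  ref <- uni[1:13]
  pred <- c(uni[1:8], uni[14:15])
  res <- evaluate_reconstruction(pred, ref, uni)
  expect_equal(res[c("TP", "FP", "FN", "TN")],
               list(TP = 8L, FP = 2L, FN = 5L, TN = 5L))
  expect_equal(res$accuracy, 0.65)
  expect_equal(res$TP + res$TN + res$FP + res$FN, length(uni))

  expect_equal(evaluate_reconstruction(ref, ref, uni)$accuracy, 1)
  comp <- evaluate_reconstruction(setdiff(uni, ref), ref, uni)
  expect_equal(comp$accuracy, 0)
  expect_equal(comp$TP, 0L)
  expect_equal(comp$TN, 0L)

  expect_error(evaluate_reconstruction("zz", ref, uni), "subset")
  expect_error(evaluate_reconstruction(ref, ref, character(0)), "empty")
})

test_that("mantel permutation diagnostic matches the plain correlation", {
  set.seed(3)
  labels <- sprintf("s%d", 1:10)
  base <- runif(45)
  A <- sym_matrix(labels, base)
  B <- sym_matrix(labels, base + rnorm(45, 0, 0.05))
  res <- mantel_permutation(A, B, n_perm = 99L, seed = 5L)
  pv <- align_layers(list(a = A, b = B))
  expect_equal(res$r, pearson_cor(pv$a, pv$b)$r, tolerance = 1e-12)
  expect_lte(res$p, 0.05)   # strong association, permutations rarely beat it
})
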