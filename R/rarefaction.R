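#' Rarefaction of the pan-reactome over random species samples
#'
#' Draws `n_perm` uniform random species orderings (without replacement) and,
#' along each ordering, counts pan, core and accessory reactions on the first
#' `N` species for every requested sample size (nested design: the sample of
#' size `N + 1` extends the sample of size `N`). With `exhaustive = TRUE` all
#' `n!` orderings are enumerated instead (small collections only), which makes
#' permutation means exact expectations over uniform species subsets.
#'
#' @param occ Binary species x reaction occurrence matrix.
#' @param sizes Integer vector of sample sizes `N`; defaults to `1:n_species`.
#' @param n_perm Number of random orderings (ignored when `exhaustive`).
#' @param seed Integer seed; mandatory for random sampling.
#' @param exhaustive Enumerate all orderings (requires `n_species <= 8`).
#' @return A `rarefaction_curve` data frame with columns `N`, `perm`, `pan`,
#'   `core`, `accessory`, and attributes `n_species`, `n_perm`, `seed`.
#' @export
rarefy <- function(occ, sizes = NULL, n_perm = 100L, seed = NULL,
                   exhaustive = FALSE) {
  validate_occurrence(occ)
  n <- nrow(occ)
  m <- ncol(occ)
  if (is.null(sizes)) sizes <- seq_len(n)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L) || any(sizes > n)) {
    stop("parameter error: sizes must lie in [1, n_species]", call. = FALSE)
  }
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to 8 species", call. = FALSE)
    orderings <- all_permutations(n)
  } else {
    if (is.null(seed)) stop("`seed` is required for random rarefaction",
                            call. = FALSE)
    if (n_perm < 1L) stop("parameter error: n_perm must be >= 1", call. = FALSE)
    set.seed(seed)
    orderings <- replicate(n_perm, sample.int(n), simplify = FALSE)
  }
  storage.mode(occ) <- "integer"
  res <- vector("list", length(orderings))
  for (p in seq_along(orderings)) {
    ord <- orderings[[p]]
    Pt <- t(occ[ord, , drop = FALSE])          # items x species
    ones <- rowSums(Pt)
    firstone <- rep.int(n + 1L, m)
    hasone <- ones > 0L
    if (any(hasone)) {
      firstone[hasone] <- max.col(Pt[hasone, , drop = FALSE],
                                  ties.method = "first")
    }
    firstzero <- rep.int(n + 1L, m)            # n+1 == "never loses presence"
    haszero <- ones < n
    if (any(haszero)) {
      firstzero[haszero] <- max.col(1L - Pt[haszero, , drop = FALSE],
                                    ties.method = "first")
    }
    cum_gain <- cumsum(tabulate(firstone, nbins = n))
    cum_loss <- cumsum(tabulate(firstzero, nbins = n))
    pan <- cum_gain[sizes]
    core <- m - cum_loss[sizes]
    res[[p]] <- data.frame(N = sizes, perm = p, pan = pan, core = core,
                           accessory = pan - core)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out,
            class = c("rarefaction_curve", "data.frame"),
            n_species = n,
            n_perm = length(orderings),
            seed = if (exhaustive) NA_integer_ else seed)
}

# all permutations of 1..n as a list (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in sub) {
      out[[k]] <- c(i, rest[s])
      k <- k + 1L
    }
  }
  out
}

#' Fit Heaps' law to a rarefaction curve
#'
#' Fits the power law `n = k * N^gamma` to the aggregated pan counts by
#' nonlinear least squares (Levenberg-Marquardt), initialized from an ordinary
#' least-squares fit of `log(n)` on `log(N)`. The pan-reactome is called
#' `CLOSED` when the fitted exponent `gamma < 1`, `OPEN` otherwise. Note this
#' follows the operative rule used for reactome data; the classical pan-genome
#' convention of Tettelin and colleagues instead calls a pan-genome open for
#' any `0 < gamma < 1` under this parameterisation of Heaps' law.
#'
#' An optional bootstrap over permutations (resampling whole orderings with
#' replacement, then re-aggregating and refitting) gives a percentile
#' confidence interval for `gamma` as a diagnostic.
#'
#' @param curve A `rarefaction_curve`, or any data frame with columns `N` and
#'   `pan` (and optionally `perm`).
#' @param aggregate How to aggregate pan counts per `N` before fitting:
#'   `"mean"` (default) or `"median"`.
#' @param n_boot Bootstrap replicates for the `gamma` confidence interval
#'   (0 disables; only available when the curve holds > 1 permutation).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `heaps_fit`: list with `k`, `gamma`, `rss`, `r2`,
#'   `classification` (`"CLOSED"`/`"OPEN"`), `ci_gamma` (length-2 numeric or
#'   `NULL`), `aggregate`, `n_points`.
#' @export
fit_heaps <- function(curve, aggregate = c("mean", "median"), n_boot = 200L,
                      boot_seed = 1L) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(curve), all(c("N", "pan") %in% names(curve)))
  aggfun <- if (aggregate == "mean") mean else stats::median
  fit_one <- function(df) {
    Ns <- sort(unique(df$N))
    y <- vapply(Ns, function(nn) aggfun(df$pan[df$N == nn]), numeric(1))
    if (length(Ns) < 3L) stop("need >= 3 distinct N values to fit Heaps' law",
                              call. = FALSE)
    if (any(y <= 0)) stop("non-positive aggregated pan counts", call. = FALSE)
    ols <- stats::lm(log(y) ~ log(Ns))
    start <- list(k = exp(unname(stats::coef(ols)[1])),
                  gamma = unname(stats::coef(ols)[2]))
    dat <- data.frame(N = Ns, y = y)
    co <- tryCatch({
      nl <- minpack.lm::nlsLM(y ~ k * N^gamma, data = dat, start = start,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      stats::coef(nl)
    }, error = function(e) {
      # an exact log-log fit (zero residual) is already the NLS optimum;
      # keep the OLS solution when the refinement step cannot proceed
      c(k = start$k, gamma = start$gamma)
    })
    pred <- co[["k"]] * Ns^co[["gamma"]]
    list(k = co[["k"]], gamma = co[["gamma"]],
         rss = sum((y - pred)^2),
         tss = sum((y - mean(y))^2))
  }
  f <- fit_one(curve)
  r2 <- if (f$tss > 0) 1 - f$rss / f$tss else if (f$rss <= 1e-12) 1 else NA_real_
  ci <- NULL
  if (n_boot > 0L && "perm" %in% names(curve)) {
    perms <- unique(curve$perm)
    if (length(perms) > 1L) {
      set.seed(boot_seed)
      gb <- vapply(seq_len(n_boot), function(b) {
        pick <- sample(perms, length(perms), replace = TRUE)
        df <- do.call(rbind, lapply(pick, function(p) {
          curve[curve$perm == p, c("N", "pan")]
        }))
        tryCatch(fit_one(df)$gamma, error = function(e) NA_real_)
      }, numeric(1))
      ci <- unname(stats::quantile(gb, c(0.025, 0.975), na.rm = TRUE))
    }
  }
  structure(
    list(k = f$k, gamma = f$gamma, rss = f$rss, r2 = r2,
         classification = if (f$gamma < 1) "CLOSED" else "OPEN",
         ci_gamma = ci, aggregate = aggregate,
         n_points = length(unique(curve$N))),
    class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps' law fit: n = %.4g * N^%.4g  [%s]\n",
              x$k, x$gamma, x$classification))
  if (!is.null(x$ci_gamma)) {
    cat(sprintf("  gamma 95%% bootstrap CI: [%.4g, %.4g]\n",
                x$ci_gamma[1], x$ci_gamma[2]))
  }
  cat(sprintf("  RSS = %.4g, R2 = %.4g over %d sizes (%s-aggregated)\n",
              x$rss, x$r2, x$n_points, x$aggregate))
  invisible(x)
}
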