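## Permutation-based differential expression in the style of
## Significance Analysis of Microarrays: a moderated t-like statistic
## d = (mean2 - mean1) / (s + s0) with an exchangeability constant s0
## chosen by the percentile search of Tusher et al., and a
## label-permutation estimate of the false discovery rate.

## per-gene mean difference and pooled standard error for one or many
## balanced label splits; `membership` is an n x B 0/1 matrix marking
## group-1 samples per split
sam_components <- function(x, membership) {
  n <- ncol(x)
  n1 <- colSums(membership)
  n2 <- n - n1
  sum1 <- x %*% membership
  sumsq1 <- (x * x) %*% membership
  tot <- rowSums(x)
  totsq <- rowSums(x * x)
  m1 <- sweep(sum1, 2L, n1, "/")
  m2 <- sweep(tot - sum1, 2L, n2, "/")
  ss1 <- sumsq1 - sweep(sum1 * sum1, 2L, n1, "/")
  ss2 <- (totsq - sumsq1) - sweep((tot - sum1)^2, 2L, n2, "/")
  pooled <- sweep(pmax(ss1 + ss2, 0), 2L, n - 2, "/")
  s <- sqrt(sweep(pooled, 2L, 1 / n1 + 1 / n2, "*"))
  list(r = m2 - m1, s = s)
}

#' SAM moderated d statistic
#'
#' `d_i = (mean_2 - mean_1) / (s_i + s0)` with `s_i` the pooled
#' (equal-variance) standard error of the difference. When `s0` is not
#' supplied it is chosen as the percentile of the `s_i` minimizing the
#' coefficient of variation of the d spread across s-quantile windows
#' (Tusher-style search); with fewer than 100 genes the median of the
#' `s_i` is used instead. Genes with zero variance in both groups and
#' zero mean difference get `d = 0`.
#'
#' @param x expression matrix (genes x samples), assumed log scale.
#' @param labels group label per column; exactly two levels, each with
#'   at least two samples. The first level (factor order, or order of
#'   appearance) is group 1; positive d means higher in group 2.
#' @param s0 optional fixed exchangeability constant.
#' @return Named numeric vector of d values, with attributes `s0`,
#'   `s` (the per-gene standard errors) and `r` (mean differences).
#' @export
sam_statistic <- function(x, labels, s0 = NULL) {
  x <- as.matrix(x)
  labels <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  stopifnot(ncol(x) == length(labels))
  if (nlevels(labels) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  membership <- matrix(as.numeric(labels == levels(labels)[1]), ncol = 1)
  comp <- sam_components(x, membership)
  r <- comp$r[, 1]
  s <- comp$s[, 1]
  if (is.null(s0)) s0 <- sam_s0(r, s)
  d <- r / (s + s0)
  d[s + s0 == 0 & r == 0] <- 0
  names(d) <- rownames(x)
  attr(d, "s0") <- s0
  attr(d, "s") <- s
  attr(d, "r") <- r
  d
}

## Tusher-style s0 percentile search: pick the percentile of {s_i}
## minimizing the coefficient of variation of the d spread (MAD / 0.64)
## across 100 s-quantile windows.
sam_s0 <- function(r, s) {
  if (length(s) < 100L) return(stats::median(s))
  alphas <- seq(0, 1, by = 0.05)
  s_alpha <- stats::quantile(s, alphas, names = FALSE)
  breaks <- unique(stats::quantile(s, seq(0, 1, length.out = 101),
                                   names = FALSE))
  win <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- vapply(s_alpha, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, function(di) stats::mad(di, constant = 1 / 0.64))
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  s_alpha[which.min(cv)]
}

## all (or a seeded sample of) balanced label splits as an n x B 0/1
## membership matrix; exhaustive enumeration includes the observed
## (identity) split, sampling excludes it
sam_splits <- function(labels, n_permutations, seed = NULL) {
  labels <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  n <- length(labels)
  n1 <- sum(labels == levels(labels)[1])
  total <- choose(n, n1)
  if (total <= n_permutations) {
    if (total < n_permutations) {
      message("sam_fdr: only ", total, " distinct label splits exist; ",
              "using all of them")
    }
    idx <- utils::combn(n, n1)
    membership <- matrix(0, n, ncol(idx))
    membership[cbind(as.vector(idx),
                     rep(seq_len(ncol(idx)), each = n1))] <- 1
    return(list(membership = membership, exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  identity_key <- paste(sort(which(labels == levels(labels)[1])),
                        collapse = ",")
  seen <- character(0)
  cols <- list()
  while (length(cols) < n_permutations) {
    pick <- sort(sample.int(n, n1))
    key <- paste(pick, collapse = ",")
    if (key == identity_key || key %in% seen) next
    seen <- c(seen, key)
    v <- numeric(n)
    v[pick] <- 1
    cols[[length(cols) + 1L]] <- v
  }
  list(membership = do.call(cbind, cols), exhaustive = FALSE)
}

#' Permutation FDR for the SAM statistic
#'
#' Computes observed d values (with s0 fixed from the observed data),
#' recomputes d under balanced label permutations, and estimates, for
#' every symmetric cutoff `c` taken from the observed `|d|` values, the
#' false discovery rate as (estimated false calls at `c`) / (observed
#' calls at `c`). The significant set is the largest one whose
#' estimated FDR is at or below `target_fdr`.
#'
#' When the number of distinct balanced splits does not exceed
#' `n_permutations` the enumeration is exhaustive (e.g. 70 splits for
#' 4 vs 4) and includes the observed split, which makes the estimator
#' an add-one permutation estimator; otherwise `n_permutations`
#' distinct random splits (excluding the observed one) are drawn under
#' `seed`. The estimated false-call count is the mean exceedance over
#' permutations (`estimator = "mean"`, default — see the vignette for
#' why the mean rather than the median makes the null operating
#' characteristics honest); the per-cutoff median is also reported.
#'
#' @param x expression matrix (genes x samples).
#' @param labels two-level group label per column.
#' @param n_permutations requested number of permutations.
#' @param target_fdr target false discovery rate.
#' @param seed seed for permutation sampling (unused when exhaustive).
#' @param estimator `"mean"` or `"median"` permutation exceedance.
#' @return A `sam_result`: list with `d`, `s0`, `fdr_table`
#'   (`cutoff`, `n_observed`, `false_mean`, `false_median`, `fdr`),
#'   `cutoff` (chosen threshold on `|d|`, `Inf` when nothing passes),
#'   `significant` (gene ids), `n_permutations_used`, `exhaustive`,
#'   `estimator`, `target_fdr`.
#' @export
sam_fdr <- function(x, labels, n_permutations = 100, target_fdr = 0.05,
                    seed = NULL, estimator = c("mean", "median")) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x)
  d_obs <- sam_statistic(x, labels)
  s0 <- attr(d_obs, "s0")
  splits <- sam_splits(labels, n_permutations, seed)
  comp <- sam_components(x, splits$membership)
  d_perm <- abs(comp$r / (comp$s + s0))
  d_perm[comp$s + s0 == 0 & comp$r == 0] <- 0

  ad <- abs(as.numeric(d_obs))
  cutoffs <- sort(unique(ad), decreasing = TRUE)
  ad_sorted <- sort(ad)
  n_obs <- length(ad) - findInterval(cutoffs, ad_sorted, left.open = TRUE)
  exceed <- apply(d_perm, 2L, function(col) {
    cs <- sort(col)
    length(cs) - findInterval(cutoffs, cs, left.open = TRUE)
  })
  if (is.null(dim(exceed))) exceed <- matrix(exceed, nrow = length(cutoffs))
  false_mean <- rowMeans(exceed)
  false_median <- apply(exceed, 1L, stats::median)
  est <- if (estimator == "mean") false_mean else false_median
  fdr <- pmin(est / pmax(n_obs, 1L), 1)
  ok <- which(fdr <= target_fdr)
  if (length(ok)) {
    pick <- ok[which.max(n_obs[ok])]  # largest significant set
    cutoff <- cutoffs[pick]
    significant <- names(d_obs)[ad >= cutoff]
  } else {
    cutoff <- Inf
    significant <- character(0)
  }
  structure(list(d = d_obs, s0 = s0,
                 fdr_table = data.frame(cutoff = cutoffs,
                                        n_observed = n_obs,
                                        false_mean = false_mean,
                                        false_median = false_median,
                                        fdr = fdr),
                 cutoff = cutoff, significant = significant,
                 n_permutations_used = ncol(splits$membership),
                 exhaustive = splits$exhaustive,
                 estimator = estimator, target_fdr = target_fdr),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("sam_result: ", length(x$d), " genes, ",
      x$n_permutations_used, if (x$exhaustive) " (exhaustive)" else "",
      " permutations, s0 = ", signif(x$s0, 4), "\n",
      "  ", length(x$significant), " significant at FDR <= ",
      x$target_fdr, " (|d| >= ", signif(x$cutoff, 4), ")\n", sep = "")
  invisible(x)
}
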