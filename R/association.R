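# Count strict inversions (pairs i<j with v[i] > v[j]) by bottom-up
# mergesort. Used by kendall_tau_b to get the discordant-pair count in
# O(n log n) without enumerating pairs.
#' @noRd
count_inversions <- function(v) {
  n <- length(v)
  inv <- 0
  width <- 1L
  while (width < n) {
    i <- 1L
    while (i + width <= n) {
      mid <- i + width - 1L
      hi <- min(i + 2L * width - 1L, n)
      left <- v[i:mid]
      right <- v[(mid + 1L):hi]
      # left, right sorted; for each r count left values > r
      inv <- inv + sum(length(left) - findInterval(right, left))
      v[i:hi] <- c(left, right)[order(c(left, right))]
      i <- i + 2L * width
    }
    width <- 2L * width
  }
  inv
}

#' Kendall rank correlation tau-b with tie-corrected inference
#'
#' Computes tau-b = (C - D) / sqrt((n0 - n1)(n0 - n2)) where C and D are the
#' concordant and discordant pair counts, n0 = n(n-1)/2 and n1, n2 are the
#' within-tie pair counts of `x` and `y`. The default p-value is two-sided
#' from the asymptotic normal approximation of S = C - D with the classical
#' tie-corrected variance (the behaviour of the scipy `kendalltau` default
#' under ties). `p_method = "exact"` enumerates all permutations of `y`
#' (n <= 8) and is intended as a small-sample oracle.
#'
#' Fibrosis stages are heavily tied, so tau-b — the only tau variant defined
#' under ties — is the estimator used throughout the screening stage.
#'
#' @param x,y numeric vectors of equal length (n >= 2); ties allowed
#' @param p_method `"asymptotic"` (default) or `"exact"`
#' @return A list with `tau_b`, `p_value`, `S` (C - D) and `n`.
#' @export
kendall_tau_b <- function(x, y, p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need at least two observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed; drop first")
  ord <- order(x, y)
  xs <- x[ord]; ys <- y[ord]
  # within tied-x runs ys is ascending, so inversions only cross distinct x
  dis <- count_inversions(ys)
  n0 <- n * (n - 1) / 2
  tx <- rle(xs)$lengths
  ty <- rle(sort(y))$lengths
  jt <- rle(cumsum(c(TRUE, diff(xs) != 0 | diff(ys) != 0)))$lengths
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  n3 <- sum(jt * (jt - 1) / 2)
  S <- n0 - n1 - n2 + n3 - 2 * dis
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0)
    stop("degenerate input: all values tied in x or y; tau-b undefined")
  tau <- max(-1, min(1, S / den))
  if (p_method == "exact") {
    p <- kendall_exact_p(x, y, S)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    var_s <- (v0 - vt - vu) / 18 +
      sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    if (n > 2)
      var_s <- var_s + sum(tx * (tx - 1) * (tx - 2)) *
        sum(ty * (ty - 1) * (ty - 2)) / (9 * n * (n - 1) * (n - 2))
    z <- S / sqrt(var_s)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(tau_b = tau, p_value = p, S = S, n = n)
}

# Exact permutation p for |S|: enumerate all n! orderings of y. The tau-b
# denominator is permutation-invariant, so comparing |S| compares |tau|.
#' @noRd
kendall_exact_p <- function(x, y, S_obs) {
  n <- length(x)
  if (n > 8) stop("exact permutation p only for n <= 8")
  perms <- permutations_of(n)
  hits <- 0L
  for (k in seq_len(nrow(perms))) {
    yp <- y[perms[k, ]]
    s <- 0
    for (i in seq_len(n - 1)) {
      dx <- sign(x[(i + 1):n] - x[i])
      dy <- sign(yp[(i + 1):n] - yp[i])
      s <- s + sum(dx * dy)
    }
    if (abs(s) >= abs(S_obs) - 1e-9) hits <- hits + 1L
  }
  hits / nrow(perms)
}

#' @noRd
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Screen all bins in one base group for association with fibrosis stage
#'
#' For each bin, samples of the requested sex x sample-type stratum with a
#' non-missing beta are correlated (Kendall tau-b) against their fibrosis
#' stage. Bins observed in fewer than `min_individuals` samples, or whose
#' betas converge to fewer than `min_unique` distinct values (after rounding
#' to 6 decimals), are marked filtered and can never be significant; the
#' same applies when the observed stages are all tied (tau undefined).
#' Significance is a strict comparison `p < alpha`; no multiple-testing
#' correction is applied — the cross-group intersection stage is the
#' control.
#'
#' @param bbm a `BinBetaMatrix`
#' @param metadata validated sample metadata
#' @param base_group one of `base_groups()`
#' @param alpha significance level (strict `<`)
#' @param min_individuals minimum samples with observed beta (default 4)
#' @param min_unique minimum distinct beta values (default 3)
#' @return A `data.table`: `bin_index`, `base_group`, `n_obs`, `n_unique`,
#'   `tau_b`, `p_value`, `filtered`, `significant`.
#' @export
screen_bins <- function(bbm, metadata, base_group,
                        alpha = 0.05, min_individuals = 4L, min_unique = 3L) {
  stopifnot(inherits(bbm, "BinBetaMatrix"))
  md <- validate_sample_metadata(metadata)
  stopifnot(base_group %in% base_groups())
  ids <- intersect(bbm$samples, md$sample_id[md$base_group == base_group])
  if (length(ids) == 0) stop("no samples in base group ", base_group)
  stage <- md$fibrosis_stage[match(ids, md$sample_id)]
  bmat <- bbm$beta[, ids, drop = FALSE]
  nb <- nrow(bmat)
  tau <- rep(NA_real_, nb); pv <- rep(NA_real_, nb)
  n_obs <- integer(nb); n_unique <- integer(nb)
  for (i in seq_len(nb)) {
    b <- bmat[i, ]
    obs <- !is.na(b)
    n_obs[i] <- sum(obs)
    n_unique[i] <- length(unique(round(b[obs], 6)))
    if (n_obs[i] < min_individuals || n_unique[i] < min_unique) next
    yy <- stage[obs]
    if (length(unique(yy)) < 2) next  # tau degenerate: treat as filtered
    kt <- kendall_tau_b(b[obs], yy)
    tau[i] <- kt$tau_b; pv[i] <- kt$p_value
  }
  filt <- is.na(pv)
  data.table(bin_index = bbm$bins$bin_index, base_group = base_group,
             n_obs = n_obs, n_unique = n_unique, tau_b = tau, p_value = pv,
             filtered = filt,
             significant = !filt & !is.na(pv) & pv < alpha)
}

#' Screen all four base groups
#'
#' @inheritParams screen_bins
#' @param ... passed to [screen_bins()]
#' @return Named list of screening tables, one per base group.
#' @export
screen_all_groups <- function(bbm, metadata, ...) {
  res <- lapply(base_groups(), function(g) screen_bins(bbm, metadata, g, ...))
  names(res) <- base_groups()
  res
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact distribution when both groups have n <= 10 and there are no ties;
#' normal approximation with tie correction (and continuity correction)
#' otherwise. Used for the low/high fibrosis contrasts.
#'
#' @param a,b numeric vectors, both non-empty
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 10 && length(b) <= 10 && !ties
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value
  )
}

#' Dichotomize fibrosis stage into low/high
#'
#' "low" for stages strictly below `cut` (default 2), "high" otherwise.
#'
#' @param stage integer vector of stages in 0..4
#' @param cut threshold stage (default 2)
#' @return Factor with levels `low`, `high`.
#' @export
fibrosis_group <- function(stage, cut = 2L) {
  if (anyNA(stage) || !all(stage %in% 0:4))
    stop("fibrosis stage must be an integer in 0..4")
  factor(ifelse(stage < cut, "low", "high"), levels = c("low", "high"))
}
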