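# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||_2
# subject to x >= 0. Deterministic; A is small (markers x cell types).
#' @noRd
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A); b <- as.numeric(b)
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * nrow(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b))
  it <- 0L; maxit <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && it < maxit) {
    it <- it + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Build and validate a reference atlas
#'
#' Marker-bin by cell-type matrix of reference beta values. Each marker row
#' must separate the cell types: its max-min spread across cell types must
#' reach `separation` (default 0.5), the knob that encodes atlas quality.
#'
#' @param A numeric matrix (markers x cell types), values in [0, 1], with
#'   dimnames
#' @param separation minimum per-row spread (default 0.5)
#' @return The validated matrix with class `reference_atlas`.
#' @export
reference_atlas <- function(A, separation = 0.5) {
  A <- as.matrix(A)
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("atlas needs marker rownames and cell-type colnames")
  if (anyNA(A) || any(A < 0 | A > 1))
    stop("atlas beta values must lie in [0, 1]")
  spread <- apply(A, 1, function(r) diff(range(r)))
  if (any(spread < separation))
    stop(sum(spread < separation), " marker row(s) with spread < ",
         separation)
  structure(A, class = c("reference_atlas", "matrix"),
            separation = separation)
}

#' Read / write an atlas TSV (rows = marker bins, columns = cell types)
#'
#' @param path TSV path
#' @param separation passed to [reference_atlas()]
#' @return A `reference_atlas`.
#' @export
read_atlas <- function(path, separation = 0.5) {
  dt <- fread(path, header = TRUE, sep = "\t", showProgress = FALSE)
  A <- as.matrix(dt[, -1, with = FALSE])
  rownames(A) <- as.character(dt[[1]])
  reference_atlas(A, separation)
}

#' @rdname read_atlas
#' @param atlas a `reference_atlas`
#' @export
write_atlas <- function(atlas, path) {
  out <- data.table(marker = rownames(atlas))
  out <- cbind(out, as.data.table(unclass(atlas)))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Estimate cell-type proportions for one sample
#'
#' Constrained least squares of the sample's marker-bin betas against the
#' atlas: w = argmin ||A'w - b'||_2 with w >= 0 and sum(w) = 1, where A'
#' and b' are restricted to the markers observed in the sample. The default
#' enforces the simplex by renormalizing the NNLS solution (the common,
#' well-conditioned choice); `method = "simplex"` appends a heavily
#' weighted sum-to-one row to the NNLS system instead. Requires at least
#' `min_coverage` of marker bins observed; a rank-deficient restricted
#' atlas flags the result unstable.
#'
#' @param atlas a `reference_atlas`
#' @param b named numeric vector of sample betas over (a superset of) the
#'   atlas markers; `NA` = missing
#' @param min_coverage minimum fraction of markers observed (default 0.5)
#' @param method `"renormalize"` (default) or `"simplex"`
#' @param sample_id optional identifier carried into the result
#' @return A `deconvolution_result`: list with `w` (named proportions),
#'   `residual_norm`, `n_markers`, `unstable`, `sample_id`.
#' @export
estimate_proportions <- function(atlas, b, min_coverage = 0.5,
                                 method = c("renormalize", "simplex"),
                                 sample_id = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(atlas, "reference_atlas"))
  A <- unclass(atlas)
  if (!is.null(names(b))) b <- b[rownames(A)]
  if (length(b) != nrow(A)) stop("beta vector does not match atlas markers")
  keep <- !is.na(b)
  if (mean(keep) < min_coverage)
    stop("only ", round(100 * mean(keep)), "% of marker bins observed ",
         "(need >= ", round(100 * min_coverage), "%)")
  Ak <- A[keep, , drop = FALSE]; bk <- as.numeric(b[keep])
  unstable <- qr(Ak)$rank < ncol(Ak)
  if (unstable)
    warning("atlas rank-deficient after dropping missing markers; ",
            "result flagged unstable")
  if (method == "renormalize") {
    w <- nnls_solve(Ak, bk)
    s <- sum(w)
    if (s <= 0) {
      warning("all-zero NNLS solution; returning uniform proportions")
      w <- rep(1 / ncol(Ak), ncol(Ak))
    } else w <- w / s
  } else {
    lambda <- 1e3 * max(1, max(abs(Ak)))
    w <- nnls_solve(rbind(Ak, lambda), c(bk, lambda))
    w <- w / sum(w)  # remove residual drift from the penalty row
  }
  names(w) <- colnames(A)
  structure(list(sample_id = sample_id, w = w,
                 residual_norm = sqrt(sum((Ak %*% w - bk)^2)),
                 n_markers = sum(keep), unstable = unstable),
            class = "deconvolution_result")
}

#' Deconvolve a matrix of samples
#'
#' @inheritParams estimate_proportions
#' @param betas markers x samples matrix (rownames = atlas markers)
#' @param ... passed to [estimate_proportions()]
#' @return List with `proportions` (samples x cell types), `residual_norm`
#'   and `unstable` per sample.
#' @export
deconvolve_samples <- function(atlas, betas, ...) {
  stopifnot(is.matrix(betas))
  res <- lapply(colnames(betas), function(s)
    estimate_proportions(atlas, betas[, s], sample_id = s, ...))
  props <- do.call(rbind, lapply(res, `[[`, "w"))
  rownames(props) <- colnames(betas)
  list(proportions = props,
       residual_norm = vapply(res, `[[`, numeric(1), "residual_norm"),
       unstable = vapply(res, `[[`, logical(1), "unstable"))
}

#' Compare one cell type's proportions between fibrosis groups
#'
#' Two-sided Wilcoxon rank-sum test of the per-sample proportions, low
#' versus high fibrosis (stage dichotomized at `fibrosis_cut`).
#'
#' @param proportions samples x cell-types matrix (rownames = sample ids)
#'   as from [deconvolve_samples()], or an externally produced table
#' @param metadata sample metadata covering those samples
#' @param cell_type column to compare
#' @param fibrosis_cut stage threshold (default 2)
#' @return List with `p_value`, `n_low`, `n_high`, `median_low`,
#'   `median_high`.
#' @export
compare_proportions_by_fibrosis <- function(proportions, metadata, cell_type,
                                            fibrosis_cut = 2L) {
  md <- validate_sample_metadata(metadata)
  ids <- intersect(rownames(proportions), md$sample_id)
  if (length(ids) == 0) stop("no overlap between proportions and metadata")
  grp <- fibrosis_group(md$fibrosis_stage[match(ids, md$sample_id)],
                        fibrosis_cut)
  v <- proportions[ids, cell_type]
  lo <- v[grp == "low"]; hi <- v[grp == "high"]
  if (length(lo) < 2 || length(hi) < 2)
    stop("need >= 2 samples per fibrosis group (got ", length(lo), " low, ",
         length(hi), " high)")
  list(p_value = wilcoxon_rank_sum(lo, hi),
       n_low = length(lo), n_high = length(hi),
       median_low = median(lo), median_high = median(hi))
}
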