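# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Write lines to a temp file and return its path.
tmpfile <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# Minimal metadata table: `n` samples per base group, stages recycled.
make_metadata <- function(n = 8, stages = c(1, 1, 2, 2, 3, 3, 4, 4)) {
  rows <- list()
  for (sex in c("male", "female")) for (ty in c("tissue", "cfDNA")) {
    st <- rep_len(stages, n)
    for (i in seq_len(n)) {
      id <- paste0(substr(sex, 1, 1), substr(ty, 1, 1), i)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, subject_id = id, sex = sex, sample_type = ty,
        fibrosis_stage = st[i])
    }
  }
  validate_sample_metadata(do.call(rbind, rows))
}

# BinBetaMatrix straight from a beta matrix (counts faked as 10x coverage).
bbm_from_beta <- function(beta, chrom = "chr1") {
  nb <- nrow(beta)
  pos <- seq(0L, by = 1000L, length.out = nb)
  bins <- build_bins(setNames(list(pos), chrom))
  n_tot <- matrix(10L, nb, ncol(beta), dimnames = dimnames(beta))
  n_tot[is.na(beta)] <- 0L
  n_meth <- matrix(as.integer(round(10 * beta)), nb, ncol(beta),
                   dimnames = dimnames(beta))
  n_meth[is.na(beta)] <- 0L
  structure(list(bins = bins, samples = colnames(beta), beta = beta,
                 n_meth = n_meth, n_total = n_tot),
            class = "BinBetaMatrix")
}

# gene track from a compact spec list: list(list(chrom,start,end,name,strand,
# blocks=data.table(start,end)))
make_gene_track <- function(genes) {
  tr <- data.table::rbindlist(lapply(genes, function(g) {
    data.table::data.table(
      chrom = g$chrom, start = g$start, end = g$end, name = g$name,
      strand = if (is.null(g$strand)) "+" else g$strand,
      blocks = if (is.null(g$blocks)) list(NULL) else list(g$blocks))
  }))
  methbin:::as_feature_track(tr, "gene")
}

make_track <- function(kind, chrom, start, end, name = NULL,
                       strand = NULL) {
  tr <- data.table::data.table(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = if (is.null(name)) sprintf("f%03d", seq_along(start)) else name,
    strand = if (is.null(strand)) "." else strand)
  methbin:::as_feature_track(tr, kind)
}

# Independent O(n^2) Kendall oracle: direct pair counting plus the
# tie-corrected normal p recomputed from scratch.
kendall_oracle <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
  }
  tx <- as.vector(table(x)); ty <- as.vector(table(y))
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- (C - D) / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v <- (v0 - vt - vu) / 18 +
    sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  if (n > 2)
    v <- v + sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  p <- min(1, 2 * stats::pnorm(-abs((C - D) / sqrt(v))))
  list(tau = tau, p = p, S = C - D)
}

# Exhaustive Wilcoxon rank-sum oracle (no ties): all C(n, n1) group
# assignments of the pooled ranks, two-sided p.
wilcoxon_oracle <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2, function(idx)
    sum(rank(c(a, b))[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
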