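#' Cluster CpG sites into bins with the gap rule
#'
#' Adjacent CpG sites on the same chromosome are merged into one bin when
#' the distance between their plus-strand C positions is strictly less than
#' `max_gap` (default 65 bp); a gap of `max_gap` or more splits. The result
#' is a partition of all sites; singleton bins are allowed. Bin spans run
#' from the first member CpG to the last member plus 2 (covering the dyad),
#' and `bin_index` increases in genomic order so indices are cohort-stable
#' when bins are built once from the union of CpG positions.
#'
#' @param positions either a named list of sorted, unique integer vectors
#'   (one per chromosome) or a data.frame with `chrom` and `pos` columns
#' @param max_gap integer; merge adjacent sites closer than this (bp)
#' @return A `bin_set`: a `data.table` with `bin_index`, `chrom`, `start`,
#'   `end`, `n_cpg` and a `cpgs` list column of member positions.
#' @export
build_bins <- function(positions, max_gap = 65L) {
  stopifnot(max_gap >= 1)
  if (is.data.frame(positions)) {
    stopifnot(all(c("chrom", "pos") %in% names(positions)))
    positions <- split(as.integer(positions$pos),
                       as.character(positions$chrom))
  }
  stopifnot(is.list(positions))
  chroms <- names(positions)
  if (length(positions) && is.null(chroms))
    stop("positions list must be named by chromosome")
  chroms <- chroms[order(chrom_rank(chroms), chroms)]
  pieces <- lapply(chroms, function(ch) {
    p <- as.integer(positions[[ch]])
    if (length(p) == 0) return(NULL)
    if (is.unsorted(p, strictly = TRUE))
      stop("positions on ", ch, " must be sorted and unique")
    grp <- cumsum(c(TRUE, diff(p) >= max_gap))
    sp <- split(p, grp)
    data.table(chrom = ch,
               start = vapply(sp, `[`, integer(1), 1L),
               end = vapply(sp, function(v) v[length(v)] + 2L, integer(1)),
               n_cpg = lengths(sp),
               cpgs = sp)
  })
  bins <- rbindlist(pieces)
  if (nrow(bins) == 0)
    bins <- data.table(chrom = character(), start = integer(),
                       end = integer(), n_cpg = integer(), cpgs = list())
  bins[, bin_index := seq_len(.N)]
  setcolorder(bins, c("bin_index", "chrom", "start", "end", "n_cpg", "cpgs"))
  setattr(bins, "class", c("bin_set", class(bins)))
  bins[]
}

# Long lookup table mapping every member CpG position to its bin.
#' @noRd
bin_lookup <- function(bins) {
  data.table(chrom = rep(bins$chrom, bins$n_cpg),
             pos = unlist(bins$cpgs, use.names = FALSE),
             bin_index = rep(bins$bin_index, bins$n_cpg),
             key = c("chrom", "pos"))
}

#' Bin-level beta matrix
#'
#' Aggregates per-CpG read counts into bins and computes the bin beta value
#' per sample. The default (`aggregate = "reads"`) pools read counts, so
#' beta is the ratio of methylated CpG observations to all CpG observations
#' in the bin — the average methylation fraction. `aggregate = "cpg_mean"`
#' instead averages per-CpG betas over covered sites. Beta is missing
#' wherever the bin has zero coverage in a sample.
#'
#' @param records a `meth_records` table (any number of samples)
#' @param bins a `bin_set` built from the union of the records' positions
#' @param aggregate `"reads"` (pooled counts, default) or `"cpg_mean"`
#' @return A `BinBetaMatrix`: list with `bins`, `samples`, and
#'   bins x samples matrices `beta`, `n_meth`, `n_total`.
#' @export
compute_bin_beta <- function(records, bins, aggregate = c("reads", "cpg_mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(bins, "bin_set"))
  lk <- bin_lookup(bins)
  rec <- as.data.table(records)[, .(sample_id, chrom, pos, n_meth, n_unmeth)]
  rec <- lk[rec, on = c("chrom", "pos")]
  if (anyNA(rec$bin_index))
    stop("record position not covered by any bin (bins built from a ",
         "different site set): first offender ",
         rec[is.na(bin_index)][1, paste0(chrom, ":", pos)])
  samples <- sort(unique(rec$sample_id))
  nb <- nrow(bins); ns <- length(samples)
  m_meth <- matrix(0L, nb, ns, dimnames = list(bins$bin_index, samples))
  m_tot <- matrix(0L, nb, ns, dimnames = list(bins$bin_index, samples))
  agg <- rec[, .(n_meth = sum(n_meth), n_total = sum(n_meth + n_unmeth)),
             by = .(bin_index, sample_id)]
  i <- cbind(match(agg$bin_index, bins$bin_index),
             match(agg$sample_id, samples))
  m_meth[i] <- agg$n_meth
  m_tot[i] <- agg$n_total
  if (aggregate == "reads") {
    beta <- ifelse(m_tot > 0, m_meth / m_tot, NA_real_)
  } else {
    rec[, beta := ifelse(n_meth + n_unmeth > 0,
                         n_meth / (n_meth + n_unmeth), NA_real_)]
    aggm <- rec[!is.na(beta),
                .(beta = mean(beta)), by = .(bin_index, sample_id)]
    beta <- matrix(NA_real_, nb, ns, dimnames = list(bins$bin_index, samples))
    beta[cbind(match(aggm$bin_index, bins$bin_index),
               match(aggm$sample_id, samples))] <- aggm$beta
  }
  structure(list(bins = bins, samples = samples, beta = beta,
                 n_meth = m_meth, n_total = m_tot),
            class = "BinBetaMatrix")
}

#' @export
print.BinBetaMatrix <- function(x, ...) {
  cat("BinBetaMatrix:", nrow(x$beta), "bins x", length(x$samples),
      "samples;", sprintf("%.1f%%", 100 * mean(is.na(x$beta))),
      "missing cells\n")
  invisible(x)
}

#' Write a bin table as BED4
#'
#' @param bins a `bin_set`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_bin_bed <- function(bins, path) {
  fwrite(bins[, .(chrom, start, end, bin_index)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Write the beta matrix as wide TSV (missing values as NA)
#'
#' @param bbm a `BinBetaMatrix`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(bbm, path) {
  out <- data.table(bin_index = bbm$bins$bin_index)
  out <- cbind(out, as.data.table(bbm$beta))
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
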