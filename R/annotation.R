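# 0-based half-open intervals -> GRanges (1-based closed)
#' @noRd
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' Nearest gene for each bin
#'
#' Minimal genomic distance between the bin interval and any gene body on
#' the same chromosome; distance is the gap length, 0 when touching or
#' overlapping. Ties are broken by the alphabetically first gene symbol.
#' The sign is negative when the gene lies 5' of the bin in reference
#' orientation (lower coordinates), positive when 3', and 0 on overlap.
#'
#' @param bins a `bin_set` (or any table with `bin_index`, `chrom`,
#'   `start`, `end`)
#' @param gene_track a gene `feature_track`
#' @return `data.table` with `bin_index`, `nearest_gene`,
#'   `signed_distance`; `NA` with a warning for bins on chromosomes without
#'   genes.
#' @export
nearest_gene <- function(bins, gene_track) {
  bt <- as.data.table(bins)[, .(bin_index, chrom, start, end)]
  gt <- as.data.table(gene_track)
  res_gene <- rep(NA_character_, nrow(bt))
  res_dist <- rep(NA_real_, nrow(bt))
  missing_chrom <- FALSE
  for (ch in unique(bt$chrom)) {
    bi <- which(bt$chrom == ch)
    g <- gt[chrom == ch]
    if (nrow(g) == 0) { missing_chrom <- TRUE; next }
    for (k in bi) {
      gap <- pmax(0L, g$start - bt$end[k], bt$start[k] - g$end)
      best <- which(gap == min(gap))
      if (length(best) > 1) best <- best[order(g$name[best])][1]
      res_gene[k] <- g$name[best]
      res_dist[k] <- if (gap[best] == 0) 0 else
        if (g$end[best] <= bt$start[k]) -gap[best] else gap[best]
    }
  }
  if (missing_chrom)
    warning("some bins lie on chromosomes with no annotated gene")
  data.table(bin_index = bt$bin_index, nearest_gene = res_gene,
             signed_distance = res_dist)
}

# distance from interval [s,e) to a point p (0 inside, gap otherwise)
#' @noRd
interval_point_dist <- function(s, e, p) {
  pmax(0L, s - p, p - (e - 1L))
}

#' Positional flags for each bin
#'
#' Computes, per bin: `near_tss` (strand-aware TSS within strictly less
#' than `tss_window` bp), `in_cpg_island` (at least 1 bp overlap with an
#' island interval, optionally padded by `island_slop`), `intergenic` (no
#' gene-body overlap), and `first_exon_intron` (overlap with the 5'-most
#' exon or the first intron of any transcript carrying block structure;
#' `NA` when the gene track has no blocks).
#'
#' @inheritParams nearest_gene
#' @param island_track a CpG-island `feature_track`
#' @param tss_window strict TSS distance threshold in bp (default 1500)
#' @param island_slop padding added to island intervals (default 0)
#' @return `data.table` keyed by `bin_index` with the four logical flags.
#' @export
classify_region <- function(bins, gene_track, island_track,
                            tss_window = 1500L, island_slop = 0L) {
  bt <- as.data.table(bins)[, .(bin_index, chrom, start, end)]
  gt <- as.data.table(gene_track)
  it <- as.data.table(island_track)
  gr_bins <- as_granges0(bt$chrom, bt$start, bt$end)

  overlaps_any <- function(track_dt, slop = 0L) {
    if (nrow(track_dt) == 0) return(rep(FALSE, nrow(bt)))
    gr <- as_granges0(track_dt$chrom, pmax(0L, track_dt$start - slop),
                      track_dt$end + slop)
    IRanges::overlapsAny(gr_bins, gr)
  }

  in_island <- overlaps_any(it, island_slop)
  genic <- overlaps_any(gt)

  near <- rep(FALSE, nrow(bt))
  if (nrow(gt) > 0) {
    tss_by_chrom <- split(gt$tss, gt$chrom)
    for (ch in names(tss_by_chrom)) {
      bi <- which(bt$chrom == ch)
      tv <- tss_by_chrom[[ch]]
      for (k in bi) {
        d <- min(interval_point_dist(bt$start[k], bt$end[k], tv))
        near[k] <- d < tss_window
      }
    }
  }

  fei <- rep(NA, nrow(bt))
  if ("blocks" %in% names(gt)) {
    feat <- first_exon_intron_intervals(gt)
    fei <- if (nrow(feat) == 0) rep(FALSE, nrow(bt)) else
      as.logical(IRanges::overlapsAny(
        gr_bins, as_granges0(feat$chrom, feat$start, feat$end)))
  }

  data.table(bin_index = bt$bin_index, near_tss = near,
             in_cpg_island = in_island, intergenic = !genic,
             first_exon_intron = fei)
}

# First exon and first intron of every transcript with blocks, strand-aware:
# on "-" the 5'-most exon is the block with the largest coordinates.
#' @noRd
first_exon_intron_intervals <- function(gt) {
  out <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    b <- gt$blocks[[i]]
    if (is.null(b) || nrow(b) == 0) next
    b <- b[order(b$start)]
    minus <- identical(gt$strand[i], "-")
    fe <- if (minus) b[nrow(b)] else b[1]
    rows <- data.table(chrom = gt$chrom[i], start = fe$start, end = fe$end)
    if (nrow(b) >= 2) {
      fi <- if (minus)
        data.table(chrom = gt$chrom[i],
                   start = b$end[nrow(b) - 1L], end = b$start[nrow(b)])
      else
        data.table(chrom = gt$chrom[i], start = b$end[1L], end = b$start[2L])
      if (fi$start < fi$end) rows <- rbind(rows, fi)
    }
    out[[i]] <- rows
  }
  rbindlist(out)
}

#' chromHMM state of each bin
#'
#' State of the segment with the largest overlap; exact overlap ties go to
#' the segment with the smaller start. Bins in regions not covered by any
#' segment get `NA` with a warning (chromHMM segmentations are normally
#' genome-tiling).
#'
#' @inheritParams nearest_gene
#' @param chromhmm_track a chromHMM `feature_track` (state in `state`)
#' @return Character vector of state labels aligned with the bin rows.
#' @export
assign_chromhmm_state <- function(bins, chromhmm_track) {
  bt <- as.data.table(bins)[, .(bin_index, chrom, start, end)]
  tr <- as.data.table(chromhmm_track)
  if (nrow(tr) == 0) {
    warning("empty chromHMM track; all states NA")
    return(rep(NA_character_, nrow(bt)))
  }
  gr_bins <- as_granges0(bt$chrom, bt$start, bt$end)
  gr_seg <- as_granges0(tr$chrom, tr$start, tr$end)
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_seg)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- data.table(
    q = qh, state = tr$state[sh], seg_start = tr$start[sh],
    width = pmin(bt$end[qh], tr$end[sh]) - pmax(bt$start[qh], tr$start[sh]))
  setorder(ov, q, -width, seg_start)
  best <- ov[!duplicated(q)]
  res <- rep(NA_character_, nrow(bt))
  res[best$q] <- best$state
  if (anyNA(res))
    warning(sum(is.na(res)), " bin(s) not covered by any chromHMM segment")
  res
}

#' Full bin annotation table
#'
#' Joins nearest gene, positional flags, and (optionally) one chromHMM
#' state column per cell type.
#'
#' @inheritParams classify_region
#' @param chromhmm_tracks named list of chromHMM `feature_track`s, one per
#'   cell type (may be `NULL`)
#' @return `data.table` keyed by `bin_index` with all annotation columns;
#'   chromHMM columns are named `state_<celltype>`.
#' @export
annotate_bins <- function(bins, gene_track, island_track,
                          chromhmm_tracks = NULL, tss_window = 1500L,
                          island_slop = 0L) {
  ann <- merge(nearest_gene(bins, gene_track),
               classify_region(bins, gene_track, island_track,
                               tss_window, island_slop),
               by = "bin_index")
  for (ct in names(chromhmm_tracks))
    ann[[paste0("state_", ct)]] <-
      assign_chromhmm_state(bins, chromhmm_tracks[[ct]])
  ann
}

#' Gene list for pathway-analysis export
#'
#' Selects bins carrying a given intersection label under one of the
#' selection modes, and returns their nearest/overlapping gene symbols,
#' deduplicated and sorted. Modes: `tissue_strict` requires the bin to be
#' in a CpG island AND TSS-proximal; `or_relaxed` requires island OR
#' TSS-proximal; `extended` requires Kendall p < `alpha_extended` in every
#' contributing base group and a chromHMM state difference between the two
#' annotated cell types.
#'
#' @param labels output of [label_all_bins()]
#' @param annotations output of [annotate_bins()]
#' @param target_label one of Tissue, cfDNA, Male, Female, All
#' @param mode `"tissue_strict"`, `"or_relaxed"` or `"extended"`
#' @param screen_results named list of [screen_bins()] tables (needed for
#'   `extended`)
#' @param alpha_extended stricter p threshold for `extended` (default 0.01)
#' @param state_cols the two `state_*` annotation columns compared in
#'   `extended` mode (default: the first two present)
#' @return Character vector of gene symbols (possibly empty, with warning).
#' @export
select_pathway_input <- function(labels, annotations, target_label,
                                 mode = c("tissue_strict", "or_relaxed",
                                          "extended"),
                                 screen_results = NULL,
                                 alpha_extended = 0.01, state_cols = NULL) {
  mode <- match.arg(mode)
  lab <- as.data.table(labels)[label == target_label]
  ann <- as.data.table(annotations)
  dt <- merge(lab, ann, by = "bin_index")
  keep <- switch(mode,
    tissue_strict = dt$in_cpg_island & dt$near_tss,
    or_relaxed = dt$in_cpg_island | dt$near_tss,
    extended = {
      if (is.null(screen_results))
        stop("extended mode requires screen_results")
      if (is.null(state_cols))
        state_cols <- grep("^state_", names(dt), value = TRUE)[1:2]
      if (length(state_cols) != 2 || anyNA(state_cols))
        stop("extended mode requires two chromHMM state columns")
      pmat <- vapply(base_groups(), function(g) {
        r <- screen_results[[g]]
        r$p_value[match(dt$bin_index, r$bin_index)]
      }, numeric(nrow(dt)))
      if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = nrow(dt))
      pok <- vapply(seq_len(nrow(dt)), function(i) {
        gs <- strsplit(dt$contributing_groups[i], ",")[[1]]
        all(!is.na(pmat[i, match(gs, base_groups())]) &
              pmat[i, match(gs, base_groups())] < alpha_extended)
      }, logical(1))
      s1 <- dt[[state_cols[1]]]; s2 <- dt[[state_cols[2]]]
      pok & !is.na(s1) & !is.na(s2) & s1 != s2
    })
  genes <- sort(unique(dt$nearest_gene[keep & !is.na(dt$nearest_gene)]))
  if (length(genes) == 0)
    warning("no genes selected for label ", target_label, " in mode ", mode)
  genes
}
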