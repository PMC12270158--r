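#' Core 15-state chromHMM mnemonics
#'
#' Labels of the ENCODE Core 15-state model, in model order, as used in
#' UCSC segmentation tracks.
#'
#' @return Character vector of the 15 state labels.
#' @export
chromhmm_states <- function() {
  c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk", "6_EnhG",
    "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv", "11_BivFlnk",
    "12_EnhBiv", "13_ReprPC", "14_ReprPCWk", "15_Quies")
}

#' Chromatin state-transition table between two cell types
#'
#' Tallies, over a set of bins, the joint (cell type A state, cell type B
#' state) assignments into a state-grid count matrix and its proportions.
#' Bins with an `NA` state in either cell type are excluded and counted.
#'
#' @param states_a,states_b character vectors of per-bin state labels for
#'   the two cell types (same length, aligned)
#' @param levels the state grid labels (default [chromhmm_states()],
#'   extended with any unseen observed label)
#' @param group `"associated"` or `"background"`
#' @return A `transition_table`: list with `counts`, `proportions`,
#'   `group`, `n_excluded`.
#' @export
build_transition_table <- function(states_a, states_b, levels = NULL,
                                   group = c("associated", "background")) {
  group <- match.arg(group)
  stopifnot(length(states_a) == length(states_b))
  if (length(states_a) == 0) stop("empty bin set")
  if (is.null(levels))
    levels <- union(chromhmm_states(),
                    stats::na.omit(c(states_a, states_b)))
  ok <- !is.na(states_a) & !is.na(states_b)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " bin(s) excluded for missing chromHMM state")
  if (!any(ok)) stop("no bins with states in both cell types")
  counts <- table(factor(states_a[ok], levels = levels),
                  factor(states_b[ok], levels = levels))
  counts <- unclass(counts)
  structure(list(counts = counts, proportions = counts / sum(counts),
                 group = group, n_excluded = n_excluded),
            class = "transition_table")
}

#' Transition enrichment of associated versus background bins
#'
#' Cell-wise ratio of associated over background transition proportions.
#' Flags: `enriched` where the finite ratio exceeds `fold` (default 1.5),
#' `low_support` where fewer than `min_bins` associated bins back the cell
#' (default 30; rendered faded in the source figure), `absent` where no
#' associated bin shows the transition, and `infinite` where the background
#' proportion is 0 but associated bins exist (reported separately, never
#' `enriched`).
#'
#' @param assoc,background `transition_table`s on the same grid
#' @param fold enrichment threshold (strict `>`)
#' @param min_bins associated-bin support threshold
#' @return A `chromhmm_enrichment`: list with matrices `ratio`, `n_assoc`
#'   and logical flag matrices `enriched`, `low_support`, `absent`,
#'   `infinite`.
#' @export
compute_enrichment <- function(assoc, background, fold = 1.5,
                               min_bins = 30L) {
  stopifnot(inherits(assoc, "transition_table"),
            inherits(background, "transition_table"))
  if (!identical(dimnames(assoc$counts), dimnames(background$counts)))
    stop("transition tables are on different state grids")
  if (sum(background$counts) == 0) stop("background table is empty")
  pa <- assoc$proportions
  pb <- background$proportions
  ratio <- pa / pb
  infinite <- pb == 0 & assoc$counts > 0
  ratio[pb == 0] <- NA_real_
  ratio[infinite] <- Inf
  structure(list(
    ratio = ratio,
    n_assoc = assoc$counts,
    enriched = is.finite(ratio) & ratio > fold & assoc$counts > 0,
    low_support = assoc$counts < min_bins,
    absent = assoc$counts == 0,
    infinite = infinite,
    fold = fold, min_bins = min_bins
  ), class = "chromhmm_enrichment")
}

#' Genes nearest to bins in enriched, adequately supported transitions
#'
#' @param enrichment a `chromhmm_enrichment`
#' @param bin_info `data.table` for the associated bins with columns
#'   `state_a`, `state_b`, `nearest_gene`
#' @return Deduplicated, sorted gene symbols (warning when empty).
#' @export
enriched_gene_list <- function(enrichment, bin_info) {
  stopifnot(inherits(enrichment, "chromhmm_enrichment"))
  bi <- as.data.table(bin_info)
  stopifnot(all(c("state_a", "state_b", "nearest_gene") %in% names(bi)))
  qual <- enrichment$enriched & !enrichment$low_support
  keep <- rep(FALSE, nrow(bi))
  ok <- !is.na(bi$state_a) & !is.na(bi$state_b) &
    bi$state_a %in% rownames(qual) & bi$state_b %in% colnames(qual)
  keep[ok] <- qual[cbind(bi$state_a[ok], bi$state_b[ok])]
  genes <- sort(unique(bi$nearest_gene[keep & !is.na(bi$nearest_gene)]))
  if (length(genes) == 0)
    warning("no enriched, adequately supported transition cells")
  genes
}

#' Write an enrichment matrix and its flags as TSV
#'
#' @param enrichment a `chromhmm_enrichment`
#' @param ratio_path,flags_path output paths
#' @return `ratio_path`, invisibly.
#' @export
write_enrichment <- function(enrichment, ratio_path, flags_path) {
  rm_ <- enrichment$ratio
  out <- data.table(state_a = rownames(rm_))
  out <- cbind(out, as.data.table(rm_))
  fwrite(out, ratio_path, sep = "\t", na = "NA")
  idx <- which(!enrichment$absent, arr.ind = TRUE)
  flags <- data.table(
    state_a = rownames(rm_)[idx[, 1]], state_b = colnames(rm_)[idx[, 2]],
    n_assoc = enrichment$n_assoc[idx], ratio = rm_[idx],
    enriched = enrichment$enriched[idx],
    low_support = enrichment$low_support[idx],
    infinite = enrichment$infinite[idx])
  fwrite(flags, flags_path, sep = "\t", na = "NA")
  invisible(ratio_path)
}
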