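#' @title Methylation call records
#' @description Internal record table: one row per CpG site per sample, with
#'   0-based plus-strand positions and read counts. All parsers normalize
#'   into this shape; all coordinates in the package are 0-based half-open
#'   (BED convention).
#' @param sample_id,chrom,pos,n_meth,n_unmeth vectors of equal length
#' @return A `data.table` with class `meth_records`, sorted by
#'   (chrom, pos) in natural chromosome order.
#' @keywords internal
#' @export
new_meth_records <- function(sample_id, chrom, pos, n_meth, n_unmeth) {
  dt <- data.table(sample_id = as.character(sample_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   n_meth = as.integer(n_meth),
                   n_unmeth = as.integer(n_unmeth))
  validate_meth_records(dt)
  dt <- dt[order_genomic(chrom, pos)]
  setattr(dt, "class", c("meth_records", class(dt)))
  dt[]
}

#' Validate a methylation record table
#'
#' Checks the record invariants: non-negative counts, no NA positions, and
#' positions unique per (sample_id, chrom).
#'
#' @param dt a record table as produced by the parsers
#' @return `dt`, invisibly, or an error.
#' @export
validate_meth_records <- function(dt) {
  stopifnot(is.data.frame(dt),
            all(c("sample_id", "chrom", "pos", "n_meth", "n_unmeth") %in%
                  names(dt)))
  if (anyNA(dt$pos) || anyNA(dt$n_meth) || anyNA(dt$n_unmeth))
    stop("methylation records contain missing fields")
  if (any(dt$n_meth < 0) || any(dt$n_unmeth < 0))
    stop("negative read counts in methylation records")
  if (any(dt$pos < 0)) stop("negative positions in methylation records")
  if (anyDuplicated(dt[, c("sample_id", "chrom", "pos")]))
    stop("duplicate positions per (sample_id, chrom) after strand collapsing")
  invisible(dt)
}

# Collapse CpG dyads onto the plus-strand C and sum counts. `pos0` must
# already be the 0-based plus-strand C position for every row.
#' @noRd
collapse_records <- function(sample_id, chrom, pos0, n_meth, n_unmeth) {
  dt <- data.table(sample_id = sample_id, chrom = chrom, pos = pos0,
                   n_meth = n_meth, n_unmeth = n_unmeth)
  dt <- dt[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
           by = .(sample_id, chrom, pos)]
  new_meth_records(dt$sample_id, dt$chrom, dt$pos, dt$n_meth, dt$n_unmeth)
}

#' Read a Bismark-style cytosine report
#'
#' Tab-separated columns: chromosome, 1-based position, strand, methylated
#' count, unmethylated count, context (and optionally the trinucleotide).
#' Only CpG-context rows are consumed. Positions are converted to 0-based
#' and, when `collapse_strands` is `TRUE` (the default and the standard
#' WGBS practice), minus-strand calls are added onto the plus-strand C of
#' the dyad (1-based G at p collapses to 0-based C at p - 2).
#'
#' @param path file path
#' @param sample_id identifier attached to every record
#' @param collapse_strands collapse CpG dyads onto the plus-strand C?
#' @return A `meth_records` table (possibly empty).
#' @export
read_cytosine_report <- function(path, sample_id, collapse_strands = TRUE) {
  if (file.size(path) == 0)
    return(new_meth_records(character(), character(), integer(),
                            integer(), integer()))
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = "character", showProgress = FALSE)
  if (nrow(dt) == 0)
    return(new_meth_records(character(), character(), integer(),
                            integer(), integer()))
  if (ncol(dt) < 6)
    stop("cytosine report needs >= 6 tab-separated columns, found ",
         ncol(dt))
  pos1 <- suppressWarnings(as.integer(dt[[2]]))
  nm <- suppressWarnings(as.integer(dt[[4]]))
  nu <- suppressWarnings(as.integer(dt[[5]]))
  strand <- dt[[3]]
  bad <- which(is.na(pos1) | is.na(nm) | is.na(nu) |
                 !(strand %in% c("+", "-")) | dt[[1]] == "")
  if (length(bad))
    stop("parse error in cytosine report at line ", bad[1])
  if (any(nm < 0) || any(nu < 0))
    stop("negative counts in cytosine report at line ",
         which(nm < 0 | nu < 0)[1])
  keep <- dt[[6]] %in% c("CG", "CpG")
  if (!any(keep))
    return(new_meth_records(character(), character(), integer(),
                            integer(), integer()))
  chrom <- dt[[1]][keep]
  pos0 <- pos1[keep] - 1L
  strand <- strand[keep]
  if (collapse_strands) {
    pos0[strand == "-"] <- pos0[strand == "-"] - 1L
  }
  collapse_records(sample_id, chrom, pos0, nm[keep], nu[keep])
}

#' Read a bedMethyl file
#'
#' Standard bedMethyl (BED9+2): 0-based half-open interval of the cytosine,
#' column 10 valid coverage, column 11 percent methylated. The methylated
#' count is reconstructed as `round(coverage * percent / 100)`. Zero-coverage
#' rows are retained with undefined beta. Minus-strand rows collapse to the
#' plus-strand C of the dyad when `collapse_strands = TRUE`.
#'
#' @inheritParams read_cytosine_report
#' @return A `meth_records` table.
#' @export
read_bedmethyl <- function(path, sample_id, collapse_strands = TRUE) {
  if (file.size(path) == 0)
    return(new_meth_records(character(), character(), integer(),
                            integer(), integer()))
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              showProgress = FALSE)
  if (nrow(dt) == 0)
    return(new_meth_records(character(), character(), integer(),
                            integer(), integer()))
  if (ncol(dt) < 11)
    stop("bedMethyl needs >= 11 columns, found ", ncol(dt))
  cov <- suppressWarnings(as.integer(dt[[10]]))
  pct <- suppressWarnings(as.numeric(dt[[11]]))
  if (anyNA(cov) || anyNA(pct))
    stop("parse error in bedMethyl at line ", which(is.na(cov) | is.na(pct))[1])
  if (any(pct < 0 | pct > 100))
    stop("percent methylated outside [0,100] at line ",
         which(pct < 0 | pct > 100)[1])
  if (any(cov < 0)) stop("negative coverage in bedMethyl")
  pos0 <- as.integer(dt[[2]])
  strand <- if (ncol(dt) >= 6) as.character(dt[[6]]) else rep("+", nrow(dt))
  if (collapse_strands) pos0[strand == "-"] <- pos0[strand == "-"] - 1L
  n_meth <- as.integer(round(cov * pct / 100))
  collapse_records(sample_id, dt[[1]], pos0, n_meth, cov - n_meth)
}

#' Write methylation records as bedMethyl
#'
#' @param records a `meth_records` table for a single sample
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(records, path) {
  validate_meth_records(records)
  cov <- records$n_meth + records$n_unmeth
  pct <- ifelse(cov > 0, 100 * records$n_meth / cov, 0)
  out <- data.table(records$chrom, records$pos, records$pos + 1L, "CpG",
                    pmin(cov, 1000L), "+", records$pos, records$pos + 1L,
                    "0,0,0", cov, round(pct, 2))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a feature BED track
#'
#' BED3+ with optional name (4), score (5) and strand (6) columns; gene
#' tracks may carry BED12 block columns (10-12), used to locate first
#' exons/introns. chromHMM tracks keep the 4th column verbatim as the state
#' label. Gene tracks get a strand-aware `tss` column (interval start on
#' `+`, `end - 1` on `-`). Unsorted input is sorted with a warning.
#'
#' @param path BED file path
#' @param kind one of `"gene"`, `"cpg_island"`, `"chromhmm"`
#' @return A `data.table` with class `feature_track` and attribute `kind`;
#'   columns `chrom`, `start`, `end`, `name`, `strand` (genes), `state`
#'   (chromhmm), `tss` (genes) and a `blocks` list column when BED12 blocks
#'   are present.
#' @export
read_feature_bed <- function(path, kind = c("gene", "cpg_island", "chromhmm")) {
  kind <- match.arg(kind)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              showProgress = FALSE)
  if (nrow(dt) == 0) {
    tr <- data.table(chrom = character(), start = integer(), end = integer(),
                     name = character(), strand = character())
    return(as_feature_track(tr, kind))
  }
  if (ncol(dt) < 3) stop("BED needs >= 3 columns")
  tr <- data.table(chrom = as.character(dt[[1]]),
                   start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]))
  tr$name <- if (ncol(dt) >= 4) as.character(dt[[4]]) else
    sprintf("feature_%06d", seq_len(nrow(tr)))
  tr$strand <- if (ncol(dt) >= 6) as.character(dt[[6]]) else "+"
  if (ncol(dt) >= 12) {
    sizes <- lapply(strsplit(as.character(dt[[11]]), ","), as.integer)
    offs <- lapply(strsplit(as.character(dt[[12]]), ","), as.integer)
    tr$blocks <- Map(function(s, o, st) {
      if (length(s) == 0 || anyNA(s)) return(NULL)
      data.table(start = st + o, end = st + o + s)
    }, sizes, offs, tr$start)
  }
  as_feature_track(tr, kind)
}

#' @noRd
as_feature_track <- function(tr, kind) {
  if (any(tr$start >= tr$end) && nrow(tr) > 0)
    stop("feature with start >= end in ", kind, " track")
  if (!all(tr$strand %in% c("+", "-", "."))) stop("invalid strand field")
  ord <- order_genomic(tr$chrom, tr$start)
  if (is.unsorted(ord)) {
    warning("unsorted ", kind, " track; sorting")
    tr <- tr[ord]
  }
  if (kind == "gene" && nrow(tr) > 0)
    tr[, tss := ifelse(strand == "-", end - 1L, start)]
  if (kind == "chromhmm") setnames(tr, "name", "state")
  setattr(tr, "kind", kind)
  setattr(tr, "class", c("feature_track", class(tr)))
  tr[]
}

#' Write a deduplicated, alphabetically sorted gene list
#'
#' One symbol per line, the format pasted into web enrichment tools.
#'
#' @param genes character vector of gene symbols
#' @param path output path
#' @return `path`, invisibly; warns and writes an empty file for an empty
#'   list.
#' @export
write_gene_list <- function(genes, path) {
  genes <- sort(unique(as.character(genes[!is.na(genes)])))
  if (length(genes) == 0) {
    warning("empty gene list written to ", path)
    file.create(path)
  } else {
    writeLines(genes, path)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with header; required columns `sample_id`, `subject_id`, `sex`
#' (male/female), `sample_type` (tissue/cfDNA), `fibrosis_stage` (0-4).
#' Extra clinical covariates are carried through. A `base_group` column
#' (sex x sample type) is added.
#'
#' @param path TSV path
#' @return A `data.table` of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- fread(path, header = TRUE, sep = "\t", showProgress = FALSE)
  validate_sample_metadata(md)
}

#' Validate sample metadata
#'
#' @param md a data.frame of sample metadata
#' @return The validated table with a `base_group` column, invisibly usable.
#' @export
validate_sample_metadata <- function(md) {
  md <- as.data.table(md)
  req <- c("sample_id", "subject_id", "sex", "sample_type", "fibrosis_stage")
  if (!all(req %in% names(md)))
    stop("metadata must contain columns: ", paste(req, collapse = ", "))
  if (!all(md$sex %in% c("male", "female"))) stop("sex must be male/female")
  if (!all(md$sample_type %in% c("tissue", "cfDNA")))
    stop("sample_type must be tissue/cfDNA")
  if (!all(md$fibrosis_stage %in% 0:4))
    stop("fibrosis_stage must be an integer in 0..4")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md[, base_group := base_group_of(sex, sample_type)]
  md[]
}
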