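#' Pipeline configuration
#'
#' Collects every tunable threshold with the defaults used throughout the
#' analysis: 65-bp bin gap, alpha 0.05 (0.01 extended), at least 4
#' individuals and 3 unique beta values per screened bin, 1500-bp TSS
#' window, 1.5-fold transition enrichment on at least 30 bins, fibrosis
#' dichotomized at stage 2.
#'
#' @param input named list of input paths (`methylation` = named vector of
#'   per-sample report paths, `metadata`, `genes`, `islands`, `chromhmm` =
#'   named vector of two BEDs, `atlas`, `atlas_betas`); leave `NULL` to
#'   simulate instead
#' @param outdir output directory
#' @param seed integer seed for the simulated inputs
#' @param ... overrides for the parameter defaults
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, outdir = tempfile("methbin_run"),
                            seed = 1L, ...) {
  cfg <- list(input = input, outdir = outdir, seed = as.integer(seed),
              max_gap = 65L, alpha = 0.05, alpha_extended = 0.01,
              min_individuals = 4L, min_unique = 3L, tss_window = 1500L,
              fold = 1.5, min_bins = 30L, fibrosis_cut = 2L,
              priority = c("tissue", "cfDNA", "sex"),
              sim = list())
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown pipeline parameter: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with any subset of [pipeline_config()] fields
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- js[setdiff(names(js), c("input", "outdir", "seed"))]
  do.call(pipeline_config,
          c(list(input = js$input,
                 outdir = if (is.null(js$outdir)) tempfile("methbin_run")
                          else js$outdir,
                 seed = if (is.null(js$seed)) 1L else js$seed),
            args))
}

#' @noRd
load_pipeline_inputs <- function(cfg) {
  if (is.null(cfg$input)) {
    sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    genome <- generate_genome(sc)
    cohort <- generate_cohort(sc, genome)
    mix <- generate_atlas_and_mixtures(
      sc, stages = cohort$metadata[sample_type == "cfDNA", fibrosis_stage],
      sample_ids = cohort$metadata[sample_type == "cfDNA", sample_id])
    list(metadata = cohort$metadata, records = cohort$records,
         genes = genome$genes, islands = genome$islands,
         chromhmm = genome$chromhmm, atlas = mix$atlas,
         atlas_betas = mix$betas, truth = cohort$truth)
  } else {
    inp <- cfg$input
    recs <- rbindlist(lapply(names(inp$methylation), function(s) {
      p <- inp$methylation[[s]]
      if (grepl("\\.bed(methyl)?$", p)) read_bedmethyl(p, s)
      else read_cytosine_report(p, s)
    }))
    hmm <- lapply(inp$chromhmm, read_feature_bed, kind = "chromhmm")
    list(metadata = read_sample_metadata(inp$metadata),
         records = new_meth_records(recs$sample_id, recs$chrom, recs$pos,
                                    recs$n_meth, recs$n_unmeth),
         genes = read_feature_bed(inp$genes, "gene"),
         islands = read_feature_bed(inp$islands, "cpg_island"),
         chromhmm = hmm,
         atlas = if (!is.null(inp$atlas)) read_atlas(inp$atlas) else NULL,
         atlas_betas = if (!is.null(inp$atlas_betas)) {
           dt <- fread(inp$atlas_betas)
           m <- as.matrix(dt[, -1, with = FALSE]); rownames(m) <- dt[[1]]
           m
         } else NULL,
         truth = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Stages, in order: bin construction, bin beta matrix, Kendall screening
#' in the four base groups, intersection labeling, annotation (nearest
#' gene, TSS/island flags, chromHMM states), pathway gene-list export,
#' intergenic chromHMM transition enrichment (fibrosis-associated versus
#' unassociated intergenic bins), reference-atlas deconvolution and
#' low/high-fibrosis comparison per cell type. Every stage writes a plain
#' TSV under `outdir` and is recorded, with an md5 checksum, in
#' `manifest.json`; filter counts go to the log (stderr).
#'
#' @param cfg a [pipeline_config()] (or a JSON path readable by
#'   [read_pipeline_config()])
#' @return The manifest, invisibly: list of stage outputs with checksums.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  paths <- character()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inp <- stage("load", load_pipeline_inputs(cfg))
  fwrite(inp$metadata, out("metadata.tsv"), sep = "\t")
  paths["metadata"] <- out("metadata.tsv")

  bins <- stage("bin", build_bins(
    unique(as.data.table(inp$records)[, .(chrom, pos)]),
    max_gap = cfg$max_gap))
  message("built ", nrow(bins), " bins")
  write_bin_bed(bins, out("bins.bed")); paths["bins"] <- out("bins.bed")

  bbm <- stage("beta", compute_bin_beta(inp$records, bins))
  write_beta_matrix(bbm, out("beta_matrix.tsv"))
  paths["beta_matrix"] <- out("beta_matrix.tsv")

  screens <- stage("screen", screen_all_groups(
    bbm, inp$metadata, alpha = cfg$alpha,
    min_individuals = cfg$min_individuals, min_unique = cfg$min_unique))
  for (g in base_groups())
    message(g, ": ", sum(!screens[[g]]$filtered), " tested, ",
            sum(screens[[g]]$significant), " significant")
  fwrite(rbindlist(screens), out("screening.tsv"), sep = "\t", na = "NA")
  paths["screening"] <- out("screening.tsv")

  labels <- stage("label", label_all_bins(screens, priority = cfg$priority))
  fwrite(labels, out("labels.tsv"), sep = "\t")
  paths["labels"] <- out("labels.tsv")

  ann <- stage("annotate", annotate_bins(
    bins, inp$genes, inp$islands, inp$chromhmm,
    tss_window = cfg$tss_window))
  fwrite(ann, out("annotation.tsv"), sep = "\t", na = "NA")
  paths["annotation"] <- out("annotation.tsv")

  stage("genelists", {
    for (lb in c("Tissue", "cfDNA", "Male", "Female", "All")) {
      mode <- if (lb == "Tissue") "tissue_strict" else "or_relaxed"
      gl <- suppressWarnings(select_pathway_input(labels, ann, lb, mode))
      f <- out(paste0("genes_", lb, ".txt"))
      suppressWarnings(write_gene_list(gl, f))
      paths[paste0("genes_", lb)] <- f
    }
    gl <- suppressWarnings(select_pathway_input(
      labels, ann, "Tissue", "extended", screen_results = screens,
      alpha_extended = cfg$alpha_extended))
    suppressWarnings(write_gene_list(gl, out("genes_Tissue_extended.txt")))
    paths["genes_Tissue_extended"] <- out("genes_Tissue_extended.txt")
  })

  enr <- stage("enrich-chromhmm", {
    sc <- names(inp$chromhmm)[1:2]
    sa <- ann[[paste0("state_", sc[1])]]; sb <- ann[[paste0("state_", sc[2])]]
    sig_any <- Reduce(`|`, lapply(screens, `[[`, "significant"))
    assoc_i <- which(labels$label != "none" & ann$intergenic)
    bg_i <- which(!sig_any & ann$intergenic)
    if (length(assoc_i) == 0 || length(bg_i) == 0) {
      message("skipping transition enrichment: no ",
              if (length(assoc_i) == 0) "associated" else "background",
              " intergenic bins")
      NULL
    } else {
      e <- compute_enrichment(
        build_transition_table(sa[assoc_i], sb[assoc_i],
                               group = "associated"),
        build_transition_table(sa[bg_i], sb[bg_i], group = "background"),
        fold = cfg$fold, min_bins = cfg$min_bins)
      write_enrichment(e, out("enrichment_ratio.tsv"),
                       out("enrichment_flags.tsv"))
      paths["enrichment_ratio"] <- out("enrichment_ratio.tsv")
      paths["enrichment_flags"] <- out("enrichment_flags.tsv")
      bi <- data.table(bin_index = labels$bin_index[assoc_i],
                       state_a = sa[assoc_i], state_b = sb[assoc_i],
                       nearest_gene = ann$nearest_gene[assoc_i])
      gl <- suppressWarnings(enriched_gene_list(e, bi))
      suppressWarnings(write_gene_list(gl, out("genes_enriched.txt")))
      paths["genes_enriched"] <- out("genes_enriched.txt")
      e
    }
  })

  if (!is.null(inp$atlas) && !is.null(inp$atlas_betas)) {
    stage("deconvolve", {
      dec <- deconvolve_samples(inp$atlas, inp$atlas_betas)
      pt <- data.table(sample_id = rownames(dec$proportions))
      pt <- cbind(pt, as.data.table(dec$proportions))
      fwrite(pt, out("proportions.tsv"), sep = "\t")
      paths["proportions"] <- out("proportions.tsv")
      cmp <- rbindlist(lapply(colnames(dec$proportions), function(ct) {
        r <- tryCatch(
          compare_proportions_by_fibrosis(dec$proportions, inp$metadata,
                                          ct, cfg$fibrosis_cut),
          error = function(e) NULL)
        if (is.null(r)) NULL else data.table(cell_type = ct,
                                             p_value = r$p_value,
                                             n_low = r$n_low,
                                             n_high = r$n_high,
                                             median_low = r$median_low,
                                             median_high = r$median_high)
      }))
      fwrite(cmp, out("proportion_comparison.tsv"), sep = "\t")
      paths["proportion_comparison"] <- out("proportion_comparison.tsv")
    })
  }

  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[c("max_gap", "alpha", "alpha_extended",
                       "min_individuals", "min_unique", "tss_window",
                       "fold", "min_bins", "fibrosis_cut")],
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message("pipeline complete; manifest at ", out("manifest.json"))
  invisible(manifest)
}
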