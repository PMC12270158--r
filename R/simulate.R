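#' Simulation configuration
#'
#' Defaults emulate the study cohort: 38 subjects (18 male / 20 female),
#' fibrosis-stage margins 0/7/7/3/1 (male) and 2/8/4/5/1 (female), 30
#' paired tissue+cfDNA subjects with 2 male cfDNA-only, 2 male and 4 female
#' tissue-only. CpG positions come from a two-component gap mixture (dense
#' island clusters, geometric open-sea gaps) so the 65-bp rule yields both
#' multi-CpG bins and singletons. Coverage is negative binomial, 30x mean
#' for tissue and 10x for cfDNA (dispersion 0.3); bin baselines are bimodal
#' on the logit scale (hypomethylated islands, methylated open sea), and
#' subject-level noise enters on the logit scale (sd 0.1, about 0.025 on
#' the beta scale at mid-range) before binomial read sampling. Planted
#' effects shift the mean beta by `delta * stage` in exactly the base
#' groups a target label implies.
#'
#' @param seed integer RNG seed; all generator output is deterministic
#'   given the config
#' @param ... overrides for any default field
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = 38L,
    stage_margins = list(male = c(`0` = 0L, `1` = 7L, `2` = 7L, `3` = 3L,
                                  `4` = 1L),
                         female = c(`0` = 2L, `1` = 8L, `2` = 4L, `3` = 5L,
                                    `4` = 1L)),
    pairing = list(male = c(paired = 14L, tissue_only = 2L, cfdna_only = 2L),
                   female = c(paired = 16L, tissue_only = 4L,
                              cfdna_only = 0L)),
    n_chromosomes = 2L,
    n_cpgs = 10000L,
    island = list(rate = 0.03, cpgs_mean = 20, min_cpgs = 5, gap_mean = 18),
    opensea_gap_mean = 300,
    coverage = list(tissue = 30, cfDNA = 10, dispersion = 0.3),
    baseline = list(island_mu = -1.6, opensea_mu = 1.6, sd = 0.5),
    noise_sd = 0.1,
    max_gap = 65L,
    min_plant_cpgs = 10L,
    effects = data.table(
      target_label = rep(c("Tissue", "cfDNA", "Male", "Female", "All"), 2),
      delta = 0.08,
      direction = rep(c(1, -1), each = 5)),
    genes = list(n = 60L, tss_island_frac = 0.5,
                 len_range = c(3000L, 12000L)),
    celltypes = c("cellA", "cellB"),
    atlas = list(K = 10L, M = 500L, separation = 0.5, noise_sd = 0.02,
                 hepatocyte_base = 0.2, fibrosis_shift = 0.15,
                 dirichlet = 1, weight_noise_sd = 0.02)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !is.data.frame(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  if (sum(unlist(cfg$stage_margins)) != cfg$n_subjects)
    stop("stage margins must sum to n_subjects")
  for (s in c("male", "female"))
    if (sum(cfg$pairing[[s]]) != sum(cfg$stage_margins[[s]]))
      stop("pairing counts must sum to the ", s, " margin")
  if (!is.null(cfg$effects) && nrow(cfg$effects) > 0 &&
      any(abs(cfg$effects$delta) > 0.25))
    stop("per-stage beta shift delta must lie in [-0.25, 0.25]")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome: CpG positions and feature tracks
#'
#' CpG sites are laid down in units: with probability `island$rate` a dense
#' cluster (Poisson size around `island$cpgs_mean`, internal gaps well
#' under 65 bp, recorded in the island track), otherwise a single site;
#' consecutive units are separated by geometric open-sea gaps (mean
#' `opensea_gap_mean`), occasionally short enough to merge. Gene models
#' (BED12-style blocks, random strand) put a fraction of TSSs at island
#' starts; chromHMM tracks tile each chromosome per cell type.
#'
#' @param config a [sim_config()]
#' @return List with `cpgs` (data.table chrom/pos), `islands`, `genes`
#'   (feature tracks), `chromhmm` (named list of tracks) and
#'   `chrom_lengths`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_chr <- config$n_chromosomes
    per_chrom <- if (n_chr > 0) ceiling(config$n_cpgs / n_chr) else 0L
    cpgs <- list(); islands <- list(); lens <- integer(0)
    for (ci in seq_len(n_chr)) {
      ch <- paste0("chr", ci)
      pos <- integer(0); isl <- list(); cur <- 1000L
      while (length(pos) < per_chrom && config$n_cpgs > 0) {
        if (runif(1) < config$island$rate) {
          m <- max(config$island$min_cpgs,
                   rpois(1, config$island$cpgs_mean))
          gaps <- pmin(rgeom(m - 1, 1 / config$island$gap_mean) + 2L, 60L)
          ps <- cur + cumsum(c(0L, gaps))
          isl[[length(isl) + 1L]] <-
            data.table(chrom = ch, start = ps[1], end = ps[m] + 2L)
        } else ps <- cur
        pos <- c(pos, ps)
        cur <- pos[length(pos)] +
          rgeom(1, 1 / config$opensea_gap_mean) + 1L
      }
      pos <- head(pos, per_chrom)
      cpgs[[ci]] <- data.table(chrom = ch, pos = pos)
      islands[[ci]] <- rbindlist(isl)
      lens[ch] <- if (length(pos)) pos[length(pos)] + 5000L else 10000L
    }
    cpgs <- rbindlist(cpgs)
    if (nrow(cpgs) == 0) cpgs <- data.table(chrom = character(),
                                            pos = integer())
    islands <- rbindlist(islands)
    if (nrow(islands) == 0)
      islands <- data.table(chrom = character(), start = integer(),
                            end = integer())
    islands[, `:=`(name = sprintf("island_%05d", seq_len(.N)),
                   strand = ".")]
    islands <- as_feature_track(islands, "cpg_island")
    genes <- synth_genes(config, islands, lens)
    hmm <- lapply(config$celltypes, function(ct) synth_chromhmm(lens))
    names(hmm) <- config$celltypes
    list(cpgs = cpgs, islands = islands, genes = genes, chromhmm = hmm,
         chrom_lengths = lens)
  })
}

#' @noRd
synth_genes <- function(config, islands, lens) {
  n <- config$genes$n
  if (n == 0 || length(lens) == 0 || config$n_cpgs == 0) {
    tr <- data.table(chrom = character(), start = integer(),
                     end = integer(), name = character(),
                     strand = character())
    return(as_feature_track(tr, "gene"))
  }
  n_isl <- round(n * config$genes$tss_island_frac)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    strand <- sample(c("+", "-"), 1)
    L <- round(runif(1, config$genes$len_range[1], config$genes$len_range[2]))
    if (i <= n_isl && nrow(islands) > 0) {
      k <- sample(nrow(islands), 1)
      tss <- if (strand == "+") islands$start[k] else islands$end[k] - 1L
      ch <- islands$chrom[k]
    } else {
      ch <- sample(names(lens), 1)
      tss <- round(runif(1, 2000, max(3000, lens[ch] - 2000)))
    }
    gs <- if (strand == "+") tss else tss - L + 1L
    ge <- gs + L
    gs <- max(0L, as.integer(gs)); ge <- as.integer(max(ge, gs + 200L))
    e1 <- round(runif(1, 150, 400)); i1 <- round(0.25 * (ge - gs))
    e2 <- 200L; e3 <- 300L
    i2 <- (ge - gs) - e1 - i1 - e2 - e3
    blocks <- if (i2 > 0)
      data.table(start = gs + c(0L, e1 + i1, e1 + i1 + e2 + i2),
                 end = gs + c(e1, e1 + i1 + e2, ge - gs))
    else data.table(start = gs, end = ge)
    rows[[i]] <- data.table(chrom = ch, start = gs, end = ge,
                            name = sprintf("GENE%04d", i), strand = strand,
                            blocks = list(blocks))
  }
  suppressWarnings(as_feature_track(rbindlist(rows), "gene"))
}

# Quiescent-heavy state composition, geometric segment lengths on a 200-bp
# grid, tiling the chromosome.
#' @noRd
synth_chromhmm <- function(lens) {
  states <- chromhmm_states()
  probs <- c(0.05, 0.03, 0.01, 0.07, 0.08, 0.02, 0.10, 0.01, 0.10,
             0.01, 0.01, 0.02, 0.02, 0.04, 0.43)
  rows <- lapply(names(lens), function(ch) {
    brk <- 0L; out <- list()
    while (brk < lens[ch]) {
      w <- 200L * (1L + rgeom(1, 0.1))
      out[[length(out) + 1L]] <-
        data.table(chrom = ch, start = brk,
                   end = min(brk + w, lens[ch]),
                   name = sample(states, 1, prob = probs), strand = ".")
      brk <- brk + w
    }
    rbindlist(out)
  })
  as_feature_track(rbindlist(rows), "chromhmm")
}

#' Generate the cohort metadata table
#'
#' Subjects receive sex, fibrosis stage (per-sex margins) and pairing
#' status; each subject contributes a tissue sample, a cfDNA sample, or
#' both. Clinical covariates (diabetes, BMI) are decorative.
#'
#' @param config a [sim_config()]
#' @return A validated metadata `data.table`.
#' @export
generate_metadata <- function(config) {
  rows <- list()
  sid <- 0L
  for (s in c("male", "female")) {
    stages <- sample(rep(0:4, config$stage_margins[[s]]))
    status <- sample(rep(names(config$pairing[[s]]), config$pairing[[s]]))
    for (i in seq_along(stages)) {
      sid <- sid + 1L
      subj <- sprintf("S%02d", sid)
      types <- switch(status[i], paired = c("tissue", "cfDNA"),
                      tissue_only = "tissue", cfdna_only = "cfDNA")
      for (ty in types)
        rows[[length(rows) + 1L]] <- data.table(
          sample_id = paste0(subj, "_", ty), subject_id = subj, sex = s,
          sample_type = ty, fibrosis_stage = stages[i],
          diabetes = sample(c("yes", "no"), 1),
          bmi = round(rnorm(1, 29.4, 3), 1))
    }
  }
  validate_sample_metadata(rbindlist(rows))
}

#' @noRd
label_target_groups <- function(target_label) {
  switch(target_label,
         Tissue = c("male_tissue", "female_tissue"),
         cfDNA = c("male_cfDNA", "female_cfDNA"),
         Male = c("male_tissue", "male_cfDNA"),
         Female = c("female_tissue", "female_cfDNA"),
         All = base_groups(),
         stop("unknown target label: ", target_label))
}

#' Generate a cohort of methylation records with planted effects
#'
#' Bins are built from the genome's CpG positions; each bin gets a bimodal
#' logit-scale baseline (islands low, open sea high) and each subject a
#' per-bin logit-normal deviation shared between that subject's tissue and
#' cfDNA samples. Planted bins (drawn from bins with at least
#' `min_plant_cpgs` CpGs, so they pass the association filters by
#' construction) shift the sample's mean beta by
#' `direction * delta * stage` in exactly the base groups implied by their
#' target label. Per-CpG coverage is negative binomial by sample type and
#' methylated counts binomial given the bin beta.
#'
#' @param config a [sim_config()]
#' @param genome output of [generate_genome()] under the same config
#' @return List with `metadata`, `records` (a `meth_records` table over
#'   all samples), `bins`, and `truth` (planted bins with labels and
#'   effect sizes).
#' @export
generate_cohort <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    md <- generate_metadata(config)
    bins <- build_bins(genome$cpgs, max_gap = config$max_gap)
    nb <- nrow(bins)
    effects <- as.data.table(config$effects)
    if (nrow(effects) > 0) {
      eligible <- bins$bin_index[bins$n_cpg >= config$min_plant_cpgs]
      if (length(eligible) < nrow(effects))
        stop("not enough bins with >= ", config$min_plant_cpgs,
             " CpGs to plant ", nrow(effects), " effects")
      effects[, bin_index := sample(eligible, nrow(effects))]
    } else effects <- data.table(target_label = character(),
                                 delta = numeric(), direction = numeric(),
                                 bin_index = integer())
    if (nrow(effects) > 0 && any(!effects$bin_index %in% bins$bin_index))
      stop("planted bin index out of range")

    gr_bins <- as_granges0(bins$chrom, bins$start, bins$end)
    isl <- as.data.table(genome$islands)
    in_island <- if (nrow(isl) > 0)
      IRanges::overlapsAny(gr_bins, as_granges0(isl$chrom, isl$start,
                                                isl$end))
    else rep(FALSE, nb)
    mu <- rnorm(nb,
                ifelse(in_island, config$baseline$island_mu,
                       config$baseline$opensea_mu),
                config$baseline$sd)
    # planted baselines leave headroom for delta * stage in either direction
    for (k in seq_len(nrow(effects))) {
      i <- match(effects$bin_index[k], bins$bin_index)
      b0 <- if (effects$direction[k] > 0) runif(1, 0.15, 0.5) else
        runif(1, 0.5, 0.85)
      mu[i] <- log(b0 / (1 - b0))
    }
    subjects <- unique(md$subject_id)
    U <- matrix(rnorm(nb * length(subjects), 0, config$noise_sd), nb,
                dimnames = list(NULL, subjects))
    cpg_bin <- rep(bins$bin_index, bins$n_cpg)  # genomic order of bins' CpGs
    cpg_chrom <- rep(bins$chrom, bins$n_cpg)
    cpg_pos <- unlist(bins$cpgs, use.names = FALSE)
    n_cpg_tot <- length(cpg_pos)
    size <- 1 / config$coverage$dispersion
    recs <- vector("list", nrow(md))
    for (r in seq_len(nrow(md))) {
      beta <- stats::plogis(mu + U[, md$subject_id[r]])
      for (k in seq_len(nrow(effects))) {
        if (md$base_group[r] %in% label_target_groups(effects$target_label[k])) {
          i <- match(effects$bin_index[k], bins$bin_index)
          beta[i] <- beta[i] + effects$direction[k] * effects$delta[k] *
            md$fibrosis_stage[r]
        }
      }
      beta <- pmin(pmax(beta, 0), 1)
      cov_mean <- config$coverage[[md$sample_type[r]]]
      cov <- rnbinom(n_cpg_tot, mu = cov_mean, size = size)
      nm <- rbinom(n_cpg_tot, cov, beta[match(cpg_bin, bins$bin_index)])
      recs[[r]] <- data.table(sample_id = md$sample_id[r],
                              chrom = cpg_chrom, pos = cpg_pos,
                              n_meth = nm, n_unmeth = cov - nm)
    }
    rec <- rbindlist(recs)
    rec <- new_meth_records(rec$sample_id, rec$chrom, rec$pos,
                            rec$n_meth, rec$n_unmeth)
    list(metadata = md, records = rec, bins = bins, truth = effects[])
  })
}

#' Generate a reference atlas and synthetic mixtures with known weights
#'
#' Marker betas are near 0/1 (every row spread comfortably above the
#' configured separation); each cell type owns a share of markers. Sample
#' weights put `hepatocyte_base` (+ `fibrosis_shift` for high-fibrosis
#' samples, stage >= 2) on the hepatocyte compartment, with the remainder
#' Dirichlet-distributed over the other cell types. Observed betas are
#' `A %*% w` plus clipped Gaussian noise.
#'
#' @param config a [sim_config()]
#' @param stages integer vector of fibrosis stages, one per sample to
#'   simulate (default: 20 samples, stages recycled over 0..4)
#' @param sample_ids optional sample names
#' @return List with `atlas` (a `reference_atlas`), `weights` (samples x
#'   cell types, the ground truth), `betas` (markers x samples), `stages`.
#' @export
generate_atlas_and_mixtures <- function(config, stages = NULL,
                                        sample_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ac <- config$atlas
  if (ac$K < 2) stop("need at least 2 cell types")
  if (ac$M < ac$K) stop("need at least as many markers as cell types")
  if (ac$separation > 0.8)
    stop("separation ", ac$separation, " infeasible for near-0/1 markers")
  with_seed(config$seed + 2L, {
    pool <- c("hepatocyte", "Tcell", "monocyte", "granulocyte", "Bcell",
              "NKcell", "endothelial", "smooth_muscle",
              "kidney_epithelial", "pancreas_alpha", "adipocyte",
              "colon_epithelial")
    cts <- if (ac$K <= length(pool)) pool[seq_len(ac$K)] else
      c(pool, sprintf("cell_%02d", seq_len(ac$K - length(pool))))
    A <- matrix(runif(ac$M * ac$K, 0.02, 0.12), ac$M, ac$K,
                dimnames = list(sprintf("marker_%04d", seq_len(ac$M)), cts))
    owner <- rep_len(seq_len(ac$K), ac$M)
    A[cbind(seq_len(ac$M), owner)] <- runif(ac$M, 0.88, 0.98)
    # some markers shared by a second cell type (needs K >= 3 to keep the
    # per-row separation invariant)
    extra <- if (ac$K >= 3) runif(ac$M) < 0.3 else rep(FALSE, ac$M)
    if (any(extra)) {
      second <- (owner[extra] %% ac$K) + 1L
      A[cbind(which(extra), second)] <- runif(sum(extra), 0.88, 0.98)
    }
    atlas <- reference_atlas(A, ac$separation)
    if (is.null(stages)) stages <- rep_len(0:4, 20)
    ns <- length(stages)
    if (is.null(sample_ids)) sample_ids <- sprintf("mix%03d", seq_len(ns))
    h <- pmin(pmax(ac$hepatocyte_base + ac$fibrosis_shift * (stages >= 2) +
                     rnorm(ns, 0, ac$weight_noise_sd), 0), 1)
    W <- matrix(0, ns, ac$K, dimnames = list(sample_ids, cts))
    hep <- match("hepatocyte", cts, nomatch = 1L)
    for (i in seq_len(ns)) {
      g <- rgamma(ac$K - 1, ac$dirichlet)
      W[i, hep] <- h[i]
      W[i, -hep] <- (1 - h[i]) * g / sum(g)
    }
    B <- A %*% t(W) + matrix(rnorm(ac$M * ns, 0, ac$noise_sd), ac$M, ns)
    B <- pmin(pmax(B, 0), 1)
    colnames(B) <- sample_ids
    list(atlas = atlas, weights = W, betas = B, stages = stages)
  })
}
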