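small_cfg <- function(seed = 1, ...) sim_config(seed = seed,
                                                n_cpgs = 1200L, ...)

test_that("generator output is deterministic in the seed", {
  g1 <- generate_genome(small_cfg()); g2 <- generate_genome(small_cfg())
  expect_identical(g1$cpgs, g2$cpgs)
  c1 <- generate_cohort(small_cfg(), g1)
  c2 <- generate_cohort(small_cfg(), g2)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth, c2$truth)
  g3 <- generate_genome(small_cfg(seed = 2))
  expect_false(identical(g1$cpgs, g3$cpgs))
})

test_that("genome has island bins and singletons; tracks are valid", {
  g <- generate_genome(small_cfg())
  bins <- build_bins(g$cpgs)
  expect_true(any(bins$n_cpg >= 5))
  expect_true(any(bins$n_cpg == 1))
  expect_s3_class(g$genes, "feature_track")
  expect_true(all(g$genes$end > g$genes$start))
  # chromHMM tracks tile each chromosome without gaps
  for (tr in g$chromhmm) {
    for (ch in unique(tr$chrom)) {
      seg <- tr[tr$chrom == ch, ]
      expect_equal(seg$start[-1], seg$end[-nrow(seg)])
      expect_true(all(seg$state %in% chromhmm_states()))
    }
  }
  empty <- generate_genome(sim_config(n_cpgs = 0L, genes = list(n = 0L)))
  expect_equal(nrow(empty$cpgs), 0L)
})

test_that("cohort metadata reproduces the study margins", {
  md <- generate_cohort(small_cfg(), generate_genome(small_cfg()))$metadata
  subj <- unique(md[, c("subject_id", "sex", "fibrosis_stage")])
  expect_equal(nrow(subj), 38L)
  expect_equal(sum(subj$sex == "male"), 18L)
  expect_equal(as.integer(table(factor(subj$fibrosis_stage[subj$sex == "male"],
                                       levels = 0:4))),
               c(0L, 7L, 7L, 3L, 1L))
  expect_equal(as.integer(table(factor(subj$fibrosis_stage[subj$sex == "female"],
                                       levels = 0:4))),
               c(2L, 8L, 4L, 5L, 1L))
  paired <- table(table(md$subject_id))
  expect_equal(as.integer(paired["2"]), 30L)  # 30 paired subjects
  expect_equal(as.integer(paired["1"]), 8L)
  expect_equal(sum(md$sample_type == "tissue"), 36L)   # 30 + 2 + 4
  expect_equal(sum(md$sample_type == "cfDNA"), 32L)    # 30 + 2
})

test_that("generated records pass the io validators end to end", {
  co <- generate_cohort(small_cfg(), generate_genome(small_cfg()))
  expect_silent(validate_meth_records(co$records))
  expect_silent(invisible(validate_sample_metadata(co$metadata)))
  # write one sample out and read it back through the parser
  s <- co$metadata$sample_id[1]
  p <- tempfile(fileext = ".bed")
  write_bedmethyl(co$records[co$records$sample_id == s, ], p)
  back <- read_bedmethyl(p, s)
  expect_equal(nrow(back), sum(co$records$sample_id == s))
})

test_that("planted bins pass the association filters by construction", {
  co <- generate_cohort(small_cfg(seed = 7), generate_genome(small_cfg(seed = 7)))
  bbm <- compute_bin_beta(co$records, co$bins)
  scr <- screen_all_groups(bbm, co$metadata)
  for (k in seq_len(nrow(co$truth))) {
    for (g in methbin:::label_target_groups(co$truth$target_label[k])) {
      row <- scr[[g]][bin_index == co$truth$bin_index[k]]
      expect_false(row$filtered)
    }
  }
})

test_that("config validation rejects inconsistent worlds", {
  expect_error(sim_config(n_subjects = 10L), "margins")
  expect_error(sim_config(effects = data.table::data.table(
    target_label = "All", delta = 0.3, direction = 1)), "0.25")
  expect_error(sim_config(bogus_field = 1), "unknown config field")
})

test_that("atlas mixtures: simplex weights, pure samples, fibrosis shift", {
  cfg <- sim_config(seed = 5)
  mix <- generate_atlas_and_mixtures(cfg, stages = rep(0:4, 8))
  expect_equal(unname(rowSums(mix$weights)), rep(1, 40), tolerance = 1e-12)
  expect_true(all(mix$weights >= 0))
  # hepatocyte fraction differs by ~ the configured shift between groups
  hi <- mix$stages >= 2
  d <- mean(mix$weights[hi, "hepatocyte"]) -
    mean(mix$weights[!hi, "hepatocyte"])
  expect_lt(abs(d - 0.15), 0.04)
  # noiseless pure sample equals the atlas column exactly
  cfg2 <- sim_config(seed = 5, atlas = list(K = 2L, M = 20L, noise_sd = 0,
                                            hepatocyte_base = 1,
                                            fibrosis_shift = 0,
                                            weight_noise_sd = 0))
  mix2 <- generate_atlas_and_mixtures(cfg2, stages = 0)
  expect_equal(unname(mix2$betas[, 1]), unname(unclass(mix2$atlas)[, 1]),
               tolerance = 1e-12)
  expect_error(
    generate_atlas_and_mixtures(sim_config(atlas = list(K = 1L))),
    "at least 2")
  expect_error(
    generate_atlas_and_mixtures(sim_config(atlas = list(M = 4L))),
    "markers")
})
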