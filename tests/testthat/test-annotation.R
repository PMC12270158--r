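toy_bins <- function(starts, width = 100L, chrom = "chr1") {
  data.table::data.table(bin_index = seq_along(starts), chrom = chrom,
                         start = as.integer(starts),
                         end = as.integer(starts + width))
}

test_that("nearest gene: distance, overlap, alphabetical tie-break", {
  gt <- make_track("gene", "chr1", c(1000L, 5600L), c(2000L, 6000L),
                   name = c("A", "B"), strand = c("+", "+"))
  ng <- nearest_gene(toy_bins(5000), gt)
  expect_equal(ng$nearest_gene, "B")
  expect_equal(ng$signed_distance, 500)     # gene 3' of the bin
  ng2 <- nearest_gene(toy_bins(1500), gt)
  expect_equal(ng2$signed_distance, 0)      # overlap
  gt3 <- make_track("gene", "chr1", c(100L, 700L), c(200L, 800L),
                    name = c("ZZZ", "AAA"))
  ng3 <- nearest_gene(toy_bins(400), gt3)   # 200 bp from both
  expect_equal(ng3$nearest_gene, "AAA")
  expect_equal(ng3$signed_distance, 200)    # AAA lies 3' (positive)
  expect_warning(
    nearest_gene(toy_bins(1, chrom = "chrUn"), gt), "no annotated gene")
})

test_that("nearest gene equals all-pairs brute force", {
  set.seed(9)
  for (rep in 1:50) {
    nb <- sample(1:5, 1); ng_ <- sample(1:8, 1)
    bins <- toy_bins(sample.int(50000, nb), width = sample(50:500, 1))
    gs <- sort(sample.int(50000, ng_))
    gt <- make_track("gene", "chr1", gs, gs + sample(100:2000, ng_, TRUE),
                     name = sprintf("G%02d", sample(ng_)))
    got <- nearest_gene(bins, gt)
    for (i in seq_len(nb)) {
      gap <- pmax(0, gt$start - bins$end[i], bins$start[i] - gt$end)
      best <- which(gap == min(gap))
      if (length(best) > 1) best <- best[order(gt$name[best])][1]
      expect_equal(got$nearest_gene[i], gt$name[best])
      expect_equal(abs(got$signed_distance[i]), min(gap))
    }
  }
})

test_that("TSS window is strict and island overlap is 1 bp", {
  # plus-strand TSS at 10000; bins ending 1400 and 1500 bp short of it
  gt <- make_track("gene", "chr1", 10000L, 12000L, name = "G",
                   strand = "+")
  it <- make_track("cpg_island", "chr1", 300L, 400L)
  bins <- toy_bins(c(8500, 8400, 350, 150), width = 100L)
  cr <- classify_region(bins, gt, it)
  expect_true(cr$near_tss[1])     # distance 1400 < 1500
  expect_false(cr$near_tss[2])    # distance exactly 1500
  expect_true(cr$in_cpg_island[3])
  expect_false(cr$in_cpg_island[4])
  expect_true(all(cr$intergenic[1:4]))
})

test_that("first exon/intron flags are strand-aware", {
  # minus-strand 2-exon gene: first intron is the gap nearest the high end
  g <- list(list(chrom = "chr1", start = 1000L, end = 5000L, name = "G",
                 strand = "-",
                 blocks = data.table::data.table(start = c(1000L, 4000L),
                                                 end = c(2000L, 5000L))))
  gt <- make_gene_track(g)
  bins <- toy_bins(c(3000, 1500, 4200))
  cr <- classify_region(bins, gt, make_track("cpg_island", "chr1", 1L, 2L))
  expect_true(cr$first_exon_intron[1])   # in the 2000..4000 first intron
  expect_false(cr$first_exon_intron[2])  # last exon (3' end of the gene)
  expect_true(cr$first_exon_intron[3])   # 5'-most exon
  expect_false(any(cr$intergenic))
})

test_that("classification is independent of track row order", {
  set.seed(10)
  gs <- sort(sample.int(30000, 6))
  gt <- make_track("gene", "chr1", gs, gs + 800L,
                   name = sprintf("G%d", 1:6),
                   strand = sample(c("+", "-"), 6, TRUE))
  it <- make_track("cpg_island", "chr1", c(100L, 9000L), c(500L, 9400L))
  bins <- toy_bins(sample.int(30000, 10))
  a <- classify_region(bins, gt, it)
  perm <- sample(6)
  gt2 <- suppressWarnings(methbin:::as_feature_track(
    data.table::as.data.table(gt)[perm], "gene"))
  b <- classify_region(bins, gt2, it)
  expect_equal(a, b)
  # intergenic xor gene-overlapping, never both
  d <- nearest_gene(bins, gt)$signed_distance
  expect_equal(a$intergenic, d != 0)
})

test_that("chromHMM assignment: largest overlap, tie to earlier segment", {
  tr <- make_track("chromhmm", "chr1", c(0L, 600L, 1000L),
                   c(600L, 1000L, 5000L),
                   name = c("7_Enh", "15_Quies", "9_Het"))
  bins <- toy_bins(c(100, 540, 500), width = 100L)
  # bin2: 60 bp in Enh, 40 in Quies; bin3: 50/50 split
  st <- assign_chromhmm_state(bins, tr)
  expect_equal(st, c("7_Enh", "7_Enh", "7_Enh"))
  tr2 <- make_track("chromhmm", "chr1", c(0L, 550L), c(550L, 5000L),
                    name = c("7_Enh", "15_Quies"))
  expect_equal(assign_chromhmm_state(toy_bins(500, width = 100L), tr2),
               "7_Enh")   # exact 50/50 -> earlier segment
  expect_warning(
    st3 <- assign_chromhmm_state(toy_bins(9e6), tr), "not covered")
  expect_true(is.na(st3))
})

test_that("pathway input selection implements the three modes", {
  labs <- data.table::data.table(
    bin_index = 1:5, label = c("Tissue", "Tissue", "Tissue", "cfDNA",
                               "Tissue"),
    contributing_groups = "male_tissue,female_tissue")
  ann <- data.table::data.table(
    bin_index = 1:5,
    nearest_gene = c("G1", "G2", "G3", "G4", "G5"),
    signed_distance = 0,
    near_tss = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    in_cpg_island = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    intergenic = FALSE, first_exon_intron = FALSE,
    state_cellA = c("1_TssA", "1_TssA", "7_Enh", "9_Het", "15_Quies"),
    state_cellB = c("15_Quies", "1_TssA", "7_Enh", "9_Het", "15_Quies"))
  expect_equal(select_pathway_input(labs, ann, "Tissue", "tissue_strict"),
               "G1")                                  # island AND TSS
  expect_equal(select_pathway_input(labs, ann, "Tissue", "or_relaxed"),
               c("G1", "G2", "G3"))
  scr <- lapply(setNames(base_groups(), base_groups()), function(g)
    data.table::data.table(bin_index = 1:5,
                           p_value = c(0.005, 0.5, 0.02, 0.001, 0.005)))
  expect_equal(
    select_pathway_input(labs, ann, "Tissue", "extended",
                         screen_results = scr),
    "G1")   # p < 0.01 in contributing groups AND state difference
  expect_warning(
    out <- select_pathway_input(labs[label == "Male"], ann, "Male",
                                "or_relaxed"),
    "no genes")
  expect_equal(out, character())
})
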