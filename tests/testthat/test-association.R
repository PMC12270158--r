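test_that("tau-b endpoints and tie handling match direct pair counting", {
  expect_equal(kendall_tau_b(1:4, 1:4)$tau_b, 1)
  expect_equal(kendall_tau_b(1:4, 4:1)$tau_b, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 3)
  o <- kendall_oracle(x, y)
  kt <- kendall_tau_b(x, y)
  expect_equal(kt$tau_b, o$tau, tolerance = 1e-14)
  expect_equal(kt$p_value, o$p, tolerance = 1e-12)
  expect_error(kendall_tau_b(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("exact permutation p agrees with asymptotic ranking and itself", {
  # small-n oracle: enumeration of all 6! permutations
  set.seed(5)
  x <- c(1, 2, 2, 3, 4, 5); y <- c(2, 1, 3, 3, 5, 4)
  pe <- kendall_tau_b(x, y, p_method = "exact")$p_value
  # independent enumeration using sampling-free full permutation of y
  perm_p <- local({
    S_obs <- kendall_oracle(x, y)$S
    hits <- 0L; total <- 0L
    idx <- seq_along(y)
    rec <- function(prefix, rest) {
      if (length(rest) == 0) {
        total <<- total + 1L
        if (abs(kendall_oracle(x, y[prefix])$S) >= abs(S_obs) - 1e-9)
          hits <<- hits + 1L
        return(invisible())
      }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(), idx)
    hits / total
  })
  expect_equal(pe, perm_p, tolerance = 1e-12)
})

test_that("antisymmetry: tau(x, -y) = -tau(x, y) with unchanged p", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    x <- sample(1:6, n, TRUE); y <- sample(1:5, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    a <- kendall_tau_b(x, y); b <- kendall_tau_b(x, -y)
    expect_equal(b$tau_b, -a$tau_b, tolerance = 1e-14)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-14)
  }
})

test_that("screening applies the observation and uniqueness filters", {
  md <- make_metadata(8, stages = c(1, 1, 2, 2, 3, 3, 4, 4))
  ids <- md$sample_id[md$base_group == "male_tissue"]
  beta <- matrix(NA_real_, 3, length(ids), dimnames = list(NULL, ids))
  beta[1, 1:3] <- c(0.1, 0.5, 0.9)                   # 3 observed -> filtered
  beta[2, ] <- rep(c(0.2, 0.5), 4)                   # 2 unique -> filtered
  set.seed(11)
  beta[3, ] <- 0.1 * md$fibrosis_stage[match(ids, md$sample_id)] +
    rnorm(8, 0, 0.01)                                # planted trend
  bbm <- bbm_from_beta(beta)
  res <- screen_bins(bbm, md, "male_tissue")
  expect_true(res$filtered[1])
  expect_true(res$filtered[2])
  expect_false(res$significant[1] || res$significant[2])
  expect_true(res$significant[3])
  expect_error(screen_bins(bbm, md[0, ], "male_tissue"), "no samples")
})

test_that("screening power is monotone in the planted effect size", {
  md <- make_metadata(8)
  ids <- md$sample_id[md$base_group == "female_tissue"]
  stage <- md$fibrosis_stage[match(ids, md$sample_id)]
  set.seed(21)
  power <- vapply(c(0, 0.05, 0.15, 0.3), function(eff) {
    hits <- 0L
    for (r in 1:150) {
      b <- eff * stage + rnorm(8, 0, 0.05)
      kt <- tryCatch(kendall_tau_b(b, stage), error = function(e) NULL)
      if (!is.null(kt) && kt$p_value < 0.05) hits <- hits + 1L
    }
    hits / 150
  }, numeric(1))
  expect_true(all(diff(power) >= -0.02))  # non-decreasing up to MC noise
  expect_lt(power[1], 0.12)               # near-nominal at zero effect
  expect_gt(power[4], 0.9)
})

test_that("wilcoxon rank-sum: identical groups, exact small-sample cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)),
               wilcoxon_oracle(c(1, 2), c(3, 4)), tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(5, c(1, 2, 3, 4)),
               wilcoxon_oracle(5, c(1, 2, 3, 4)), tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("fibrosis dichotomization cuts at stage 2", {
  expect_equal(as.character(fibrosis_group(c(0, 1, 2, 4))),
               c("low", "low", "high", "high"))
  expect_error(fibrosis_group(5), "0..4")
  expect_error(fibrosis_group(NA), "0..4")
})
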