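toy_atlas <- function(K = 3, M = 60, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(M * K, 0.02, 0.1), M, K,
              dimnames = list(sprintf("m%03d", 1:M),
                              sprintf("ct%d", 1:K)))
  A[cbind(1:M, rep_len(1:K, M))] <- runif(M, 0.9, 0.98)
  reference_atlas(A)
}

test_that("pure samples and exact mixtures are recovered", {
  A <- toy_atlas()
  r <- estimate_proportions(A, A[, 2])
  expect_equal(unname(r$w), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(r$residual_norm, 1e-9)

  b <- 0.7 * A[, 1] + 0.3 * A[, 3]
  r2 <- estimate_proportions(A, b)
  expect_equal(unname(r2$w), c(0.7, 0, 0.3), tolerance = 1e-6)
  r2s <- estimate_proportions(A, b, method = "simplex")
  expect_equal(unname(r2s$w), c(0.7, 0, 0.3), tolerance = 1e-6)

  # complementary 0/1 two-type atlas, flat 0.5 sample -> symmetric weights
  A2 <- reference_atlas(matrix(c(rep(c(1, 0), 10), rep(c(0, 1), 10)), 20, 2,
                               dimnames = list(sprintf("m%d", 1:20),
                                               c("a", "b"))))
  r3 <- estimate_proportions(A2, rep(0.5, 20))
  expect_equal(unname(r3$w), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("proportions are a simplex vector; atlas columns permute weights", {
  A <- toy_atlas(K = 5, M = 100)
  set.seed(2)
  w0 <- c(0.4, 0.3, 0.2, 0.05, 0.05)
  b <- drop(unclass(A) %*% w0) + rnorm(100, 0, 0.02)
  r <- estimate_proportions(A, pmin(pmax(b, 0), 1))
  expect_true(all(r$w >= 0))
  expect_equal(sum(r$w), 1, tolerance = 1e-9)
  perm <- c(3, 1, 5, 2, 4)
  Ap <- reference_atlas(unclass(A)[, perm])
  rp <- estimate_proportions(Ap, pmin(pmax(b, 0), 1))
  expect_equal(unname(rp$w), unname(r$w[perm]), tolerance = 1e-8)
})

test_that("missing markers: pairwise dropping, coverage floor, rank warning", {
  A <- toy_atlas()
  b <- 0.5 * A[, 1] + 0.5 * A[, 2]
  b[sample(60, 20)] <- NA
  r <- estimate_proportions(A, b)
  expect_equal(r$n_markers, 40L)
  expect_equal(unname(r$w), c(0.5, 0.5, 0), tolerance = 1e-6)
  b2 <- b; b2[1:40] <- NA
  expect_error(estimate_proportions(A, b2), "50%")
  # duplicated cell-type column -> rank deficient -> unstable flag
  c1 <- rep(c(0.95, 0.05), 5)
  Adup <- reference_atlas(matrix(c(c1, 1 - c1, 1 - c1), 10, 3,
                                 dimnames = list(sprintf("m%d", 1:10),
                                                 c("a", "b", "b2"))))
  expect_warning(ru <- estimate_proportions(Adup, unclass(Adup)[, 1]),
                 "rank-deficient")
  expect_true(ru$unstable)
})

test_that("recovery error grows with noise on average", {
  A <- toy_atlas(K = 4, M = 200, seed = 3)
  set.seed(33)
  err <- vapply(c(0, 0.02, 0.05, 0.1), function(sdv) {
    e <- 0
    for (r in 1:30) {
      w <- rgamma(4, 1); w <- w / sum(w)
      b <- pmin(pmax(drop(unclass(A) %*% w) + rnorm(200, 0, sdv), 0), 1)
      e <- e + mean(abs(estimate_proportions(A, b)$w - w))
    }
    e / 30
  }, numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("atlas validation enforces separation and dimnames", {
  A <- matrix(0.5, 4, 2, dimnames = list(paste0("m", 1:4), c("a", "b")))
  expect_error(reference_atlas(A), "spread")
  expect_error(reference_atlas(matrix(c(0, 1), 1, 2)), "dimnames|rownames")
  expect_error(reference_atlas(matrix(c(-0.1, 1), 1, 2,
                                      dimnames = list("m", c("a", "b")))),
               "\\[0, 1\\]")
})

test_that("fibrosis comparison of proportions", {
  md <- make_metadata(6, stages = c(0, 0, 1, 2, 2, 3))
  ids <- md$sample_id[md$base_group == "male_tissue"]
  props <- matrix(c(rep(c(0.1, 0.2, 0.3), 2), rep(0.5, 6)), 6, 2,
                  dimnames = list(ids, c("hepatocyte", "Tcell")))
  r <- compare_proportions_by_fibrosis(props, md, "hepatocyte")
  expect_equal(r$p_value, 1.0)  # identical proportion sets in both groups
  expect_error(
    compare_proportions_by_fibrosis(props[1:3, , drop = FALSE],
                                    md[md$sample_id %in% ids[1:3]],
                                    "hepatocyte"),
    ">= 2 samples")
})
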