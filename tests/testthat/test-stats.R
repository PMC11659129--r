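test_that("ROI aggregation matches brute-force masked statistics", {
  df <- tibble::tibble(roi_id = rep(1:2, each = 4),
                       value = c(1, 3, 1, 3, 7, 7, 7, 7))
  agg <- aggregate_roi(df)
  expect_equal(agg$value[agg$roi_id == 1], 2)
  expect_equal(agg$value[agg$roi_id == 2], 7)
  # invalid voxels excluded from the aggregate
  df2 <- tibble::tibble(roi_id = 1, value = c(1, 2, 3, 100),
                        valid = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(aggregate_roi(df2)$value, median(c(1, 2, 3)))
  # ROI dropped when under 25% of voxels are valid
  df3 <- tibble::tibble(roi_id = 1, value = rep(5, 10),
                        valid = c(TRUE, rep(FALSE, 9)))
  expect_true(aggregate_roi(df3)$dropped)
  expect_true(is.na(aggregate_roi(df3)$value))
  set.seed(41)
  df4 <- tibble::tibble(roi_id = 1, value = rnorm(20),
                        valid = runif(20) > 0.3)
  expect_equal(aggregate_roi(df4)$value, median(df4$value[df4$valid]))
})

test_that("Mann-Whitney U is exact on separated small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)   # 2 * 1/choose(6,3)
  expect_identical(r$method, "exact")
  # identical multisets: p = 1
  r2 <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(r2$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney exact path equals full-enumeration oracle with ties", {
  set.seed(51)
  for (r in 1:5) {
    x <- sample(1:4, 5, replace = TRUE)
    y <- sample(1:4, 4, replace = TRUE)
    got <- mann_whitney_u(x, y)
    # independent oracle: all group assignments of the pooled sample
    pooled <- c(x, y)
    nx <- length(x)
    u_of <- function(a, b) {
      s <- 0
      for (ai in a) s <- s + sum(ai > b) + 0.5 * sum(ai == b)
      s
    }
    us <- apply(utils::combn(length(pooled), nx), 2,
                function(ix) u_of(pooled[ix], pooled[-ix]))
    mu <- nx * length(y) / 2
    p_or <- mean(abs(us - mu) >= abs(got$U - mu) - 1e-12)
    expect_equal(got$U, u_of(x, y))
    expect_equal(got$p, p_or)
  }
})

test_that("the normal approximation agrees with the exact p at n = 8, 8", {
  set.seed(52)
  x <- rnorm(8); y <- rnorm(8, 0.8)
  exact <- mann_whitney_u(x, y)
  expect_identical(exact$method, "exact")
  # force the approximation path via a large-sample copy with identical ranks
  approx_p <- {
    r <- rank(c(x, y)); U <- sum(r[1:8]) - 8 * 9 / 2
    mu <- 32; sigma2 <- 8 * 8 / 12 * 17
    2 * pnorm((abs(U - mu) - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  expect_lt(abs(exact$p - approx_p), 0.01)
})

test_that("ROC analysis handles separation, ties, and matches pair counting", {
  sep <- roc_analysis(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  same <- roc_analysis(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$auc, 0.5)
  set.seed(61)
  for (r in 1:10) {
    x <- sample(1:6, 12, replace = TRUE) + rnorm(12, 0, 0.01)
    y <- sample(1:6, 9, replace = TRUE) + rnorm(9, 0, 0.01)
    got <- roc_analysis(x, y)
    oracle <- max(pair_count_auc(x, y), 1 - pair_count_auc(x, y))
    expect_equal(got$auc, oracle, tolerance = 1e-12)
  }
  expect_error(roc_analysis(numeric(0), 1:3), "non-empty")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  x <- rnorm(40, 1); y <- rnorm(30)
  got <- roc_analysis(x, y)
  ref <- suppressMessages(pROC::roc(
    response = c(rep(1, 40), rep(0, 30)), predictor = c(x, y)))
  expect_equal(got$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("the Youden cutoff equals brute-force maximization over thresholds", {
  set.seed(63)
  x <- rnorm(25, 1.2); y <- rnorm(20)
  got <- roc_analysis(x, y)
  thr <- sort(unique(c(x, y)))
  j <- vapply(thr, function(cut) mean(x >= cut) + mean(y < cut) - 1, numeric(1))
  expect_equal(mean(x >= got$cutoff) + mean(y < got$cutoff) - 1, max(j))
  # accuracy at the cutoff
  acc <- (sum(x >= got$cutoff) + sum(y < got$cutoff)) / 45
  expect_equal(got$accuracy, acc)
})

test_that("AUC orientation and complement identities hold", {
  set.seed(64)
  x <- rnorm(15); y <- rnorm(15, 1.5)  # normals higher: orientation flips
  got <- roc_analysis(x, y)
  expect_gte(got$auc, 0.5)
  expect_identical(got$direction, "<=")
  expect_equal(got$auc, 1 - pair_count_auc(x, y), tolerance = 1e-12)
  # monotone-transform invariance
  z <- roc_analysis(exp(x), exp(y))
  expect_equal(z$auc, got$auc)
})

test_that("Spearman matrix equals first-principles rank correlation with categories", {
  set.seed(71)
  n <- 6
  a <- tibble::tibble(roi_id = 1:n, F = rnorm(n), PS = rnorm(n))
  b <- tibble::tibble(roi_id = 1:n, Ktrans = rnorm(n), Kep = rnorm(n))
  got <- spearman_matrix(a, b)
  for (i in seq_len(nrow(got))) {
    rr <- spearman_brute(a[[got$row_param[i]]], b[[got$col_param[i]]])
    expect_equal(got$r[i], rr, tolerance = 1e-12)
  }
  # monotone transforms give |r| = 1, strong
  x <- runif(10)
  m1 <- spearman_matrix(tibble::tibble(roi_id = 1:10, F = x),
                        tibble::tibble(roi_id = 1:10, Ktrans = exp(3 * x)))
  expect_equal(m1$r, 1)
  expect_identical(m1$category, "strong")
  m2 <- spearman_matrix(tibble::tibble(roi_id = 1:10, F = x),
                        tibble::tibble(roi_id = 1:10, Ktrans = -x))
  expect_equal(m2$r, -1)
  expect_identical(m2$category, "strong")
  expect_error(spearman_matrix(a[1:2, ], b[1:2, ]), "fewer than 3")
})

test_that("correlation strength categories use the quoted half-open intervals", {
  expect_identical(dcekin:::spearman_category(c(0.81, 0.8, 0.51, 0.5, 0.31, 0.3, -0.9)),
                   c("strong", "moderate", "moderate", "weak", "weak", "none",
                     "strong"))
})
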