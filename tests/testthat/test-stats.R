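test_that("Pearson correlations: exact lines, the printed example, affine invariance", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10))
  out <- pairwise_correlations(d, "x", c("y", "z"))
  expect_equal(out$r[out$y == "y"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$y == "z"], -1, tolerance = 1e-12)

  # hand computation for {(1,2),(2,1),(3,4),(4,3),(5,6)}:
  # sum dx dy = 10, sum dx^2 = 10, sum dy^2 = 14.8 -> r = 10/sqrt(148)
  ex <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 6))
  expect_equal(pairwise_correlations(ex, "x", "y")$r, 10 / sqrt(148),
               tolerance = 1e-12)

  # affine transforms change r only through the sign of the slope
  set.seed(3)
  a <- rnorm(30); b <- a + rnorm(30)
  d2 <- tibble::tibble(a = a, b = b, b2 = -3 * b + 7)
  r1 <- pairwise_correlations(d2, "a", "b")$r
  r2 <- pairwise_correlations(d2, "a", "b2")$r
  expect_equal(r2, -r1, tolerance = 1e-12)

  # zero-variance variable is flagged and skipped
  d3 <- tibble::tibble(a = a, c = rep(1, 30))
  out3 <- pairwise_correlations(d3, "a", "c")
  expect_true(out3$skipped)
  expect_true(is.na(out3$r))
})

test_that("paired Wilcoxon matches exhaustive enumeration for small n", {
  set.seed(7)
  for (n in c(5, 6, 8, 10)) {
    for (rep in 1:3) {
      a <- round(rnorm(n, 10, 2), 3)
      b <- round(a + rnorm(n, 0.5, 1.5), 3)
      if (any(a == b) || any(duplicated(abs(a - b)))) next
      got <- group_difference_test(a, b, mode = "paired")
      expect_equal(got$p_value, enumerate_signed_rank_p(a, b), tolerance = 1e-12)
    }
  }
  # samples close except one large pair, n = 6: enumeration oracle
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1.11, 1.93, 3.05, 3.83, 5.21, 6.7)
  got <- group_difference_test(a, b, mode = "paired")
  expect_equal(got$p_value, enumerate_signed_rank_p(a, b), tolerance = 1e-12)

  expect_error(group_difference_test(1:4, 1:4, mode = "paired"),
               class = "pw_stats_error")
})

test_that("unpaired rank-sum matches enumeration and near-identical samples give p ~ 1", {
  set.seed(11)
  a <- round(rnorm(6, 10, 2), 3)
  b <- round(rnorm(5, 10, 2), 3)
  got <- group_difference_test(a, b, mode = "unpaired")
  expect_equal(got$p_value, enumerate_rank_sum_p(a, b), tolerance = 1e-12)

  # equal samples up to alternating hair-line tie-breaks: no shift, p ~ 1
  a2 <- c(1.0, 2.1, 3.2, 4.3, 5.4, 6.5)
  b2 <- a2 + c(1e-3, -2e-3, 3e-3, -4e-3, 5e-3, -6e-3)
  p <- group_difference_test(a2, b2, mode = "paired")$p_value
  expect_gt(p, 0.5)
})

test_that("male/female CO separation is detected at population scale", {
  set.seed(5)
  m <- vapply(1:200, function(i) sample_subject("M")$co, 1.0)
  f <- vapply(1:200, function(i) sample_subject("F")$co, 1.0)
  expect_lt(group_difference_test(m, f, mode = "unpaired")$p_value, 0.05)
  expect_gt(mean(m), mean(f))
})

test_that("stepwise regression recovers a planted single-predictor model", {
  set.seed(21)
  n <- 80
  dat <- tibble::tibble(
    k1 = rnorm(n, 1, 0.5), k3 = rnorm(n, 9, 2),
    inv_k1 = NA, inv_k3 = NA,
    s_r = rnorm(n, 1.4, 0.3), s_c = rnorm(n, 9, 2),
    co = rnorm(n, 4, 0.6), tau = runif(n, 0.06, 0.14),
    sv = rnorm(n, 55, 12)
  )
  dat$inv_k1 <- 1 / abs(dat$k1 + 2)
  dat$inv_k3 <- 1 / dat$k3
  dat$AI <- 1600 * dat$tau + rnorm(n, 0, 2)
  mod <- stepwise_regression(dat, "AI")
  expect_equal(mod$terms, "tau")
  expect_gt(coef(mod$fit)[["tau"]], 0)

  # pure-noise response selects nothing at large n
  dat$AI <- rnorm(n)
  expect_length(stepwise_regression(dat, "AI")$terms, 0)

  # exact linear model in two predictors is recovered with R^2 = 1
  dat$AI <- 2 * dat$co + 5 * dat$s_r
  mod2 <- stepwise_regression(dat, "AI")
  expect_setequal(mod2$terms, c("co", "s_r"))
  expect_equal(mod2$r2, 1, tolerance = 1e-9)
})

test_that("stepwise selection ignores predictor column order", {
  set.seed(31)
  n <- 60
  dat <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  dat$y <- 3 * dat$b + rnorm(n, 0, 0.3)
  m1 <- stepwise_regression(dat, "y", predictors = c("a", "b", "c"))
  m2 <- stepwise_regression(dat, "y", predictors = c("c", "b", "a"))
  expect_setequal(m1$terms, m2$terms)
  expect_equal(sort(m1$coefficients), sort(m2$coefficients), tolerance = 1e-12)
})

test_that("stepwise AI convenience wrapper builds the canonical candidate set", {
  set.seed(41)
  n <- 50
  cohort <- tibble::tibble(
    k1 = runif(n, 0.2, 3), k3 = runif(n, 5, 15),
    s_r = runif(n, 0.8, 2), s_c = runif(n, 5, 12),
    co = runif(n, 3, 5.5), tau = runif(n, 0.07, 0.13),
    sv = runif(n, 40, 80)
  )
  cohort$AI <- 1632.5 * cohort$tau - 20.1 + rnorm(n, 0, 2)
  mod <- stepwise_ai_regression(cohort)
  expect_true("tau" %in% mod$terms)
  expect_gt(mod$coefficients[["tau"]], 0)
  expect_s3_class(tidy(mod), "tbl_df")
  expect_equal(glance(mod)$n_terms, length(mod$terms))
})
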