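# independent enumeration oracles ------------------------------------

# exact two-sided rank-sum p by enumerating all C(n1+n2, n1) rank splits
rank_sum_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  center <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - center) >= abs(obs - center) - 1e-12)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
signed_rank_oracle <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  stats <- as.matrix(signs) %*% r
  mean(abs(stats - center) >= abs(obs - center) - 1e-12)
}

# Kruskal-Wallis H from the defining rank formula (no tie correction
# needed for distinct values)
kw_oracle <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  12 / (n * (n + 1)) *
    sum(lengths(groups) * (rbar - (n + 1) / 2)^2)
}

test_that("rank-sum matches the exact enumeration oracle", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(rank_sum_oracle(x, y), 0.1)
  res <- rank_sum_test(x, y)
  expect_equal(res$p_value, 0.1)
  expect_match(res$notes, "exact")

  # random small samples, no ties: implementation == oracle
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- sample(seq(1, 199, 2), 5); b <- sample(seq(2, 200, 2), 6)
    })
    expect_equal(rank_sum_test(a, b, mode = "exact")$p_value,
                 rank_sum_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum degenerate and large-sample branches behave", {
  same <- rank_sum_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_match(same$notes, "degenerate")

  tied <- rank_sum_test(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(tied$p_value, 1, tolerance = 1e-9)

  big <- rank_sum_test(1:50, 51:100)
  expect_lt(big$p_value, 1e-10)
  expect_match(big$notes, "normal")
})

test_that("signed-rank matches the exact enumeration oracle", {
  expect_equal(signed_rank_oracle(1:5), 0.0625)
  res <- signed_rank_test(c(11, 12, 13, 14, 15), c(10, 10, 10, 10, 10))
  expect_equal(res$p_value, 0.0625)

  sym <- signed_rank_test(c(0, 0, 0, 0), c(2, 1, -1, -2))
  expect_equal(sym$p_value, 1, tolerance = 1e-9)

  one <- signed_rank_test(2, 1)
  expect_equal(one$p_value, 1)

  expect_error(signed_rank_test(c(1, 2), c(1, 2)), "zero")

  for (seed in 1:10) {
    withr::with_seed(seed, d <- sample(c(-1, 1), 7, TRUE) * sample(50, 7))
    expect_equal(signed_rank_test(d, rep(0, 7), mode = "exact")$p_value,
                 signed_rank_oracle(d), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis reproduces the rank-formula oracle", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(kw_oracle(g), 7.2)
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, 7.2, tolerance = 1e-9)
  expect_match(res$notes, "df = 2")

  const <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), "two")
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum test", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      a <- rnorm(15); b <- rnorm(12, mean = runif(1, 0, 1.5))
    })
    p_kw <- kruskal_wallis(list(a, b))$p_value
    p_rs <- rank_sum_test(a, b, mode = "normal")$p_value
    expect_lt(abs(p_kw - p_rs), 0.03)
    expect_equal(p_kw < 0.05, p_rs < 0.05)
  }
})

test_that("exact and normal branches agree near the crossover sizes", {
  rel_err <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      a <- sample(1000, 6); b <- sample(1000, 6)
    })
    pe <- rank_sum_test(a, b, mode = "exact")$p_value
    pn <- rank_sum_test(a, b, mode = "normal")$p_value
    abs(pn - pe) / pe
  }, numeric(1))
  expect_lt(median(rel_err), 0.1)
  expect_lt(max(rel_err), 0.25)
})

test_that("rank tests are invariant under monotone transforms", {
  withr::with_seed(5, {
    a <- rlnorm(20); b <- rlnorm(18, 0.5)
  })
  expect_equal(rank_sum_test(a, b)$p_value,
               rank_sum_test(log(a), log(b))$p_value)
  g3 <- a[1:18] + b
  expect_equal(kruskal_wallis(list(a, b, g3))$p_value,
               kruskal_wallis(list(a^3, b^3, g3^3))$p_value)
})

test_that("pairwise follow-up is symmetric and degenerate-safe", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  pw <- pairwise_lsd(g)
  expect_equal(nrow(pw), 3L)
  z12 <- abs(pw$z[pw$group_1 == "1" & pw$group_2 == "2"])
  z23 <- abs(pw$z[pw$group_1 == "2" & pw$group_2 == "3"])
  expect_equal(z12, z23)
  expect_s3_class(attr(pw, "omnibus"), "swd_test")

  same <- pairwise_lsd(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(all(same$p_value == 1))
  expect_true(all(same$z == 0))
})

test_that("unadjusted pairwise tests hold the nominal type-I rate", {
  withr::with_seed(99, {
    hits <- replicate(1000, {
      g <- list(rnorm(10), rnorm(10), rnorm(10))
      pairwise_lsd(g)$p_value < 0.05
    })
  })
  rate <- mean(hits)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("condition comparisons report medians and detect published shifts", {
  same <- compare_conditions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_equal(same$medians[[1]], same$medians[[2]])

  expect_error(compare_conditions(1:3, 1:4, design = "paired"), "equal-length")

  # knockout VPA shift: medians 2.4 -> 3.0 s at session-scale n
  ko <- swd_preset("ko_vpa")
  withr::with_seed(17, {
    d_before <- 1 + rlnorm(120, log(1.4), 0.55)      # median ~2.4 s
    d_after <- 1 + rlnorm(120, ko$swd_duration_lognorm_mu,
                          ko$swd_duration_lognorm_sigma)  # median ~3.0 s
  })
  shift <- compare_conditions(d_before, d_after)
  expect_lt(shift$p_value, 0.01)
  expect_lt(shift$medians[[1]], shift$medians[[2]])

  # wild-type VPA shift: medians 2.2 -> 1.9 s
  withr::with_seed(18, {
    w_before <- 1 + rlnorm(400, log(1.2), 0.8)
    w_after <- 1 + rlnorm(400, log(0.9), 0.8)
  })
  wt_shift <- compare_conditions(w_before, w_after)
  expect_lt(wt_shift$p_value, 0.05)
  expect_gt(wt_shift$medians[[1]], wt_shift$medians[[2]])
})
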