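test_that("normal exceedance probability matches the closed form", {
  expect_equal(q_from_normal(1, 1, 0.3, 0.4), 0.5)
  expect_equal(q_from_normal(0.15, 0, 0.1, 0.1),
               pnorm(0.15 / (0.1 * sqrt(2))), tolerance = 1e-12)
  expect_equal(round(q_from_normal(0.15, 0, 0.1, 0.1), 4), 0.8556)
  expect_equal(q_from_normal(1e6, 0, 1, 1), 1)
  expect_error(q_from_normal(1, 0, 0, 0), "degenerate")
})

test_that("aGRP sampling distribution has the stated mean and variance", {
  d <- agrp_sampling_distribution(0.5, 10, 10)
  expect_equal(d$mean, 0)
  expect_equal(d$variance, 0.0025)
  expect_equal(d$variance, agrp_null_variance(10, 10))
  d2 <- agrp_sampling_distribution(0.8556, 50, 50)
  expect_equal(d2$mean, 0.7112)
  expect_warning(d0 <- agrp_sampling_distribution(1, 10, 10), "degenerate")
  expect_equal(d0$variance, 0)
})

test_that("asymptotic p-values are two-sided, symmetric and monotone", {
  expect_equal(asymptotic_pvalue(0, 10, 10), 1)
  expect_equal(asymptotic_pvalue(0.098, 10, 10), 0.05, tolerance = 1e-3)
  expect_equal(asymptotic_pvalue(0.098, 10, 10),
               asymptotic_pvalue(-0.098, 10, 10))
  Ts <- seq(0, 1, 0.05)
  p <- asymptotic_pvalue(Ts, 8, 12)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("permutation p-values are deterministic given a seed and smoothed", {
  set.seed(5)
  x <- matrix(rnorm(20 * 12), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  cls <- rep(c("tumor", "normal"), each = 6)
  p1 <- permutation_pvalues(x, cls, B = 100, seed = 9)
  p2 <- permutation_pvalues(x, cls, B = 100, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 101))
  expect_error(permutation_pvalues(x, cls, B = 5, seed = 1), "B")

  # constant gene: every permuted |T| equals |T_obs|, so p = 1
  xc <- rbind(const = rep(3, 12))
  colnames(xc) <- paste0("s", 1:12)
  expect_equal(unname(permutation_pvalues(xc, cls, B = 50, seed = 1)), 1)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration (n+m <= 10)", {
  set.seed(21)
  vals <- c(rnorm(5, 2), rnorm(5, 0))  # separated groups, n = m = 5
  x <- matrix(vals, nrow = 1, dimnames = list("g", paste0("s", 1:10)))
  cls <- rep(c("tumor", "normal"), each = 5)
  tobs <- oracle_agrp_T(vals[1:5], vals[6:10])
  tall <- exact_perm_T(vals, 5)
  p_exact <- mean(abs(tall) >= abs(tobs) - 1e-12)
  B <- 4000
  p_mc <- unname(permutation_pvalues(x, cls, B = B, seed = 3))
  # binomial Monte-Carlo error around the exact permutation p
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(p_mc - p_exact), 4 * se + 2 / B)

  # same check for GRP at tau = 0.7
  tobs_g <- oracle_grp(vals[1:5], vals[6:10], 0.7)$T
  tall_g <- exact_perm_T(vals, 5, method = "grp", tau = 0.7)
  p_exact_g <- mean(abs(tall_g) >= abs(tobs_g) - 1e-12)
  p_mc_g <- unname(permutation_pvalues(x, cls, method = "grp", tau = 0.7,
                                       B = B, seed = 4))
  se_g <- sqrt(max(p_exact_g * (1 - p_exact_g), 0.25 / B) / B)
  expect_lt(abs(p_mc_g - p_exact_g), 4 * sqrt(p_exact_g * (1 - p_exact_g) / B) + 2 / B)

  # complete separation approaches the minimal two-sided tail
  vsep <- c(10, 11, 12, 1, 2, 3)
  xs <- matrix(vsep, nrow = 1, dimnames = list("g", paste0("s", 1:6)))
  cls3 <- rep(c("tumor", "normal"), each = 3)
  tall3 <- exact_perm_T(vsep, 3)
  p_exact3 <- mean(abs(tall3) >= 1 - 1e-12)  # T_obs = 1
  expect_equal(p_exact3, 2 / 20)  # both extreme assignments out of C(6,3)
  p_mc3 <- unname(permutation_pvalues(xs, cls3, B = 4000, seed = 5))
  expect_lt(abs(p_mc3 - p_exact3), 4 * sqrt(p_exact3 * (1 - p_exact3) / 4000) + 2 / 4000)
})

test_that("permutation p-values increase in stability with B", {
  set.seed(33)
  x <- matrix(rnorm(40 * 12), nrow = 40,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:12)))
  cls <- rep(c("tumor", "normal"), each = 6)
  # Monte-Carlo scatter of p across independent shuffle sets shrinks with B
  spread <- sapply(c(20, 200, 2000), function(B) {
    ps <- sapply(1:5, function(s)
      permutation_pvalues(x, cls, B = B, seed = 100 + s))
    mean(apply(ps, 1, sd))
  })
  expect_true(all(diff(spread) < 0))
})

test_that("permutation p-values are near-uniform on null data", {
  set.seed(8)
  x <- matrix(rnorm(400 * 20), nrow = 400,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:20)))
  cls <- rep(c("tumor", "normal"), each = 10)
  p <- permutation_pvalues(x, cls, B = 400, seed = 2)
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(p < alpha)
    se <- sqrt(alpha * (1 - alpha) / 400)
    expect_lt(abs(frac - alpha), 4 * se + 0.005)
  }
})

test_that("BH adjustment validates input and applies the step-up rule", {
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # monotone non-decreasing in sorted-p order
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("BH controls the false discovery proportion on mixed simulations", {
  set.seed(44)
  fdp <- replicate(40, {
    p <- c(runif(180), rbeta(20, 0.05, 1))  # 180 null, 20 signal genes
    q <- bh_adjust(p)
    called <- which(q < 0.1)
    if (!length(called)) 0 else mean(called <= 180)
  })
  expect_lt(mean(fdp), 0.1 + 0.05)
})
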