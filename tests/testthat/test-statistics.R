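test_that("exceedance proportions follow the >=/<= indicator definitions", {
  pr <- exceedance_proportions(c(3, 1), c(2, 4))
  expect_equal(pr$l, c(0.5, 0))
  expect_equal(pr$k, c(0.5, 0))

  pr <- exceedance_proportions(c(5, 3), c(1, 2))
  expect_equal(pr$l, c(1, 1))
  expect_equal(pr$k, c(1, 1))

  # all ties: >= and <= are both satisfied everywhere
  pr <- exceedance_proportions(c(7, 7), c(7, 7))
  expect_equal(pr$l, c(1, 1))
  expect_equal(pr$k, c(1, 1))

  expect_error(exceedance_proportions(numeric(0), 1:3), "at least one")
  expect_error(exceedance_proportions(c(1, NA), 1:3), "missing")
})

test_that("regulation profile thresholds at tau with the printed asymmetry", {
  pr <- list(l = c(0.5, 0), k = c(0.5, 0), n = 2, m = 2)
  expect_equal(as.integer(regulation_profile(pr, 0.7)), c(0L, -1L, 0L, -1L))
  # boundary >= at tau = 0.5: no zeros possible
  expect_equal(as.integer(regulation_profile(pr, 0.5)), c(1L, -1L, 1L, -1L))
  pr2 <- list(l = c(1, 1), k = c(1, 1), n = 2, m = 2)
  expect_equal(as.integer(regulation_profile(pr2, 0.9)), c(1L, 1L, 1L, 1L))
  expect_error(regulation_profile(pr, 0.4), "tau")
  expect_error(regulation_profile(pr, 1.2), "tau")
})

test_that("GRP statistic counts up- and down-status samples over both blocks", {
  # gene [3,1 | 2,4] at tau = 0.7: both informative samples point down
  r <- structure(c(0L, -1L, 0L, -1L), tau = 0.7)
  g <- grp_statistic(r, 2, 2)
  expect_equal(g$s_u, 0); expect_equal(g$s_d, 2)
  expect_equal(g$T, -0.5); expect_equal(g$S, 0.5)

  r <- structure(c(1L, -1L, 1L, -1L), tau = 0.5)
  g <- grp_statistic(r, 2, 2)
  expect_equal(g$s_u, 2); expect_equal(g$s_d, 2)
  expect_equal(g$T, 0); expect_equal(g$S, 1)

  # complete separation: every sample has status +1, maximal statistic
  g <- grp_statistic(c(1L, 1L, 1L, 1L), 2, 2)
  expect_equal(g$s_u, 4); expect_equal(g$s_d, 0); expect_equal(g$T, 1)

  expect_error(grp_statistic(c(1L, 0L), 2, 2), "length")
})

test_that("GRP at tau = 0.5 thresholds the exceedance proportions", {
  set.seed(99)
  for (i in 1:50) {
    inst <- random_instance()
    pr <- exceedance_proportions(inst$tumor, inst$normal)
    g <- regulation_stat(inst$tumor, inst$normal, method = "grp",
                         tau = 0.5)
    n_up <- sum(pr$l >= 0.5) + sum(pr$k >= 0.5)
    expect_equal(g$T, 2 * n_up / (inst$n + inst$m) - 1)
    expect_equal(g$S, 1)  # zero-free profile at tau = 0.5
  }
  # complete separation gives the maximal statistic at any tau
  expect_equal(regulation_stat(c(9, 8), c(1, 2), method = "grp",
                               tau = 0.9)$T, 1)
})

test_that("aGRP statistic matches its closed form and handles ties", {
  st <- agrp_statistic(exceedance_proportions(c(3, 1), c(2, 4)))
  expect_equal(st$p_up, 0.25)
  expect_equal(st$p_down, 0.75)
  expect_equal(st$T, -0.5)
  expect_equal(regulation_stat(c(5, 3), c(1, 2))$T, 1)
  # constant gene: all-ties pathology gives T = 1 by the printed indicators
  expect_equal(regulation_stat(c(4, 4), c(4, 4))$T, 1)
})

test_that("matrix-wide statistics agree with per-gene application", {
  x <- rbind(g1 = c(3, 1, 2, 4), g2 = c(5, 3, 1, 2))
  colnames(x) <- paste0("s", 1:4)
  cls <- rep(c("tumor", "normal"), each = 2)
  res <- compute_statistics(x, cls)
  expect_equal(res$T, c(-0.5, 1))
  expect_equal(res$gene_id, c("g1", "g2"))

  resg <- compute_statistics(x, cls, method = "grp", tau = 0.7)
  expect_equal(resg$T, c(-0.5, 1))
  expect_error(compute_statistics(x, cls, method = "grp"), "tau")
})

test_that("aGRP equals the brute-force pair count on random instances", {
  set.seed(42)
  for (i in 1:1000) {
    inst <- random_instance()
    expect_equal(regulation_stat(inst$tumor, inst$normal)$T,
                 oracle_agrp_T(inst$tumor, inst$normal))
  }
})

test_that("kernel statistics agree with the R reference path, ties included", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    # discrete values force ties within and across classes
    vals <- sample(1:4, n + m, replace = TRUE)
    x <- matrix(as.numeric(vals), nrow = 1,
                dimnames = list("g", paste0("s", seq_len(n + m))))
    cls <- rep(c("tumor", "normal"), c(n, m))
    tau <- sample(c(0.5, 0.6, 0.7, 0.9), 1)
    a <- compute_statistics(x, cls)
    expect_equal(a$T, oracle_agrp_T(vals[1:n], vals[-(1:n)]))
    g <- compute_statistics(x, cls, method = "grp", tau = tau)
    og <- oracle_grp(vals[1:n], vals[-(1:n)], tau)
    expect_equal(g$T, og$T)
    expect_equal(g$p_up + g$p_down, og$S)
  }
})

test_that("complementarity: aGRP sums to 1, GRP sums depend on tau", {
  set.seed(11)
  x <- matrix(rnorm(50 * 12), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  cls <- rep(c("tumor", "normal"), each = 6)
  a <- compute_statistics(x, cls)
  expect_equal(a$p_up + a$p_down, rep(1, 50))
  expect_true(all(a$T >= -1 & a$T <= 1))
  g5 <- compute_statistics(x, cls, method = "grp", tau = 0.5)
  expect_equal(g5$p_up + g5$p_down, rep(1, 50))
  g8 <- compute_statistics(x, cls, method = "grp", tau = 0.8)
  expect_true(all(g8$p_up + g8$p_down <= 1 + 1e-12))
  expect_true(all(g8$T >= -1 & g8$T <= 1))
})

test_that("statistics are invariant under strictly increasing transforms", {
  set.seed(13)
  x <- matrix(rnorm(30 * 10), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  cls <- rep(c("tumor", "normal"), each = 5)
  for (f in list(exp, function(v) v^3, function(v) 10 * v + 3)) {
    expect_equal(compute_statistics(f(x), cls)$T,
                 compute_statistics(x, cls)$T)
    expect_equal(compute_statistics(f(x), cls, method = "grp", tau = 0.7)$T,
                 compute_statistics(x, cls, method = "grp", tau = 0.7)$T)
  }
})

test_that("aGRP is antisymmetric under class-label exchange on tie-free data", {
  set.seed(17)
  x <- matrix(rnorm(30 * 11), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:11)))
  cls <- rep(c("tumor", "normal"), c(5, 6))
  swapped <- ifelse(cls == "tumor", "normal", "tumor")
  expect_equal(compute_statistics(x, swapped)$T,
               -compute_statistics(x, cls)$T)
})

test_that("datasets validate their class structure", {
  x <- matrix(rnorm(8), 2, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(expression_dataset(x, rep("tumor", 4)), "two classes")
  expect_error(expression_dataset(x, c("a", "b", "c", "a")), "two classes")
  expect_error(expression_dataset(x, c("x", "x", "y", "y")), "case")
  ds <- expression_dataset(x, c("x", "x", "y", "y"), case = "y")
  expect_equal(ds$n, 2)
  expect_equal(ds$class[1:2], c("y", "y"))  # case block first
  xna <- x; xna[1, 2] <- NA
  expect_error(expression_dataset(xna, rep(c("tumor", "normal"), 2)),
               "missing value")
})
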