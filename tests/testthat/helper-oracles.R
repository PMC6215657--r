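# Independent brute-force oracles: direct translations of the defining
# formulas, deliberately written without reusing package internals.

oracle_props <- function(tumor, normal) {
  list(l = sapply(tumor, function(a) mean(normal <= a)),
       k = sapply(normal, function(a) mean(tumor >= a)))
}

# pair-enumeration aGRP: T = 2 #{(i,j): tumor_i >= normal_j} / (nm) - 1
oracle_agrp_T <- function(tumor, normal) {
  U <- sum(outer(tumor, normal, ">="))
  2 * U / (length(tumor) * length(normal)) - 1
}

oracle_grp <- function(tumor, normal, tau) {
  n <- length(tumor); m <- length(normal)
  l <- sapply(tumor, function(a) sum(a >= normal) / m)
  k <- sapply(normal, function(a) sum(a <= tumor) / n)
  status <- function(p) {
    if (p >= tau) 1L else if (1 - p > tau) -1L else 0L
  }
  r <- c(vapply(l, status, integer(1)), vapply(k, status, integer(1)))
  s_u <- sum(r == 1)
  s_d <- sum(r == -1)
  list(T = (s_u - s_d) / (n + m), s_u = s_u, s_d = s_d,
       S = (s_u + s_d) / (n + m))
}

# AUC by exhaustive pair counting, ties as 1/2
oracle_auc <- function(scores, de) {
  pos <- scores[de]; neg <- scores[!de]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exact permutation null of T: enumerate all choose(N, n) labelings
exact_perm_T <- function(values, n, method = "agrp", tau = NULL) {
  N <- length(values)
  sets <- utils::combn(N, n)
  apply(sets, 2, function(idx) {
    tum <- values[idx]; nor <- values[-idx]
    if (method == "agrp") oracle_agrp_T(tum, nor)
    else oracle_grp(tum, nor, tau)$T
  })
}

# random tie-free instance generator
random_instance <- function(nmax = 8) {
  n <- sample(2:nmax, 1); m <- sample(2:nmax, 1)
  list(tumor = rnorm(n), normal = rnorm(m), n = n, m = m)
}
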