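#' Exceedance probability between two normal distributions
#'
#' For `Y1 ~ N(mu1, s1^2)` and `Y2 ~ N(mu2, s2^2)` independently,
#' \deqn{q = P(Y_1 \ge Y_2) = \Phi\!\big((\mu_1-\mu_2)/\sqrt{\sigma_1^2+\sigma_2^2}\big).}
#' This is the per-pair up-regulation probability that calibrates the
#' sampling distribution of the aGRP statistic on two-normal data.
#'
#' @param mu1,mu2 class means.
#' @param s1,s2 class standard deviations (not both zero).
#' @return The probability `q` in `[0, 1]`.
#' @examples
#' q_from_normal(0.15, 0, 0.1, 0.1)  # ~ 0.8556
#' @export
q_from_normal <- function(mu1, mu2, s1, s2) {
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  if (s1 == 0 && s2 == 0)
    stop("degenerate distributions: s1 and s2 are both zero")
  pnorm((mu1 - mu2) / sqrt(s1^2 + s2^2))
}

#' Sampling distribution of the aGRP statistic on two-normal data
#'
#' With per-pair exceedance probability `q` (see [q_from_normal()]) and
#' class sizes `n`, `m`, the aGRP estimator is asymptotically
#' \deqn{T \sim N\!\Big(2q-1,\; \frac{2(n^2+m^2)\,q(1-q)}{nm(n+m)^2}\Big).}
#'
#' @param q per-pair exceedance probability in `[0, 1]`.
#' @param n,m class sizes.
#' @return A list with `mean` and `variance`.
#' @examples
#' agrp_sampling_distribution(0.5, 10, 10)  # mean 0, variance 0.0025
#' @export
agrp_sampling_distribution <- function(q, n, m) {
  if (q < 0 || q > 1) stop("`q` must be in [0, 1]")
  if (q == 0 || q == 1) {
    warning("degenerate q (0 or 1): variance is 0")
    return(list(mean = 2 * q - 1, variance = 0))
  }
  list(mean = 2 * q - 1,
       variance = 2 * (n^2 + m^2) * q * (1 - q) / (n * m * (n + m)^2))
}

#' Asymptotic null variance of the aGRP statistic
#'
#' Under the null (`q = 1/2`) the asymptotic approximation gives
#' `T ~ N(0, (n^2+m^2) / (2 n m (n+m)^2))`.
#'
#' Note this variance rests on an independence approximation across the
#' summed exceedance proportions and is considerably smaller than the exact
#' label-permutation variance of `T` (which is `(n+m+1)/(3nm)` for tie-free
#' data); asymptotic p-values are therefore anti-conservative relative to
#' the permutation null. See the package vignette.
#'
#' @param n,m class sizes.
#' @return The null variance.
#' @examples
#' agrp_null_variance(10, 10)  # 0.0025
#' @export
agrp_null_variance <- function(n, m) {
  (n^2 + m^2) / (2 * n * m * (n + m)^2)
}

#' Asymptotic two-sided p-value for an observed aGRP statistic
#'
#' Uses the asymptotic normal null (see [agrp_null_variance()]):
#' `p = 2 (1 - Phi(|T| / sigma0))`, clipped to `(0, 1]` (zero p-values are
#' raised to machine epsilon so downstream log transforms stay finite).
#'
#' @param T observed statistic(s) in `[-1, 1]` (vectorised).
#' @param n,m class sizes (both at least 2).
#' @return p-value(s) in `(0, 1]`.
#' @examples
#' asymptotic_pvalue(0.098, 10, 10)  # ~ 0.050
#' @export
asymptotic_pvalue <- function(T, n, m) {
  if (n < 2 || m < 2) stop("n and m must both be >= 2")
  s0 <- sqrt(agrp_null_variance(n, m))
  p <- 2 * pnorm(abs(T) / s0, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.eps), 1)
}

#' Permutation p-values for the regulation statistics
#'
#' Estimates two-sided per-gene p-values by randomly shuffling the sample
#' class labels. All genes share the same `B` label shuffles (which keeps
#' p-values comparable across genes and lets the kernel vectorise), and
#' the estimate is smoothed as
#' \deqn{p = \big(1 + \#\{b : |T_b| \ge |T_{obs}|\}\big) / (B + 1),}
#' so `p >= 1/(B+1) > 0` always.
#'
#' @inheritParams compute_statistics
#' @param B number of label permutations (at least 10; default 1000).
#' @param seed integer seed for reproducible shuffles (optional; when
#'   `NULL` the current RNG state is used).
#' @return Named numeric vector of p-values, one per gene.
#' @examples
#' sim <- simulate_simple(G_null = 20, G_de = 0, n = 5, seed = 1)
#' p <- permutation_pvalues(sim$null$dataset, B = 50, seed = 2)
#' head(p)
#' @export
permutation_pvalues <- function(x, class = NULL, method = c("agrp", "grp"),
                                tau = NULL, B = 1000, seed = NULL,
                                case = NULL) {
  method <- match.arg(method)
  if (!is.numeric(B) || length(B) != 1 || B < 10)
    stop("`B` must be a single permutation count >= 10")
  B <- as.integer(B)
  ds <- as_grp_data(x, class, case)
  if (ds$n < 2 || ds$m < 2)
    stop("at least 2 samples per class are required")
  if (method == "grp") {
    if (is.null(tau)) stop("`tau` is required for method = \"grp\"")
    check_tau(tau)
  }
  tau_eff <- if (is.null(tau)) 0.5 else tau
  so <- sorted_rows(ds$values)
  lab_obs <- as.integer(ds$class == ds$case)
  tobs <- stat_matrix_cpp(so$xs, so$ord, lab_obs, ds$n, ds$m,
                          method == "agrp", tau_eff)[, 1]
  labmat <- shuffle_labels(lab_obs, B, seed)
  cnt <- perm_count_cpp(so$xs, so$ord, labmat, ds$n, ds$m,
                        method == "agrp", tau_eff, tobs)
  p <- (1 + cnt) / (B + 1)
  names(p) <- rownames(ds$values)
  p
}

# B random shuffles of the 0/1 label vector, as an (n+m) x B matrix.
shuffle_labels <- function(lab, B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(lab)
  vapply(seq_len(B), function(b) sample(lab, N), integer(N))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]) with input validation: p-values must lie in
#' `(0, 1]`.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted values, order-preserving with respect to the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}
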