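#' Exceedance proportions of a gene's expression values
#'
#' For one gene, computes for each tumor sample the proportion `l_i` of
#' normal samples whose expression it meets or exceeds, and for each normal
#' sample the proportion `k_j` of tumor samples that meet or exceed it:
#' \deqn{l_i = \frac{1}{m}\sum_k I(a_{1i} \ge a_{2k}), \qquad
#'       k_j = \frac{1}{n}\sum_k I(a_{2j} \le a_{1k}).}
#' Ties count as exceedance in both directions (the indicators are `>=` and
#' `<=`), so a constant gene has all proportions equal to 1; see
#' [cv_filter()] for removing such uninformative genes.
#'
#' @param tumor numeric vector of expression values in the case class.
#' @param normal numeric vector of expression values in the control class.
#' @return A list with components `l` (length `n`, multiples of `1/m`),
#'   `k` (length `m`, multiples of `1/n`), `n` and `m`.
#' @examples
#' exceedance_proportions(c(3, 1), c(2, 4))
#' @export
exceedance_proportions <- function(tumor, normal) {
  if (!length(tumor) || !length(normal))
    stop("both classes need at least one sample")
  if (anyNA(tumor) || anyNA(normal)) stop("missing values not allowed")
  l <- vapply(tumor, function(a) sum(a >= normal), numeric(1)) / length(normal)
  k <- vapply(normal, function(a) sum(a <= tumor), numeric(1)) / length(tumor)
  list(l = l, k = k, n = length(tumor), m = length(normal))
}

#' Tri-state regulation profile of a gene
#'
#' Thresholds the exceedance proportions at the regulation confidence cutoff
#' `tau` to assign each sample an up-regulated (+1), down-regulated (-1) or
#' non-regulated (0) status. A tumor sample is +1 when `l_i >= tau` and -1
#' when `1 - l_i > tau` (note the asymmetric boundary, which makes the
#' profile zero-free at `tau = 0.5`); normal samples use `k_j` the same way.
#'
#' @param props exceedance proportions from [exceedance_proportions()].
#' @param tau regulation confidence cutoff in `[0.5, 1]`.
#' @return Integer vector of length `n + m` in `{-1, 0, 1}`, tumor block
#'   first, with `tau` attached as an attribute.
#' @examples
#' pr <- exceedance_proportions(c(3, 1), c(2, 4))
#' regulation_profile(pr, tau = 0.7)
#' @export
regulation_profile <- function(props, tau) {
  check_tau(tau)
  tri <- function(p) {
    up <- p >= tau - 1e-9
    down <- !up & (1 - p > tau + 1e-9)
    ifelse(up, 1L, ifelse(down, -1L, 0L))
  }
  r <- c(tri(props$l), tri(props$k))
  attr(r, "tau") <- tau
  r
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) ||
      tau < 0.5 || tau > 1)
    stop("`tau` must be a single value in [0.5, 1]")
  invisible(tau)
}

#' GRP statistic from a regulation profile
#'
#' Estimates the regulation probabilities from the tri-state profile via
#' the total-probability decomposition over the two classes: `s_u` counts
#' the samples whose status is +1 (up-regulation evidence — a tumor sample
#' exceeding most normals, or a normal sample exceeded by most tumors),
#' `s_d` the samples with status -1, and
#' \deqn{P(U) = s_u/(n+m), \quad P(D) = s_d/(n+m), \quad T = P(U) - P(D).}
#' At `tau = 0.5` this is the hard-threshold counterpart of the aGRP
#' estimator (thresholding each exceedance proportion instead of averaging
#' it), and a completely separated gene scores `T = 1`.
#' The class priors are the empirical frequencies `n/(n+m)` and `m/(n+m)`.
#' The sum `S = P(U) + P(D)` equals 1 at `tau = 0.5` and decreases as `tau`
#' grows.
#'
#' @param profile integer regulation profile from [regulation_profile()],
#'   tumor block first.
#' @param n,m number of tumor and normal samples (`n + m` must equal
#'   `length(profile)`).
#' @return A list with `p_up`, `p_down`, `T`, `S`, `s_u`, `s_d`,
#'   `method = "grp"` and `tau` (if available from the profile).
#' @examples
#' pr <- exceedance_proportions(c(3, 1), c(2, 4))
#' grp_statistic(regulation_profile(pr, 0.7), n = 2, m = 2)
#' @export
grp_statistic <- function(profile, n, m) {
  if (length(profile) != n + m)
    stop("profile length must equal n + m")
  s_u <- sum(profile == 1L)
  s_d <- sum(profile == -1L)
  p_up <- s_u / (n + m)
  p_down <- s_d / (n + m)
  list(p_up = p_up, p_down = p_down, T = p_up - p_down, S = p_up + p_down,
       s_u = s_u, s_d = s_d, method = "grp", tau = attr(profile, "tau"))
}

#' aGRP statistic from exceedance proportions
#'
#' The cutoff-free unbiased estimator of the regulation probabilities:
#' \deqn{P(U) = \frac{1}{n+m}\Big(\sum_i l_i + \sum_j k_j\Big), \quad
#'       P(D) = 1 - P(U), \quad T = 2 P(U) - 1.}
#' Algebraically `T = 2U/(nm) - 1` with `U` the number of (tumor, normal)
#' pairs whose tumor value meets or exceeds the normal value, i.e. a
#' rescaling of the Mann-Whitney exceedance proportion to `[-1, 1]`.
#'
#' @param props exceedance proportions from [exceedance_proportions()].
#' @return A list with `p_up`, `p_down`, `T` and `method = "agrp"`;
#'   `p_up + p_down == 1` always holds.
#' @examples
#' agrp_statistic(exceedance_proportions(c(3, 1), c(2, 4)))
#' @export
agrp_statistic <- function(props) {
  p_up <- (sum(props$l) + sum(props$k)) / (props$n + props$m)
  list(p_up = p_up, p_down = 1 - p_up, T = 2 * p_up - 1, method = "agrp")
}

#' Per-gene regulation statistic
#'
#' Convenience wrapper computing the GRP or aGRP statistic for a single
#' gene from its raw expression values.
#'
#' @inheritParams exceedance_proportions
#' @param method `"agrp"` (default) or `"grp"`.
#' @param tau regulation confidence cutoff, required for `method = "grp"`.
#' @return See [agrp_statistic()] / [grp_statistic()].
#' @examples
#' regulation_stat(c(5, 3), c(1, 2), method = "agrp")
#' @export
regulation_stat <- function(tumor, normal, method = c("agrp", "grp"),
                            tau = NULL) {
  method <- match.arg(method)
  props <- exceedance_proportions(tumor, normal)
  if (method == "agrp") return(agrp_statistic(props))
  if (is.null(tau)) stop("`tau` is required for method = \"grp\"")
  grp_statistic(regulation_profile(props, tau), props$n, props$m)
}

#' Matrix-wide regulation statistics
#'
#' Computes the per-gene statistic `T` (and the regulation probabilities)
#' for every gene of a two-group dataset, without significance assessment.
#' This is the computational core of [grp_test()].
#'
#' @param x a [expression_dataset()] object, or a numeric matrix
#'   (genes x samples) together with `class`.
#' @param class sample class labels (ignored when `x` is a `grp_data`).
#' @param method `"agrp"` (default) or `"grp"`.
#' @param tau regulation confidence cutoff, required for `method = "grp"`.
#' @param case case-class label, see [expression_dataset()].
#' @return A data.frame with columns `gene_id`, `T`, `p_up`, `p_down`, in
#'   the row order of the input matrix.
#' @examples
#' x <- rbind(g1 = c(3, 1, 2, 4), g2 = c(5, 3, 1, 2))
#' colnames(x) <- paste0("s", 1:4)
#' compute_statistics(x, rep(c("tumor", "normal"), each = 2))
#' @export
compute_statistics <- function(x, class = NULL, method = c("agrp", "grp"),
                               tau = NULL, case = NULL) {
  method <- match.arg(method)
  ds <- as_grp_data(x, class, case)
  if (ds$n < 2 || ds$m < 2)
    stop("at least 2 samples per class are required")
  if (method == "grp") {
    if (is.null(tau)) stop("`tau` is required for method = \"grp\"")
    check_tau(tau)
  } else if (!is.null(tau)) {
    warning("`tau` is ignored for method = \"agrp\"")
  }
  so <- sorted_rows(ds$values)
  lab <- as.integer(ds$class == ds$case)
  st <- stat_matrix_cpp(so$xs, so$ord, lab, ds$n, ds$m,
                        method == "agrp", if (is.null(tau)) 0.5 else tau)
  data.frame(gene_id = rownames(ds$values), T = st[, 1],
             p_up = st[, 2], p_down = st[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Row-wise sort of the expression matrix for the C++ kernel: values
# ascending plus the 0-based sample order. O(G (n+m) log(n+m)).
sorted_rows <- function(x) {
  G <- nrow(x); N <- ncol(x)
  ord <- matrix(0L, G, N)
  xs <- matrix(0, G, N)
  for (g in seq_len(G)) {
    o <- order(x[g, ])
    ord[g, ] <- o - 1L
    xs[g, ] <- x[g, o]
  }
  list(xs = xs, ord = ord)
}
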