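#' Confusion metrics at a p-value threshold
#'
#' Calls a gene positive when `p < alpha` and scores the calls against the
#' ground-truth labels: sensitivity over truly differential genes (truth
#' `"up"` or `"down"`), specificity over null genes, and overall
#' classification accuracy `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param p per-gene p-values.
#' @param truth per-gene labels in `"null"`, `"up"`, `"down"` (any
#'   non-"null" label counts as truly differential).
#' @param alpha threshold in (0, 1); default 0.05.
#' @return A list with `sensitivity`, `specificity`, `accuracy` (a metric
#'   whose truth class is empty is `NA`), the confusion counts `tp`, `fp`,
#'   `tn`, `fn`, and `alpha`.
#' @examples
#' confusion_metrics(c(0.01, 0.2), c("up", "null"), alpha = 0.05)
#' @export
confusion_metrics <- function(p, truth, alpha = 0.05) {
  if (length(p) != length(truth)) stop("`p` and `truth` lengths differ")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  pos <- p < alpha
  de <- truth != "null"
  tp <- sum(pos & de); fn <- sum(!pos & de)
  fp <- sum(pos & !de); tn <- sum(!pos & !de)
  list(sensitivity = if (any(de)) tp / (tp + fn) else NA_real_,
       specificity = if (any(!de)) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(p),
       tp = tp, fp = fp, tn = tn, fn = fn, alpha = alpha)
}

#' Type-I error and power at a threshold
#'
#' @param p_null p-values of truly null genes.
#' @param p_de p-values of truly differential genes.
#' @param alpha threshold in (0, 1).
#' @return A list with `type1_error` (fraction of null genes with
#'   `p < alpha`) and `power` (fraction of DE genes with `p < alpha`).
#' @examples
#' type1_and_power(runif(100), rep(1e-6, 10), alpha = 0.05)
#' @export
type1_and_power <- function(p_null, p_de, alpha = 0.05) {
  if (!length(p_null) || !length(p_de)) stop("empty p-value input")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  list(type1_error = mean(p_null < alpha), power = mean(p_de < alpha))
}

#' Area under the ROC curve of a gene ranking
#'
#' Computes the AUC of ranking genes by `scores` (higher = more likely
#' differential) against the truth labels, via the rank form of the
#' Mann-Whitney exceedance probability. An optional `tiebreak` vector
#' (higher = ranked first among equal scores) resolves score ties, e.g.
#' rank by `abs(T)` with ties broken by smaller p-value
#' (`tiebreak = -p`); remaining full ties contribute 1/2 per pair.
#'
#' @param scores per-gene ranking scores.
#' @param truth per-gene labels as in [confusion_metrics()] (or a logical
#'   vector, `TRUE` = differential).
#' @param tiebreak optional secondary ranking key.
#' @return The AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 1, 0), c("up", "null", "null"), tiebreak = c(2, 1, 0))
#' @export
roc_auc <- function(scores, truth, tiebreak = NULL) {
  if (length(scores) != length(truth)) stop("length mismatch")
  de <- if (is.logical(truth)) truth else truth != "null"
  n1 <- sum(de); n0 <- sum(!de)
  if (n1 == 0 || n0 == 0)
    stop("both truth classes are required for an ROC curve")
  key <- rank(scores, ties.method = "average")
  if (!is.null(tiebreak)) {
    # strict primary order by score, secondary by tiebreak
    key <- rank(scores, ties.method = "min") * (length(scores) + 1) +
      rank(tiebreak, ties.method = "average")
  }
  r <- rank(key, ties.method = "average")
  (sum(r[de]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Split significant genes by regulation direction
#'
#' Partitions a set of significant genes by the sign of their statistic:
#' positive `T` (up-regulated in the case class, oncogene-like), negative
#' `T` (down-regulated, tumor suppressor-like); genes with `T` exactly 0
#' are reported separately as undirected.
#'
#' @param T named per-gene statistic vector (or a [grp_test()] fit).
#' @param calls character vector of significant gene ids (must be a subset
#'   of the names of `T`); for a `grp_test` fit, defaults to the genes
#'   whose `direction` is not `"none"`.
#' @return A list with character vectors `up`, `down` and `undirected`.
#' @examples
#' direction_split(c(a = 0.9, b = -0.9, c = 0.2), calls = c("a", "b"))
#' @export
direction_split <- function(T, calls = NULL) {
  if (inherits(T, "grp_test")) {
    fit <- T
    T <- stats::setNames(fit$table$T, fit$table$gene_id)
    if (is.null(calls))
      calls <- fit$table$gene_id[fit$table$direction %in% c("up", "down")]
  }
  if (is.null(names(T))) stop("`T` must be named by gene id")
  if (is.null(calls)) calls <- names(T)
  if (!all(calls %in% names(T)))
    stop("`calls` contains genes absent from `T`")
  tc <- T[calls]
  list(up = names(tc)[tc > 0], down = names(tc)[tc < 0],
       undirected = names(tc)[tc == 0])
}

#' Cross-dataset consistency of the regulation statistic
#'
#' Bins genes by the magnitude of their statistic into the intervals
#' `[eta, eta + 0.1]` and, per interval, measures how consistently the
#' datasets agree: `prop_common` is the fraction of genes present in all
#' datasets among the union of genes falling in the interval in any
#' dataset, and `prop_same_direction` is the fraction of those common
#' genes whose statistic sign is identical across all datasets. Interval
#' membership treats the shared endpoint as belonging to the lower
#' interval (so the bins are `[0.5, 0.6], (0.6, 0.7], ...`).
#'
#' @param stat_tables a list (length >= 2) of named numeric vectors
#'   mapping gene id to statistic `T`, one per dataset.
#' @param eta_grid interval start points (default `seq(0.5, 0.9, 0.1)`).
#' @return A data.frame with columns `eta_lo`, `eta_hi`, `n_union`,
#'   `n_common`, `prop_common`, `prop_same_direction` (proportions are
#'   `NA` when the interval's union, or the common set, is empty).
#' @examples
#' tabs <- list(d1 = c(a = 0.95, b = 0.55), d2 = c(a = 0.92, b = -0.58))
#' consistency_analysis(tabs)
#' @export
consistency_analysis <- function(stat_tables, eta_grid = seq(0.5, 0.9, 0.1)) {
  if (!is.list(stat_tables) || length(stat_tables) < 2)
    stop("at least two datasets are required")
  if (any(!vapply(stat_tables, function(t) is.numeric(t) && !is.null(names(t)),
                  logical(1))))
    stop("each stat table must be a named numeric vector")
  out <- data.frame(eta_lo = eta_grid, eta_hi = eta_grid + 0.1,
                    n_union = NA_integer_, n_common = NA_integer_,
                    prop_common = NA_real_, prop_same_direction = NA_real_)
  for (i in seq_along(eta_grid)) {
    lo <- eta_grid[i]; hi <- eta_grid[i] + 0.1
    eps <- 1e-12
    members <- lapply(stat_tables, function(t) {
      a <- abs(t)
      # closed lowest bin, then half-open (lo, hi]
      inb <- if (i == 1) a >= lo - eps & a <= hi + eps
             else a > lo + eps & a <= hi + eps
      names(t)[inb]
    })
    uni <- Reduce(union, members)
    com <- Reduce(intersect, members)
    out$n_union[i] <- length(uni)
    out$n_common[i] <- length(com)
    out$prop_common[i] <- if (length(uni)) length(com) / length(uni) else NA_real_
    if (length(com)) {
      signs <- vapply(stat_tables, function(t) sign(t[com]),
                      numeric(length(com)))
      signs <- matrix(signs, nrow = length(com))
      out$prop_same_direction[i] <-
        mean(apply(signs, 1, function(s) all(s == s[1])))
    }
  }
  out
}

#' Benchmark a method over replicate simulations
#'
#' Applies [grp_test()] to each replicate dataset and scores it against
#' the simulator truth at threshold `alpha` on the raw p-values (the
#' benchmark protocol), collecting sensitivity, specificity, AUC (ranking
#' by `|T|`, ties broken by smaller p), accuracy, type-I error and power.
#'
#' @param sims list of `grp_sim` objects (see [replicate_study()]).
#' @param method,tau,p.value,B passed to [grp_test()].
#' @param seeds optional integer vector, one permutation seed per
#'   replicate.
#' @param alpha threshold on the raw p-value.
#' @return A data.frame with one row per replicate and a `summary`
#'   attribute: a data.frame of per-metric mean and sd.
#' @examples
#' sims <- replicate_study(simulate_clumped, seeds = 1:2, G = 100, n = 6,
#'                         n_null = 60, n_up = 20, n_down = 20)
#' res <- benchmark_replicates(sims, B = 50, seeds = 11:12)
#' attr(res, "summary")
#' @export
benchmark_replicates <- function(sims, method = "agrp", tau = NULL,
                                 p.value = "permutation", B = 1000,
                                 seeds = NULL, alpha = 0.05) {
  stopifnot(length(sims) >= 1)
  if (is.null(seeds)) seeds <- rep(list(NULL), length(sims))
  if (length(seeds) != length(sims))
    stop("one permutation seed per replicate is required")
  rows <- lapply(seq_along(sims), function(i) {
    sim <- sims[[i]]
    fit <- grp_test(sim$dataset, method = method, tau = tau,
                    p.value = p.value, B = B, seed = seeds[[i]],
                    alpha = alpha, bh = FALSE)
    tab <- fit$table
    cm <- confusion_metrics(tab$p_raw, sim$truth, alpha)
    de <- sim$truth != "null"
    auc <- if (any(de) && any(!de))
      roc_auc(abs(tab$T), sim$truth, tiebreak = -tab$p_raw) else NA_real_
    data.frame(replicate = i,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               auc = auc, accuracy = cm$accuracy,
               type1_error = if (any(!de)) mean(tab$p_raw[!de] < alpha)
                             else NA_real_,
               power = if (any(de)) mean(tab$p_raw[de] < alpha)
                       else NA_real_)
  })
  res <- do.call(rbind, rows)
  metrics <- setdiff(names(res), "replicate")
  attr(res, "summary") <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(mm) mean(res[[mm]]), numeric(1)),
    sd = vapply(metrics, function(mm) sd(res[[mm]]), numeric(1)),
    reps = nrow(res), alpha = alpha, row.names = NULL)
  res
}
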