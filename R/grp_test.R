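#' Two-group differential expression test via regulation probabilities
#'
#' The main fitting function. For every gene it estimates the regulation
#' probability statistic `T = P(U) - P(D)` between the case (tumor) and
#' control (normal) classes — with the cutoff-free aGRP estimator by
#' default, or the hard-cutoff GRP estimator when `method = "grp"` — and
#' attaches two-sided significance: a permutation null over shared label
#' shuffles (default) or the asymptotic normal null for aGRP. Raw p-values
#' are Benjamini-Hochberg adjusted, and each significant gene is assigned a
#' regulation direction by the sign of `T` (positive: up-regulated in the
#' case class, oncogene-like; negative: down-regulated, tumor
#' suppressor-like).
#'
#' @inheritParams compute_statistics
#' @param p.value significance engine: `"permutation"` (default),
#'   `"asymptotic"` (aGRP only), or `"none"` to skip p-values.
#' @param B number of label permutations (default 1000).
#' @param seed integer seed for the permutation shuffles.
#' @param alpha significance threshold used for the direction call.
#' @param bh if `TRUE` (default) the direction call thresholds the
#'   BH-adjusted value, otherwise the raw p-value.
#' @return An object of class `grp_test`: a list with `table` (data.frame
#'   with columns `gene_id`, `T`, `p_up`, `p_down`, `p_raw`, `q_bh`,
#'   `direction`, in input gene order), the design sizes `n`, `m`, and the
#'   run settings. Methods: `print`, `summary`, `coef` (named `T` vector),
#'   `plot` (volcano-style), `as.data.frame`.
#' @examples
#' sim <- simulate_simple(G_null = 50, G_de = 50, n = 10, seed = 1)
#' ds <- merge_datasets(sim$null, sim$de)
#' fit <- grp_test(ds$dataset, B = 100, seed = 2)
#' fit
#' head(as.data.frame(fit))
#' @seealso [compute_statistics()], [permutation_pvalues()],
#'   [asymptotic_pvalue()]
#' @export
grp_test <- function(x, class = NULL, method = c("agrp", "grp"), tau = NULL,
                     p.value = c("permutation", "asymptotic", "none"),
                     B = 1000, seed = NULL, alpha = 0.05, bh = TRUE,
                     case = NULL) {
  method <- match.arg(method)
  p.value <- match.arg(p.value)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single value in (0, 1)")
  ds <- as_grp_data(x, class, case)
  stats_df <- compute_statistics(ds, method = method, tau = tau)

  p_raw <- q_bh <- rep(NA_real_, nrow(stats_df))
  if (p.value == "asymptotic") {
    if (method != "agrp")
      stop("the asymptotic null is derived for aGRP only; ",
           "use p.value = \"permutation\" for GRP")
    p_raw <- asymptotic_pvalue(stats_df$T, ds$n, ds$m)
  } else if (p.value == "permutation") {
    p_raw <- permutation_pvalues(ds, method = method, tau = tau,
                                 B = B, seed = seed)
  }
  direction <- rep(NA_character_, nrow(stats_df))
  if (p.value != "none") {
    q_bh <- bh_adjust(p_raw)
    crit <- if (bh) q_bh else p_raw
    direction <- ifelse(crit >= alpha, "none",
                        ifelse(stats_df$T > 0, "up",
                               ifelse(stats_df$T < 0, "down", "none")))
  }
  tab <- cbind(stats_df,
               data.frame(p_raw = unname(p_raw), q_bh = q_bh,
                          direction = direction, stringsAsFactors = FALSE))
  structure(list(table = tab, method = method, tau = tau, engine = p.value,
                 B = if (p.value == "permutation") B else NULL,
                 seed = seed, alpha = alpha, bh = bh,
                 n = ds$n, m = ds$m, case = ds$case, control = ds$control,
                 call = match.call()),
            class = "grp_test")
}

#' @export
print.grp_test <- function(x, ...) {
  cat(sprintf("grp_test: %s statistic%s, %d genes, %d %s vs %d %s\n",
              if (x$method == "agrp") "aGRP" else "GRP",
              if (!is.null(x$tau)) sprintf(" (tau = %g)", x$tau) else "",
              nrow(x$table), x$n, x$case, x$m, x$control))
  if (x$engine != "none") {
    cat(sprintf("significance: %s%s; direction at %s < %g\n", x$engine,
                if (!is.null(x$B)) sprintf(" (B = %d)", x$B) else "",
                if (x$bh) "BH q" else "raw p", x$alpha))
    ncall <- table(factor(x$table$direction, c("up", "down", "none")))
    cat(sprintf("called: %d up, %d down, %d not significant\n",
                ncall[["up"]], ncall[["down"]], ncall[["none"]]))
  }
  invisible(x)
}

#' @export
summary.grp_test <- function(object, n_top = 10, ...) {
  tab <- object$table
  o <- order(if (object$engine == "none") -abs(tab$T) else tab$q_bh,
             -abs(tab$T))
  structure(list(fit = object, top = head(tab[o, , drop = FALSE], n_top)),
            class = "summary.grp_test")
}

#' @export
print.summary.grp_test <- function(x, ...) {
  print(x$fit)
  cat("\ntop genes:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.grp_test <- function(object, ...) {
  stats::setNames(object$table$T, object$table$gene_id)
}

#' @export
as.data.frame.grp_test <- function(x, ...) x$table

#' Volcano-style plot of a regulation-probability fit
#'
#' Plots `-log10(p)` against the statistic `T`, colouring genes by their
#' direction call.
#'
#' @param x a [grp_test()] fit with p-values.
#' @param ... passed to [graphics::plot()].
#' @export
plot.grp_test <- function(x, ...) {
  if (x$engine == "none")
    stop("fit has no p-values; rerun with a significance engine")
  tab <- x$table
  col <- c(up = "firebrick", down = "navy", none = "grey60")[tab$direction]
  plot(tab$T, -log10(tab$p_raw), col = col, pch = 16, cex = 0.6,
       xlab = expression(T == P(U) - P(D)), ylab = expression(-log[10](p)),
       xlim = c(-1, 1), ...)
  abline(h = -log10(x$alpha), lty = 2, col = "grey40")
  legend("topleft", legend = c("up", "down", "not significant"),
         col = c("firebrick", "navy", "grey60"), pch = 16, bty = "n")
  invisible(x)
}
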