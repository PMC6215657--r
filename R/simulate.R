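#' Simple two-normal benchmark simulator
#'
#' Generates the two gene groups of the simple benchmark design: group I
#' (`G_null` genes) has all `2n` values i.i.d. standard normal in both
#' classes; group II (`G_de` genes) has tumor-class values i.i.d.
#' `N(delta, sigma^2)` and normal-class values i.i.d. `N(0, sigma^2)`, so
#' every group II gene is truly up-regulated with per-pair exceedance
#' probability `q = pnorm(delta / (sigma * sqrt(2)))` (about 0.8556 at the
#' defaults `delta = 0.15`, `sigma = 0.1`).
#'
#' @param G_null number of null genes (group I); default 1000.
#' @param G_de number of differentially expressed genes (group II);
#'   default 1000.
#' @param n samples per class; the benchmark design uses 6, 10, 20, 50.
#' @param delta mean shift of the tumor class in group II (default 0.15).
#' @param sigma common standard deviation in group II (default 0.1).
#' @param seed integer seed; the same seed reproduces the matrices exactly.
#' @return A list with components `null` and `de` (either may be absent if
#'   its gene count is 0), each a `grp_sim` object: a list with `dataset`
#'   (a [expression_dataset()]), `truth` (per-gene `"null"`/`"up"`) and
#'   `params`.
#' @examples
#' sim <- simulate_simple(G_null = 100, G_de = 100, n = 10, seed = 1)
#' sim$de
#' @export
simulate_simple <- function(G_null = 1000, G_de = 1000, n = 10,
                            delta = 0.15, sigma = 0.1, seed = NULL) {
  if (sigma <= 0) stop("`sigma` must be positive")
  if (n < 2) stop("`n` must be at least 2")
  if (G_null < 0 || G_de < 0 || G_null + G_de < 1)
    stop("invalid gene counts")
  if (!is.null(seed)) set.seed(seed)
  samp <- c(paste0("T", seq_len(n)), paste0("N", seq_len(n)))
  cls <- rep(c("tumor", "normal"), each = n)
  params <- list(design = "simple", G_null = G_null, G_de = G_de, n = n,
                 delta = delta, sigma = sigma, seed = seed)
  out <- list()
  if (G_null > 0) {
    x0 <- matrix(rnorm(G_null * 2 * n), nrow = G_null,
                 dimnames = list(sprintf("null_g%04d", seq_len(G_null)), samp))
    out$null <- new_grp_sim(expression_dataset(x0, cls),
                            rep("null", G_null), params)
  }
  if (G_de > 0) {
    x1 <- cbind(matrix(rnorm(G_de * n, mean = delta, sd = sigma), nrow = G_de),
                matrix(rnorm(G_de * n, mean = 0, sd = sigma), nrow = G_de))
    dimnames(x1) <- list(sprintf("de_g%04d", seq_len(G_de)), samp)
    out$de <- new_grp_sim(expression_dataset(x1, cls),
                          rep("up", G_de), params)
  }
  out
}

new_grp_sim <- function(dataset, truth, params) {
  stopifnot(length(truth) == nrow(dataset$values))
  structure(list(dataset = dataset, truth = truth, params = params),
            class = "grp_sim")
}

#' @export
print.grp_sim <- function(x, ...) {
  tt <- table(factor(x$truth, c("null", "up", "down")))
  cat(sprintf("grp_sim (%s design): %d genes x %d samples; truth: %d null, %d up, %d down\n",
              x$params$design, nrow(x$dataset$values), ncol(x$dataset$values),
              tt[["null"]], tt[["up"]], tt[["down"]]))
  invisible(x)
}

#' Merge simulated datasets sharing a sample design
#'
#' Stacks the gene rows of two or more `grp_sim` objects (e.g. the null and
#' DE groups from [simulate_simple()]) into one dataset with concatenated
#' truth labels.
#'
#' @param ... `grp_sim` objects with identical sample ids and classes.
#' @return A single `grp_sim` object.
#' @export
merge_datasets <- function(...) {
  sims <- list(...)
  if (length(sims) == 1 && is.list(sims[[1]]) && !inherits(sims[[1]], "grp_sim"))
    sims <- sims[[1]]
  stopifnot(length(sims) >= 1, all(vapply(sims, inherits, TRUE, "grp_sim")))
  ref <- sims[[1]]$dataset
  for (s in sims[-1]) {
    if (!identical(colnames(s$dataset$values), colnames(ref$values)) ||
        !identical(s$dataset$class, ref$class))
      stop("datasets must share sample ids and classes")
  }
  x <- do.call(rbind, lapply(sims, function(s) s$dataset$values))
  truth <- unlist(lapply(sims, `[[`, "truth"), use.names = FALSE)
  new_grp_sim(expression_dataset(x, ref$class, case = ref$case),
              truth, sims[[1]]$params)
}

#' Correlated gene-clump expression simulator
#'
#' Generates heterogeneous microarray-like expression data with a
#' block-correlated noise background, mimicking co-regulated gene clumps:
#'
#' 1. Genes are partitioned into clumps whose sizes are drawn uniformly
#'    from `{1, ..., clump_max}` (the last clump is truncated to fit `G`),
#'    each clump receiving a compound-symmetric correlation
#'    `rho ~ U(0.5, 1)`.
#' 2. For each sample the clump noise vector is drawn from
#'    `N(0, (1 - rho) I + rho 1 1')`.
#' 3. Baseline values are `x_gj = mu_g + omega_g e_gj` with baseline mean
#'    `mu_g ~ 1000 chi^2_5` and noise scale
#'    `omega_g = exp(beta0/2) mu_g^(beta1/2)`; at the defaults
#'    `beta0 = -5, beta1 = 2` this gives a constant coefficient of
#'    variation `exp(beta0/2)` of about 8.2%.
#' 4. Differential genes multiply (up) or divide (down) the tumor-class
#'    mean by the ratio `r_g = 1 + 2^(-1/2) exp(beta0/2) delta_g`,
#'    `delta_g ~ U(delta_range[1], delta_range[2])`, with `omega`
#'    recomputed from the class-specific mean (set `shared_omega = TRUE`
#'    to keep the baseline noise scale instead).
#'
#' With the default `delta_range = c(1, 2)` the expression ratios fall in
#' about (1.058, 1.116) — subtle shifts of roughly 0.7–1.4 baseline
#' standard deviations, the regime where partial power at moderate sample
#' sizes is expected. See the vignette for discussion of this choice.
#'
#' @param G total number of genes (default 10000).
#' @param n samples per class (default 10).
#' @param n_null,n_up,n_down truth design; defaults 6000/2000/2000. Must
#'   sum to `G`. DE labels are assigned to genes uniformly at random,
#'   independent of clump membership.
#' @param beta0,beta1 noise-scale parameters (defaults -5 and 2).
#' @param delta_range range of the effect-size draw `delta_g`.
#' @param clump_max largest clump size (default 100).
#' @param shared_omega keep the baseline `omega` for DE genes.
#' @param seed integer seed.
#' @return A `grp_sim` object; `params` records the full design, including
#'   the realised clump sizes and correlations.
#' @examples
#' sim <- simulate_clumped(G = 200, n = 6, n_null = 120, n_up = 40,
#'                         n_down = 40, seed = 1)
#' sim
#' @export
simulate_clumped <- function(G = 10000, n = 10, n_null = 0.6 * G,
                             n_up = 0.2 * G, n_down = 0.2 * G,
                             beta0 = -5, beta1 = 2, delta_range = c(1, 2),
                             clump_max = 100, shared_omega = FALSE,
                             seed = NULL) {
  if (n < 2) stop("`n` must be at least 2")
  n_null <- round(n_null); n_up <- round(n_up); n_down <- round(n_down)
  if (n_null < 0 || n_up < 0 || n_down < 0 || n_null + n_up + n_down != G)
    stop("truth design must be non-negative and sum to G")
  if (length(delta_range) != 2 || delta_range[1] > delta_range[2])
    stop("`delta_range` must be an increasing pair")
  if (!is.null(seed)) set.seed(seed)

  # clump partition: i.i.d. uniform sizes, last clump truncated to fit G
  sizes <- integer(0)
  while (sum(sizes) < G)
    sizes <- c(sizes, sample.int(clump_max, size = ceiling(G / clump_max) + 8,
                                 replace = TRUE))
  sizes <- sizes[cumsum(sizes) - sizes < G]
  sizes[length(sizes)] <- G - sum(sizes[-length(sizes)])
  nclump <- length(sizes)
  clump <- rep.int(seq_len(nclump), sizes)
  rho <- runif(nclump, 0.5, 1)

  # compound-symmetric clump noise: sqrt(1-rho) z_gj + sqrt(rho) w_cj
  N <- 2 * n
  z <- matrix(rnorm(G * N), G, N)
  w <- matrix(rnorm(nclump * N), nclump, N)
  e <- sqrt(1 - rho[clump]) * z + sqrt(rho[clump]) * w[clump, , drop = FALSE]

  mu <- 1000 * rchisq(G, df = 5)
  omega <- exp(beta0 / 2) * mu^(beta1 / 2)
  x <- mu + omega * e

  truth <- sample(rep(c("null", "up", "down"), c(n_null, n_up, n_down)))
  delta <- runif(G, delta_range[1], delta_range[2])
  ratio <- 1 + 2^(-0.5) * exp(beta0 / 2) * delta
  mu_t <- mu
  mu_t[truth == "up"] <- mu[truth == "up"] * ratio[truth == "up"]
  mu_t[truth == "down"] <- mu[truth == "down"] / ratio[truth == "down"]
  omega_t <- if (shared_omega) omega else exp(beta0 / 2) * mu_t^(beta1 / 2)
  de <- truth != "null"
  x[de, seq_len(n)] <- mu_t[de] + omega_t[de] * e[de, seq_len(n), drop = FALSE]

  dimnames(x) <- list(sprintf("g%05d", seq_len(G)),
                      c(paste0("T", seq_len(n)), paste0("N", seq_len(n))))
  ds <- expression_dataset(x, rep(c("tumor", "normal"), each = n))
  params <- list(design = "clumped", G = G, n = n, n_null = n_null,
                 n_up = n_up, n_down = n_down, beta0 = beta0, beta1 = beta1,
                 delta_range = delta_range, clump_max = clump_max,
                 shared_omega = shared_omega, seed = seed,
                 clump_sizes = sizes, clump_rho = rho, clump = clump,
                 delta = delta, ratio = ratio)
  new_grp_sim(ds, truth, params)
}

#' Generate independent replicate datasets
#'
#' Runs a simulator once per seed to produce independent replicate
#' datasets, the design used to report benchmark metrics as mean +/- sd
#' over (by default 20) replicates.
#'
#' @param generator a simulator function taking a `seed` argument, e.g.
#'   [simulate_clumped()] or a wrapper around [simulate_simple()].
#' @param seeds integer vector, one seed per replicate (duplicates warn).
#' @param ... further arguments passed to `generator`.
#' @return A list of simulator results, one per seed.
#' @examples
#' reps <- replicate_study(simulate_clumped, seeds = 1:3, G = 50, n = 6,
#'                         n_null = 30, n_up = 10, n_down = 10)
#' length(reps)
#' @export
replicate_study <- function(generator, seeds, ...) {
  if (!length(seeds)) stop("at least one seed is required")
  if (anyDuplicated(seeds))
    warning("duplicate seeds: replicates will not be independent")
  lapply(seeds, function(s) generator(seed = s, ...))
}
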