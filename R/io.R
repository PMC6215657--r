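#' Read an expression matrix and sample labels
#'
#' Reads a delimited text expression matrix (genes in rows, first column
#' gene ids, header row of sample ids) plus a two-column sample/class
#' labels file, and validates them into an [expression_dataset()]. The
#' delimiter (tab or comma) is auto-detected per file. Errors name the
#' offending gene, sample or class.
#'
#' @param matrix_path path to the matrix file.
#' @param labels_path path to the labels file (header `sample`, `class`;
#'   any header names are accepted, the first two columns are used).
#' @param case case-class label, see [expression_dataset()].
#' @return A `grp_data` object.
#' @export
read_expression <- function(matrix_path, labels_path, case = NULL) {
  sep <- detect_sep(matrix_path)
  raw <- read.table(matrix_path, header = TRUE, sep = sep,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"")
  if (ncol(raw) < 2) stop("matrix file needs a gene-id column plus samples")
  gene_ids <- as.character(raw[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     v[bad[1]], gene_ids[bad[1]], colnames(vals)[j]))
      vals[[j]] <- vn
    }
    if (anyNA(vals[[j]]))
      stop(sprintf("missing value at gene '%s', sample '%s'",
                   gene_ids[which(is.na(vals[[j]]))[1]], colnames(vals)[j]))
  }
  x <- as.matrix(vals)
  rownames(x) <- gene_ids

  lsep <- detect_sep(labels_path)
  lab <- read.table(labels_path, header = TRUE, sep = lsep,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("labels file needs sample and class columns")
  cls <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  if (anyDuplicated(names(cls)))
    stop("duplicate sample id(s) in labels file")
  missing_s <- setdiff(colnames(x), names(cls))
  if (length(missing_s))
    stop("matrix sample(s) absent from labels: ",
         paste(missing_s, collapse = ", "))
  cls <- cls[colnames(x)]
  lev <- unique(cls)
  if (length(lev) != 2)
    stop("labels must define exactly two classes, found: ",
         paste(lev, collapse = ", "))
  expression_dataset(x, cls, case = case)
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

fmt_num <- function(x) {
  # full-precision decimal serialization so write/read round-trips exactly
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
}

#' Write an expression dataset (and optional truth) to delimited text
#'
#' Writes the matrix as tab-delimited genes x samples text with full
#' numeric precision (a write/read round trip reproduces the values
#' exactly), the labels as a two-column sample/class file, and — for
#' simulated data — the per-gene truth and the parameter record.
#'
#' @param ds a `grp_data` or `grp_sim` object.
#' @param matrix_path,labels_path output paths.
#' @param truth_path optional path for the gene/truth table (`grp_sim`
#'   input only).
#' @param config_path optional path for the simulation parameter record,
#'   written in DCF key-value format.
#' @return Invisibly, `ds`.
#' @export
write_expression <- function(ds, matrix_path, labels_path,
                             truth_path = NULL, config_path = NULL) {
  sim <- NULL
  if (inherits(ds, "grp_sim")) { sim <- ds; ds <- ds$dataset }
  stopifnot(inherits(ds, "grp_data"))
  x <- ds$values
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(g)
               paste(c(rownames(x)[g], fmt_num(x[g, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, matrix_path)
  writeLines(c("sample\tclass",
               paste(colnames(x), ds$class, sep = "\t")), labels_path)
  if (!is.null(truth_path)) {
    if (is.null(sim)) stop("truth output requires a grp_sim input")
    writeLines(c("gene_id\ttruth",
                 paste(rownames(x), sim$truth, sep = "\t")), truth_path)
  }
  if (!is.null(config_path)) {
    if (is.null(sim)) stop("config output requires a grp_sim input")
    p <- sim$params
    p <- p[vapply(p, function(v) is.atomic(v) && length(v) <= 2, logical(1))]
    write.dcf(data.frame(lapply(p, function(v)
      paste(v, collapse = ",")), check.names = FALSE), config_path)
  }
  invisible(ds)
}

#' Collapse probe rows to gene rows
#'
#' Averages the rows (probe intensities) mapping to the same gene id, the
#' standard microarray preprocessing step before gene-level analysis.
#' Probes absent from the map are dropped with a message.
#'
#' @param ds a `grp_data` object whose rownames are probe ids.
#' @param map a data.frame whose first two columns are probe id and gene
#'   id (many probes per gene allowed).
#' @return A `grp_data` object with one row per mapped gene.
#' @examples
#' x <- rbind(p1 = c(1, 3, 2, 2), p2 = c(3, 5, 2, 2))
#' colnames(x) <- paste0("s", 1:4)
#' ds <- expression_dataset(x, rep(c("tumor", "normal"), each = 2))
#' collapse_probes(ds, data.frame(probe = c("p1", "p2"),
#'                                gene = c("X", "X")))
#' @export
collapse_probes <- function(ds, map) {
  stopifnot(inherits(ds, "grp_data"), is.data.frame(map), ncol(map) >= 2)
  probe2gene <- stats::setNames(as.character(map[[2]]), as.character(map[[1]]))
  keep <- rownames(ds$values) %in% names(probe2gene)
  if (!any(keep)) stop("no probes map to a gene; check the probe map")
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " unmapped probe(s) dropped")
  x <- ds$values[keep, , drop = FALSE]
  gene <- probe2gene[rownames(x)]
  collapsed <- rowsum(x, group = gene) / as.vector(table(gene)[sort(unique(gene))])
  expression_dataset(collapsed, ds$class, case = ds$case)
}

#' Coefficient-of-variation filter
#'
#' Removes low-variability genes: a gene is retained when its coefficient
#' of variation `sd / |mean|` over all samples is at least `cutoff`.
#' Genes with mean exactly zero are dropped. Besides removing
#' uninformative near-constant genes, this eliminates the all-ties
#' pathology of the exceedance indicators (a constant gene scores
#' `T = 1`).
#'
#' @param ds a `grp_data` object.
#' @param cutoff CV threshold (default 0.05).
#' @return The filtered `grp_data`; removal counts are messaged.
#' @export
cv_filter <- function(ds, cutoff = 0.05) {
  stopifnot(inherits(ds, "grp_data"))
  if (cutoff < 0) stop("`cutoff` must be non-negative")
  mu <- rowMeans(ds$values)
  sdv <- apply(ds$values, 1, sd)
  keep <- mu != 0 & (sdv / abs(mu)) >= cutoff
  if (!any(keep)) stop("CV filter removed every gene")
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " gene(s) removed by CV filter (cutoff ",
                      cutoff, ")")
  expression_dataset(ds$values[keep, , drop = FALSE], ds$class,
                     case = ds$case)
}

#' Write per-gene results to delimited text
#'
#' Writes the per-gene table of a [grp_test()] fit (or a compatible
#' data.frame) with columns `gene_id`, `T`, `p_up`, `p_down`, `p_raw`,
#' `q_bh`, `direction`, ordered by ascending `q_bh` then descending
#' `|T|`, at full numeric precision.
#'
#' @param fit a `grp_test` fit or a data.frame with the columns above.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return Invisibly, the ordered data.frame that was written.
#' @export
write_results <- function(fit, path, sep = "\t") {
  tab <- if (inherits(fit, "grp_test")) fit$table else fit
  cols <- c("gene_id", "T", "p_up", "p_down", "p_raw", "q_bh", "direction")
  missing_c <- setdiff(cols, names(tab))
  if (length(missing_c))
    stop("results table lacks column(s): ", paste(missing_c, collapse = ", "))
  tab <- tab[cols]
  if (nrow(tab)) {
    o <- order(tab$q_bh, -abs(tab$T), tab$gene_id)
    tab <- tab[o, , drop = FALSE]
  }
  lines <- paste(cols, collapse = sep)
  if (nrow(tab)) {
    body <- vapply(seq_len(nrow(tab)), function(i)
      paste(c(tab$gene_id[i], fmt_num(unlist(tab[i, 2:6])),
              as.character(tab$direction[i])), collapse = sep),
      character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(tab)
}

#' Read a results file written by [write_results()]
#'
#' @param path path to the results file.
#' @return A data.frame with the standard result columns.
#' @export
read_results <- function(path) {
  sep <- detect_sep(path)
  read.table(path, header = TRUE, sep = sep, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Bundles the settings of an analysis run into a validated record that
#' serializes to and from DCF key-value text, so every run can log and
#' reproduce its full configuration.
#'
#' @param method `"agrp"` or `"grp"`.
#' @param tau regulation confidence cutoff (GRP only).
#' @param pvalue_engine `"permutation"` or `"asymptotic"`.
#' @param B permutation count.
#' @param seed integer seed.
#' @param alpha significance threshold.
#' @param bh use BH-adjusted values for the direction call.
#' @param cv_cutoff CV filter threshold (`NA` disables the filter).
#' @return An object of class `run_config`.
#' @export
run_config <- function(method = "agrp", tau = NULL,
                       pvalue_engine = "permutation", B = 1000,
                       seed = NULL, alpha = 0.05, bh = TRUE,
                       cv_cutoff = NA_real_) {
  method <- match.arg(method, c("agrp", "grp"))
  pvalue_engine <- match.arg(pvalue_engine, c("permutation", "asymptotic"))
  if (method == "grp") check_tau(tau)
  structure(list(method = method, tau = tau, pvalue_engine = pvalue_engine,
                 B = B, seed = seed, alpha = alpha, bh = bh,
                 cv_cutoff = cv_cutoff),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- lapply(config, function(v) if (is.null(v)) "" else as.character(v))
  write.dcf(as.data.frame(flat, stringsAsFactors = FALSE), path)
  invisible(config)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  d <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(v) if (is.null(v) || v == "") NULL else as.numeric(v)
  run_config(method = d$method,
             tau = num(d$tau),
             pvalue_engine = d$pvalue_engine,
             B = as.integer(num(d$B)),
             seed = if (is.null(num(d$seed))) NULL else as.integer(num(d$seed)),
             alpha = num(d$alpha),
             bh = as.logical(d$bh),
             cv_cutoff = if (is.null(num(d$cv_cutoff))) NA_real_
                         else num(d$cv_cutoff))
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s\n", nm,
                if (is.null(x[[nm]])) "<unset>" else paste(x[[nm]],
                                                           collapse = ",")))
  invisible(x)
}
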