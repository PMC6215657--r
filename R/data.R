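#' Construct a labelled two-group expression dataset
#'
#' Bundles a genes-by-samples expression matrix with a binary class
#' assignment (case/tumor vs control/normal). Both microarray intensities
#' and RNA-seq counts are accepted: the regulation-probability statistics
#' are comparison-based and use only the within-gene ordering of values.
#'
#' @param x numeric matrix, genes in rows (unique rownames required),
#'   samples in columns (unique colnames required). Missing values are
#'   rejected; drop or impute them beforehand.
#' @param class character or factor of length `ncol(x)` giving each
#'   sample's class; exactly two distinct classes are required. May be
#'   named by sample id, in which case it is matched to `colnames(x)`.
#' @param case the class label to treat as the case (tumor) group.
#'   Defaults to `"tumor"` when that label is present; otherwise it must
#'   be given explicitly.
#'
#' @return An object of class `grp_data`: a list with elements `values`
#'   (the matrix, case columns first), `class` (character vector aligned
#'   to columns), `case`, `control`, `n` (case count) and `m` (control
#'   count).
#' @examples
#' x <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' ds <- expression_dataset(x, rep(c("tumor", "normal"), each = 5))
#' ds
#' @export
expression_dataset <- function(x, class, case = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("`x` must have unique rownames (gene ids)")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("`x` must have unique colnames (sample ids)")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value in expression matrix at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  class <- as.character(class)
  if (!is.null(names(class))) {
    missing_s <- setdiff(colnames(x), names(class))
    if (length(missing_s))
      stop("sample(s) absent from class labels: ",
           paste(missing_s, collapse = ", "))
    class <- class[colnames(x)]
  }
  if (length(class) != ncol(x))
    stop("`class` must have one entry per sample column")
  if (anyNA(class)) stop("missing class labels")
  lev <- unique(class)
  if (length(lev) != 2)
    stop("exactly two classes required, found: ", paste(lev, collapse = ", "))
  if (is.null(case)) {
    if ("tumor" %in% lev) case <- "tumor"
    else stop("`case` must name the case class (one of: ",
              paste(lev, collapse = ", "), ")")
  }
  if (!case %in% lev)
    stop(sprintf("case class '%s' not present in labels", case))
  control <- setdiff(lev, case)
  ord <- order(match(class, c(case, control)))
  x <- x[, ord, drop = FALSE]
  class <- class[ord]
  structure(list(values = x, class = class, case = case, control = control,
                 n = sum(class == case), m = sum(class == control)),
            class = "grp_data")
}

#' @export
print.grp_data <- function(x, ...) {
  cat(sprintf("grp_data: %d genes x %d samples (%d %s / %d %s)\n",
              nrow(x$values), ncol(x$values), x$n, x$case, x$m, x$control))
  invisible(x)
}

#' @export
dim.grp_data <- function(x) dim(x$values)

# Coerce matrix + class to grp_data if needed (internal).
as_grp_data <- function(x, class = NULL, case = NULL) {
  if (inherits(x, "grp_data")) return(x)
  if (is.null(class)) stop("`class` labels required when `x` is a matrix")
  expression_dataset(x, class, case = case)
}
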