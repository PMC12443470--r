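# Cross-species comparison of descriptor tables by principal components.

#' Principal component analysis of a descriptor table
#'
#' Standardizes the panel variables column-wise (z-scores; correlation-matrix
#' PCA) by default — the panel mixes Angstrom, degrees and unitless scores —
#' and decomposes them into orthonormal components. Constant variables are
#' dropped with a warning when standardizing. A deterministic sign convention
#' is applied: the largest-magnitude entry of each loading column is
#' positive, so loadings plots are reproducible run to run.
#'
#' @param table data.frame of descriptor records: a `model_label` column
#'   (optional) plus numeric variable columns, >= 3 rows.
#' @param standardize logical, default TRUE (correlation PCA); FALSE uses
#'   the covariance matrix.
#' @param n_components number of components to retain, default 2.
#' @return list of class `hinge_pca` with `scores` (models x components),
#'   `loadings` (variables x components, orthonormal columns),
#'   `explained_variance_ratio`, `variable_names`, `model_labels`,
#'   `dropped_variables`.
#' @export
run_pca <- function(table, standardize = TRUE, n_components = 2L) {
  table <- as.data.frame(table)
  labels <- if ("model_label" %in% names(table)) as.character(table$model_label)
            else paste0("model_", seq_len(nrow(table)))
  num <- table[, setdiff(names(table), "model_label"), drop = FALSE]
  num <- num[, vapply(num, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) < 3L) stop("PCA needs at least 3 model rows")
  sds <- vapply(num, stats::sd, numeric(1))
  dropped <- character(0)
  if (standardize && any(sds == 0)) {
    dropped <- names(num)[sds == 0]
    warning("dropping constant variable(s) before standardization: ",
            paste(dropped, collapse = ", "))
    num <- num[, sds > 0, drop = FALSE]
  }
  if (ncol(num) < 2L) stop("PCA needs at least 2 non-constant variables")
  pr <- stats::prcomp(as.matrix(num), center = TRUE, scale. = standardize)
  k <- min(n_components, ncol(pr$rotation))
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  # sign convention: largest |entry| of each loading column positive
  for (j in seq_len(k)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  rownames(scores) <- labels
  structure(list(scores = scores,
                 loadings = load,
                 explained_variance_ratio = evr[seq_len(k)],
                 variable_names = colnames(num),
                 model_labels = labels,
                 dropped_variables = dropped,
                 center = pr$center,
                 scale = if (standardize) pr$scale else NULL),
            class = "hinge_pca")
}

#' @export
print.hinge_pca <- function(x, ...) {
  cat("PCA of", length(x$model_labels), "models x",
      length(x$variable_names), "variables\n")
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}
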