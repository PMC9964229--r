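# Verification statistics: Pearson correlation with qualitative banding,
# correlation-matrix PCA, and agglomerative hierarchical clustering with a
# heatmap export. These cross-check the network's sensitivity rankings.

#' Qualitative band for a correlation coefficient
#'
#' |r| < 0.1 negligible; \[0.1, 0.4) low; \[0.4, 0.7) medium; >= 0.7 high,
#' with the sign prepended for non-negligible bands. Thresholds follow the
#' common applied-statistics convention and are configurable.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\] (NA allowed).
#' @param thresholds Increasing cutpoints `c(negligible, low, medium)`,
#'   default `c(0.1, 0.4, 0.7)`.
#' @return Character vector of band labels.
#' @examples
#' band_correlation(-0.55)  # "medium negative"
#' @export
band_correlation <- function(r, thresholds = c(0.1, 0.4, 0.7)) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("|r| must not exceed 1", call. = FALSE)
  }
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0))
  vapply(r, function(x) {
    if (is.na(x)) return(NA_character_)
    a <- abs(x)
    if (a < thresholds[1]) return("negligible")
    mag <- if (a < thresholds[2]) "low" else if (a < thresholds[3])
      "medium" else "high"
    paste(mag, if (x >= 0) "positive" else "negative")
  }, character(1))
}

#' Pearson correlation matrix with p-values and bands
#'
#' Column-wise Pearson r between `X` and `Y` (or within `X`), two-sided
#' p-values from the t transform with n - 2 degrees of freedom, and
#' qualitative band labels. Constant columns give NA entries with an
#' `undefined` flag rather than an error. No multiple-testing correction is
#' applied; p-values are raw.
#'
#' @param X data.frame/matrix of numeric variables (rows = samples, >= 3).
#' @param Y Optional second table with the same row count; default `X`.
#' @param thresholds Passed to [band_correlation()].
#' @return Object of class `correlation_report`: list with matrices `r`,
#'   `p`, `band`, `undefined`, plus `n` and `thresholds`.
#' @export
pearson_matrix <- function(X, Y = X, thresholds = c(0.1, 0.4, 0.7)) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same row count",
                               call. = FALSE)
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 rows", call. = FALSE)
  constX <- apply(X, 2L, function(v) stats::sd(v) == 0)
  constY <- apply(Y, 2L, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(X, Y))
  undefined <- outer(constX, constY, "|")
  r[undefined] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  band <- matrix(band_correlation(as.numeric(r), thresholds), nrow(r),
                 ncol(r), dimnames = dimnames(r))
  structure(list(r = r, p = p, band = band, undefined = undefined,
                 n = n, thresholds = thresholds),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pearson correlation report (n = %d, bands at %s)\n", x$n,
              paste(x$thresholds, collapse = "/")))
  print(round(x$r, 3))
  invisible(x)
}

#' Tidy a correlation report into a long table
#' @param report A `correlation_report`.
#' @return data.frame with columns `var_x`, `var_y`, `r`, `p`, `band`.
#' @export
correlation_table <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  g <- expand.grid(var_x = rownames(report$r), var_y = colnames(report$r),
                   stringsAsFactors = FALSE)
  data.frame(g, r = as.numeric(report$r), p = as.numeric(report$p),
             band = as.character(report$band), stringsAsFactors = FALSE)
}

#' PCA on the correlation matrix
#'
#' Z-scores the variables, eigendecomposes their correlation matrix, and
#' fixes each loading vector's sign so its largest-magnitude entry is
#' positive (a platform-stable convention). Scores are the z-scored data
#' projected on the loadings.
#'
#' @param X Samples x variables (>= 3 samples, non-constant columns).
#' @return Object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (variables x components, orthonormal columns),
#'   `explained` (variance fractions summing to 1), `sdev`.
#' @export
pca_scores <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need >= 3 samples", call. = FALSE)
  if (any(apply(X, 2L, stats::sd) == 0)) {
    stop("constant column(s); correlation PCA undefined", call. = FALSE)
  }
  Z <- scale(X)
  eg <- eigen(stats::cor(X), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(ncol(load))))
  scores <- Z %*% load
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = load,
                 explained = ev / sum(ev), sdev = sqrt(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("correlation PCA:", ncol(x$loadings), "components\n")
  cat("explained:", paste0(round(100 * x$explained, 1), "%",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Agglomerative hierarchical clustering with heatmap export
#'
#' Clusters the items (rows) of `X` on z-scored features, by default with
#' Euclidean distance and average linkage (Ward available via
#' `linkage = "ward"`). The heatmap export is the z-scored matrix plus the
#' leaf orders of rows and of columns (columns clustered on the transposed
#' z-matrix).
#'
#' @param X Items x features (>= 2 items).
#' @param linkage `"average"` (default), `"ward"`, `"complete"` or
#'   `"single"`.
#' @param metric `"euclidean"` (default) or any [stats::dist()] method.
#' @param zscore Z-score columns before clustering (default `TRUE`).
#' @return Object of class `hca_result`: `merge`, `height`, `order`,
#'   `labels`, `linkage`, `metric`, `hclust` (the underlying object),
#'   `heatmap` (list with `matrix`, `row_order`, `col_order`).
#' @export
hca <- function(X, linkage = "average", metric = "euclidean",
                zscore = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 items", call. = FALSE)
  methods <- c(average = "average", ward = "ward.D2",
               complete = "complete", single = "single")
  if (!linkage %in% names(methods)) {
    stop("unknown linkage: ", linkage, call. = FALSE)
  }
  ok_metric <- c("euclidean", "maximum", "manhattan", "canberra", "binary",
                 "minkowski")
  if (!metric %in% ok_metric) stop("unknown metric: ", metric,
                                   call. = FALSE)
  Z <- if (zscore) {
    apply(X, 2L, function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
  } else X
  rownames(Z) <- rownames(X)
  hc <- stats::hclust(stats::dist(Z, method = metric),
                      method = methods[[linkage]])
  col_order <- if (ncol(Z) >= 2L) {
    stats::hclust(stats::dist(t(Z), method = metric),
                  method = methods[[linkage]])$order
  } else seq_len(ncol(Z))
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, linkage = linkage, metric = metric,
                 hclust = hc,
                 heatmap = list(matrix = Z, row_order = hc$order,
                                col_order = col_order)),
            class = "hca_result")
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("hierarchical clustering: %d items, %s linkage, %s distance\n",
              length(x$order), x$linkage, x$metric))
  invisible(x)
}
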