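#' Scatter-matrix cluster-separability criterion
#'
#' `J = tr(S_W^-1 S_B)`: trace of the inverse within-cluster scatter
#' matrix times the between-cluster scatter matrix, over a hard
#' assignment. A singular within-scatter is ridge-regularized with a
#' message.
#'
#' @param x numeric sample x feature matrix.
#' @param assign cluster assignment vector (one entry per row of `x`).
#' @param ridge relative ridge used when `S_W` is singular.
#' @return the scalar criterion J (>= 0 for separable data).
#' @export
scatter_criterion <- function(x, assign, ridge = 1e-8) {
  x <- as.matrix(x)
  cls <- unique(assign)
  mu <- colMeans(x)
  p <- ncol(x)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (cl in cls) {
    xi <- x[assign == cl, , drop = FALSE]
    mi <- colMeans(xi)
    cc <- sweep(xi, 2, mi)
    sw <- sw + crossprod(cc)
    sb <- sb + nrow(xi) * tcrossprod(mi - mu)
  }
  inv <- tryCatch(solve(sw), error = function(e) {
    message("within-cluster scatter singular; ridge-regularized inverse used")
    solve(sw + diag(ridge * max(diag(sw), 1), p))
  })
  sum(diag(inv %*% sb))
}

#' Validate class separability with fuzzy C-means clustering
#'
#' Clusters the chosen feature columns with fuzzy C-means (fuzzifier
#' m = 2), hardens memberships by maximum degree, matches clusters to the
#' true labels by the best of the two possible assignments, and reports
#' the clustering accuracy together with the scatter-based separability
#' criterion `J = tr(S_W^-1 S_B)` computed from the hard assignment
#' (within- and between-cluster scatter matrices). Clustering runs on
#' z-scored columns (mixed feature scales would otherwise dominate the
#' distances) while J is evaluated on the raw feature values, so it
#' reflects the data's own scatter ratio. Large J means the
#' clusters are far apart relative to their spread; a singular `S_W` is
#' ridge-regularized with a message.
#'
#' @param data data frame with feature columns and a label column.
#' @param features character vector of feature columns.
#' @param label_col name of the two-class reference label column.
#' @param n_clusters number of clusters (default 2).
#' @param m fuzzifier (default 2).
#' @param seed seed for center initialization.
#' @param max_iter fuzzy C-means iteration cap.
#' @return object of class `cluster_report`: list with `cluster_accuracy`
#'   (%), `J`, `memberships` (sample x cluster matrix, rows sum to 1) and
#'   `assignment`.
#' @examples
#' d <- sim_feature_dataset(uva_group_spec(), seed = 1)
#' fuzzy_cmeans_validate(d, c("gamma:F", "gamma:F-Pa", "gamma:F-C"))
#' @export
fuzzy_cmeans_validate <- function(data, features, label_col = "label",
                                  n_clusters = 2, m = 2, seed = 1,
                                  max_iter = 300) {
  y <- droplevels(as.factor(data[[label_col]]))
  raw <- as.matrix(data[features])
  x <- scale(raw)
  keep <- apply(x, 2, function(v) all(is.finite(v)))
  x <- x[, keep, drop = FALSE]
  if (nrow(x) < n_clusters) abort("fewer samples than clusters")
  set.seed(seed)
  fit <- e1071::cmeans(x, centers = n_clusters, m = m,
                       iter.max = max_iter, method = "cmeans")
  hard <- apply(fit$membership, 1, which.max)
  # best label<->cluster matching over the two permutations (2 clusters)
  lv <- levels(y)
  acc1 <- mean(lv[hard] == y)
  acc2 <- mean(lv[3 - hard] == y)
  if (acc2 > acc1) hard <- 3 - hard
  structure(
    list(cluster_accuracy = 100 * max(acc1, acc2),
         J = scatter_criterion(raw[, keep, drop = FALSE], hard),
         memberships = fit$membership,
         assignment = factor(lv[hard], levels = lv)),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> accuracy %.2f%%, J = %.3f\n",
              x$cluster_accuracy, x$J))
  invisible(x)
}

#' @rdname fuzzy_cmeans_validate
#' @param x a `cluster_report` object.
#' @param ... unused.
#' @export
glance.cluster_report <- function(x, ...) {
  tibble(cluster_accuracy = x$cluster_accuracy, J = x$J,
         n = nrow(x$memberships))
}
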