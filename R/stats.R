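#' Two-group Welch t-tests with Bonferroni correction
#'
#' Runs a Welch two-sample t-test per feature between the two label
#' groups, Bonferroni-corrects the p-values across the tested set, and
#' flags significance at the corrected 1e-4 (`"****"`) and 1e-3 (`"***"`)
#' tiers used when reporting group differences. Welch's form is used
#' because the groups are unequal in size and need not share a variance.
#'
#' @param data data frame with feature columns and a label column.
#' @param features feature columns to test; default: all complete numeric
#'   columns except the label.
#' @param label_col name of the two-class label column.
#' @return tibble with columns `feature`, `mean_1`, `mean_2` (group means
#'   in factor-level order), `t`, `p`, `p_adj` and `stars`.
#' @export
group_ttest <- function(data, features = NULL, label_col = "label") {
  y <- droplevels(as.factor(data[[label_col]]))
  if (nlevels(y) != 2) abort("labels must contain exactly 2 classes")
  if (min(table(y)) < 2) abort("need at least 2 samples per group")
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, label_col)
    features <- features[colSums(is.na(data[features])) == 0]
  }
  g1 <- y == levels(y)[1]
  res <- purrr::map_dfr(features, function(f) {
    a <- data[[f]][g1]; b <- data[[f]][!g1]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate: no variance anywhere; identical means are a perfect null
      tv <- if (mean(a) == mean(b)) 0 else Inf
      pv <- if (mean(a) == mean(b)) 1 else 0
    } else {
      ht <- stats::t.test(a, b)
      tv <- unname(ht$statistic); pv <- ht$p.value
    }
    tibble(feature = f, mean_1 = mean(a), mean_2 = mean(b), t = tv, p = pv)
  })
  res$p_adj <- stats::p.adjust(res$p, method = "bonferroni")
  res$stars <- ifelse(res$p_adj <= 1e-4, "****",
                      ifelse(res$p_adj <= 1e-3, "***", ""))
  res
}

#' Pearson correlations between key and probe features
#'
#' Computes Pearson's r with its two-sided p-value for every (key, probe)
#' pair and keeps the pairs significant at the 95% confidence level
#' (p < 0.05). Constant columns cannot be correlated and are skipped with
#' a message.
#'
#' @param data data frame holding all involved columns.
#' @param key_features,probe_features character vectors of column names.
#' @param alpha significance threshold (default 0.05).
#' @return tibble with columns `key`, `probe`, `r`, `p`, sorted by `key`.
#' @export
key_feature_correlations <- function(data, key_features, probe_features,
                                     alpha = 0.05) {
  out <- list()
  for (kf in key_features) {
    for (pf in probe_features) {
      if (kf == pf) next
      a <- data[[kf]]; b <- data[[pf]]
      if (is.null(a) || is.null(b)) abort("correlation column not found")
      keep <- !is.na(a) & !is.na(b)
      if (stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0) {
        message("constant column; pair skipped: ", kf, " ~ ", pf)
        next
      }
      ct <- stats::cor.test(a[keep], b[keep], method = "pearson")
      out[[paste(kf, pf)]] <- tibble(key = kf, probe = pf,
                                     r = unname(ct$estimate), p = ct$p.value)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(tibble(key = character(), probe = character(),
                                    r = numeric(), p = numeric()))
  res[res$p < alpha, ]
}

#' Project samples onto the first two principal components
#'
#' PCA on z-scored feature columns (the cognitive and functional features
#' live on incomparable scales), returning per-sample coordinates on the
#' top two variance axes for visualizing the classified groups. Rank-1
#' data gets a zero second component with a message.
#'
#' @param data data frame with the feature columns.
#' @param features character vector of >= 2 feature columns.
#' @return tibble with columns `PC1`, `PC2` and attribute
#'   `"explained_var"` (fractions of variance).
#' @export
pca_project <- function(data, features) {
  if (length(features) < 2) abort("need at least 2 features")
  x <- as.matrix(data[features])
  sds <- apply(x, 2, stats::sd)
  x <- scale(x, scale = ifelse(sds > 0, sds, 1))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  scores <- pc$x
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  if (ncol(scores) < 2 || pc$sdev[2]^2 < 1e-12 * pc$sdev[1]^2) {
    message("data are effectively rank 1; second component zeroed")
    out <- tibble(PC1 = scores[, 1], PC2 = 0)
    attr(out, "explained_var") <- c(ev[1], 0)
    return(out)
  }
  out <- tibble(PC1 = scores[, 1], PC2 = scores[, 2])
  attr(out, "explained_var") <- ev[1:2]
  out
}
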