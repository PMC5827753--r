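make_folds <- function(y, cv = c("loocv", "kfold"), k = 10, seed = 1,
                       max_refold = 20) {
  cv <- match.arg(cv)
  n <- length(y)
  if (cv == "loocv") return(seq_len(n))
  if (k > n) abort("more folds than samples")
  for (try in 0:max_refold) {
    set.seed(seed + try)
    fold <- integer(n)
    for (cl in levels(y)) {            # stratified: round-robin within class
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      nlevels(droplevels(y[fold != f])) == 2
    }, logical(1)))
    if (ok) {
      if (try > 0) message("refolded ", try, " time(s) to keep both classes ",
                           "in every training split")
      return(fold)
    }
  }
  abort("could not build folds with both classes in every training split")
}

fit_predict_fold <- function(x, y, train, test, cost) {
  mu <- colMeans(x[train, , drop = FALSE])
  sg <- apply(x[train, , drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1                     # constant-in-fold column: center only
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  fit <- e1071::svm(xs[train, , drop = FALSE], y[train],
                    kernel = "linear", cost = cost, scale = FALSE)
  stats::predict(fit, xs[test, , drop = FALSE])
}

svm_cv_predict <- function(x, y, fold, cost) {
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in unique(fold)) {
    test <- which(fold == f)
    pred[test] <- fit_predict_fold(x, y, which(fold != f), test, cost)
  }
  pred
}

classification_scores <- function(truth, pred, positive) {
  acc <- 100 * mean(pred == truth)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 200 * prec * rec / (prec + rec) else 0
  list(accuracy = acc, f_score = f1)
}

#' Cross-validated linear SVM trust classification
#'
#' Fits a linear support-vector machine (cost C = 1 by default) on a
#' chosen feature subset and evaluates it by leave-one-out or stratified
#' 10-fold cross-validation. Features are z-scored inside each training
#' fold only, so no information from held-out samples leaks into the
#' scaling. Under LOOCV each held-out sample is the feature vector of one
#' full recording, so the result is deterministic given the data; k-fold
#' results depend on the fold seed.
#'
#' @param data data frame with feature columns and a label column.
#' @param features character vector of feature columns to use.
#' @param label_col name of the two-class label column (default `"label"`).
#' @param cv `"loocv"` or `"kfold"`.
#' @param k number of folds for `cv = "kfold"` (default 10, stratified by
#'   label; refolded with a new seed if a training split loses a class).
#' @param cost SVM regularization parameter C (default 1).
#' @param seed fold-assignment seed (k-fold only).
#' @param positive label treated as the positive class for the F-score
#'   (default `"trustworthy"` when present, else the second factor level).
#' @return object of class `trust_svm_eval`: list with `accuracy` and
#'   `f_score` (both percentages), `predictions` (tibble: `index`,
#'   `truth`, `pred`, `fold`), `cv_scheme`, `features`.
#' @examples
#' d <- sim_feature_dataset(uva_group_spec(), seed = 1)
#' ev <- evaluate_svm(d, features = c("gamma:F", "gamma:F-Pa", "gamma:F-C"),
#'                    cv = "loocv")
#' glance(ev)
#' @export
evaluate_svm <- function(data, features, label_col = "label",
                         cv = c("loocv", "kfold"), k = 10, cost = 1,
                         seed = 1, positive = NULL) {
  cv <- match.arg(cv)
  if (length(features) == 0) abort("`features` must be non-empty")
  missing <- setdiff(features, names(data))
  if (length(missing)) abort(paste0("feature column(s) not found: ",
                                    paste(missing, collapse = ", ")))
  y <- droplevels(as.factor(data[[label_col]]))
  if (nlevels(y) != 2) abort("labels must contain exactly 2 classes")
  if (is.null(positive)) {
    positive <- if ("trustworthy" %in% levels(y)) "trustworthy" else
      levels(y)[2]
  }
  x <- as.matrix(data[features])
  if (anyNA(x)) abort("missing values in active feature columns")
  fold <- make_folds(y, cv, k = k, seed = seed)
  pred <- svm_cv_predict(x, y, fold, cost)
  sc <- classification_scores(y, pred, positive)
  structure(
    list(accuracy = sc$accuracy, f_score = sc$f_score,
         predictions = tibble(index = seq_along(y), truth = y, pred = pred,
                              fold = fold),
         cv_scheme = if (cv == "loocv") "LOOCV" else paste0(k, "-fold"),
         features = features, positive = positive, cost = cost),
    class = "trust_svm_eval"
  )
}

#' @export
print.trust_svm_eval <- function(x, ...) {
  cat(sprintf("<trust_svm_eval> %s, %d features: accuracy %.2f%%, F-score %.2f%%\n",
              x$cv_scheme, length(x$features), x$accuracy, x$f_score))
  invisible(x)
}

#' @rdname evaluate_svm
#' @param x a `trust_svm_eval` object.
#' @param ... unused.
#' @export
tidy.trust_svm_eval <- function(x, ...) x$predictions

#' @rdname evaluate_svm
#' @export
glance.trust_svm_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, f_score = x$f_score,
         cv_scheme = x$cv_scheme, n_features = length(x$features),
         n = nrow(x$predictions))
}

#' Sweep the number of selected features against CV accuracy
#'
#' For each dimension d from 2 to `max_dim`, selects the top-d features by
#' kernel-target alignment and scores a cross-validated linear SVM on
#' them. The optimum dimension is the smallest d attaining the maximum
#' accuracy over the sweep (the minimal set of highest-ranking features
#' with maximal accuracy). Feature ranking can run once on the full table
#' (`selection = "outside"`, the default, matching a reporting-oriented
#' sweep) or inside every training fold (`selection = "inside"`, which
#' removes selection bias at higher cost); the mode is recorded in the
#' result.
#'
#' @inheritParams evaluate_svm
#' @param features candidate feature columns; default: all complete
#'   numeric columns except the label.
#' @param max_dim largest dimension tried (default 15, capped at the
#'   number of candidates).
#' @param selection `"outside"` or `"inside"` (see Details).
#' @param seed seed for KTA initialization and fold assignment.
#' @return object of class `kta_sweep`: list with `curve` (tibble `dim`,
#'   `accuracy`), `optimum` (smallest best d), `ranking` (full-data
#'   [kta_rank_features()] ranking tibble), `cv_scheme`, `selection`.
#' @export
sweep_dimension <- function(data, label_col = "label", features = NULL,
                            cv = c("loocv", "kfold"), k = 10,
                            max_dim = 15, cost = 1, seed = 1,
                            selection = c("outside", "inside")) {
  cv <- match.arg(cv)
  selection <- match.arg(selection)
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(features, label_col)
    features <- features[colSums(is.na(data[features])) == 0]
  }
  max_dim <- min(max_dim, length(features))
  if (max_dim < 2) abort("need at least 2 candidate features")
  y <- droplevels(as.factor(data[[label_col]]))
  x <- as.matrix(data[features])
  fold <- make_folds(y, cv, k = k, seed = seed)
  full_rank <- kta_rank_features(data, label_col = label_col,
                                 features = features,
                                 n_select = max_dim, seed = seed)
  fold_ranks <- if (selection == "inside") {
    lapply(unique(fold), function(f) {
      kta_rank_features(data[fold != f, , drop = FALSE],
                        label_col = label_col, features = features,
                        n_select = max_dim, seed = seed)$ranking$feature
    })
  }
  positive <- if ("trustworthy" %in% levels(y)) "trustworthy" else
    levels(y)[2]
  dims <- 2:max_dim
  acc <- vapply(dims, function(d) {
    pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
    for (fi in seq_along(unique(fold))) {
      f <- unique(fold)[fi]
      feats <- if (selection == "outside") {
        head(full_rank$ranking$feature, d)
      } else {
        head(fold_ranks[[fi]], d)
      }
      test <- which(fold == f)
      pred[test] <- fit_predict_fold(x[, feats, drop = FALSE], y,
                                     which(fold != f), test, cost)
    }
    100 * mean(pred == y)
  }, numeric(1))
  curve <- tibble(dim = dims, accuracy = acc)
  structure(
    list(curve = curve,
         optimum = dims[which(acc == max(acc))[1]],
         max_accuracy = max(acc),
         ranking = full_rank$ranking,
         cv_scheme = if (cv == "loocv") "LOOCV" else paste0(k, "-fold"),
         selection = selection),
    class = "kta_sweep"
  )
}

#' @export
print.kta_sweep <- function(x, ...) {
  cat(sprintf("<kta_sweep> %s, selection %s: optimum %d features at %.2f%%\n",
              x$cv_scheme, x$selection, x$optimum, x$max_accuracy))
  invisible(x)
}

#' @rdname sweep_dimension
#' @param x a `kta_sweep` object.
#' @param ... unused.
#' @export
tidy.kta_sweep <- function(x, ...) x$curve

#' @rdname sweep_dimension
#' @export
glance.kta_sweep <- function(x, ...) {
  tibble(optimum = x$optimum, max_accuracy = x$max_accuracy,
         cv_scheme = x$cv_scheme, selection = x$selection)
}

#' Contrast trust classification against complexity classification
#'
#' On a combined table carrying both a trust label and a task (complexity)
#' label, runs the same cross-validated linear SVM on the same fixed
#' feature subset twice — once per label set — and returns both reports.
#' When the features encode trust-related brain state but not task
#' complexity, trust accuracy is high while complexity accuracy stays
#' near chance.
#'
#' @inheritParams evaluate_svm
#' @param trust_col,task_col names of the trust and task label columns.
#' @return object of class `trust_complexity_contrast`: list with `trust`
#'   and `complexity` (both [evaluate_svm()] reports).
#' @export
complexity_vs_trust_experiment <- function(data, features,
                                           trust_col = "label",
                                           task_col = "task",
                                           cv = c("loocv", "kfold"), k = 10,
                                           cost = 1, seed = 1) {
  cv <- match.arg(cv)
  res <- list(
    trust = evaluate_svm(data, features, label_col = trust_col, cv = cv,
                         k = k, cost = cost, seed = seed),
    complexity = evaluate_svm(data, features, label_col = task_col, cv = cv,
                              k = k, cost = cost, seed = seed)
  )
  class(res) <- "trust_complexity_contrast"
  res
}

#' @export
print.trust_complexity_contrast <- function(x, ...) {
  cat(sprintf("<trust_complexity_contrast> trust %.2f%% vs complexity %.2f%%\n",
              x$trust$accuracy, x$complexity$accuracy))
  invisible(x)
}

#' @rdname complexity_vs_trust_experiment
#' @param x a `trust_complexity_contrast` object.
#' @param ... unused.
#' @export
tidy.trust_complexity_contrast <- function(x, ...) {
  bind_rows(
    dplyr::mutate(glance(x$trust), target = "trust"),
    dplyr::mutate(glance(x$complexity), target = "complexity")
  )
}
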