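#' Ternary discretization of expression by the mean +/- sd rule
#'
#' Per gene, with cohort mean `mu` and sample standard deviation `s`:
#' values strictly above `mu + s` become 1, strictly below `mu - s`
#' become -1, everything else (boundaries included) becomes 0. `mu` and
#' `s` are computed within the given cohort, so discovery and validation
#' cohorts must be discretized separately to absorb platform offsets.
#' Zero-variance genes discretize to all zeros with a warning.
#'
#' @param m Gene-by-sample numeric matrix (>= 2 samples).
#' @return An integer matrix of the same shape with values in
#'   \{-1, 0, 1\}.
#' @export
discretize <- function(m) {
  assert_expression_matrix(m)
  if (ncol(m) < 2L) stop("discretization needs >= 2 samples", call. = FALSE)
  mu <- rowMeans(m)
  s <- row_sds(m)
  if (any(s == 0)) {
    warning(sprintf("%d zero-variance genes discretized to all zeros",
                    sum(s == 0)), call. = FALSE)
  }
  out <- matrix(0L, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  out[m > mu + s] <- 1L
  out[m < mu - s] <- -1L
  out
}

#' Train a decision tree on discretized biomarker expression
#'
#' Fits a seeded classification tree (Gini impurity, no depth limit,
#' minimum leaf size 1, no pruning) on samples-as-rows ternary features.
#'
#' @param x Ternary gene-by-sample matrix from [discretize()] (features
#'   are the genes).
#' @param labels Character/factor vector of class labels, one per
#'   sample.
#' @param seed Integer seed (the fit is deterministic; the seed fixes
#'   any surrogate tie-breaking).
#' @param minsplit,minbucket,cp [rpart::rpart.control] settings; the
#'   defaults grow the tree fully.
#' @return An [rpart::rpart] model whose features are named by gene.
#' @export
train_tree <- function(x, labels, seed = 1L, minsplit = 2L, minbucket = 1L,
                       cp = 0) {
  if (length(labels) != ncol(x)) {
    stop("one label per sample required", call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  df <- as.data.frame(t(x))
  df$.label <- labels
  set.seed(seed)
  rpart::rpart(.label ~ ., data = df, method = "class",
               control = rpart::rpart.control(minsplit = minsplit,
                                              minbucket = minbucket,
                                              cp = cp, xval = 0L))
}

#' Predict class labels from a trained tree
#'
#' @param model An [rpart::rpart] model from [train_tree()].
#' @param x Ternary gene-by-sample matrix with the training features.
#' @return Character vector of predicted labels, one per sample.
#' @export
predict_tree <- function(model, x) {
  df <- as.data.frame(t(x))
  as.character(stats::predict(model, newdata = df, type = "class"))
}

#' Per-class precision/recall/F1 classification report
#'
#' Computes, for each class label, precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, their harmonic mean F1, and support (true count),
#' plus macro and support-weighted averages and overall accuracy.
#' Classes absent from the predictions get precision 0 by convention.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param labels Optional explicit class ordering (defaults to the
#'   sorted union of observed labels).
#' @return A list of class `classification_report` with `per_class` (a
#'   data frame `label`, `precision`, `recall`, `f1`, `support`),
#'   `macro_avg`, `weighted_avg` (each precision/recall/f1), and
#'   `accuracy`.
#' @export
classification_report <- function(true_labels, predicted_labels,
                                  labels = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  labels <- labels %||% sort(unique(c(true_labels, predicted_labels)))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), labels)
  if (length(bad) > 0L) {
    stop("labels outside the declared set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  per <- lapply(labels, function(lb) {
    tp <- sum(true_labels == lb & predicted_labels == lb)
    fp <- sum(true_labels != lb & predicted_labels == lb)
    fn <- sum(true_labels == lb & predicted_labels != lb)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(label = lb, precision = precision, recall = recall, f1 = f1,
               support = tp + fn, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  avg <- function(weights) {
    c(precision = sum(per$precision * weights),
      recall = sum(per$recall * weights),
      f1 = sum(per$f1 * weights))
  }
  structure(list(
    per_class = per,
    macro_avg = avg(rep(1 / nrow(per), nrow(per))),
    weighted_avg = avg(w),
    accuracy = mean(true_labels == predicted_labels)),
    class = "classification_report")
}

#' Balanced accuracy (mean per-class recall)
#' @param report A [classification_report()].
#' @return Mean of the per-class recalls.
#' @export
balanced_accuracy <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  mean(report$per_class$recall)
}

#' @export
print.classification_report <- function(x, ...) {
  df <- x$per_class
  df[, c("precision", "recall", "f1")] <-
    round(df[, c("precision", "recall", "f1")], 2)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy: %.2f  macro-F1: %.2f  weighted-F1: %.2f\n",
              x$accuracy, x$macro_avg[["f1"]], x$weighted_avg[["f1"]]))
  invisible(x)
}

#' Train on a discovery cohort and evaluate on a validation cohort
#'
#' Restricts both cohorts to the biomarker features, discretizes each
#' cohort independently by its own mean +/- sd rule, trains the decision
#' tree on the discovery cohort and reports validation performance.
#' Response labels are mapped NOCR -> `recurrence` (resistant patients
#' relapse) and CR -> `non-recurrence`.
#'
#' @param biomarkers Character vector of feature gene ids.
#' @param train_expr,train_annotation Discovery expression matrix and
#'   annotation.
#' @param test_expr,test_annotation Validation expression matrix and
#'   annotation.
#' @param seed Integer seed passed to [train_tree()].
#' @return A list with `model`, `report` (a [classification_report()]
#'   on the validation cohort), `predictions` and `features`.
#' @export
validate_biomarkers <- function(biomarkers, train_expr, train_annotation,
                                test_expr, test_annotation, seed = 1L) {
  features <- intersect(biomarkers,
                        intersect(rownames(train_expr), rownames(test_expr)))
  if (length(features) == 0L) {
    stop("no biomarker features shared by both cohorts", call. = FALSE)
  }
  to_label <- function(response) {
    ifelse(response == "NOCR", "recurrence", "non-recurrence")
  }
  tr_ann <- match_annotation(colnames(train_expr), train_annotation)
  te_ann <- match_annotation(colnames(test_expr), test_annotation)
  x_tr <- discretize(train_expr[features, , drop = FALSE])
  x_te <- discretize(test_expr[features, , drop = FALSE])
  model <- train_tree(x_tr, to_label(tr_ann$response), seed = seed)
  pred <- predict_tree(model, x_te)
  report <- classification_report(to_label(te_ann$response), pred,
                                  labels = c("non-recurrence", "recurrence"))
  list(model = model, report = report, predictions = pred,
       features = features)
}
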