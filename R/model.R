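# Classifier training, binary-classification metrics, stratified k-fold
# cross-validation and the benchmark driver.

CLASSIFIER_FAMILIES <- c("random_forest", "svm", "gradient_boosting",
                         "decision_tree", "logistic_regression")

#' Classifier specification
#'
#' Family plus hyperparameters plus seed. Engines: random forest via
#' \pkg{ranger} (500 trees, sqrt(p) candidate features per split,
#' unrestricted depth), SVM via \pkg{e1071} (RBF kernel, probability
#' model), gradient boosting via \pkg{xgboost} (100 rounds, learning rate
#' 0.1), decision tree via \pkg{rpart}, and L2-regularized logistic
#' regression via \pkg{glmnet} (ridge, lambda = 1/n). Every fit is
#' deterministic given (spec, data, seed).
#'
#' @param family one of `r paste(CLASSIFIER_FAMILIES, collapse = ", ")`.
#' @param seed integer seed recorded in every report.
#' @param params named list overriding engine defaults (e.g.
#'   `num_trees`, `nrounds`, `eta`, `cost`, `lambda`).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = CLASSIFIER_FAMILIES, seed = 1L,
                            params = list()) {
  family <- match.arg(family)
  structure(list(family = family, seed = as.integer(seed), params = params),
            class = "classifier_spec")
}

#' Train a binary classifier
#'
#' Fits the engine named by the spec on a numeric feature matrix and 0/1
#' labels. The fitted handle predicts a continuous score in [0, 1]
#' (probability of the positive class) and a binary call at threshold 0.5
#' via [predict_scores()] / [compute_metrics()].
#'
#' @param spec a [classifier_spec()].
#' @param x numeric feature matrix with column names, rows = samples.
#' @param y binary labels (0/1), one per row of x.
#' @return A `bitter_model` handle.
#' @export
train_classifier <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(x))
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("labels must match rows of x")
  if (length(unique(y)) < 2)
    stop("training data must contain both classes")
  p <- spec$params
  yf <- factor(y, levels = c(0L, 1L))
  fit <- switch(spec$family,
    random_forest = ranger::ranger(
      x = x, y = yf, probability = TRUE,
      num.trees = p$num_trees %||% 500,
      min.node.size = p$min_node_size %||% 1,
      num.threads = 1, seed = spec$seed),
    svm = with_seed(spec$seed,
      e1071::svm(x = x, y = yf, probability = TRUE, scale = FALSE,
                 kernel = p$kernel %||% "radial", cost = p$cost %||% 1)),
    gradient_boosting = with_seed(spec$seed,
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = p$eta %||% 0.1,
                      max_depth = p$max_depth %||% 6,
                      nthread = 1, seed = spec$seed),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = p$nrounds %||% 100, verbose = 0)),
    decision_tree = {
      d <- as.data.frame(x)
      names(d) <- paste0("F", seq_len(ncol(x)))
      d$.y <- yf
      with_seed(spec$seed, rpart::rpart(.y ~ ., data = d, method = "class"))
    },
    logistic_regression = glmnet::glmnet(
      x, yf, family = "binomial", alpha = 0,
      lambda = p$lambda %||% 1 / nrow(x)))
  structure(list(spec = spec, fit = fit, feature_names = colnames(x)),
            class = "bitter_model")
}

#' Predict positive-class scores
#'
#' @param model a [train_classifier()] handle.
#' @param x feature matrix whose columns include the training columns.
#' @return Numeric scores in [0, 1], one per row.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "bitter_model"), is.matrix(x))
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing))
    stop("prediction matrix lacks column(s) ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  fam <- model$spec$family
  if (fam == "random_forest") {
    pr <- predict(model$fit, data = x, num.threads = 1)$predictions
    unname(pr[, "1"])
  } else if (fam == "svm") {
    pr <- predict(model$fit, newdata = x, probability = TRUE)
    unname(attr(pr, "probabilities")[, "1"])
  } else if (fam == "gradient_boosting") {
    unname(predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  } else if (fam == "decision_tree") {
    d <- as.data.frame(x)
    names(d) <- paste0("F", seq_len(ncol(x)))
    unname(predict(model$fit, newdata = d, type = "prob")[, "1"])
  } else {
    unname(predict(model$fit, newx = x, type = "response")[, 1])
  }
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive is scored above a
#' randomly chosen negative, with ties counted one half — computed from
#' midranks (Mann-Whitney form), hence invariant under strictly monotone
#' score transforms.
#'
#' @param truth binary 0/1 labels, both classes present.
#' @param scores numeric scores.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(truth, scores) {
  truth <- as.integer(truth)
  stopifnot(length(truth) == length(scores))
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary-classification metrics
#'
#' Thresholds the scores (call positive when `score >= threshold`),
#' tabulates the confusion matrix over the positive (bitter) and negative
#' classes, and reports sensitivity `Sn = TP/(TP+FN)`, specificity
#' `Sp = TN/(TN+FP)`, accuracy `ACC = (TP+TN)/n`, Matthews correlation
#' `MCC = (TP*TN - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` and
#' [auroc()]. A degenerate MCC denominator (a zero row or column of the
#' confusion matrix) yields MCC = 0 with `mcc_degenerate = TRUE`.
#'
#' @param truth binary 0/1 labels.
#' @param scores numeric scores in the same order.
#' @param threshold decision threshold, default 0.5.
#' @return An `evaluation_report` list with the confusion counts and
#'   metrics.
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- as.integer(truth)
  stopifnot(length(truth) == length(scores), all(truth %in% 0:1))
  call <- as.integer(scores >= threshold)
  TP <- sum(call == 1L & truth == 1L)
  FP <- sum(call == 1L & truth == 0L)
  TN <- sum(call == 0L & truth == 0L)
  FN <- sum(call == 0L & truth == 1L)
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  degenerate <- denom == 0
  mcc <- if (degenerate) 0 else (TP * TN - FN * FP) / denom
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN,
    Sn = TP / (TP + FN), Sp = TN / (TN + FP),
    ACC = (TP + TN) / length(truth),
    MCC = mcc, mcc_degenerate = degenerate,
    AUROC = auroc(truth, scores),
    threshold = threshold, n = length(truth)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report (n = %d): Sn %.3f  Sp %.3f  ACC %.3f  MCC %.3f  AUROC %.3f\n",
    x$n, x$Sn, x$Sp, x$ACC, x$MCC, x$AUROC))
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# stratified fold assignment: within each class, shuffle then deal round-robin
make_stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Seeded stratified folds (per-class fold sizes differ by at most one);
#' each fold is held out once, a model is trained on the remainder and
#' scored on the fold. The primary aggregate report is computed on the
#' pooled out-of-fold scores; per-fold reports and their metric means are
#' also returned.
#'
#' @param spec a [classifier_spec()].
#' @param x feature matrix.
#' @param y binary 0/1 labels; each class needs at least `k` members.
#' @param k number of folds, default 10.
#' @param seed fold/shuffle seed (defaults to the spec seed).
#' @return List with `pooled` (an `evaluation_report` on pooled
#'   out-of-fold predictions), `folds` (per-fold reports), `fold_mean`
#'   (named means of Sn/Sp/ACC/MCC/AUROC across folds), `fold_id` and
#'   `scores` (out-of-fold scores in input order).
#' @export
cross_validate <- function(spec, x, y, k = 10, seed = spec$seed) {
  y <- as.integer(y)
  if (k < 2) stop("k must be at least 2")
  counts <- table(factor(y, levels = 0:1))
  if (any(counts < k))
    stop("each class needs at least k = ", k, " members")
  fold <- make_stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold == f
    model <- train_classifier(spec, x[!test, , drop = FALSE], y[!test])
    scores[test] <- predict_scores(model, x[test, , drop = FALSE])
    reports[[f]] <- compute_metrics(y[test], scores[test])
  }
  metric_names <- c("Sn", "Sp", "ACC", "MCC", "AUROC")
  fold_mean <- vapply(metric_names, function(m)
    mean(vapply(reports, `[[`, numeric(1), m)), numeric(1))
  list(pooled = compute_metrics(y, scores), folds = reports,
       fold_mean = fold_mean, fold_id = fold, scores = scores)
}

#' Train on one split and evaluate on the other
#'
#' @param spec a [classifier_spec()].
#' @param x_train,y_train training matrix and labels.
#' @param x_test,y_test evaluation matrix and labels.
#' @return An `evaluation_report` on the evaluation set.
#' @export
evaluate_split <- function(spec, x_train, y_train, x_test, y_test) {
  model <- train_classifier(spec, x_train, y_train)
  compute_metrics(as.integer(y_test), predict_scores(model, x_test))
}

report_row <- function(feature, dim, classifier, mode, r) {
  data.frame(feature = feature, dimension = dim, classifier = classifier,
             mode = mode, AUROC = r$AUROC, Sn = r$Sn, Sp = r$Sp,
             ACC = r$ACC, MCC = r$MCC, stringsAsFactors = FALSE)
}

#' Full benchmark: single features, fusion and classifier comparison
#'
#' Runs the whole study design on a labeled peptide set: an 8:2
#' stratified split, per-encoder random-forest models (cross-validation
#' and independent-set rows for each of the ten descriptor families), the
#' fused representation after zero-column removal, and a classifier
#' comparison on the fused features.
#'
#' @param x a labeled [peptide_set()].
#' @param cfg an [encoder_config()].
#' @param specs list of [classifier_spec()]s evaluated on the fused
#'   features; the first is also used for the per-feature rows.
#' @param seed master seed driving the split and the folds.
#' @param train_fraction training proportion of the stratified split.
#' @param k cross-validation folds.
#' @param zero_filter fit the zero-column filter on the training
#'   partition only (default, no leakage) or on the full dataset.
#' @return List with `report` (a data frame, one row per
#'   feature/classifier/mode), `schema` (the fitted [fit_zero_filter()]
#'   schema) and `split` (the [stratified_split()] partitions).
#' @export
run_benchmark <- function(x, cfg = encoder_config(),
                          specs = list(classifier_spec("random_forest")),
                          seed = 1, train_fraction = 0.8, k = 10,
                          zero_filter = c("train", "all")) {
  zero_filter <- match.arg(zero_filter)
  split <- stratified_split(x, train_fraction, seed)
  m_train <- fuse(split$train, cfg)
  m_test <- fuse(split$test, cfg)
  y_train <- unname(fusion_labels(m_train))
  y_test <- unname(fusion_labels(m_test))
  schema <- if (zero_filter == "train") fit_zero_filter(m_train, "train")
            else fit_zero_filter(rbind(m_train, m_test), "all")
  f_train <- apply_schema(m_train, schema)
  f_test <- apply_schema(m_test, schema)

  rows <- list()
  enc_prefix <- paste0("^", ENCODER_ORDER, "\\.")
  for (e in seq_along(ENCODER_ORDER)) {
    cols <- grep(enc_prefix[e], colnames(m_train))
    xe_train <- m_train[, cols, drop = FALSE]
    xe_test <- m_test[, cols, drop = FALSE]
    cv <- cross_validate(specs[[1]], xe_train, y_train, k, seed)
    ind <- evaluate_split(specs[[1]], xe_train, y_train, xe_test, y_test)
    rows[[length(rows) + 1]] <- report_row(
      ENCODER_ORDER[e], length(cols), specs[[1]]$family, "cv", cv$pooled)
    rows[[length(rows) + 1]] <- report_row(
      ENCODER_ORDER[e], length(cols), specs[[1]]$family, "independent", ind)
  }
  for (spec in specs) {
    cv <- cross_validate(spec, f_train, y_train, k, seed)
    ind <- evaluate_split(spec, f_train, y_train, f_test, y_test)
    rows[[length(rows) + 1]] <- report_row(
      "Fusion", ncol(f_train), spec$family, "cv", cv$pooled)
    rows[[length(rows) + 1]] <- report_row(
      "Fusion", ncol(f_train), spec$family, "independent", ind)
  }
  list(report = do.call(rbind, rows), schema = schema, split = split,
       seed = seed)
}

#' Train a full prediction pipeline
#'
#' Encodes a labeled peptide set, fits the zero-column filter, and trains
#' a classifier on the filtered fused features. The returned pipeline
#' embeds the schema and encoder parameters so prediction-time encoding
#' is column-consistent.
#'
#' @param x a labeled [peptide_set()].
#' @param cfg an [encoder_config()].
#' @param spec a [classifier_spec()].
#' @return A `bitter_pipeline`.
#' @export
train_pipeline <- function(x, cfg = encoder_config(),
                           spec = classifier_spec("random_forest")) {
  m <- fuse(x, cfg)
  schema <- fit_zero_filter(m, "train")
  fm <- apply_schema(m, schema)
  model <- train_classifier(spec, fm, unname(fusion_labels(m)))
  structure(list(cfg = cfg, schema = schema, model = model),
            class = "bitter_pipeline")
}

#' Predict bitterness for new peptides
#'
#' @param object a [train_pipeline()] result.
#' @param newdata a [peptide_set()].
#' @param threshold decision threshold.
#' @param ... unused.
#' @return Data frame with `id`, `score` and binary `call`.
#' @export
predict.bitter_pipeline <- function(object, newdata, threshold = 0.5, ...) {
  m <- apply_schema(fuse(newdata, object$cfg), object$schema)
  score <- predict_scores(object$model, m)
  data.frame(id = newdata$id, score = score,
             call = as.integer(score >= threshold),
             stringsAsFactors = FALSE)
}
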